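#' @name CellVideo-accessors
#' @title Accessors for CellVideo objects
#' @description Extract the object table, frame indices, frame interval,
#'   acquisition times, image size and sample metadata of a
#'   [CellVideo-class].
#' @param x,object a \code{CellVideo}.
#' @param frame integer frame index.
#' @return \code{videoObjects}: the full object data.frame;
#'   \code{getFrame}: the objects of one frame (possibly zero rows);
#'   \code{frameIndices}: integer vector; \code{frameTimes}: acquisition
#'   times in minutes (\code{frameIndices * frameInterval});
#'   \code{nFrames}: number of frames; \code{frameInterval},
#'   \code{imageSize}, \code{sampleMeta}: the corresponding slots.
NULL

#' @rdname CellVideo-accessors
#' @export
setGeneric("videoObjects", function(x) standardGeneric("videoObjects"))
#' @rdname CellVideo-accessors
#' @export
setGeneric("frameIndices", function(x) standardGeneric("frameIndices"))
#' @rdname CellVideo-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname CellVideo-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname CellVideo-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname CellVideo-accessors
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))
#' @rdname CellVideo-accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname CellVideo-accessors
#' @export
setGeneric("getFrame", function(x, frame) standardGeneric("getFrame"))

#' @rdname CellVideo-accessors
setMethod("videoObjects", "CellVideo", function(x) x@objects)
#' @rdname CellVideo-accessors
setMethod("frameIndices", "CellVideo", function(x) x@frameIndices)
#' @rdname CellVideo-accessors
setMethod("frameInterval", "CellVideo", function(x) x@frameInterval)
#' @rdname CellVideo-accessors
setMethod("frameTimes", "CellVideo",
          function(x) x@frameIndices * x@frameInterval)
#' @rdname CellVideo-accessors
setMethod("nFrames", "CellVideo", function(x) length(x@frameIndices))
#' @rdname CellVideo-accessors
setMethod("imageSize", "CellVideo", function(x) x@imageSize)
#' @rdname CellVideo-accessors
setMethod("sampleMeta", "CellVideo", function(x) x@sampleMeta)
#' @rdname CellVideo-accessors
setMethod("getFrame", "CellVideo", function(x, frame) {
  x@objects[x@objects$frame == frame, , drop = FALSE]
})

#' @rdname CellVideo-accessors
setMethod("show", "CellVideo", function(object) {
  cls <- table(factor(object@objects$class, levels = cellClasses()))
  cat("CellVideo:", object@sampleMeta$sample_id, "\n")
  cat(sprintf("  %d frame(s) at %g min interval (%g h span), image %g x %g px\n",
              length(object@frameIndices), object@frameInterval,
              max(c(0, object@frameIndices)) * object@frameInterval / 60,
              object@imageSize[1], object@imageSize[2]))
  cat(sprintf("  %d labelled object(s): %s\n", nrow(object@objects),
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
  cat(sprintf("  dose %g Gy, %s\n", object@sampleMeta$dose_gy,
              if (isTRUE(object@sampleMeta$irradiated)) "irradiated"
              else "sham"))
})

#' @describeIn GrowthFit-class fitted parameters (A, t0, tau).
#' @param object a \code{GrowthFit} or \code{LQModel}.
#' @export
setMethod("coef", "GrowthFit", function(object) object@coefficients)

#' @describeIn GrowthFit-class parameter covariance matrix.
#' @export
setMethod("vcov", "GrowthFit", function(object) object@vcov)

#' @describeIn GrowthFit-class print a fit summary.
setMethod("show", "GrowthFit", function(object) {
  p <- object@coefficients
  se <- sqrt(diag(object@vcov))
  cat("Offset-exponential growth fit (", object@channel, " cells)\n",
      sep = "")
  cat(sprintf("  A   = %.3g +/- %.2g\n", p["A"], se[1]))
  cat(sprintf("  t0  = %.3g +/- %.2g h\n", p["t0"], se[2]))
  cat(sprintf("  tau = %.3g +/- %.2g h\n", p["tau"], se[3]))
  cat(sprintf("  chi2 = %.4g, corrected R2 = %.4g, %d points\n",
              object@chi2, object@r2cor, nrow(object@data)))
})

#' @describeIn LQModel-class fitted parameters (alpha, beta).
#' @export
setMethod("coef", "LQModel", function(object) object@coefficients)

#' @describeIn LQModel-class parameter covariance matrix.
#' @export
setMethod("vcov", "LQModel", function(object) object@vcov)

#' @describeIn LQModel-class print the model.
setMethod("show", "LQModel", function(object) {
  p <- object@coefficients
  se <- sqrt(diag(object@vcov))
  cat("Linear-quadratic survival model SF(D) = exp(-(alpha*D + beta*D^2))\n")
  cat(sprintf("  alpha = %.4g +/- %.2g 1/Gy\n", p["alpha"], se[1]))
  cat(sprintf("  beta  = %.4g +/- %.2g 1/Gy^2\n", p["beta"], se[2]))
})
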