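#' Cell morphology classes
#'
#' The four morphology classes used to label cells in phase-contrast frames:
#' attached living cells (\code{liv}), detached round (mitotic) cells
#' (\code{round}), actively separating cell pairs (\code{div}) and dead cells
#' (\code{dead}). The first three together are the vital classes.
#'
#' @return Character vector of the four class labels, in canonical order.
#' @examples
#' cellClasses()
#' vitalClasses()
#' @export
cellClasses <- function() c("liv", "round", "div", "dead")

#' @rdname cellClasses
#' @export
vitalClasses <- function() c("liv", "round", "div")

.OBJECT_COLS <- c("frame", "x_min", "y_min", "x_max", "y_max",
                  "class", "confidence", "object_id")

#' CellVideo: per-frame bounding-box annotations of a live-cell video
#'
#' An S4 container for the labelled objects of a time-lapse video. Each
#' object is an axis-aligned box in 0-based, half-open pixel coordinates
#' (\code{[x_min, x_max) x [y_min, y_max)}, x right, y down) tagged with one
#' of the four morphology classes, a confidence in [0, 1] (1 for ground
#' truth) and an optional stable object id used for lineage and census
#' linking. Frames are indexed 1, 2, ... and acquired at a constant interval,
#' so frame \code{k} corresponds to time \code{k * frameInterval} minutes
#' (frame 1 is the 5-minute timepoint at the default cadence).
#'
#' @slot objects data.frame with columns \code{frame, x_min, y_min, x_max,
#'   y_max, class, confidence, object_id}; one row per labelled box.
#' @slot frameIndices integer vector of all frame indices present in the
#'   video (strictly increasing); frames with no objects are legal.
#' @slot frameInterval numeric, minutes between consecutive frames.
#' @slot imageSize numeric length-2, image width and height in pixels.
#' @slot sampleMeta list of sample metadata: \code{sample_id} (character),
#'   \code{dose_gy} (non-negative numeric), \code{irradiated} (logical).
#'
#' @seealso [cellVideo()], [readAnnotations()], [simulatePopulation()]
#' @export
setClass("CellVideo",
         representation(objects = "data.frame",
                        frameIndices = "integer",
                        frameInterval = "numeric",
                        imageSize = "numeric",
                        sampleMeta = "list"))

setValidity("CellVideo", function(object) {
  msg <- character()
  obj <- object@objects
  missing_cols <- setdiff(.OBJECT_COLS, names(obj))
  if (length(missing_cols))
    return(paste("objects is missing columns:",
                 paste(missing_cols, collapse = ", ")))
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number")
  if (length(object@imageSize) != 2L || any(object@imageSize <= 0))
    msg <- c(msg, "imageSize must be two positive numbers (width, height)")
  if (is.unsorted(object@frameIndices, strictly = TRUE))
    msg <- c(msg, "frameIndices must be strictly increasing")
  if (any(object@frameIndices < 1L))
    msg <- c(msg, "frame indices must be positive")
  if (nrow(obj)) {
    if (!all(obj$frame %in% object@frameIndices))
      msg <- c(msg, "objects reference frames absent from frameIndices")
    bad_cls <- setdiff(unique(obj$class), cellClasses())
    if (length(bad_cls))
      msg <- c(msg, paste("unknown class label(s):",
                          paste(bad_cls, collapse = ", ")))
    if (any(obj$x_max <= obj$x_min) || any(obj$y_max <= obj$y_min))
      msg <- c(msg, "all boxes must have strictly positive width and height")
    if (any(obj$confidence < 0 | obj$confidence > 1))
      msg <- c(msg, "confidence must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellVideo
#'
#' @param objects data.frame of labelled boxes; missing \code{confidence}
#'   defaults to 1 (ground truth), missing \code{object_id} to \code{NA}.
#'   May have zero rows.
#' @param frameIndices integer frame indices covered by the video; defaults
#'   to the frames present in \code{objects}.
#' @param frameInterval minutes between frames (default 5).
#' @param imageSize image (width, height) in pixels.
#' @param sampleMeta list with \code{sample_id}, \code{dose_gy},
#'   \code{irradiated}; missing entries are filled with defaults.
#' @return A validated [CellVideo-class] object.
#' @examples
#' boxes <- data.frame(frame = 1, x_min = 10, y_min = 10,
#'                     x_max = 30, y_max = 25, class = "liv")
#' v <- cellVideo(boxes, imageSize = c(100, 100))
#' nFrames(v)
#' @export
cellVideo <- function(objects = NULL, frameIndices = NULL,
                      frameInterval = 5, imageSize = c(1388, 1040),
                      sampleMeta = list()) {
  if (is.null(objects) || !nrow(objects)) {
    objects <- data.frame(frame = integer(), x_min = numeric(),
                          y_min = numeric(), x_max = numeric(),
                          y_max = numeric(), class = character(),
                          confidence = numeric(), object_id = character(),
                          stringsAsFactors = FALSE)
  } else {
    objects <- as.data.frame(objects)
    if (is.null(objects$confidence)) objects$confidence <- 1
    if (is.null(objects$object_id)) objects$object_id <- NA_character_
    objects$object_id <- as.character(objects$object_id)
    objects$frame <- as.integer(objects$frame)
    objects$class <- as.character(objects$class)
    objects <- objects[.OBJECT_COLS]
    objects <- objects[order(objects$frame), , drop = FALSE]
    rownames(objects) <- NULL
  }
  if (is.null(frameIndices)) frameIndices <- sort(unique(objects$frame))
  meta <- list(sample_id = "sample", dose_gy = 0, irradiated = FALSE)
  meta[names(sampleMeta)] <- sampleMeta
  new("CellVideo", objects = objects,
      frameIndices = as.integer(frameIndices),
      frameInterval = frameInterval,
      imageSize = as.numeric(imageSize), sampleMeta = meta)
}

#' GrowthFit: offset-exponential growth model fit
#'
#' Result of fitting the piecewise growth model
#' \deqn{n(t) = 1 \quad (t \le t_0), \qquad
#'       n(t) = (1 - A) + A e^{(t - t_0)/\tau} \quad (t > t_0)}
#' to a normalized cell-count series, where \eqn{t_0} is the arrest offset
#' (hours), \eqn{\tau} the growth constant (hours) and \eqn{A} the
#' amplitude. The model is continuous at \eqn{t_0} with \eqn{n(t_0) = 1}.
#'
#' @slot coefficients named numeric (A, t0, tau).
#' @slot vcov 3x3 covariance matrix of the parameters.
#' @slot chi2 weighted residual sum of squares.
#' @slot r2cor corrected (adjusted) R-squared.
#' @slot confLevel confidence level of the reported band (default 0.63).
#' @slot data data.frame of the fitted points (time_h, n, sigma).
#' @slot channel which count channel was fitted ("total" or "vital").
#' @seealso [fitGrowth()], [cgsf()]
#' @export
setClass("GrowthFit",
         representation(coefficients = "numeric", vcov = "matrix",
                        chi2 = "numeric", r2cor = "numeric",
                        confLevel = "numeric", data = "data.frame",
                        channel = "character"))

setValidity("GrowthFit", function(object) {
  p <- object@coefficients
  if (!all(c("A", "t0", "tau") %in% names(p)))
    return("coefficients must be named A, t0, tau")
  if (p[["tau"]] <= 0) return("tau must be positive")
  if (!identical(dim(object@vcov), c(3L, 3L)))
    return("vcov must be 3x3")
  TRUE
})

#' LQModel: linear-quadratic dose-response model
#'
#' Clonogenic survival as a function of dose,
#' \eqn{SF(D) = \exp(-(\alpha D + \beta D^2))}, the standard form for
#' dose-response of colony formation. \eqn{\alpha} has units 1/Gy,
#' \eqn{\beta} 1/Gy^2; \eqn{SF(0) = 1} always.
#'
#' @slot coefficients named numeric (alpha, beta).
#' @slot vcov 2x2 covariance matrix of (alpha, beta).
#' @seealso [lqFit()], [lqEvaluate()]
#' @export
setClass("LQModel",
         representation(coefficients = "numeric", vcov = "matrix"))

setValidity("LQModel", function(object) {
  if (!all(c("alpha", "beta") %in% names(object@coefficients)))
    return("coefficients must be named alpha, beta")
  if (!identical(dim(object@vcov), c(2L, 2L)))
    return("vcov must be 2x2")
  TRUE
})

#' Construct an LQModel from parameter values
#'
#' @param alpha linear coefficient (1/Gy).
#' @param beta quadratic coefficient (1/Gy^2).
#' @param se_alpha,se_beta standard errors; default 0.
#' @return An [LQModel-class] object (parameters assumed independent).
#' @examples
#' m <- lqModel(0.156, 0.0235, 0.045, 0.0055)
#' lqEvaluate(m, 4)
#' @export
lqModel <- function(alpha, beta, se_alpha = 0, se_beta = 0) {
  new("LQModel", coefficients = c(alpha = alpha, beta = beta),
      vcov = diag(c(se_alpha^2, se_beta^2)))
}
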