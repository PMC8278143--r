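#' Detector-noise configuration
#'
#' Parameters of the detector emulator, which turns a ground-truth video
#' into imperfect predictions mimicking the failure modes of a deep-learning
#' cell detector: missed objects, box jitter, class confusion (most notably
#' round cells labelled as living and vice versa), spurious detections, and
#' a hard cap on the number of detections per frame (pretrained detection
#' backbones commonly cap at 100 objects, so crowded frames lose cells).
#'
#' Default rates describe a well-trained detector on moderately crowded
#' frames: a 2 percent miss rate, sub-pixel corner jitter, 5 percent
#' round-to-liv confusion, and rare spurious boxes. These defaults
#' keep per-frame mAP above 90 percent on frames under the detection cap and
#' are fully tunable.
#'
#' @param miss_prob per-object false-negative probability.
#' @param spurious_rate expected false-positive boxes per frame (Poisson).
#' @param jitter_sd_px Gaussian standard deviation added independently to
#'   every box corner coordinate.
#' @param confusion 4x4 row-stochastic class-confusion matrix (rows = true
#'   class, columns = emitted class, order liv, round, div, dead).
#' @param confidence_model Beta parameters for the confidence of true and
#'   spurious detections: list with \code{tp = c(shape1, shape2)} and
#'   \code{fp = c(shape1, shape2)}.
#' @param max_detections cap on detections per frame (highest-confidence
#'   kept); default 100.
#' @param nms_iou IoU threshold of the non-maximum suppression applied to
#'   the emitted detections, in (0, 1].
#' @param seed integer RNG seed.
#' @return A validated list of class \code{"NoiseConfig"}.
#' @seealso [applyDetectorNoise()], [nms()]
#' @export
noiseConfig <- function(miss_prob = 0.02,
                        spurious_rate = 0.2,
                        jitter_sd_px = 0.5,
                        confusion = NULL,
                        confidence_model = list(tp = c(18, 2),
                                                fp = c(2, 5)),
                        max_detections = 100,
                        nms_iou = 0.7,
                        seed = 1L) {
  if (is.null(confusion)) {
    # dominant detector error: round cells labelled as living
    confusion <- diag(4)
    confusion[2, 1] <- 0.05; confusion[2, 2] <- 0.95
  }
  dimnames(confusion) <- list(cellClasses(), cellClasses())
  cfg <- list(miss_prob = miss_prob, spurious_rate = spurious_rate,
              jitter_sd_px = jitter_sd_px, confusion = confusion,
              confidence_model = confidence_model,
              max_detections = as.integer(max_detections),
              nms_iou = nms_iou, seed = as.integer(seed))
  .validate_noise_config(cfg)
  class(cfg) <- c("NoiseConfig", "list")
  cfg
}

#' @rdname noiseConfig
#' @export
identityNoiseConfig <- function(seed = 1L) {
  noiseConfig(miss_prob = 0, spurious_rate = 0, jitter_sd_px = 0,
              confusion = diag(4), nms_iou = 1, seed = seed)
}

.validate_noise_config <- function(cfg) {
  if (cfg$miss_prob < 0 || cfg$miss_prob > 1)
    stop("miss_prob must lie in [0, 1]")
  if (cfg$spurious_rate < 0 || cfg$jitter_sd_px < 0)
    stop("spurious_rate and jitter_sd_px must be non-negative")
  if (!identical(dim(cfg$confusion), c(4L, 4L)) ||
      any(abs(rowSums(cfg$confusion) - 1) > 1e-8) ||
      any(cfg$confusion < 0))
    stop("confusion must be a 4x4 row-stochastic matrix")
  if (cfg$nms_iou <= 0 || cfg$nms_iou > 1)
    stop("nms_iou must lie in (0, 1]")
  if (cfg$max_detections < 1) stop("max_detections must be at least 1")
  invisible(cfg)
}

#' Emulate an imperfect detector on a ground-truth video
#'
#' Per frame: each ground-truth object is dropped with probability
#' \code{miss_prob}; survivors get Gaussian corner jitter, a class sampled
#' from the confusion row of their true class, and a confidence drawn from
#' the true-positive confidence model. Spurious boxes (Poisson count per
#' frame, random placement and class, low confidence) are added. Non-maximum
#' suppression at \code{nms_iou} is applied and the result is truncated to
#' the \code{max_detections} highest-confidence objects.
#'
#' Emitted objects keep the \code{object_id} of the truth object they came
#' from (spurious boxes get none), which is bookkeeping only - evaluation
#' never uses ids.
#'
#' @param truth a ground-truth [CellVideo-class].
#' @param noise a [noiseConfig()] list.
#' @return A [CellVideo-class] of predictions.
#' @examples
#' sim <- simulatePopulation(simConfig(n_initial = 8, duration_h = 2))
#' pred <- applyDetectorNoise(sim$video, noiseConfig(seed = 2))
#' @export
applyDetectorNoise <- function(truth, noise) {
  stopifnot(is(truth, "CellVideo"))
  .validate_noise_config(noise)
  set.seed(noise$seed)
  classes <- cellClasses()
  fw <- truth@imageSize[1]; fh <- truth@imageSize[2]
  cm <- noise$confidence_model
  out <- vector("list", length(truth@frameIndices))
  for (j in seq_along(truth@frameIndices)) {
    fi <- truth@frameIndices[j]
    gt <- getFrame(truth, fi)
    det <- NULL
    if (nrow(gt)) {
      keep <- stats::runif(nrow(gt)) >= noise$miss_prob
      det <- gt[keep, , drop = FALSE]
      n <- nrow(det)
      if (n) {
        if (noise$jitter_sd_px > 0) {
          det$x_min <- det$x_min + stats::rnorm(n, 0, noise$jitter_sd_px)
          det$x_max <- det$x_max + stats::rnorm(n, 0, noise$jitter_sd_px)
          det$y_min <- det$y_min + stats::rnorm(n, 0, noise$jitter_sd_px)
          det$y_max <- det$y_max + stats::rnorm(n, 0, noise$jitter_sd_px)
          bad <- det$x_max <= det$x_min | det$y_max <= det$y_min
          det <- det[!bad, , drop = FALSE]
          n <- nrow(det)
        }
        if (n) {
          true_idx <- match(det$class, classes)
          det$class <- vapply(true_idx, function(ci)
            sample(classes, 1, prob = noise$confusion[ci, ]), character(1))
          det$confidence <- stats::rbeta(n, cm$tp[1], cm$tp[2])
        }
      }
    }
    n_fp <- stats::rpois(1, noise$spurious_rate)
    if (n_fp > 0) {
      wfp <- stats::runif(n_fp, 15, 60)
      hfp <- stats::runif(n_fp, 15, 60)
      xfp <- stats::runif(n_fp, 0, fw - wfp)
      yfp <- stats::runif(n_fp, 0, fh - hfp)
      fp <- data.frame(frame = fi, x_min = xfp, y_min = yfp,
                       x_max = xfp + wfp, y_max = yfp + hfp,
                       class = sample(classes, n_fp, replace = TRUE),
                       confidence = stats::rbeta(n_fp, cm$fp[1], cm$fp[2]),
                       object_id = NA_character_,
                       stringsAsFactors = FALSE)
      det <- rbind(det, fp)
    }
    if (!is.null(det) && nrow(det)) {
      det <- nms(det, noise$nms_iou)
      if (nrow(det) > noise$max_detections)
        det <- det[seq_len(noise$max_detections), , drop = FALSE]
      out[[j]] <- det
    }
  }
  objects <- do.call(rbind, out)
  cellVideo(objects, frameIndices = truth@frameIndices,
            frameInterval = truth@frameInterval,
            imageSize = truth@imageSize, sampleMeta = truth@sampleMeta)
}
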