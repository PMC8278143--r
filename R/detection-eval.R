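.frame_list <- function(x) {
  if (is(x, "CellVideo"))
    return(lapply(x@frameIndices, function(fi) getFrame(x, fi)))
  if (is.data.frame(x)) return(list(x))
  stop("expected a CellVideo or a single-frame data.frame")
}

#' Match predicted boxes against ground truth in one frame
#'
#' Greedy one-to-one assignment in the standard detection-metric
#' convention: predictions are visited in decreasing confidence (ties by
#' input order); each takes the not-yet-matched ground-truth box of highest
#' IoU at or above \code{iou_threshold} (restricted to its own class when
#' \code{class_aware}). Remaining ground truth are false negatives,
#' remaining predictions false positives.
#'
#' @param gt,pred data.frames of one frame's objects (box columns,
#'   \code{class}; \code{pred} also \code{confidence}).
#' @param iou_threshold matching threshold in (0, 1].
#' @param class_aware logical; require equal classes for a match. Run with
#'   \code{FALSE} to obtain cross-class pairs for a confusion matrix.
#' @return A list of class \code{"MatchResult"}: \code{pairs} (data.frame
#'   \code{gt_idx, pred_idx, iou, gt_class, pred_class}),
#'   \code{unmatched_gt} and \code{unmatched_pred} (row indices),
#'   \code{iou_threshold}, \code{class_aware}.
#' @export
matchFrame <- function(gt, pred, iou_threshold = 0.5, class_aware = TRUE) {
  if (!is.numeric(iou_threshold) || length(iou_threshold) != 1L ||
      iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must be a single number in (0, 1]")
  n_gt <- nrow(gt); n_pred <- nrow(pred)
  pairs <- data.frame(gt_idx = integer(), pred_idx = integer(),
                      iou = numeric(), gt_class = character(),
                      pred_class = character(), stringsAsFactors = FALSE)
  if (n_gt && n_pred) {
    iom <- iouMatrix(gt, pred)
    taken <- logical(n_gt)
    ord <- order(-pred$confidence, seq_len(n_pred))
    for (p in ord) {
      cand <- iom[, p]
      cand[taken] <- -1
      if (class_aware) cand[gt$class != pred$class[p]] <- -1
      g <- which.max(cand)
      if (length(g) && cand[g] >= iou_threshold) {
        taken[g] <- TRUE
        pairs[nrow(pairs) + 1L, ] <- list(g, p, iom[g, p],
                                          gt$class[g], pred$class[p])
      }
    }
  }
  structure(list(pairs = pairs,
                 unmatched_gt = setdiff(seq_len(n_gt), pairs$gt_idx),
                 unmatched_pred = setdiff(seq_len(n_pred), pairs$pred_idx),
                 gt_classes = if (n_gt) gt$class else character(),
                 pred_classes = if (n_pred) pred$class else character(),
                 iou_threshold = iou_threshold, class_aware = class_aware),
            class = "MatchResult")
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall numeric in [0, 1] (vectorized).
#' @return \code{2 * recall * precision / (recall + precision)}; \code{NaN}
#'   when both are 0.
#' @examples
#' f1Score(0.90, 0.98)  # 0.94
#' @export
f1Score <- function(precision, recall) {
  2 * recall * precision / (recall + precision)
}

#' Per-class classification scores from matching results
#'
#' Aggregates one or more class-agnostic [matchFrame()] results into a
#' 4x4 confusion matrix over matched pairs (true class x predicted class)
#' and per-class true/false positives and negatives, precision, recall and
#' F1. A cross-class match counts as a false positive for the predicted
#' class and a false negative for the true class; unmatched predictions and
#' ground truth count likewise. A score whose denominator is zero is
#' reported as \code{NA}, not 0, and is dropped from the mean row.
#'
#' @param matches a \code{MatchResult} or a list of them (computed with
#'   \code{class_aware = FALSE} so cross-class pairs exist).
#' @return A list of class \code{"ClassScores"}: \code{confusion} (4x4
#'   count matrix) and \code{scores} (data.frame with rows for each class
#'   plus a \code{"mean"} row; columns TP, FP, FN, precision, recall, f1).
#' @export
classificationScores <- function(matches) {
  if (inherits(matches, "MatchResult")) matches <- list(matches)
  classes <- cellClasses()
  conf <- matrix(0L, 4, 4, dimnames = list(true = classes,
                                           predicted = classes))
  fp_un <- fn_un <- stats::setNames(numeric(4), classes)
  for (m in matches) {
    if (nrow(m$pairs))
      for (i in seq_len(nrow(m$pairs)))
        conf[m$pairs$gt_class[i], m$pairs$pred_class[i]] <-
          conf[m$pairs$gt_class[i], m$pairs$pred_class[i]] + 1L
    for (cl in m$pred_classes[m$unmatched_pred])
      fp_un[cl] <- fp_un[cl] + 1
    for (cl in m$gt_classes[m$unmatched_gt])
      fn_un[cl] <- fn_un[cl] + 1
  }
  tp <- diag(conf)
  fp <- colSums(conf) - tp + fp_un
  fn <- rowSums(conf) - tp + fn_un
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               f1Score(precision, recall), NA_real_)
  scores <- data.frame(TP = tp, FP = fp, FN = fn, precision = precision,
                       recall = recall, f1 = f1, row.names = classes)
  scores["mean", ] <- c(NA, NA, NA,
                        mean(precision, na.rm = TRUE),
                        mean(recall, na.rm = TRUE),
                        mean(f1, na.rm = TRUE))
  structure(list(confusion = conf, scores = scores),
            class = "ClassScores")
}

.ap_from_flags <- function(tp_flags, conf, n_gt,
                           interpolation = c("envelope", "11point")) {
  interpolation <- match.arg(interpolation)
  ord <- order(-conf, seq_along(conf))
  tp <- cumsum(tp_flags[ord])
  fp <- cumsum(!tp_flags[ord])
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  pr <- data.frame(recall = recall, precision = precision)
  if (interpolation == "envelope") {
    # precision envelope: at recall r use max precision at recall >= r
    menv <- rev(cummax(rev(precision)))
    dr <- diff(c(0, recall))
    ap <- sum(dr * menv)
  } else {
    ap <- mean(vapply(seq(0, 1, 0.1), function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1)))
  }
  list(pr_points = pr, ap = ap)
}

#' Average precision of one class at one IoU threshold
#'
#' Predictions of the class are matched per frame (greedy, decreasing
#' confidence, class-aware) at the given IoU threshold, then pooled over
#' frames and sorted by confidence; cumulative precision-recall points are
#' integrated into the AP. The default integration is the all-point
#' precision-envelope area (the precision at recall r is the maximum
#' precision attained at any recall >= r); classic 11-point interpolation is
#' available behind the \code{interpolation} switch.
#'
#' @param gt,pred [CellVideo-class] objects or single-frame data.frames.
#' @param cls one of [cellClasses()].
#' @param iou_threshold matching threshold.
#' @param interpolation \code{"envelope"} (default) or \code{"11point"}.
#' @return A list of class \code{"APResult"}: \code{pr_points}, \code{ap},
#'   \code{n_gt}, \code{n_pred}. If the class has no ground-truth instance
#'   the AP is undefined and \code{ap} is \code{NA}.
#' @export
averagePrecision <- function(gt, pred, cls, iou_threshold = 0.5,
                             interpolation = c("envelope", "11point")) {
  interpolation <- match.arg(interpolation)
  gt_frames <- .frame_list(gt)
  pred_frames <- .frame_list(pred)
  stopifnot(length(gt_frames) == length(pred_frames))
  n_gt <- sum(vapply(gt_frames, function(f) sum(f$class == cls),
                     numeric(1)))
  if (n_gt == 0)
    return(structure(list(pr_points = NULL, ap = NA_real_, n_gt = 0,
                          n_pred = NA), class = "APResult"))
  conf <- numeric(); tp_flags <- logical()
  for (j in seq_along(gt_frames)) {
    g <- gt_frames[[j]][gt_frames[[j]]$class == cls, , drop = FALSE]
    p <- pred_frames[[j]][pred_frames[[j]]$class == cls, , drop = FALSE]
    if (!nrow(p)) next
    m <- matchFrame(g, p, iou_threshold, class_aware = TRUE)
    flags <- logical(nrow(p))
    flags[m$pairs$pred_idx] <- TRUE
    conf <- c(conf, p$confidence)
    tp_flags <- c(tp_flags, flags)
  }
  if (!length(conf))
    return(structure(list(pr_points = data.frame(recall = numeric(),
                                                 precision = numeric()),
                          ap = 0, n_gt = n_gt, n_pred = 0),
                     class = "APResult"))
  res <- .ap_from_flags(tp_flags, conf, n_gt, interpolation)
  structure(list(pr_points = res$pr_points, ap = res$ap, n_gt = n_gt,
                 n_pred = length(conf)), class = "APResult")
}

#' Mean AP of one class over the IoU threshold sweep
#'
#' The per-class AP averaged over IoU thresholds 0.50 to 0.95 in steps of
#' 0.05 (10 thresholds), the standard sweep for detection benchmarks.
#'
#' @inheritParams averagePrecision
#' @param thresholds the IoU sweep.
#' @return Mean AP in [0, 1], or \code{NA} if the class is absent from the
#'   ground truth.
#' @export
apBar <- function(gt, pred, cls, thresholds = seq(0.5, 0.95, by = 0.05),
                  interpolation = c("envelope", "11point")) {
  interpolation <- match.arg(interpolation)
  aps <- vapply(thresholds, function(th)
    averagePrecision(gt, pred, cls, th, interpolation)$ap, numeric(1))
  mean(aps)
}

#' Mean average precision (percent)
#'
#' The mean of the per-class [apBar()] over the classes present in the
#' ground truth, reported in percent. With \code{scope = "frame"} the score
#' is computed separately for every frame, yielding a time series together
#' with per-class AP-bar values and ground-truth/prediction counts.
#'
#' By default classes with no ground-truth instance in the evaluation scope
#' are excluded from the mean (most frames contain no dividing cell, and
#' scoring an absent class 0 would dominate the mean unfairly);
#' \code{absent_class = "zero"} scores them 0 instead.
#'
#' @inheritParams apBar
#' @param scope \code{"pooled"} (one score over all frames) or
#'   \code{"frame"} (per-frame series).
#' @param absent_class \code{"exclude"} (default) or \code{"zero"}.
#' @return \code{scope = "pooled"}: a single percentage. \code{scope =
#'   "frame"}: a data.frame with columns \code{frame, time_min},
#'   \code{ap_bar_<class>}, \code{map}, and per-class \code{gt_<class>},
#'   \code{pred_<class>} counts.
#' @examples
#' f <- data.frame(x_min = c(0, 40), y_min = c(0, 0),
#'                 x_max = c(20, 70), y_max = c(20, 25),
#'                 class = c("liv", "dead"), confidence = 1)
#' mapScore(f, f)  # identical predictions score 100
#' @export
mapScore <- function(gt, pred, scope = c("pooled", "frame"),
                     thresholds = seq(0.5, 0.95, by = 0.05),
                     absent_class = c("exclude", "zero"),
                     interpolation = c("envelope", "11point")) {
  scope <- match.arg(scope)
  absent_class <- match.arg(absent_class)
  interpolation <- match.arg(interpolation)
  classes <- cellClasses()
  pooled_map <- function(g, p) {
    bars <- vapply(classes, function(cl)
      apBar(g, p, cl, thresholds, interpolation), numeric(1))
    if (absent_class == "zero") bars[is.na(bars)] <- 0
    if (all(is.na(bars))) return(c(rep(NA_real_, 4), NA_real_))
    c(bars, mean(bars, na.rm = TRUE))
  }
  if (scope == "pooled") {
    v <- pooled_map(gt, pred)
    if (is.na(v[5])) stop("no ground-truth objects in scope")
    return(unname(100 * v[5]))
  }
  stopifnot(is(gt, "CellVideo"), is(pred, "CellVideo"))
  rows <- lapply(gt@frameIndices, function(fi) {
    g <- getFrame(gt, fi); p <- getFrame(pred, fi)
    v <- pooled_map(g, p)
    counts_g <- table(factor(g$class, levels = classes))
    counts_p <- table(factor(p$class, levels = classes))
    out <- data.frame(frame = fi, time_min = fi * gt@frameInterval)
    out[paste0("ap_bar_", classes)] <- as.list(100 * v[1:4])
    out$map <- 100 * v[5]
    out[paste0("gt_", classes)] <- as.list(as.integer(counts_g))
    out[paste0("pred_", classes)] <- as.list(as.integer(counts_p))
    out
  })
  do.call(rbind, rows)
}
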