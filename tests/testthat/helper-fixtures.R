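# fixtures and independent oracles used across the suite

box_df <- function(x1, y1, x2, y2, class = "liv", confidence = 1,
                   frame = 1L, id = NA_character_) {
  data.frame(frame = as.integer(frame), x_min = x1, y_min = y1,
             x_max = x2, y_max = y2, class = class,
             confidence = confidence, object_id = id,
             stringsAsFactors = FALSE)
}

# random valid video for round-trip properties (values rounded so text
# serialization is exact)
random_video <- function(seed, n_frames = 3, max_obj = 6) {
  set.seed(seed)
  rows <- list()
  for (f in seq_len(n_frames)) {
    n <- sample(0:max_obj, 1)
    if (!n) next
    x <- round(runif(n, 0, 900), 2)
    y <- round(runif(n, 0, 700), 2)
    w <- round(runif(n, 5, 80), 2)
    h <- round(runif(n, 5, 80), 2)
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f, x_min = x, y_min = y, x_max = x + w, y_max = y + h,
      class = sample(cellClasses(), n, replace = TRUE),
      confidence = round(runif(n), 4),
      object_id = ifelse(runif(n) < 0.5, as.character(seq_len(n)),
                         NA_character_),
      stringsAsFactors = FALSE)
  }
  cellVideo(if (length(rows)) do.call(rbind, rows) else NULL,
            frameIndices = seq_len(n_frames), frameInterval = 5,
            imageSize = c(1000, 800),
            sampleMeta = list(sample_id = paste0("rv", seed),
                              dose_gy = round(runif(1, 0, 8), 1),
                              irradiated = runif(1) < 0.5))
}

# independent greedy NMS (straight re-derivation, row-by-row)
brute_nms <- function(objects, thr) {
  ord <- order(-objects$confidence, seq_len(nrow(objects)))
  kept <- list()
  for (i in ord) {
    ok <- TRUE
    for (k in kept)
      if (boxIoU(objects[i, ], objects[k, ]) >= thr) { ok <- FALSE; break }
    if (ok) kept[[length(kept) + 1L]] <- i
  }
  objects[unlist(kept), , drop = FALSE]
}

# exhaustive matching oracle: enumerate every injective pred -> gt
# assignment with IoU >= thr (class-restricted if asked), then pick the
# assignment that is lexicographically best in confidence order, each
# prediction preferring higher IoU (ties to the lower gt index).
# Unassigned predictions are encoded as (g = NA, iou = -1).
brute_match <- function(gt, pred, thr, class_aware = TRUE) {
  np <- nrow(pred); ng <- nrow(gt)
  ord <- order(-pred$confidence, seq_len(np))
  none <- list(g = NA_integer_, iou = -1)
  best <- NULL
  better <- function(pairs) {
    if (is.null(best)) return(TRUE)
    for (j in seq_len(np)) {
      if (pairs[[j]]$iou > best[[j]]$iou + 1e-12) return(TRUE)
      if (pairs[[j]]$iou < best[[j]]$iou - 1e-12) return(FALSE)
      ga <- if (is.na(pairs[[j]]$g)) Inf else pairs[[j]]$g
      gb <- if (is.na(best[[j]]$g)) Inf else best[[j]]$g
      if (ga < gb) return(TRUE)
      if (ga > gb) return(FALSE)
    }
    FALSE
  }
  assign_next <- function(k, used, pairs) {
    if (k > np) {
      if (better(pairs)) best <<- pairs
      return(invisible())
    }
    p <- ord[k]
    opts <- list(none)
    for (g in seq_len(ng)) {
      if (used[g]) next
      if (class_aware && gt$class[g] != pred$class[p]) next
      iou <- boxIoU(gt[g, ], pred[p, ])
      if (iou >= thr) opts[[length(opts) + 1L]] <- list(g = g, iou = iou)
    }
    for (o in opts) {
      pairs2 <- pairs
      pairs2[[k]] <- o
      used2 <- used
      if (!is.na(o$g)) used2[o$g] <- TRUE
      assign_next(k + 1L, used2, pairs2)
    }
  }
  assign_next(1L, logical(ng), rep(list(none), np))
  out <- data.frame(gt_idx = integer(), pred_idx = integer())
  for (j in seq_len(np))
    if (!is.na(best[[j]]$g))
      out[nrow(out) + 1L, ] <- c(best[[j]]$g, ord[j])
  out[order(out$pred_idx), , drop = FALSE]
}
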