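#' Per-frame class-count time series
#'
#' Counts the labelled objects of every frame by class, adds the vital
#' aggregate (liv + round + div) and the total, and normalizes every series
#' by the total count of the first frame, so the normalized total starts at
#' 1. Poisson counting errors (sigma(N) = sqrt(N), so sigma(n) =
#' sqrt(N)/N0) are attached for the normalized total and vital series.
#'
#' @param video a [CellVideo-class].
#' @return A data.frame of class \code{"CountSeries"} with columns
#'   \code{frame, time_min, time_h}, raw counts \code{N_liv, N_round,
#'   N_div, N_dead, N_vital, N_total}, normalized series \code{n_liv, ...,
#'   n_total}, and \code{sigma_total, sigma_vital}. The first-frame total
#'   is attached as attribute \code{"N0"}.
#' @examples
#' sim <- simulatePopulation(simConfig(n_initial = 12, duration_h = 6))
#' head(countSeries(sim$video))
#' @export
countSeries <- function(video) {
  stopifnot(is(video, "CellVideo"))
  classes <- cellClasses()
  obj <- video@objects
  counts <- vapply(video@frameIndices, function(fi) {
    cls <- obj$class[obj$frame == fi]
    as.integer(table(factor(cls, levels = classes)))
  }, integer(4))
  counts <- t(counts)
  colnames(counts) <- paste0("N_", classes)
  out <- data.frame(frame = video@frameIndices,
                    time_min = video@frameIndices * video@frameInterval)
  out$time_h <- out$time_min / 60
  out <- cbind(out, counts)
  out$N_vital <- out$N_liv + out$N_round + out$N_div
  out$N_total <- out$N_vital + out$N_dead
  N0 <- out$N_total[1]
  if (is.na(N0) || N0 == 0)
    stop("first frame has no objects; cannot normalize")
  for (cl in c(classes, "vital", "total"))
    out[[paste0("n_", cl)]] <- out[[paste0("N_", cl)]] / N0
  out$sigma_total <- sqrt(out$N_total) / N0
  out$sigma_vital <- sqrt(out$N_vital) / N0
  attr(out, "N0") <- N0
  class(out) <- c("CountSeries", "data.frame")
  out
}

.growth_model <- function(t, A, t0, tau) {
  ifelse(t <= t0, 1, (1 - A) + A * exp((t - t0) / tau))
}

#' Fit the offset-exponential growth model
#'
#' Fits the piecewise-continuous model \eqn{n(t) = 1} for \eqn{t \le t_0}
#' and \eqn{n(t) = (1 - A) + A e^{(t - t_0)/\tau}} for \eqn{t > t_0} to a
#' normalized count series by weighted least squares
#' (Levenberg-Marquardt), with weights \eqn{1/\sigma^2} from the Poisson
#' counting errors. Points before the arrest are fitted against the
#' constant branch, so they inform the estimate of \eqn{t_0}.
#'
#' @param series a [countSeries()] result, or any data.frame with columns
#'   \code{time_h}, \code{n} and \code{sigma}.
#' @param channel which series to fit when \code{series} is a
#'   \code{CountSeries}: \code{"total"} or \code{"vital"}.
#' @param conf_level level of the confidence band reported by
#'   \code{predictGrowth} (default 0.63).
#' @param start optional named start values (A, t0, tau).
#' @return A [GrowthFit-class]. A degenerate, essentially flat series
#'   yields A close to 0 with very wide t0/tau uncertainties and a warning.
#' @seealso [predictGrowth()], [cgsf()]
#' @export
fitGrowth <- function(series, channel = c("total", "vital"),
                      conf_level = 0.63, start = NULL) {
  channel <- match.arg(channel)
  if (inherits(series, "CountSeries")) {
    df <- data.frame(time_h = series$time_h,
                     n = series[[paste0("n_", channel)]],
                     sigma = series[[paste0("sigma_", channel)]])
  } else {
    stopifnot(all(c("time_h", "n", "sigma") %in% names(series)))
    df <- as.data.frame(series)[c("time_h", "n", "sigma")]
  }
  if (nrow(df) < 6)
    stop("need at least 6 time points to fit the growth model")
  df$sigma[df$sigma <= 0] <- min(df$sigma[df$sigma > 0], 1)
  if (is.null(start)) {
    above <- df$time_h[df$n > 1.1]
    t0_start <- if (length(above)) max(min(above) - 1, 0.5) else
      stats::median(df$time_h)
    start <- c(A = 0.4, t0 = t0_start, tau = 15)
  }
  do_fit <- function(st) minpack.lm::nlsLM(
    n ~ .growth_model(time_h, A, t0, tau), data = df,
    start = as.list(st), weights = 1 / df$sigma^2,
    lower = c(A = 0, t0 = 0, tau = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  fit <- tryCatch(do_fit(start), error = function(e) e)
  if (inherits(fit, "error"))
    fit <- tryCatch(do_fit(c(A = 0.05, t0 = unname(start["t0"]),
                             tau = 20)),
                    error = function(e) e)
  degenerate <- FALSE
  if (inherits(fit, "error")) {
    # essentially flat series: the exponential branch carries no signal
    if (stats::sd(df$n) <= 2 * stats::median(df$sigma)) {
      degenerate <- TRUE
      p <- c(A = 0, t0 = unname(start["t0"]), tau = unname(start["tau"]))
      V <- diag(c(stats::var(df$n), 1e4, 1e4))
    } else {
      stop("growth fit did not converge: ", conditionMessage(fit),
           call. = FALSE)
    }
  } else {
    p <- stats::coef(fit)
    V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(V))) {
      V <- diag(c(1, 1e4, 1e4))
      degenerate <- TRUE
    }
  }
  dimnames(V) <- list(c("A", "t0", "tau"), c("A", "t0", "tau"))
  fitted_n <- .growth_model(df$time_h, p["A"], p["t0"], p["tau"])
  wres <- (df$n - fitted_n) / df$sigma
  chi2 <- sum(wres^2)
  wmean <- sum(df$n / df$sigma^2) / sum(1 / df$sigma^2)
  ss_tot <- sum(((df$n - wmean) / df$sigma)^2)
  r2 <- 1 - chi2 / ss_tot
  np <- nrow(df)
  r2cor <- 1 - (1 - r2) * (np - 1) / (np - 3 - 1)
  if (p["A"] < 2 * sqrt(V[1, 1]) || degenerate) {
    degenerate <- TRUE
    warning("growth amplitude consistent with zero; ",
            "t0 and tau are poorly constrained", call. = FALSE)
  }
  out <- new("GrowthFit",
             coefficients = c(A = unname(p["A"]), t0 = unname(p["t0"]),
                              tau = unname(p["tau"])),
             vcov = V, chi2 = chi2, r2cor = r2cor, confLevel = conf_level,
             data = df, channel = channel)
  attr(out, "degenerate") <- degenerate
  out
}

.growth_gradient <- function(t, p) {
  A <- p["A"]; t0 <- p["t0"]; tau <- p["tau"]
  u <- (t - t0) / tau
  g <- rbind(A = ifelse(t <= t0, 0, exp(u) - 1),
             t0 = ifelse(t <= t0, 0, -A * exp(u) / tau),
             tau = ifelse(t <= t0, 0, -A * exp(u) * u / tau))
  g
}

#' Evaluate a growth fit with its confidence band
#'
#' Evaluates the fitted model at the requested times and attaches a
#' pointwise confidence band at the fit's configured level, obtained by
#' linearized (delta-method) propagation of the parameter covariance.
#'
#' @param fit a [GrowthFit-class].
#' @param time_h numeric vector of times (hours).
#' @return data.frame with columns \code{time_h, n, se, lower, upper}.
#' @export
predictGrowth <- function(fit, time_h) {
  p <- fit@coefficients
  n <- .growth_model(time_h, p["A"], p["t0"], p["tau"])
  g <- .growth_gradient(time_h, p)
  se <- sqrt(pmax(0, colSums(g * (fit@vcov %*% g))))
  z <- stats::qnorm((1 + fit@confLevel) / 2)
  data.frame(time_h = time_h, n = n, se = se,
             lower = n - z * se, upper = n + z * se)
}

#' @describeIn GrowthFit-class plot the fitted points, model curve and
#'   confidence band.
#' @param x a \code{GrowthFit}; \code{y} is unused.
#' @param ... passed to \code{plot}.
#' @export
setMethod("plot", signature(x = "GrowthFit", y = "missing"),
          function(x, ...) {
  df <- x@data
  tt <- seq(min(df$time_h), max(df$time_h), length.out = 200)
  band <- predictGrowth(x, tt)
  graphics::plot(df$time_h, df$n, xlab = "time after irradiation [h]",
                 ylab = "normalized cell number", ...)
  graphics::polygon(c(tt, rev(tt)), c(band$lower, rev(band$upper)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(tt, band$n, lwd = 2)
  graphics::points(df$time_h, df$n)
  invisible(x)
})

#' Cell-growth-defined survival fraction (CGSF)
#'
#' The ratio of the irradiated sample's normalized vital-cell number to the
#' sham sample's at a given time, either from two fitted growth curves
#' (\code{method = "fit"}) or directly from two raw count series
#' (\code{method = "raw"}, nearest frame). The uncertainty is propagated
#' assuming independence of the two samples (separate wells):
#' \eqn{\sigma_{CGSF} = CGSF \sqrt{(\sigma_i/n_i)^2 + (\sigma_s/n_s)^2}},
#' with per-sample uncertainties from the fits' confidence bands (at their
#' configured level) or from Poisson errors for raw series.
#'
#' @param irr,sham [GrowthFit-class] objects (method "fit") or
#'   [countSeries()] data.frames (method "raw").
#' @param t_h evaluation time(s) in hours.
#' @param method \code{"fit"} or \code{"raw"}; default chosen from the
#'   input class.
#' @return data.frame with columns \code{time_h, cgsf, sigma} (both on the
#'   0-1 scale). Requests beyond twice the fitted time range raise a
#'   warning.
#' @export
cgsf <- function(irr, sham, t_h, method = NULL) {
  if (is.null(method))
    method <- if (is(irr, "GrowthFit")) "fit" else "raw"
  if (method == "fit") {
    stopifnot(is(irr, "GrowthFit"), is(sham, "GrowthFit"))
    rng <- max(irr@data$time_h, sham@data$time_h)
    if (any(t_h > 2 * rng))
      warning("CGSF requested beyond twice the fitted time range ",
              "(extrapolation)", call. = FALSE)
    z <- stats::qnorm((1 + irr@confLevel) / 2)
    pi_ <- predictGrowth(irr, t_h)
    ps <- predictGrowth(sham, t_h)
    val <- pi_$n / ps$n
    sig <- val * sqrt(((pi_$upper - pi_$n) / z / pi_$n)^2 +
                        ((ps$upper - ps$n) / z / ps$n)^2)
    return(data.frame(time_h = t_h, cgsf = val, sigma = sig))
  }
  stopifnot(inherits(irr, "CountSeries"), inherits(sham, "CountSeries"))
  rows <- lapply(t_h, function(t) {
    ii <- which.min(abs(irr$time_h - t))
    is <- which.min(abs(sham$time_h - t))
    ni <- irr$n_vital[ii]; ns <- sham$n_vital[is]
    si <- irr$sigma_vital[ii]; ss <- sham$sigma_vital[is]
    val <- ni / ns
    data.frame(time_h = t, cgsf = val,
               sigma = val * sqrt((si / ni)^2 + (ss / ns)^2))
  })
  do.call(rbind, rows)
}

.founder_map <- function(lineage) {
  founder <- stats::setNames(rep(NA_character_, nrow(lineage)),
                             lineage$cell_id)
  for (i in seq_len(nrow(lineage))) {
    p <- lineage$parent_id[i]
    if (is.na(p)) {
      founder[i] <- lineage$cell_id[i]
    } else {
      if (!p %in% names(founder) || is.na(founder[p]))
        stop("lineage error: cell ", lineage$cell_id[i],
             " references unknown or later parent ", p, call. = FALSE)
      founder[i] <- founder[p]
    }
  }
  founder
}

#' Census of divisions per founder cell
#'
#' For every founder (a lineage record without a parent), the maximum
#' number of divisions observed along any of its descendant chains within
#' the time window - i.e. the maximum generation depth reached. Four
#' divisions per cell means at least one descendant belongs to the fifth
#' generation. Also reports the cumulative number of division events over
#' time.
#'
#' @param lineage data.frame as returned by [simulatePopulation()]
#'   (columns \code{cell_id, parent_id, generation, birth_min,
#'   division_min}). Records must be ordered so parents precede children.
#' @param window_h only events up to this time (hours) are counted
#'   (default: all).
#' @return list with \code{per_founder} (data.frame \code{founder_id,
#'   divisions}), \code{histogram} (data.frame \code{divisions,
#'   n_founders} over 0..max), \code{total_divisions}, and \code{events}
#'   (data.frame \code{time_min, cumulative} of division events).
#' @export
divisionCensus <- function(lineage, window_h = Inf) {
  window_min <- window_h * 60
  founder <- .founder_map(lineage)
  in_window <- lineage$birth_min <= window_min
  depth <- tapply(lineage$generation[in_window], founder[in_window], max)
  founders <- lineage$cell_id[is.na(lineage$parent_id)]
  per_founder <- data.frame(founder_id = founders,
                            divisions = as.integer(depth[founders]),
                            stringsAsFactors = FALSE)
  per_founder$divisions[is.na(per_founder$divisions)] <- 0L
  lv <- 0:max(per_founder$divisions, 0)
  hist <- data.frame(divisions = lv,
                     n_founders = as.integer(
                       table(factor(per_founder$divisions, levels = lv))))
  ev <- sort(lineage$division_min[!is.na(lineage$division_min) &
                                    lineage$division_min <= window_min])
  events <- data.frame(time_min = ev, cumulative = seq_along(ev))
  list(per_founder = per_founder, histogram = hist,
       total_divisions = length(ev), events = events)
}

#' Unique-dead-cell census
#'
#' Counts each dead cell exactly once within a time window, following
#' dead-labelled boxes from frame to frame so a cell that stays visible for
#' hundreds of frames contributes one death. When stable object ids are
#' present they define the identity; otherwise a dead box is linked to an
#' existing dead track if its IoU with the track's last box reaches
#' \code{link_iou} (dead cells stop moving, so linking is robust to frame
#' subsampling).
#'
#' The denominator N is the number of distinct cells observed in the
#' window: the count of distinct ids when ids are present, else the
#' first-frame total plus the division events inferred from increments of
#' the total count (an approximation, documented as such). The fraction
#' k/N carries the Poisson uncertainty sqrt(k)/N.
#'
#' @param video a [CellVideo-class].
#' @param window_h window length in hours from the start of the video.
#' @param link_iou IoU threshold in (0, 1] for frame-to-frame linking.
#' @return list of class \code{"DeathCensus"}: \code{k} unique dead cells,
#'   \code{N} cells observed, \code{fraction}, \code{sigma}
#'   (= sqrt(k)/N), and \code{track_starts_min}.
#' @examples
#' sqrt(5) / 108  # Poisson sigma for 5 deaths among 108 cells: 2.1 points
#' @export
deadCellCensus <- function(video, window_h = 24, link_iou = 0.3) {
  stopifnot(is(video, "CellVideo"))
  if (link_iou <= 0 || link_iou > 1)
    stop("link_iou must lie in (0, 1]")
  window_min <- window_h * 60
  frames <- video@frameIndices[video@frameIndices * video@frameInterval <=
                                 window_min]
  obj <- video@objects[video@objects$frame %in% frames, , drop = FALSE]
  have_ids <- nrow(obj) > 0 && !anyNA(obj$object_id)
  dead <- obj[obj$class == "dead", , drop = FALSE]
  if (have_ids) {
    first_dead <- tapply(dead$frame, dead$object_id, min)
    k <- length(first_dead)
    starts <- as.numeric(first_dead) * video@frameInterval
    N <- length(unique(obj$object_id))
  } else {
    tracks <- NULL   # data.frame of last-seen boxes per open track
    starts <- numeric()
    for (fi in frames) {
      fd <- dead[dead$frame == fi, , drop = FALSE]
      if (!nrow(fd)) next
      if (is.null(tracks) || !nrow(tracks)) {
        tracks <- fd
        starts <- c(starts, rep(fi * video@frameInterval, nrow(fd)))
        next
      }
      iom <- iouMatrix(tracks, fd)
      taken <- logical(nrow(tracks))
      new_rows <- integer()
      for (p in seq_len(nrow(fd))) {
        cand <- iom[, p]
        cand[taken] <- -1
        g <- which.max(cand)
        if (length(g) && cand[g] >= link_iou) {
          taken[g] <- TRUE
          tracks[g, ] <- fd[p, ]
        } else {
          new_rows <- c(new_rows, p)
        }
      }
      if (length(new_rows)) {
        tracks <- rbind(tracks, fd[new_rows, , drop = FALSE])
        starts <- c(starts, rep(fi * video@frameInterval,
                                length(new_rows)))
      }
    }
    k <- length(starts)
    totals <- vapply(frames, function(fi) sum(obj$frame == fi), numeric(1))
    N <- if (length(totals))
      totals[1] + sum(pmax(0, diff(totals))) else 0
  }
  structure(list(k = as.integer(k), N = as.integer(N),
                 fraction = if (N > 0) k / N else NA_real_,
                 sigma = if (N > 0) sqrt(k) / N else NA_real_,
                 track_starts_min = sort(unname(starts))),
            class = "DeathCensus")
}
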