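#' Plating efficiency and clonogenic survival fraction
#'
#' For each treated sample, the plating efficiency PE is the fraction of
#' seeded cells that formed a colony (colonies of at least 50 cells by the
#' usual scoring contract, applied at data entry). The survival fraction is
#' the sample PE divided by the mean control PE, with Gaussian error
#' propagation
#' \deqn{\Delta SF = SF \sqrt{(\Delta PE/PE)^2 + (\Delta PE_0/PE_0)^2}.}
#' The control uncertainty is the standard error of the mean over control
#' samples (at least two are required). A treated sample with replicate
#' wells gets its PE uncertainty from the SEM over wells; an unreplicated
#' sample falls back to the binomial approximation
#' \eqn{\sqrt{PE(1-PE)/seeded}}.
#'
#' @param samples data.frame of treated wells with columns
#'   \code{sample_id, dose_gy, seeded_cells, colonies}.
#' @param controls data.frame of control (0 Gy) samples, same columns.
#' @return data.frame with one row per treated sample: \code{sample_id,
#'   dose_gy, PE, dPE, PE0_mean, dPE0, SF, dSF}.
#' @examples
#' ctrl <- data.frame(sample_id = paste0("c", 1:3), dose_gy = 0,
#'                    seeded_cells = 100, colonies = c(52, 55, 50))
#' irr <- data.frame(sample_id = "s1", dose_gy = 4,
#'                   seeded_cells = 400, colonies = 120)
#' survivalFraction(irr, ctrl)
#' @export
survivalFraction <- function(samples, controls) {
  .check_colony <- function(df, what) {
    need <- c("sample_id", "seeded_cells", "colonies")
    if (!all(need %in% names(df)))
      stop(what, " must have columns ", paste(need, collapse = ", "))
    if (any(df$colonies > df$seeded_cells) || any(df$colonies < 0))
      stop(what, ": colony counts must lie in [0, seeded_cells]")
  }
  .check_colony(samples, "samples"); .check_colony(controls, "controls")
  ctrl_pe <- tapply(controls$colonies / controls$seeded_cells,
                    controls$sample_id, mean)
  if (length(ctrl_pe) < 2)
    stop("at least two control samples are needed ",
         "(the control uncertainty is a standard error of the mean)")
  PE0 <- mean(ctrl_pe)
  if (PE0 <= 0) stop("mean control plating efficiency is zero")
  dPE0 <- stats::sd(ctrl_pe) / sqrt(length(ctrl_pe))
  rows <- lapply(split(samples, samples$sample_id), function(s) {
    pe_wells <- s$colonies / s$seeded_cells
    PE <- mean(pe_wells)
    if (PE <= 0) stop("sample ", s$sample_id[1],
                      " has zero plating efficiency")
    dPE <- if (nrow(s) > 1) {
      stats::sd(pe_wells) / sqrt(nrow(s))
    } else {
      sqrt(PE * (1 - PE) / s$seeded_cells)
    }
    SF <- PE / PE0
    dSF <- SF * sqrt((dPE / PE)^2 + (dPE0 / PE0)^2)
    data.frame(sample_id = s$sample_id[1],
               dose_gy = if ("dose_gy" %in% names(s)) s$dose_gy[1] else NA,
               PE = PE, dPE = dPE, PE0_mean = PE0, dPE0 = dPE0,
               SF = SF, dSF = dSF, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate the linear-quadratic survival model
#'
#' Closed-form evaluation of \eqn{SF(D) = \exp(-(\alpha D + \beta D^2))}
#' with the uncertainty from linear propagation of the (assumed
#' independent unless the model carries a covariance) alpha/beta errors:
#' \eqn{\sigma_{SF} = SF \sqrt{(D\sigma_\alpha)^2 + (D^2\sigma_\beta)^2}}.
#'
#' @param model an [LQModel-class].
#' @param dose_gy dose(s) in Gy, non-negative.
#' @return data.frame with columns \code{dose_gy, SF, sigma}.
#' @examples
#' m <- lqModel(0.156, 0.0235, 0.045, 0.0055)
#' lqEvaluate(m, 4)   # SF = exp(-1) = 0.368, i.e. 37 %
#' @export
lqEvaluate <- function(model, dose_gy) {
  stopifnot(is(model, "LQModel"), all(dose_gy >= 0))
  p <- model@coefficients
  SF <- exp(-(p["alpha"] * dose_gy + p["beta"] * dose_gy^2))
  g <- rbind(-dose_gy * SF, -dose_gy^2 * SF)
  sigma <- sqrt(pmax(0, colSums(g * (model@vcov %*% g))))
  data.frame(dose_gy = dose_gy, SF = unname(SF), sigma = unname(sigma))
}

#' Fit the linear-quadratic model to survival data
#'
#' Taking logs makes the model exactly linear in alpha and beta:
#' \eqn{-\ln SF = \alpha D + \beta D^2}. The fit is weighted least squares
#' on \eqn{\ln SF} with weights transformed accordingly
#' (\eqn{\sigma_{\ln SF} = \sigma_{SF}/SF}); with missing or zero
#' uncertainties the fit is unweighted. Nonnegativity of alpha and beta is
#' not enforced.
#'
#' @param points data.frame with columns \code{dose_gy, SF} and optionally
#'   \code{sigma}; at least three distinct doses, all SF > 0.
#' @return An [LQModel-class] with the fit covariance.
#' @examples
#' d <- c(0, 2, 4, 6, 8)
#' pts <- data.frame(dose_gy = d, SF = exp(-(0.156 * d + 0.0235 * d^2)))
#' coef(lqFit(pts))
#' @export
lqFit <- function(points) {
  stopifnot(all(c("dose_gy", "SF") %in% names(points)))
  if (any(points$SF <= 0))
    stop("all survival fractions must be positive (log-space fit)")
  if (length(unique(points$dose_gy)) < 3)
    stop("need at least three distinct doses")
  y <- log(points$SF)
  D <- points$dose_gy
  w <- if (!is.null(points$sigma) && all(is.finite(points$sigma)) &&
             all(points$sigma > 0)) {
    (points$SF / points$sigma)^2
  } else rep(1, length(y))
  fit <- stats::lm(y ~ 0 + D + I(D^2), weights = w)
  co <- -stats::coef(fit)
  # noiseless input triggers lm's essentially-perfect-fit warning
  V <- suppressWarnings(stats::vcov(fit))
  dimnames(V) <- list(c("alpha", "beta"), c("alpha", "beta"))
  new("LQModel", coefficients = c(alpha = unname(co[1]),
                                  beta = unname(co[2])), vcov = V)
}

#' Tabulate Caspase3/7-Sytox gating fractions
#'
#' Two-channel gating of already-thresholded per-sample counts:
#' Caspase3/7+ / Sytox+ cells are late apoptotic, Caspase3/7+ / Sytox-
#' early apoptotic, Caspase3/7- / Sytox+ necrotic, and double-negative
#' cells vital. Per sample the four fractions sum to 1; across samples the
#' mean and SEM are reported, together with the derived dead fraction
#' (late apoptotic + necrotic) and the early/late shares among apoptotic
#' cells.
#'
#' @param counts data.frame with columns \code{sample_id},
#'   \code{caspase_pos_sytox_pos}, \code{caspase_pos_sytox_neg},
#'   \code{caspase_neg_sytox_pos}, \code{caspase_neg_sytox_neg}.
#' @return list with \code{per_sample} (fractions per sample),
#'   \code{summary} (data.frame \code{category, mean, sem} over the four
#'   categories plus \code{dead}), and \code{apoptotic_shares}
#'   (\code{early}, \code{late}: shares of the mean apoptotic fraction).
#' @examples
#' # mean fractions early 3.4 % and late 4.5 % give a 43 % early share
#' 0.034 / (0.034 + 0.045)
#' @export
gateFractions <- function(counts) {
  cols <- c(late_apoptotic = "caspase_pos_sytox_pos",
            early_apoptotic = "caspase_pos_sytox_neg",
            necrotic = "caspase_neg_sytox_pos",
            vital = "caspase_neg_sytox_neg")
  if (!all(cols %in% names(counts)))
    stop("counts must have columns ", paste(cols, collapse = ", "))
  if (!nrow(counts)) stop("need at least one sample")
  if (any(unlist(counts[cols]) < 0)) stop("counts must be non-negative")
  totals <- rowSums(counts[cols])
  if (any(totals == 0))
    stop("sample(s) with zero total cells: ",
         paste(counts$sample_id[totals == 0], collapse = ", "))
  fr <- sweep(as.matrix(counts[cols]), 1, totals, "/")
  colnames(fr) <- names(cols)
  per_sample <- data.frame(sample_id = counts$sample_id, fr,
                           stringsAsFactors = FALSE)
  per_sample$dead <- per_sample$late_apoptotic + per_sample$necrotic
  cats <- c(names(cols), "dead")
  n <- nrow(per_sample)
  summary <- data.frame(
    category = cats,
    mean = vapply(cats, function(cl) mean(per_sample[[cl]]), numeric(1)),
    sem = vapply(cats, function(cl)
      if (n > 1) stats::sd(per_sample[[cl]]) / sqrt(n) else 0, numeric(1)),
    row.names = NULL)
  early <- summary$mean[summary$category == "early_apoptotic"]
  late <- summary$mean[summary$category == "late_apoptotic"]
  apo <- early + late
  shares <- if (apo > 0) c(early = early / apo, late = late / apo) else
    c(early = NA_real_, late = NA_real_)
  list(per_sample = per_sample, summary = summary,
       apoptotic_shares = shares)
}
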