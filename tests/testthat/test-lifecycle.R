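mk_series <- function(A, t0, tau, noise = 0, seed = 1,
                      t = seq(5 / 60, 48, by = 0.5)) {
  set.seed(seed)
  n <- LiveCellQuant:::.growth_model(t, A, t0, tau)
  sigma <- pmax(noise * n, 1e-6)
  data.frame(time_h = t, n = n * (1 + rnorm(length(t), 0, noise)),
             sigma = sigma)
}

test_that("count series reproduce the frame-1 composition and normalization", {
  x <- seq_len(56) * 20
  cls <- c(rep("liv", 36), rep("round", 19), "dead")
  v <- cellVideo(data.frame(frame = 1L, x_min = x, y_min = 5,
                            x_max = x + 15, y_max = 20, class = cls,
                            confidence = 1, object_id = NA_character_),
                 imageSize = c(1200, 30))
  cs <- countSeries(v)
  expect_equal(unlist(cs[1, c("N_liv", "N_round", "N_div", "N_dead")],
                      use.names = FALSE), c(36, 19, 0, 1))
  expect_equal(cs$N_total, 56)
  expect_equal(cs$n_total, 1)
  expect_equal(round(cs$n_liv, 2), 0.64)
  expect_equal(cs$sigma_total, sqrt(56) / 56)
})

test_that("a constant video yields constant normalized series", {
  rows <- do.call(rbind, lapply(1:10, function(f)
    box_df(10, 10, 30, 30, frame = f)))
  cs <- countSeries(cellVideo(rows, imageSize = c(50, 50)))
  expect_true(all(cs$n_total == 1))
  expect_true(all(cs$n_vital == 1))
  expect_error(countSeries(cellVideo(NULL, frameIndices = 1:3)),
               "no objects")
})

test_that("the growth model is continuous at the arrest offset", {
  gm <- LiveCellQuant:::.growth_model
  expect_equal(gm(5.8, 0.37, 5.8, 17), 1)
  expect_equal(gm(3, 0.37, 5.8, 17), 1)
  expect_gt(gm(5.81, 0.37, 5.8, 17), 1)
  # continuity from the right
  expect_equal(gm(5.8 + 1e-9, 0.37, 5.8, 17), 1, tolerance = 1e-6)
})

test_that("fitGrowth recovers generating parameters within 3 sigma", {
  s <- mk_series(0.37, 5.8, 17, noise = 0.02, seed = 42)
  fit <- fitGrowth(s)
  p <- coef(fit); se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(p["A"] - 0.37), 3 * se["A"])
  expect_lt(abs(p["t0"] - 5.8), 3 * se["t0"])
  expect_lt(abs(p["tau"] - 17), 3 * se["tau"])
  expect_gt(fit@r2cor, 0.99)
  # band evaluation: exactly 1 before the arrest
  pr <- predictGrowth(fit, c(0, coef(fit)["t0"]))
  expect_equal(pr$n, c(1, 1))
  expect_equal(pr$se, c(0, 0))
})

test_that("repeated noisy fits keep the median tau error under 10 percent", {
  errs <- vapply(1:40, function(i) {
    s <- mk_series(0.37, 5.8, 17, noise = 0.02, seed = 100 + i,
                   t = seq(5 / 60, 48, by = 1))
    abs(coef(fitGrowth(s))["tau"] - 17) / 17
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("a flat series is flagged as a degenerate fit", {
  s <- data.frame(time_h = seq(0, 40, 2), n = 1, sigma = 0.01)
  expect_warning(fit <- fitGrowth(s), "zero|constrained")
  expect_lt(coef(fit)["A"], 0.05)
  expect_error(fitGrowth(s[1:3, ]), "at least 6")
})

test_that("CGSF of identical fits is 1 and shrinks with vanishing noise", {
  s <- mk_series(0.37, 5.8, 17, noise = 0.01, seed = 7)
  fit <- fitGrowth(s)
  r <- cgsf(fit, fit, c(10, 24, 48))
  expect_equal(r$cgsf, rep(1, 3))
  s2 <- mk_series(0.37, 5.8, 17, noise = 0.001, seed = 7)
  r2 <- cgsf(fitGrowth(s2), fitGrowth(s2), 24)
  expect_lt(r2$sigma, r$sigma[2])
  expect_warning(cgsf(fit, fit, 200), "extrapolation")
})

test_that("CGSF declines monotonically when the sham grows faster", {
  mkfit <- function(t0, tau) new("GrowthFit",
    coefficients = c(A = 0.37, t0 = t0, tau = tau),
    vcov = diag(3) * 1e-10, chi2 = 0, r2cor = 1, confLevel = 0.63,
    data = data.frame(time_h = seq(0, 48, 1), n = 1, sigma = 1),
    channel = "vital")
  r <- cgsf(mkfit(5.8, 17), mkfit(5.7, 15.3), seq(6, 48, 0.5))
  expect_true(all(diff(r$cgsf) < 0))
  # the two published growth-curve parameter sets put the ratio of
  # normalized vital counts near 0.92 at 24 h and 0.78 at 48 h
  expect_equal(round(r$cgsf[r$time_h == 24], 2), 0.92)
  expect_equal(round(r$cgsf[r$time_h == 48], 2), 0.78)
})

test_that("raw-series CGSF matches the ratio of normalized vital counts", {
  sham <- countSeries(simulatePopulation(simConfig(n_initial = 20,
                                                   duration_h = 12,
                                                   seed = 3))$video)
  irr <- countSeries(simulatePopulation(irradiatedConfig(n_initial = 20,
                                                         duration_h = 12,
                                                         seed = 4))$video)
  r <- cgsf(irr, sham, 10, method = "raw")
  i <- which.min(abs(irr$time_h - 10))
  expect_equal(r$cgsf, irr$n_vital[i] / sham$n_vital[i])
})

test_that("division census equals a hand enumeration on a built lineage", {
  # founder a: chain to depth 4 on one branch; founder b: one division;
  # founder c: none
  lin <- data.frame(
    cell_id = c("a", "b", "c", "a1", "a2", "b1", "b2", "a11", "a12",
                "a111", "a112", "a1111", "a1112"),
    parent_id = c(NA, NA, NA, "a", "a", "b", "b", "a1", "a1", "a11",
                  "a11", "a111", "a111"),
    generation = c(0, 0, 0, 1, 1, 1, 1, 2, 2, 3, 3, 4, 4),
    birth_min = c(0, 0, 0, 700, 700, 800, 800, 1400, 1400, 2100, 2100,
                  2800, 2800),
    death_min = NA_real_,
    division_min = c(700, 800, NA, 1400, NA, NA, NA, 2100, NA, 2800, NA,
                     NA, NA))
  census <- divisionCensus(lin)
  expect_equal(census$per_founder$divisions[
    match(c("a", "b", "c"), census$per_founder$founder_id)], c(4, 1, 0))
  expect_equal(census$total_divisions, 5)
  expect_equal(census$histogram$n_founders, c(1, 1, 0, 0, 1))
  # 24 h window cuts the depth-4 branch
  c24 <- divisionCensus(lin, window_h = 24)
  expect_equal(max(c24$per_founder$divisions), 2)
  orphan <- lin; orphan$parent_id[4] <- "zz"
  expect_error(divisionCensus(orphan), "lineage error")
})

test_that("every dead cell is counted exactly once", {
  # one cell dies at frame 3 and persists to frame 100
  rows <- do.call(rbind, lapply(1:100, function(f) rbind(
    box_df(10, 10, 30, 30, class = if (f >= 3) "dead" else "liv",
           frame = f),
    box_df(60, 60, 85, 85, class = "liv", frame = f))))
  v <- cellVideo(rows, imageSize = c(120, 120))
  cen <- deadCellCensus(v, window_h = 24, link_iou = 0.5)
  expect_equal(cen$k, 1L)
  expect_equal(cen$N, 2L)
  expect_equal(cen$sigma, sqrt(1) / 2)
  # no dead boxes at all
  alive <- cellVideo(box_df(1, 1, 5, 5), imageSize = c(10, 10))
  cen0 <- deadCellCensus(alive)
  expect_equal(cen0$k, 0L)
  expect_equal(cen0$fraction, 0)
  expect_error(deadCellCensus(v, link_iou = 0), "0, 1")
})

test_that("the dead census is idempotent and robust to frame subsampling", {
  sim <- simulatePopulation(simConfig(n_initial = 25, duration_h = 24,
                                      death_hazard_per_h = 0.006,
                                      seed = 13))
  v <- sim$video
  full <- deadCellCensus(v, 24)
  expect_identical(deadCellCensus(v, 24), full)
  expect_gt(full$k, 0)
  # drop the ids to exercise IoU linking; k must agree with the id-based
  # census (dead boxes do not move)
  noid <- videoObjects(v); noid$object_id <- NA_character_
  v2 <- cellVideo(noid, frameIndices = frameIndices(v),
                  imageSize = imageSize(v))
  expect_equal(deadCellCensus(v2, 24)$k, full$k)
  # keep every 4th frame: tracks persist, so k is unchanged
  keep <- frameIndices(v)[frameIndices(v) %% 4 == 0]
  sub <- cellVideo(noid[noid$frame %in% keep, ], frameIndices = keep,
                   imageSize = imageSize(v))
  expect_equal(deadCellCensus(sub, 24)$k, full$k)
})

test_that("count totals agree with simulator lineage bookkeeping", {
  sim <- simulatePopulation(simConfig(n_initial = 18, duration_h = 30,
                                      seed = 21))
  cs <- countSeries(sim$video)
  lin <- sim$lineage
  at <- function(t) sum(lin$birth_min <= t) -
    sum(!is.na(lin$division_min) & lin$division_min <= t)
  expect_equal(cs$N_total, vapply(cs$time_min, at, numeric(1)))
})
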