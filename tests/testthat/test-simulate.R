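small_cfg <- function(seed = 5, ...) {
  simConfig(n_initial = 15, duration_h = 24, seed = seed, ...)
}

test_that("the same seed reproduces the simulation bit for bit", {
  a <- simulatePopulation(small_cfg())
  b <- simulatePopulation(small_cfg())
  expect_identical(videoObjects(a$video), videoObjects(b$video))
  expect_identical(a$lineage, b$lineage)
  c <- simulatePopulation(small_cfg(seed = 6))
  expect_false(identical(videoObjects(a$video), videoObjects(c$video)))
})

test_that("nothing happens before the arrest offset", {
  sim <- simulatePopulation(simConfig(n_initial = 12, duration_h = 5,
                                      arrest_h = 6, seed = 2))
  cs <- countSeries(sim$video)
  expect_true(all(cs$N_total == 12))
  expect_true(all(cs$N_liv == cs$N_liv[1]))
  expect_equal(sum(!is.na(sim$lineage$division_min)), 0)
})

test_that("population bookkeeping is conserved frame by frame", {
  sim <- simulatePopulation(small_cfg(death_hazard_per_h = 0.01))
  cs <- countSeries(sim$video)
  # vital + dead = total, and the total never decreases
  expect_equal(cs$N_vital + cs$N_dead, cs$N_total)
  expect_true(all(diff(cs$N_total) >= 0))
  # each division adds exactly one cell: total = founders + divisions so far
  div_times <- sort(sim$lineage$division_min[
    !is.na(sim$lineage$division_min)])
  expected <- 15 + vapply(cs$time_min, function(t) sum(div_times <= t),
                          numeric(1))
  expect_equal(cs$N_total, expected)
  # every division event shows up as a div-labelled transient appearance
  obj <- videoObjects(sim$video)
  div_ids <- unique(obj$object_id[obj$class == "div"])
  expect_equal(length(div_ids), length(div_times))
  # lineage self-consistency
  lin <- sim$lineage
  both <- !is.na(lin$death_min)
  expect_true(all(lin$birth_min[both] < lin$death_min[both]))
})

test_that("founders reach three and at most four divisions over 48 h", {
  sim <- simulatePopulation(simConfig(n_initial = 20, duration_h = 48,
                                      death_hazard_per_h = 0,
                                      frac_nondividing = 0, seed = 10))
  census <- divisionCensus(sim$lineage)
  expect_lte(max(census$per_founder$divisions), 4)
  expect_gte(max(census$per_founder$divisions), 3)
})

test_that("an irradiated-style population grows slower than a sham one", {
  sham <- simulatePopulation(simConfig(n_initial = 25, seed = 3))
  irr <- simulatePopulation(irradiatedConfig(n_initial = 25, seed = 4))
  gs <- tail(countSeries(sham$video)$n_total, 1)
  gi <- tail(countSeries(irr$video)$n_total, 1)
  expect_lt(gi / gs, 1)
})

test_that("impossible configurations are rejected", {
  expect_error(simConfig(field_size = c(3, 3), n_initial = 100),
               "too small")
  expect_error(simConfig(cycle_h = c(16, 12)), "range")
  expect_error(simConfig(frac_nondividing = 1.2), "0, 1")
  expect_error(simConfig(round_duration_min = 600, div_duration_min = 200),
               "dwell")
})

test_that("zero noise returns the truth (with sampled confidences)", {
  sim <- simulatePopulation(simConfig(n_initial = 10, duration_h = 2,
                                      seed = 8))
  pred <- applyDetectorNoise(sim$video, identityNoiseConfig(seed = 1))
  tr <- videoObjects(sim$video)
  pr <- videoObjects(pred)
  key <- function(d) d[order(d$frame, d$x_min, d$y_min),
                       c("frame", "x_min", "y_min", "x_max", "y_max",
                         "class", "object_id")]
  expect_equal(key(pr), key(tr), ignore_attr = TRUE)
  expect_true(all(pr$confidence >= 0 & pr$confidence <= 1))
})

test_that("the detection cap truncates a crowded frame to 100 objects", {
  x <- rep(seq(0, 139) * 9.5, length.out = 150)
  y <- rep(seq_len(15) * 60, each = 10)[1:150]
  crowd <- cellVideo(data.frame(frame = 1L, x_min = x, y_min = y,
                                x_max = x + 8, y_max = y + 8,
                                class = "liv", confidence = 1,
                                object_id = as.character(1:150)),
                     imageSize = c(1400, 1000))
  pred <- applyDetectorNoise(crowd,
                             noiseConfig(miss_prob = 0, spurious_rate = 0,
                                         jitter_sd_px = 0,
                                         confusion = diag(4), nms_iou = 1,
                                         seed = 3))
  expect_equal(nrow(videoObjects(pred)), 100L)
})

test_that("class confusion relabels at the configured rate", {
  # 60 frames x 40 round cells, P(round -> liv) = 0.2
  n <- 40
  x <- seq_len(n) * 25
  rows <- do.call(rbind, lapply(1:60, function(f)
    data.frame(frame = f, x_min = x, y_min = 100, x_max = x + 18,
               y_max = 118, class = "round", confidence = 1,
               object_id = as.character(seq_len(n)))))
  v <- cellVideo(rows, imageSize = c(1100, 300))
  conf <- diag(4); conf[2, 1] <- 0.2; conf[2, 2] <- 0.8
  pred <- applyDetectorNoise(v, noiseConfig(miss_prob = 0,
                                            spurious_rate = 0,
                                            jitter_sd_px = 0,
                                            confusion = conf, nms_iou = 1,
                                            seed = 11))
  pr <- videoObjects(pred)
  frac <- mean(pr$class == "liv")
  m <- nrow(pr)
  # binomial oracle: 3 sigma band around 0.2
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / m))
  expect_true(all(pr$class %in% c("liv", "round")))
  # determinism of the noise channel
  pred2 <- applyDetectorNoise(v, noiseConfig(miss_prob = 0,
                                             spurious_rate = 0,
                                             jitter_sd_px = 0,
                                             confusion = conf, nms_iou = 1,
                                             seed = 11))
  expect_identical(videoObjects(pred2), pr)
})

test_that("noise configuration invariants are enforced", {
  bad <- diag(4); bad[1, 1] <- 0.5
  expect_error(noiseConfig(confusion = bad), "row-stochastic")
  expect_error(noiseConfig(miss_prob = -0.1), "0, 1")
  expect_error(noiseConfig(nms_iou = 0), "0, 1")
})
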