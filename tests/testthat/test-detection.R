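perfect_frame <- function() {
  x <- c(0, 30, 60, 90, 120, 150, 180, 210, 240, 270, 300, 330)
  data.frame(frame = 1L, x_min = x, y_min = 10, x_max = x + 22,
             y_max = 34,
             class = rep(c("liv", "liv", "liv", "round", "round", "div",
                           "dead", "liv", "round", "div", "dead", "liv")),
             confidence = 1, object_id = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("matching a frame against itself leaves no FP or FN", {
  f <- perfect_frame()
  for (thr in c(0.3, 0.5, 0.95, 1)) {
    m <- matchFrame(f, f, thr)
    expect_equal(nrow(m$pairs), nrow(f))
    expect_length(m$unmatched_gt, 0)
    expect_length(m$unmatched_pred, 0)
    expect_true(all(m$pairs$iou == 1))
  }
})

test_that("empty predictions give only false negatives", {
  f <- perfect_frame()
  empty <- f[0, ]
  m <- matchFrame(f, empty, 0.5)
  expect_length(m$unmatched_gt, nrow(f))
  expect_length(m$unmatched_pred, 0)
  expect_error(matchFrame(f, f, 0), "0, 1")
})

test_that("greedy matching equals exhaustive enumeration on small frames", {
  set.seed(23)
  for (i in 1:30) {
    ng <- sample(1:5, 1); np <- sample(1:5, 1)
    gx <- runif(ng, 0, 60); gy <- runif(ng, 0, 60)
    gt <- data.frame(frame = 1L, x_min = gx, y_min = gy,
                     x_max = gx + runif(ng, 15, 30),
                     y_max = gy + runif(ng, 15, 30),
                     class = sample(c("liv", "round"), ng, TRUE),
                     confidence = 1, object_id = NA_character_)
    px <- runif(np, 0, 60); py <- runif(np, 0, 60)
    pred <- data.frame(frame = 1L, x_min = px, y_min = py,
                       x_max = px + runif(np, 15, 30),
                       y_max = py + runif(np, 15, 30),
                       class = sample(c("liv", "round"), np, TRUE),
                       confidence = round(runif(np), 3),
                       object_id = NA_character_)
    for (aware in c(TRUE, FALSE)) {
      got <- matchFrame(gt, pred, 0.2, class_aware = aware)$pairs
      want <- brute_match(gt, pred, 0.2, class_aware = aware)
      expect_equal(got[order(got$pred_idx), c("gt_idx", "pred_idx")],
                   want, ignore_attr = TRUE,
                   info = sprintf("case %d aware %s", i, aware))
    }
  }
})

test_that("classification scores follow the precision/recall/F1 identities", {
  # harmonic-mean identity and the published per-class arithmetic
  expect_equal(f1Score(0.5, 0.5), 0.5)
  expect_equal(round(f1Score(0.90, 0.98), 2), 0.94)
  # cross-class matches count against both classes
  gt <- perfect_frame()[1:2, ]          # two liv
  pred <- gt
  pred$class <- c("liv", "round")       # one relabelled
  cs <- classificationScores(matchFrame(gt, pred, 0.5,
                                        class_aware = FALSE))
  expect_equal(cs$confusion["liv", "liv"], 1L)
  expect_equal(cs$confusion["liv", "round"], 1L)
  expect_equal(cs$scores["liv", "TP"], 1)
  expect_equal(cs$scores["liv", "FN"], 1)
  expect_equal(cs$scores["round", "FP"], 1)
  expect_equal(cs$scores["liv", "precision"], 1)     # 1 TP, 0 FP
  expect_equal(cs$scores["liv", "recall"], 0.5)
  # round has no GT: recall undefined, reported absent
  expect_true(is.na(cs$scores["round", "recall"]))
  expect_equal(cs$scores["round", "precision"], 0)
})

test_that("AP reproduces hand-enumerated precision-recall areas", {
  gt <- perfect_frame()[1, , drop = FALSE]            # 1 liv object
  hit <- gt; hit$confidence <- 0.9
  miss <- gt; miss$x_min <- 200; miss$x_max <- 222; miss$confidence <- 0.8
  # top-confidence prediction is the TP -> AP 1
  expect_equal(averagePrecision(gt, rbind(hit, miss), "liv", 0.5)$ap, 1)
  # top-confidence prediction is the FP -> PR points (0,0),(1,0.5) -> 0.5
  miss$confidence <- 0.95
  expect_equal(averagePrecision(gt, rbind(hit, miss), "liv", 0.5)$ap, 0.5)
  # no predictions at all -> AP 0; absent class -> NA
  expect_equal(averagePrecision(gt, gt[0, ], "liv", 0.5)$ap, 0)
  expect_true(is.na(averagePrecision(gt, hit, "div", 0.5)$ap))
  # perfect predictions -> AP 1 in both interpolation schemes
  f <- perfect_frame()
  expect_equal(averagePrecision(f, f, "liv", 0.5, "11point")$ap, 1)
})

test_that("the IoU sweep counts thresholds a jittered box passes", {
  # 20x20 boxes shifted so IoU = 14.6/25.4 = 0.5748 for every object:
  # AP 1 at thresholds 0.50, 0.55 and 0 above -> ap_bar = 2/10
  x <- c(0, 40, 80, 120)
  gt <- data.frame(frame = 1L, x_min = x, y_min = 0, x_max = x + 20,
                   y_max = 20, class = "liv", confidence = 1,
                   object_id = NA_character_)
  pred <- gt
  pred$x_min <- pred$x_min + 5.4; pred$x_max <- pred$x_max + 5.4
  iou <- boxIoU(gt[1, ], pred[1, ])
  expect_true(iou > 0.55 && iou < 0.60)
  expect_equal(apBar(gt, pred, "liv"), 0.2)
  expect_true(is.na(apBar(gt, pred, "round")))
  expect_equal(apBar(gt, gt, "liv"), 1)
})

test_that("AP never increases when the IoU bar is raised", {
  set.seed(77)
  sim <- simulatePopulation(simConfig(n_initial = 15, duration_h = 4,
                                      seed = 19))
  pred <- applyDetectorNoise(sim$video, noiseConfig(jitter_sd_px = 2,
                                                    miss_prob = 0.1,
                                                    spurious_rate = 1,
                                                    seed = 20))
  for (cl in c("liv", "round")) {
    aps <- vapply(seq(0.5, 0.95, 0.05), function(th)
      averagePrecision(sim$video, pred, cl, th)$ap, numeric(1))
    aps <- aps[!is.na(aps)]
    if (length(aps) > 1) expect_true(all(diff(aps) <= 1e-12))
  }
})

test_that("mAP is 100 for truth vs truth and 0 for permuted classes", {
  f <- perfect_frame()
  expect_equal(mapScore(f, f), 100)
  swap <- f
  swap$class <- c(liv = "round", round = "div", div = "dead",
                  dead = "liv")[f$class]
  expect_equal(mapScore(f, swap), 0)
  # two classes with ap_bar 1.0 and 0.5 average to 75 percent
  gt2 <- f[f$class %in% c("liv", "div"), ]
  gt2 <- gt2[c(which(gt2$class == "liv"), which(gt2$class == "div")[1]), ]
  pred2 <- gt2
  fp <- gt2[gt2$class == "div", ][1, ]
  fp$x_min <- 500; fp$x_max <- 522; fp$confidence <- 0.99
  pred2$confidence[pred2$class == "div"] <- 0.5
  expect_equal(mapScore(gt2, rbind(pred2, fp)), 75)
  expect_error(mapScore(f[0, ], f[0, ]), "no ground-truth")
})

test_that("absent classes can be excluded or scored zero", {
  f <- perfect_frame()
  liv_only <- f[f$class == "liv", ]
  expect_equal(mapScore(liv_only, liv_only, absent_class = "exclude"), 100)
  expect_equal(mapScore(liv_only, liv_only, absent_class = "zero"), 25)
})

test_that("the per-frame series carries scores, times and counts", {
  sim <- simulatePopulation(simConfig(n_initial = 10, duration_h = 1,
                                      seed = 29))
  ev <- mapScore(sim$video, sim$video, scope = "frame")
  expect_equal(nrow(ev), nFrames(sim$video))
  expect_true(all(ev$map == 100))
  expect_equal(ev$time_min, frameTimes(sim$video))
  expect_equal(ev$gt_liv, videoObjects(sim$video)$frame |>
                 table() |> as.integer())
})
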