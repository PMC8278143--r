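# LiveCellQuant

Quantitative analysis of cell populations from per-frame bounding-box
annotations of live-cell phase-contrast videos, for radiobiology and
live-cell imaging labs that follow cells for days after a treatment
instead of reading out a single fixed timepoint.

Each cell in a frame is a rectangular box tagged with one of four
morphology classes — `liv` (attached living cell), `round` (detached
mitotic cell), `div` (separating cell pair), `dead` — where
`liv + round + div` are the vital classes and the allowed transitions form
the cycle liv → round → div → two daughters, with death absorbing from any
vital state. From sequences of such frames the package computes:

* **Detection quality** of a predicted annotation against ground truth:
  IoU, greedy confidence-ordered matching, non-maximum suppression,
  per-class precision/recall/F1 and confusion matrix, average precision
  AP, its mean over the IoU sweep 0.50:0.05:0.95
  ($\overline{AP}$), and the mean over classes (mAP, in percent), pooled
  or as a per-frame time series.
* **Growth and survival endpoints**: class-count series with Poisson
  errors, the piecewise offset-exponential growth model
  $n(t) = 1$ for $t \le t_0$, $n(t) = (1-A) + A\,e^{(t-t_0)/\tau}$ for
  $t > t_0$ (weighted least squares, covariance, confidence band), and
  the cell-growth-defined survival fraction
  $\mathrm{CGSF}(t) = n_{irr}(t)/n_{sham}(t)$.
* **Death endpoints**: a unique-dead-cell census (dead boxes tracked so
  each death is counted once, fraction $k/N \pm \sqrt{k}/N$), a
  divisions-per-founder census from lineage records, and Caspase3/7–Sytox
  gating tabulation (early/late apoptotic, necrotic, vital).
* **Conventional-assay computations**: plating efficiency, survival
  fraction with Gaussian error propagation
  $\Delta SF = SF\sqrt{(\Delta PE/PE)^2+(\Delta PE_0/PE_0)^2}$, and the
  linear-quadratic model $SF(D) = e^{-(\alpha D + \beta D^2)}$ (closed-form
  evaluation and log-space weighted fit).
* **Synthetic ground truth**: an agent-based lifecycle simulator
  (asynchronous founders, 12–16 h cycles, handling-stress arrest,
  configurable death hazard and division failure; full lineage returned)
  and a detector emulator (misses, jitter, class confusion, spurious
  boxes, NMS, a 100-object cap) standing in for a trained network.

Annotations are read and written in VIA region-JSON, COCO-style detection
JSON and CSV.

## Worked example

Simulate a sham and an irradiated sample under the default study
conditions (48 h at 5-min frames), fit their growth, and compare:

```r
library(LiveCellQuant)

sham <- simulatePopulation(simConfig(seed = 1, sample_id = "sham"))
irr  <- simulatePopulation(irradiatedConfig(seed = 2))

cs <- countSeries(sham$video)
ci <- countSeries(irr$video)
tail(cs$n_total, 1)   # 6.68  -- sham grows ~6.7-fold in 48 h
tail(ci$n_total, 1)   # 4     -- irradiated growth is clearly reduced

fs <- fitGrowth(cs, channel = "vital")
fs
#> Offset-exponential growth fit (vital cells)
#>   A   = 1.3 +/- 0.021
#>   t0  = 5.66 +/- 0.077 h
#>   tau = 25.7 +/- 0.18 h
#>   chi2 = 25.7, corrected R2 = 0.9989, 576 points

fi <- fitGrowth(ci, channel = "vital")
cgsf(fi, fs, c(24, 48))
#>   time_h      cgsf       sigma
#> 1     24 0.7625078 0.001649272
#> 2     48 0.5510558 0.001696440
```

The fitted arrest offset `t0` recovers the configured ~5.7 h handling
arrest; the CGSF column is the growth-defined survival fraction of the
irradiated population relative to sham at 24 h and 48 h, with
uncertainties propagated from the two fits' confidence bands.

Divisions per founder and unique dead cells come from the simulator's
lineage and the dead-box tracker:

```r
divisionCensus(sham$lineage)$histogram
#>   divisions n_founders
#> 1         0          3
#> 2         1          3
#> 3         2          0
#> 4         3         37
#> 5         4          7

deadCellCensus(irr$video, window_h = 24)[c("k", "N", "fraction", "sigma")]
#> $k: 7   $N: 142   $fraction: 0.0493   $sigma: 0.0186
```

With a 12–16 h cycle most founders reach three divisions in 48 h and a
few reach four; about 5 % of irradiated cells die within 24 h, with the
Poisson error `sqrt(k)/N`.

Emulate an imperfect detector and score it:

```r
pred <- applyDetectorNoise(sham$video, noiseConfig(seed = 3))
mapScore(sham$video, pred)      # 53.03709 (percent, pooled over 48 h)
```

The pooled score over the whole video is pulled down by late frames,
where the population has outgrown the emulator's 100-object detection
cap; restricted to frames under the cap the same noise level scores above
90 %, which is the regime a well-trained detector reaches. A per-frame
time series (`mapScore(..., scope = "frame")`) makes that collapse
visible.

The end-to-end pipeline (simulate → perturb → evaluate → lifecycle →
survival/gating → report) is one call — `runPipeline(runConfig(...))` —
or, from a shell, `Rscript inst/scripts/run-pipeline.R --config run.yaml
--seed 1 --out results/`.

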