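---
title: "Quantifying cell lifecycles from annotated phase-contrast videos"
author: "LiveCellQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell lifecycles from annotated phase-contrast videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LiveCellQuant)
```

## The problem

Label-free live-cell phase-contrast imaging lets a radiobiology experiment
follow every cell of a population for days after treatment without fixing,
staining or transferring anything. The price is an analysis problem: each
frame holds tens to hundreds of low-contrast cells whose morphology changes
through the cell cycle. A practical representation is a rectangular
bounding box per cell, tagged with one of four morphology classes:

* **liv** — attached, flat "fried-egg" living cell;
* **round** — detached, high-edge-contrast mitotic cell;
* **div** — a cell pair in the act of separating;
* **dead** — dark, blebbing dead cell.

`liv`, `round` and `div` together are the *vital* classes. The allowed
transitions form a cycle (liv → round → div → two liv daughters), with
death possible from any vital state and absorbing.

Whether the boxes come from a human annotator or from a deep-learning
detector, the downstream questions are the same: how well do predicted
boxes agree with ground truth, how does the population grow, how many cells
divide and die, and how do these endpoints compare with the conventional
colony-forming and Caspase3/7–Sytox assays. `LiveCellQuant` implements
that entire analysis chain, plus an agent-based simulator that generates
ground-truth videos with known lineage so every estimator in the package
can be validated against a known answer.

## The data model

A `CellVideo` holds one video's labelled boxes: 0-based, half-open pixel
coordinates (`[x_min, x_max) × [y_min, y_max)`, x right, y down), a class,
a confidence in [0, 1] (ground truth carries 1, so one matching code path
serves ground-truth-vs-prediction and ground-truth-vs-ground-truth
comparisons), and an optional stable object id. Frame `k` is acquired at
`k × frameInterval` minutes — frame 1 is the 5-minute timepoint at the
default 5-minute cadence. Readers and writers cover the VIA region-JSON
export (rectangles with a class tag; tags are matched case-insensitively
against `liv/living, round, div/dividing, dead`), COCO-style detection
JSON (`bbox = [x, y, w, h]`, categories 1–4 in the order liv, round, div,
dead, `score` as confidence), and a flat CSV. Unknown tags and
non-rectangular regions are errors that name the offending record — bad
annotations must never vanish silently. The exact VIA dialect in the wild
varies; the reader targets the standard region-attribute export and also
tolerates full project files.

## The simulator: what it emulates, and what it does not

`simulatePopulation()` advances agents frame by frame. Defaults describe
the study conditions the package is built around: a CHO-K1-like epithelial
population imaged every 5 min for 48 h in a 1388 × 1040 px field,
starting from about 50 asynchronous founders; cell-cycle times drawn
uniformly from 12–16 h; a handling-stress arrest of ≈5.7 h during which
every agent holds its state (the observed initial plateau of constant cell
numbers); dwell times of 30 min in `round` and 15 min in `div` (the data
motivating this package do not constrain these, so they are configuration
with documented defaults); a small exponential death hazard (0.002/h,
matching a few percent of deaths per day) and a small permanently
non-dividing fraction. Irradiation is expressed *purely through
configuration* — `irradiatedConfig()` lengthens the arrest, slows the
cycle (13–17.5 h), raises the hazard and the non-dividing fraction, and
adds a per-cycle division-failure probability — no dose–response law is
invented. With these presets the sham population grows ≈6.4-fold and the
irradiated one ≈4.2–4.7-fold over 48 h, the observed contrast for 4 Gy
protons.

Two structural choices matter for the bookkeeping invariants:

* a cell that will not divide decides so *before* entering `round`, so
  every `div` appearance corresponds to exactly one lineage division
  event, under every configuration;
* a division replaces one agent by two daughters, so the total count
  increases by exactly one per division and never decreases (dead boxes
  persist, motionless, to the end of the video).

The simulator does **not** render pixel textures, does not model cell
crowding beyond allowing box overlap, ignores contact inhibition and
density-dependent growth slowing, and draws box sizes from simple
truncated normal distributions. Tests that pass on simulated data
therefore validate the *estimators* (given correct boxes, the metrics are
right); they say nothing about how hard real phase-contrast pixels are to
detect.

## The detector emulator

`applyDetectorNoise()` reproduces the failure modes of a two-stage
detection network without any learning: per-object misses, Gaussian corner
jitter, class confusion sampled from a row-stochastic 4 × 4 matrix,
spurious boxes at a Poisson rate, greedy class-agnostic non-maximum
suppression, and a hard cap (default 100) on detections per frame —
pretrained detection backbones commonly cap at 100 objects, which is why
crowded late-video frames lose cells wholesale. Default rates (2 % miss,
0.5 px jitter, 5 % round→liv confusion — the dominant error direction for
this morphology pair — and 0.2 spurious boxes/frame) put the emulator in
the "well-trained detector" regime of >90 % mAP on frames below the cap;
every rate is tunable to probe degradation.

## Detection scoring

`matchFrame()` follows the standard detection-metric convention: greedy
one-to-one assignment visiting predictions in decreasing confidence (ties
by input order), each taking the unmatched ground-truth box of highest IoU
at or above the threshold; ties in IoU go to the lower ground-truth index.
For frames of up to five objects the tests verify greedy assignment
against exhaustive enumeration.

`averagePrecision()` pools per-frame matches, sorts by confidence and
integrates the precision–recall curve. Two interpolation schemes are
implemented behind a switch: the all-point *precision-envelope* area
(default — consistent with the COCO lineage of the detectors this
emulates) and classic 11-point interpolation. `apBar()` averages AP over
IoU 0.50–0.95 in steps of 0.05; `mapScore()` averages over classes and
reports percent.

Classes with no ground-truth instance in the evaluation scope are
**excluded** from the mAP mean rather than scored zero (most frames
contain no `div` cell, and a structural zero would dominate a 4-class
mean); `absent_class = "zero"` provides the other convention. This
exclusion is an interpretation — near-100 % per-frame scores on div-free
frames are only consistent with it — and is therefore a documented switch
rather than a hard-coded rule.

`classificationScores()` serves the complementary classifier view: a
confusion matrix over class-agnostic matches, with cross-class matches
counted as a false positive of the predicted class and a false negative of
the true class. A precision or recall whose denominator is zero is
reported `NA`, never 0.

## Growth model and fitting

Normalized counts `n(t) = N(t)/N(t₁)` are fitted with the
piecewise-continuous offset-exponential

$$n(t) = \begin{cases} 1 & t \le t_0 \\ (1-A) + A\,e^{(t-t_0)/\tau} & t > t_0 \end{cases}$$

with amplitude $A$, arrest offset $t_0$ (h) and growth constant $\tau$
(h); the model is continuous with $n(t_0) = 1$. Points before the arrest
are fitted against the constant branch — they carry real information about
$t_0$, which is why the piecewise form is used rather than fitting only
`t > t0`. Fitting is weighted least squares (Levenberg–Marquardt via
`minpack.lm`), weights $1/\sigma^2$ from Poisson counting errors
$\sigma(n) = \sqrt{N}/N_0$. The fit reports the parameter covariance,
weighted $\chi^2$, corrected $R^2$, and a pointwise confidence band at a
configurable level (default 0.63) from linearized (delta-method)
propagation; for very short series a second start is tried, and an
essentially flat series is returned as a flagged degenerate fit
($A \approx 0$, wide $t_0/\tau$ uncertainties) rather than an error.

The cell-growth-defined survival fraction is the ratio of normalized
vital counts, irradiated over sham, at a chosen time:
$\mathrm{CGSF}(t) = n_{irr}(t)/n_{sham}(t)$. Whether such ratios are best
taken from the fitted curves or from the raw series is ambiguous in
practice, so `cgsf()` provides both (`method = "fit"` / `"raw"`). The
uncertainty assumes independence of the two samples (separate wells):
$\sigma = \mathrm{CGSF}\sqrt{(\sigma_i/n_i)^2 + (\sigma_s/n_s)^2}$.
Evaluation beyond twice the fitted range warns about extrapolation.

## Division and death censuses

`divisionCensus()` reports, per founder, the maximum number of divisions
along any descendant chain inside the window (four divisions ⇒ a
fifth-generation descendant exists), the histogram over founders, and
cumulative division events over time.

`deadCellCensus()` counts every dead cell exactly once: dead boxes are
linked frame to frame by object id when present, else by IoU against each
open track's last box (dead boxes do not move, so linking survives frame
subsampling). The denominator $N$ is the number of distinct cells observed
in the window — distinct ids when available, else the first-frame total
plus division events inferred from increments of the total count, a
documented approximation. The fraction $k/N$ carries the Poisson error
$\sqrt{k}/N$; note that published dead-cell fractions quoted with slightly
smaller errors than $\sqrt{k}/N$ cannot be reproduced from that formula,
and the package reports $\sqrt{k}/N$ as specified.

## Conventional-assay computations

Plating efficiency is colonies (≥50 cells, a data-entry contract) per
seeded cell; the survival fraction is the sample PE over the mean control
PE, with Gaussian propagation
$\Delta SF = SF\sqrt{(\Delta PE/PE)^2 + (\Delta PE_0/PE_0)^2}$. The
control uncertainty is a SEM, so at least two control samples are
required; an unreplicated sample's $\Delta PE$ falls back to the binomial
$\sqrt{PE(1-PE)/\text{seeded}}$, since the error source of unreplicated
published values is generally unstated.

The linear-quadratic dose response $SF(D) = e^{-(\alpha D + \beta D^2)}$
is fitted in log space, where it is exactly linear in $\alpha$ and
$\beta$; weights transform as $\sigma_{\ln SF} = \sigma_{SF}/SF$, and
non-negativity is deliberately not enforced. Noiseless points are
recovered to solver tolerance (the tests assert 1e-9).

Caspase3/7–Sytox gating starts from already-thresholded ± calls (no FCS
parsing): C+S+ late apoptotic, C+S− early apoptotic, C−S+ necrotic, C−S−
vital; per-sample fractions always sum to 1, means and SEMs are taken
across samples, dead = late apoptotic + necrotic, and early/late shares
among apoptotic cells are derived.

## Numerical choices and test scale

* IoU thresholds live in (0, 1]; a threshold of exactly 1 only matches
  identical boxes.
* NMS and matching break confidence ties by input order; matching breaks
  IoU ties toward the lower ground-truth index.
* The per-frame mAP regime check in the test suite uses the mean of the
  per-frame series, the same statistic used to summarize per-frame scores
  on real videos, because any nonzero miss rate occasionally zeroes the
  sole instance of a rare class in a single frame.
* Test problem sizes are the package's own choice for a fast, convincing
  suite: simulations of 10–25 founders over 2–48 h, growth-fit recovery on
  100 replicates of ~100-point series at 2 % noise, exhaustive-matching
  oracles up to 5 objects per frame. The full-scale defaults (50 founders,
  576 frames) run in about a second each.

## A complete run

```{r pipeline, eval = FALSE}
cfg <- runConfig(out_dir = "demo_run", seed = 1)
res <- runPipeline(cfg)
res$cgsf                    # CGSF table with propagated uncertainties
res$fits$sham               # offset-exponential fit of the sham sample
head(res$eval[[1]])         # per-frame detection scores
```

The bundle contains the truth and predicted annotations, per-frame
evaluation CSVs, count-series CSVs, a growth-fit report, the CGSF table
and a run log with the seed and configuration hash; rerunning with the
same configuration reproduces every file byte for byte.

## Limitations

* No multi-object tracking of vital cells: linking is implemented only
  for the dead-cell census, where static boxes make it reliable. Family
  trees of real (non-simulated) videos are out of reach until a tracker
  exists.
* The simulator's realism gaps (no crowding effects, no density-dependent
  growth, schematic box geometry) mean emulator-based mAP figures
  characterize the metrics, not any real detector.
* CGSF is a proliferation surrogate for clonogenic survival; the two
  agree only when populations grow exponentially and enough divisions are
  observed.
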