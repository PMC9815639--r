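---
title: "Pen-level early warning of tail-biting outbreaks from feeder records"
author: "tailbitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pen-level early warning of tail-biting outbreaks from feeder records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tail biting (TB) is a damaging cannibalistic behaviour of group-housed pigs.
An outbreak is costly and painful, but it announces itself: feeding behaviour
in the affected pen changes weeks before the first pig needs treatment.
Pens fitted with single-space electronic feeders already record, for every
feeder visit, the pig's identity, entry and exit times, and the grams
consumed. `tailbitr` turns those event logs into a pen-level early-warning
analysis: it frames daily feeding behaviour into fixed-size sliding windows,
labels each window by its position relative to the outbreak date, and
benchmarks standard classifiers on their ability to flag the pre-outbreak
period — under two train/test regimes that differ in how much the model is
allowed to know about the pen it predicts for.

The unit of prediction is the **pen** (pigs sharing feeders), not the
individual pig. A pen is **TB** when at least one pig had to be treated for
tail damage; **day 0** (the TB date) is the day of the first treatment.
Control (CTL) pens never had an outbreak.

## From visits to observations

Three per-pig per-day observation variables summarize each day
(00:00–23:59:59, a visit belongs to the day of its entry time):

* **DFV** — number of feeder visits (count);
* **DFC** — total feed consumed (g);
* **StdFC** — sample standard deviation of the per-visit intakes that day
  (g), undefined when the pig visited fewer than twice.

Two deliberate conventions, where the field's practice is not settled:

* *StdFC with fewer than two visits is missing, not zero* — a single visit
  carries no dispersion information; the missing cell is later median-imputed
  like any sensor gap.
* *Present-with-zero-visits is an observation; absent is missing.* The pig
  roster decides: a day inside a pig's roster interval with no visits is a
  real `(0, 0, NA)` observation, while days outside the roster produce no
  row and surface as missing window cells. Real exports that cannot
  distinguish the two can encode everything as roster presence.

## The analysis window

The classifier never sees single days. Observations are framed into an
**analysis window**: `window_days` consecutive days (default 14) × a fixed
number of pig slots (default 10) × the three variables — 420 cells at the
defaults, laid out variable-major, then pig slot, then day offset. The
window slides along each pen's recording span in 1-day steps (configurable
stride). Its first day, the **A_date**, determines the label: windows of
CTL pens are always CTL; windows of a TB pen are TB exactly when the A_date
falls inside the **TB window**, an inclusive interval of days around day 0
(default [−35, +10]; both bounds inclusive, hence 46 TB-labeled A_dates in
a fully recorded pen).

Pens rarely hold exactly 10 pigs. The 10 slots are filled with the pigs
having the most observation days, ties broken by pig id — a deterministic
rule chosen to minimize missing cells while staying reproducible, standing
in for whatever manual choice a real study would make. Pens with fewer pigs
get placeholder slots whose cells stay missing until imputation.

## Preprocessing

Three fitted transforms run in sequence, each stratified **by herd**
("by data set") and by variable, and each reusable on unseen windows:

1. **Median imputation** of missing cells;
2. **Centering and scaling** to per-stratum mean 0, SD 1 (a zero-variance
   stratum gets scale 1 with a warning);
3. **PCA**, keeping the smallest leading component set whose cumulative
   explained variance reaches `pca_variance_retained`.

By default (`preprocessing_fit = "train_only"`) all three are fitted on the
training windows only and applied unchanged to the test side, so no test
statistic leaks into the fit; `"global"` fitting (everything before the
split) is available for fidelity experiments, since published descriptions
of this design are ambiguous on the point. The retained-variance default is 0.95; there is
no canonical component count for this framing, so this knob is deliberately
prominent.

## The classifier benchmark

Seven standard classifiers are benchmarked under one shared harness
(`tb_train()`), each mapped to an established implementation:

| name | family | backend |
|---|---|---|
| `glmnet` | elastic-net logistic regression | glmnet |
| `rf` | random forest | ranger |
| `svmRadial` | RBF-kernel SVM | kernlab |
| `bayesglm` | weak-prior (ridge-MAP) logistic regression | glmnet, fixed small penalty |
| `nn` | single-hidden-layer network | nnet |
| `knn` | k-nearest neighbours (odd k in 3–31) | class |
| `pls` | PLS discriminant analysis | mixOmics |

Hyperparameters are tuned by uniform **random search capped at 10 points**
(deduplicated for finite spaces; `bayesglm` has nothing to tune), each point
scored by the mean fold-wise **true positive rate** (TB positive) under
k-fold resampling of the training windows, and the winner refitted on the
full training set. The resampling default is k = 200; descriptions of
this design sometimes state that the 200-fold scheme leaves 1% out, which
the arithmetic contradicts (1/200 = 0.5%) — we implement k as stated and
clamp it to the
training size with a warning on small data. Fold assignment depends only on
the tuning seed and the training size, never on the model, so resampling
profiles of different models are paired fold-by-fold and can be compared
with paired t-tests (Bonferroni-adjusted over the 21 model pairs).

## Split regimes and leakage

* **CV** — window-level 75/25 split, stratified by class (pure random
  splitting can leave a 17% positive class absent from a 25% test set,
  making TPR undefined). The model will usually have seen *other windows
  from the same pen*, emulating continuous monitoring of known pens.
* **LOOP** — pen-held-out: ~25% of pens, stratified by herd and status, move
  wholesale to the test side (single-pen strata stay in training with a
  warning). This emulates prediction for a pen the model has never seen.
  Pen-disjointness is asserted on every run.

The contrast between the two is the analysis's central object: with
pen-level heterogeneity, CV performance is partly *recognition* (of the pen
and of temporally adjacent windows) rather than *generalization*.
A consequence worth stating explicitly: because consecutive windows share
13 of 14 days and the TB labels form one contiguous block per pen, the CV
regime can score above chance **even when the generator injects no signal
at all** — the test window's near-duplicate neighbours sit in the training
set with the same label. Null-drift calibration is therefore assessed in
the LOOP regime, where that channel does not exist; the positive null-drift
CV kappa is not a bug but a measurement of the leakage itself.

## Performance reporting

`confusion_report()` tallies the confusion matrix with TB positive and
reports TPR, TNR, PPV, ACC with an exact (Clopper–Pearson) binomial 95% CI,
Cohen's kappa κ = (p₀ − pₑ)/(1 − pₑ) with marginal chance agreement pₑ, the
Landis–Koch band, the no-information rate (NIR, the accuracy of always
predicting CTL), and a one-sided exact binomial p-value for ACC > NIR.
Ratios with zero denominators (e.g. PPV of a model that never predicts TB)
are reported missing, never as 0.

## The synthetic generator

No raw feeder logs from the two herds this design was developed on are
publicly deposited, so the generator is a first-class module, calibrated to the published
control-class summary statistics of the two herds
(`swedish_herd()`: 42 pens, 7–14 boars, ±70 d, DFV 24.9 ± 19.4, DFC
2337 ± 757 g, StdFC 129 ± 86 g; `swiss_herd()`: 23 pens, 11–55 pigs,
±100 d, DFV 12.3 ± 6.0, DFC 2282 ± 600 g, StdFC 167 ± 96 g).

Structure, per pig-day:

* **Heterogeneity** — log-normal mean-1 multipliers per pen
  (`pen_effect_sd`, default 0.15 on the log scale) and per pig
  (`pig_effect_sd`, 0.25), independently per variable. Pen-level
  heterogeneity is what makes the CV/LOOP contrast informative.
* **Visit counts** — negative binomial (gamma-mixed Poisson). The published
  DFV dispersion (SD ≈ 0.8 × mean) is far beyond Poisson; the NB size is
  derived from the profile's marginal CV after removing the between-pen/pig
  share.
* **Daily intake** — the day's total is drawn first (log-normal day noise
  whose variance is likewise derived from the marginal target), compensated
  for the probability of a zero-visit day so the marginal mean equals the
  configured DFC exactly, then partitioned over the visits with
  gamma-distributed relative sizes targeting the StdFC per-visit SD. Daily
  intake is thus regulated at the day level — per-visit amounts within a day
  anticorrelate, as for a pig eating to satiation — and per-visit grams sum
  exactly to the daily total the features module recomputes.
* **Drift** — TB pens' expectations are scaled multiplicatively from
  `onset_day` (default −42) to day 0 (defaults: DFV ×0.7, DFC ×0.85,
  StdFC ×0.85 at day 0, linear ramp), returning to baseline over 28 days
  after day 0. The onset and the declining-DFV direction follow published
  reports of reduced feeder visits several weeks before outbreaks; the
  magnitudes are **synthetic stand-ins** — the study supplies no effect-size
  timeline of its own (its class contrasts are marginal and confounded with
  herd), so nothing here should be read as an estimate of real drift.
* Day 0 is placed uniformly in the middle third of the recording span, so
  default-sized TB windows never overrun the edge. Visit timestamps are
  cosmetic; only the date matters downstream. StdFC's own marginal moments
  are matched only approximately: the daily sample SD is a noisy statistic
  of the intake distribution and inherits variability we do not separately
  calibrate.

What the generator does **not** emulate: within-day feeding rhythms,
feeder-occupation times, drinking or climate covariates, biter/victim
identities, seasonal or batch effects, and any real-data quirk of the two
herds beyond their first two moments. A green test suite therefore shows
the pipeline's *machinery* is sound and its *contrasts* (CV vs LOOP, wide
vs narrow labeling horizon) point the right way under known signal — it is
not evidence about real-farm performance.

## Problem sizes and numerical choices

The test suite and the acceptance script run a scaled-down demo study:
one Swedish-calibrated herd of 8 pens (4 TB), 8–10 pigs per pen, ±55 d
recording (~760 windows), with 60% PCA retained variance, 5–8 resampling
folds and a random-search budget of 3–4. At this size the leading ~35
components carry the discriminative structure; retaining more mostly adds
within-pen noise dimensions that slow the learners without informing them.
The package defaults (k = 200 folds, budget 10, 95% variance) remain the
full-study conditions.

Other numerical conventions: TB-window bounds are inclusive on both ends;
ties in hyperparameter selection go to the first-drawn point; resampling
folds without a positive window contribute missing TPR and are excluded
from the tuning mean; paired profiles with zero variance of differences get
p = 1 when the difference is identically zero; feed is recorded to 0.1 g;
CSV writers emit 17 significant digits so numeric columns round-trip
bit-exactly.

## Known limitations

* The `bayesglm` entry is a ridge-MAP approximation to weak-prior Bayesian
  logistic regression, not a posterior simulation.
* LOOP holds out ~25% of pens per draw rather than literally one pen;
  with few pens per stratum the test side can be small and kappa noisy.
* Median imputation ignores the time structure of gaps; windows from pens
  with many placeholder slots are dominated by imputed constants.
* The 420-cell framing assumes a fixed pig count per window; pens far above
  10 pigs are represented by their 10 most-observed animals only.
* Labeling and drift do not coincide exactly: windows of a TB pen that
  overlap the drift ramp before day −35, or the post-day-0 recovery, are
  behaviourally abnormal yet labeled CTL. Sensitive classifiers (notably
  knn) flag them, which caps the measurable specificity on TB pens even
  when control pens draw no false alarms at all — on synthetic data with a
  temporally extended drift this boundary ambiguity is the dominant error
  mode, and distinguishing it from a genuine false alarm requires looking
  at where the flagged windows sit relative to day 0.
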