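---
title: "Estimating prescription durations from refill gaps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating prescription durations from refill gaps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seeduration)
```

## The estimation problem

Prescription registers record fill dates but often not the number of days
each fill covered. Without durations there is no exposure status, and
without exposure status most pharmacoepidemiologic designs stall. The Sessa
Empirical Estimator (SEE) infers durations from the population's own refill
rhythm, under two assumptions:

* the duration of a fill is associated with the temporal distance (in days)
  to the patient's next fill of the same drug, and
* the amount dispensed is consumed between the two fills — no stockpiling,
  so no carry-over of leftover supply.

Where those assumptions are violated (stockpilers, in-hospital supply gaps,
dose titration), the estimate degrades; the 80% ECDF trim below is the
method's only built-in defence, aimed specifically at stop/re-start gaps.

## The pipeline

Given a validated cohort (one drug, duplicate same-day fills merged, fills
inside an observational window):

1. **Gaps.** Every consecutive same-patient fill pair contributes
   `gap = day(next) − day(this)` (≥ 1 after duplicate merging).
2. **ECDF trim.** The retention cutoff is the smallest observed gap `g`
   with `ECDF(g) ≥ 0.8` — i.e. the empirical 80th percentile including
   ties (quantile type 1). All gaps `≤ g` are retained, so the retained
   fraction is *at least* 80% and the removed set contains only the largest
   gaps. We resolved the quantile-type ambiguity in favour of "retain at
   least 80%".
3. **One random pair per patient.** Among each patient's *retained* gaps,
   one is drawn uniformly. Trimming precedes sampling because the steps are
   stated in that order; a patient whose every gap exceeded the cutoff is
   simply unrepresented in the fit.
4. **Standardize and cluster.** Sampled gaps are centred by their mean and
   scaled by the sample standard deviation (n − 1). k-means
   (squared-Euclidean, Hartigan–Wong) is run for each K in 2..10 with 50
   random initializations (initial centres drawn from the distinct values,
   best within-cluster sum of squares kept), and the average silhouette
   width of each K's best partition is computed. The K with the highest
   average width wins; ties break toward the smaller K, and equidistant
   points assign to the smaller-centre cluster. K = 1 cannot be scored by
   silhouette, so the search starts at 2; the upper bound is additionally
   capped at (number of distinct sampled gaps − 1). With exactly two
   distinct values we fit K = 2 (one cluster per value); with one distinct
   value the model degenerates to a single cluster whose duration is that
   value.
5. **Cluster medians as durations.** Each cluster's duration is the
   empirical median of its member gaps on the original day scale, kept to
   0.01 day internally. We read "the median of the distribution" as the
   empirical median rather than a kernel-density estimate: the two agree in
   the limit and a KDE would add an arbitrary bandwidth choice.
6. **Assignment and end of supply.** Every fill with a following fill has
   its gap standardized with the *model's* mean/sd and assigned to the
   nearest cluster centre — including gaps above the cutoff, which
   therefore cap at the largest cluster median. A patient's last fill
   inherits the duration of that patient's most recent assigned fill;
   patients with no assigned gap at all (single fill) receive the median of
   the cluster medians rounded to the nearest day. The end of supply is the
   fill date plus the duration rounded to whole days (half away from zero),
   since register dates have daily resolution. The last-fill and
   single-fill rules are this package's choices — some rule is mandatory to
   answer exposure queries at arbitrary dates, and none is prescribed by
   the method's definition.

Exposure timelines are unions of half-open intervals `[fill, end-of-supply)`
merged per patient; all queries are half-open, so a patient is unexposed on
the end-of-supply day itself.

## The simulator

The validation cohort is synthetic: 1000 patients over 730 days, every
patient filling on day 0 with a true duration of 30 days and at least once
more, refill durations drawn uniformly from {30, 60, 90} days (months
encoded at 30 days for consistency with the 30-day initial fill), and no
carry-over. Patients belong to six adherence-trajectory groups with default
proportions (0.100, 0.093, 0.236, 0.093, 0.379, 0.099) matching the realized
group sizes of the reference simulation.

Each group is a delay generator: the next fill occurs at the previous
supply's end plus a nonnegative delay.

| group | generator | default rationale |
|---|---|---|
| high | delay ~ U(0, d(1/0.95 − 1)) after a d-day supply | availability stays ≈ 95% |
| medium | per-patient a ~ U(0.50, 0.90); delay ~ U(0, 2d(1/a − 1)) | mean delay hits the target, CMA ≈ a |
| declining | target falls linearly 0.95 → 0.40 over the window; medium-style delay at the current target | gradual decline |
| intermittent | 90-day phases alternating 0.95 (high-style) and 0.50 (medium-style) | regular high/low switching |
| partial drop-off | high-style until a change-point ~ U(180, 540) d, then each refill continues w.p. 0.5 with medium-style delays | high start, later drop-off |
| non-persistent | 1 or 2 refills (equal probability, high-style delays), then none | early discontinuation |

The verbal trajectory definitions pin down only adherence levels, not delay
laws; these generators are declared stand-ins chosen once for plausibility.
CMA (continuous multiple-interval measure of medication availability) is the
fraction of the window covered by the true-exposure union; the high group's
median CMA exceeds 0.9 by construction, and the medium group's CMA spreads
over ≈ 0.5–0.9.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: stockpiling and carry-over, dose changes and
switching, hospitalization gaps, quantity-dependent refill behaviour, and
any calendar seasonality. Dispensed quantity is emitted as true duration ×
1 unit/day (optionally ± uniform noise) purely so the researcher-defined
duration comparator can be exercised; real quantity–duration relationships
are richer.

## Evaluation

One uniform random date per patient (daily resolution, both window
endpoints included) is classified against truth: TP = truly and estimatedly
exposed, FP = only estimatedly, FN = only truly, TN = neither. From the 2×2
table we report accuracy, sensitivity (= recall), specificity, PPV
(= precision), NPV, balanced accuracy, Cohen's kappa (marginal-product
chance agreement) and F1. Zero-denominator ratios propagate as `NaN` rather
than being coerced to 0, so degenerate runs are visible. Duration
misclassification is `|true − assigned|` per fill, summarized by median and
IQR per category and pooled over TP/TN/FN.

The **balanced-subsample analysis** down-samples TP patients to the size of
the largest other class and then *re-evaluates the retained population at
freshly drawn random dates*. Merely deleting TP individuals from the table
cannot change NPV = TN/(TN + FN) — neither cell involves TP — so a pure
re-total would make the analysis vacuous for exactly the metric it is meant
to probe. Re-evaluation removes predominantly well-covered patients from
every cell's candidate pool, shifting the estimated-negative pool toward
the truly unexposed; that is the mechanism by which NPV responds to class
rebalancing.

**Event-date sensitivity** mimics biomarker-style external truth: events
exist only where exposure truly occurred, and an event is detected when any
estimated interval intersects `[event − tol, event + tol]` (default
tolerance 0; half-life-based tolerances are caller-supplied).

## Numerical choices and degenerate inputs

* Dates are integer day offsets internally (day 0 = window start); calendar
  dates only at I/O boundaries.
* Duplicate (patient, date) rows merge with quantities summed — the source
  data's handling of same-day fills is unknowable, and merging avoids
  zero-length gaps that would distort the ECDF.
* k-means uses 50 restarts with initial centres sampled from the distinct
  standardized values, guaranteeing distinct initial centres; per-K seeds
  make fits reproducible.
* Silhouette ties (exact equality) break toward smaller K; nearest-centre
  ties toward the smaller centre; end-of-supply rounding is half away from
  zero.
* All randomness flows from explicit seeds; the end-to-end replication
  derives per-stage seeds (simulate, fit, dates, balance) from one global
  seed by fixed offsets.

## Problem sizes used in the test suite

The replication runs at full study scale — 1000 patients, five seeds
averaged (a run takes a couple of seconds). The exhaustive
contiguous-partition silhouette oracle is checked on 200 random instances
of ≤ 10 points (optimal 1-D k-means partitions are contiguous, so
enumeration is over compositions; the oracle minimizes within-cluster sum
of squares per K exhaustively, then scores by a hand-rolled silhouette).
Parameter recovery uses 50 replicates of 200 high-adherence patients.
Uniformity of the random evaluation dates is checked by chi-square on
10,000 draws.

## Known limitations

* **Silhouette on discrete data.** Refill gaps are integers. When the
  sampled gaps take only a handful of distinct values (e.g. a uniformly
  high-adherence cohort, where gaps hug 30/60/90 within a few days),
  partitions with one cluster per exact value have near-zero within-cluster
  spread and average silhouette ≈ 1, so argmax-silhouette inflates K toward
  its upper bound. Cluster *medians* remain accurate — each still sits on a
  true duration — but K loses its interpretation as "number of duration
  regimens". With realistically dispersed gaps (the six-group mixture) the
  pathology disappears and K matches the duration regimens.
* **Overcoverage of refill delays.** Cluster medians are medians of gaps,
  and gaps = duration + delay, so assigned durations sit slightly above
  true durations and spill into the delay days that separate fills. On
  cohorts with a large truly-unexposed share this depresses specificity and
  PPV; sensitivity is correspondingly generous.
* **Class-imbalance-dependent metrics.** NPV and kappa are strong functions
  of the truly-exposed prevalence at the random dates, which is itself a
  property of the trajectory generators, not of the estimator. Comparisons
  of these metrics across simulators with different prevalence are not
  meaningful.
* The estimator is single-drug: no joint modelling across drugs, no
  covariate-dependent durations, no episode-stitching beyond interval
  union, and no parametric waiting-time-distribution estimation.
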