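# seeduration

Computing the duration of filled pharmacological prescriptions from fill
dates alone, using the Sessa Empirical Estimator (SEE).

## The problem

Pharmacoepidemiologic studies built on prescription registers and claims
data need to know, for every filled prescription, how many days it covered:
exposure status at any calendar date, treatment episodes, persistence and
adherence measures all derive from it. Many secondary data sources record
*when* a prescription was filled but not *how long* it lasted. The common
workarounds are researcher-defined durations (RDD) — fixed assumptions such
as "one dispensed unit per day" or the WHO Defined Daily Dose — which import
untested assumptions about dosing.

The SEE is a data-driven alternative that estimates durations from the
refill behaviour of the study population itself. For each patient, the
*refill gap* is the temporal distance in days between two consecutive fills
of the same drug. The algorithm:

1. computes the empirical cumulative distribution function (ECDF) of all
   consecutive-fill gaps and retains only its lower 80% — the discarded
   upper tail holds the artificially long gaps of stoppers and re-starters;
2. draws **one random retained gap per patient**, removing the
   over-representation of patients who refill frequently;
3. standardizes the sampled gaps (`z = (g − ḡ)/s`) and clusters them with
   k-means, selecting the number of clusters `K` that maximizes the average
   silhouette width;
4. takes the empirical median gap of each cluster (on the day scale) as the
   assigned prescription duration for every fill whose gap falls in that
   cluster;
5. sets each fill's *end of supply* to the fill date plus its assigned
   duration.

The package also ships the validation apparatus: a simulator of dispensing
histories under six medication-adherence trajectories (high, medium,
declining, intermittent, partial drop-off, non-persistent) with known true
durations; a one-unit-per-day RDD comparator; and a random-date evaluation
that classifies each patient as TP/FP/FN/TN by comparing true and estimated
exposure at one uniform random date, with ten classification metrics,
misclassification-in-days summaries, a balanced-subsample sensitivity
analysis, and sensitivity at external truth-event dates.

## Worked example

```r
library(seeduration)

rep1 <- run_replication(seed = 1)   # 1000 simulated patients, 2-year window
print(rep1$model)
```

```
<see_model> K = 3 cluster(s)
  ECDF cutoff: 94 days; standardization mean 53.65, sd 23.48
  cluster median durations (days): 31, 62, 92
  avg silhouette by K: 2=0.744  3=0.814  4=0.788  5=0.792  6=0.779  7=0.770  8=0.748  9=0.732  10=0.701
```

The simulator generated refills with true durations 30/60/90 days; the
estimator retained gaps up to 94 days, chose `K = 3` by silhouette, and
recovered cluster medians of 31, 62 and 92 days. Classifying every patient
at one random date:

```r
rep1$classification$matrix
#>  tp  fp  fn  tn
#> 598  58  16 328
m <- rep1$metrics
#> accuracy 0.926, sensitivity 0.974, specificity 0.850, PPV 0.912, NPV 0.953, kappa 0.841
```

598 of 1000 patients were truly exposed at their random date and estimated
exposed (TP); the 58 FP are mostly dates falling in a refill-delay stretch
that the slightly generous cluster medians still cover. Per-fill duration
misclassification, pooled over TP/TN/FN patients, has a 2-day median here
because the cluster medians land almost exactly on the true durations:

```r
s <- rep1$misclassification$summary
s[s$category == "pooled_tp_tn_fn", ]
#>         category    n q1 median q3
#>  pooled_tp_tn_fn 7751  1      2  2
```

On real register data, the same pipeline starts from a fills file instead of
the simulator:

```r
cohort <- validate_cohort(read_fills("fills.csv"))
model  <- fit_see(cohort, see_config(ecdf_retention = 0.8, k_max = 10, seed = 42))
assigned <- assign_durations(cohort, model)
write_durations(assigned, "durations.csv")
```

A thin command-line wrapper with `simulate`, `estimate` (`--method see|rdd`),
`evaluate` and `replicate` subcommands is installed at
`inst/cli/see.R` (`Rscript $(Rscript -e 'cat(system.file("cli/see.R", package="seeduration"))') simulate --n 1000 --out fills.csv`).

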