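# gazedissect

An R pipeline for region-of-interest (ROI) eye-tracking attention studies in
psychiatry: from raw 120 Hz binocular gaze logs, through fixation detection
and trial-level quality control, to two fixation-level attention measures and
the dependent-correlation statistics that test a trait double dissociation.

## The problem

In search-array paradigms, participants view arrays with one social target
(a human eye region) among distractors. Two measures carry distinct meaning:

* **latency to first fixation on the eyes** — time from array onset to the
  start of the first fixation inside the eyes ROI (bottom-up orienting);
* **first-pass dwell** — total fixation time in the eyes ROI from first
  entry to first exit (maintained engagement; its inverse indexes rapid
  disengagement, the avoidance half of vigilance–avoidance).

The target inference is a *double dissociation*: autistic traits (SRS raw
score) relating selectively to orienting latency, social anxiety (SPAI-C raw
score) relating selectively to dwell. Because both traits are measured in
one sample, comparing their correlations with one measure needs Steiger's
test for dependent correlations,

    Z = (z(r12) − z(r13)) · sqrt((n − 3) / (2(1 − s̄))),

with z(·) the Fisher transform and s̄ a pooled covariance term in the two
compared correlations (see the methods vignette for the full formulas,
including the partial correlation r_xy·z and the Cook's-distance outlier
screen applied per measure–trait pair).

The package also ships a seeded synthetic-cohort generator that renders
complete on-disk studies — trait tables, ROI geometry, trial logs, 120 Hz
binocular gaze streams — with *planted*, parameterised trait–attention
couplings and a ground-truth ledger, so every pipeline stage is testable
against known truth.

## Worked example

Simulate a 25-participant study at the default conditions, run the full
pipeline, and inspect the association analysis:

```r
library(gazedissect)

params <- cohort_params(n_participants = 25, seed = 7)
res <- run_study(params)

res$summaries[1:3, c("participant_id", "n_included",
                     "mean_latency_ms", "mean_dwell_ms")]
#> # A tibble: 3 × 4
#>   participant_id n_included mean_latency_ms mean_dwell_ms
#>   <chr>               <int>           <dbl>         <dbl>
#> 1 P001                   11            512.          612.
#> 2 P002                   11            675.          409.
#> 3 P003                   12            749.          491.

writeLines(head(format_association_report(res$results), 8))
#> Association analysis
#> ====================
#>
#> r(latency, SRS) = 0.781, n = 23, t(21) = 5.74, p < .001  [2 outlier(s) removed]
#> r(latency, SRS | SPAI-C) = 0.750, n = 23, t(20) = 5.06, p < .001
#> r(latency, SPAI-C) = 0.358, n = 24, t(22) = 1.80, p = 0.086  [1 outlier(s) removed]
#> r(latency, SPAI-C | SRS) = -0.080, n = 24, t(21) = -0.37, p = 0.716
#> Steiger Z (latency: SRS vs SPAI-C) = 2.009, n = 25, p = 0.045
```

Reading the output: each measure–trait pair gets a zero-order Pearson r
(after the Cook's-distance screen; removals are logged per pair) and a
partial r controlling the other trait; the Steiger line compares the two
traits' correlations with that measure on the same participants. With the
default couplings (+60 ms latency per SD of trait A, −80 ms dwell per SD of
trait B) this small cohort already shows the planted pattern: a strong
positive SRS–latency relation that survives partialling SPAI-C out, and a
SPAI-C–dwell relation in the planted negative direction.

On-disk workflows mirror the in-memory one: `generate_cohort()` writes a
cohort directory (gaze TSVs, trial-log CSV, ROI JSON, trait CSV, ledger,
manifest), `run_pipeline_bundle()` scores it into a results bundle (metrics
and summary CSVs, results CSV, text report, run log, resolved config). A
thin command-line wrapper lives at `inst/cli/gazedissect.R`.

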