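# sccscore

Self-supervised detection of serious clinical complications (SCC) from
continuous wearable recordings of vital signs and physical activity.

Patients under intensive treatment for hematologic malignancies are at high
risk of grade >= 3 complications (infections, cardiac events, hypertensive
crises).  A medical wearable records 12 physiological channels at 1 Hz —
five of them with a 0-100 signal-quality index — for hundreds of hours per
patient.  `sccscore` implements a complete anomaly-detection pipeline on such
data:

1. **Self-supervised contrastive features.**  A 1-D residual convolutional
   network maps 1000-second intervals to unit-norm 128-dimensional features
   `h = f(x)`.  It is trained only on *regular* (complication-free) hours
   with the temperature-scaled contrastive (NT-Xent) objective at
   `tau = 0.07`: two intervals of the same hour, at least 500 s apart, form a
   positive pair against the other hours of the minibatch,

   `L_i = -log exp(sim(h_i,h_i')/tau) / (exp(sim(h_i,h_i')/tau)
          + sum_{k!=i} [exp(sim(h_i,h_k')/tau) + exp(sim(h_i',h_k)/tau)])`.

   Each second enters the network as a 512-dimensional column
   (5 x 101 + 7): quality-bearing signals are placed at the position given
   by their integer quality index, the rest enter as raw z-scaled values.

2. **SCC-Score.**  With `D_train` the features of `K = 6` random intervals
   per training regular hour,

   `S(x_test) = (1/K) sum_k [ 1 - max_{h_m in D_train} sim(h_m, h_test^k) ]`,

   i.e. one minus the best cosine match to anything regular, averaged over
   `K` intervals of the test hour.  The *patient-specific* variant restricts
   `D_train` to the test patient's own regular hours.

3. **Detection test.**  Scores of held-out regular hours form an empirical
   null distribution; an hour is flagged as SCC when its score strictly
   exceeds the `(1 - alpha)` order-statistic threshold.

4. **Evaluation battery.**  AUROC (Mann-Whitney, tie credit 1/2) with
   cross-validation + bootstrap SDs, Youden cut-points, specificity at ~95%
   sensitivity, Welch t-tests at the Bonferroni level 0.05/12 = 0.0042,
   per-event-type z-score trajectories, and event-anchored score curves
   over the 120 h around diagnosis.

Because the clinical recordings behind this design are not public, the
package includes a first-class synthetic cohort generator
(`sim_config()` / `generate_cohort()`) that emulates the data structure:
inpatient and outpatient arms, circadian + slow-state + AR(1) signal
dynamics, daily 90-minute charging gaps, recording interruptions, and
injected complications with known ground truth (slow multi-hour infectious
ramps, abrupt cardiac transients).  All tests and the acceptance run operate
end to end on this simulator.

## Worked example

```r
library(sccscore)

# 12 patients x 216 h at 1 Hz, infectious ramp complications
cohort <- generate_cohort(sim_config(seed = 2024, event_mix = "ramp_only"))
fit <- scc_fit(cohort, encoder = encoder_config("test", seed = 2024),
               n_folds = 2, K = 6, alpha = 0.05, seed = 2024)
fit
#> SCC detection pipeline fit
#>   2310 hours retained (1272 regular, 1038 non-regular), 2 folds
#>   hourly AUROC (non_specific): 0.713
#>   hourly AUROC (specific): 0.815
ev <- summary(fit)
ev[ev$subset == "all", ]
#> SCC-Score performance
#>      approach granularity subset n_regular n_nonregular sensitivity specificity
#>  non_specific        hour    all       252         2076        55.8        77.8
#>      specific        hour    all       252         2076        75.3        74.2
#>  non_specific         day    all       115          102        93.1        55.7
#>      specific         day    all       115          102        89.2        87.0
#>  auroc auroc_sd      p
#>  0.713   0.0462 <2e-16
#>  0.815   0.0209 <2e-16
#>  0.822   0.0461 <2e-16
#>  0.923   0.0275 <2e-16
```

Read the table as in a clinical performance report: per approach
(cohort-wide vs patient-specific reference) and score granularity (hour /
day), the counts of regular and non-regular test units, the Youden
operating point (sensitivity / specificity in %), and the AUROC with its
cross-validation + bootstrap SD; the Welch t-test p-value is checked
against the Bonferroni level 0.0042.  Patient-specific restriction lifts
the hourly AUROC from 0.71 to 0.82, and per-day aggregation lifts both
further (0.82 / 0.92) — patient-specific per-day scores give the best
estimate, with every score guaranteed at least as large as its cohort-wide
counterpart hour by hour.

```r
det <- scc_detections(fit, "specific")            # null-distribution test
mean(det$detected[det$label == "regular"] == "SCC")
#> [1] 0.04761905                                   # empirical FPR ~ alpha

plot(fit, "anchored")   # mean SCC-Score vs hours around diagnosis
```

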