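# geoseek

Predicting future medical-facility visits from geotagged mobile search logs,
and measuring what such predictions are worth to an advertiser.

## The problem

Mobile search logs carry three signals at once: what a person searched for,
when, and where they were standing. For people on a path toward a health care
visit, all three drift in characteristic ways in the weeks before the visit —
health-related queries become more frequent and more specific, the intervals
between consecutive health searches shorten, and searches increasingly
originate near health-related places. `geoseek` implements the full analysis
pipeline that exploits this:

1. **Visit labeling by geofence dwell time.** A user whose consecutive
   searches stay within 200 m of one facility for at least 900 s is inferred
   to have visited it. Users with more than 15 facility-proximal searches in
   a calendar month, or searches near more than 5 distinct facilities in a
   month (likely staff or neighbours), are excluded; patients additionally
   need 42+ search days of history. Controls are sampled matched on search-day
   counts.
2. **Longitudinal windowing.** Each user's log is cut into an analysis window
   of exactly 41 *search days* (days with at least one search) preceding an
   endpoint — the first facility visit for patients, a random day for
   controls.
3. **Feature engineering** (per day and aggregated): search counts,
   health-search counts, mean session duration, mean text length; the
   *interval reduction score* IRS = mean_i [w + (1 − w) Δ_{i+1}/Δ_i] over
   consecutive intervals between a day's health searches (1 for ≤ 2 searches,
   < 1 under shortening, w ≈ 0.1); per-day counts of searches mapping to the
   disease / drug / device / procedure semantic groups of a medical lexicon;
   search specificity as the information content IC(t) = −ln f(c_t)/f(root)
   of the day's most specific medical term; Fisher-exact/Bonferroni-enriched
   tokens, landmark categories and location-name tokens (fitted on the
   training split only).
4. **Models.** Lasso, ridge and elastic net (5-fold CV, one-standard-error
   lambda rule), an RBF-kernel SVM (gamma = 1/p, cost by CV) and a random
   forest, evaluated by ROC AUC on a held-out 20%, with Hand–Till multiclass
   AUC for the 4-class visit-specialty task and a leave-one-feature-category-
   out ablation.
5. **Utility evaluation.** Ad impressions convert when a first visit to the
   advertised facility follows within 14 days with no visit to it in the
   previous 30; the *local show conversion rate* around each score rank, the
   linear score → bid-coefficient map onto [0.7, 1.3], and A/B relative
   changes in conversion and CPA quantify what the prediction buys.

The raw logs behind the original analysis are proprietary, so the package
ships a first-class synthetic-log simulator (`generate_world()`,
`generate_users()`, `generate_ad_stream()`) that plants exactly the
escalation signals above, with ground truth, under full seed control. All
statistical claims in the test suite are property-based: parameter recovery,
leakage and null checks, and oracle equivalences.

## Worked example

```r
library(geoseek)

cfg <- run_config(seed = 7,
  world  = world_config(n_landmarks = 60, lexicon_size = 120),
  cohort = cohort_config(n_patients = 60, n_controls = 70,
                         days_per_user = 44),
  model  = model_spec("random_forest", forest_size = 150),
  conversion = conversion_policy(window_T = 11),
  n_impressions = 260)
m <- run_pipeline(cfg)

round(m$daywise_test_auc, 3)    # 0.91
round(m$aggregate_test_auc, 3)  # 0.854
round(m$conversion_curve_spearman, 3)  # 0.814
```

The daywise model (0.91) beats the aggregate model (0.854): the *progression*
of behaviour across days carries information that window totals lose. The
Spearman correlation of 0.814 between score percentile and local show
conversion rate says that higher-scored users really do convert more often —
the monotone curve that justifies using the scores to modulate ad bids. (At
this toy cohort size the per-category ablation is noisy; the location-
dominance property is tested at n = 1000 in the acceptance suite.)

Single operations work standalone:

```r
interval_reduction_score(c(0, 600, 900), w = 0.1)  # 0.55  (intervals halve)
score_to_coefficient(c(0, 0.5, 1))                 # 0.70 1.00 1.30
haversine_distance(0, 0, 1e-4, 0)                  # 11.12 m
```

A thin CLI mirroring the pipeline stages is installed at
`inst/cli/geoseek` (`geoseek run --config run.yaml`, plus
`simulate | cohort | features | train | evaluate`).

## Acceptance script

`scripts/acceptance.R` recomputes, from a fresh run of the installed
package, the pipeline's small printed invariants — the interval reduction
score of a two-search day and the extrema of the bid-coefficient map over a
dense score grid — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — simulator, geofence/cohort, features, models, ad evaluation,
  pipeline
- `src/forest.cpp` — the built-in random forest (no forest package is
  assumed installed)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/predicting-utilization.Rmd` — methods notes: model assumptions,
  simulator design, parameter defaults, numerical choices, limitations
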