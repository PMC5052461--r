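---
title: "Predicting health care utilization from geotagged search logs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting health care utilization from geotagged search logs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind `geoseek`, the free
parameters and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The model

The package treats a future medical-facility visit as the endpoint of a
behavioural trajectory observable in mobile search logs. Three families of
signals are assumed:

* **Volume and rhythm.** People approaching a health care visit search more
  about health, and the intervals between consecutive health searches within
  a day shorten. The interval reduction score (IRS) summarizes the latter:
  with intervals $\Delta_i = t_{i+1}-t_i$ between a day's health-related
  searches,
  $$\mathrm{IRS} = \frac{1}{n-2}\sum_i \left[w + (1-w)\,
  \frac{\Delta_{i+1}}{\Delta_i}\right],$$
  equal to 1 for days with two or fewer searches. Values below 1 indicate
  shortening. The weight $w$ damps extreme ratios; small values near 0.1
  work best and 0.1 is the default.
* **Content.** Searches drift from general to specific medical subject
  matter. Specificity is the information content
  $IC(t) = -\ln\big(f(c_t)/f(\mathrm{root})\big)$ of the most specific
  medical term in a search, where $f$ is a concept's corpus frequency
  aggregated over its ontology descendants — by construction nondecreasing
  from root to leaf. The daywise score is the maximum over the day's
  searches. Searches are also counted into four semantic groups (disease,
  drug, device, procedure) via the lexicon.
* **Place.** Searches made near health-related landmarks foreshadow visits.
  Coordinates are rounded to 4 decimal places (about 11 m), resolved once
  per unique pair against a gazetteer, and counted per enriched landmark
  category; word tokens of landmark names enter as binary indicators.

A user is labeled a visitor when a contiguous run of their searches stays
inside the 200 m geofence of one facility for at least 900 s. The modelling
unit is a 41-search-day analysis window preceding an endpoint; features are
computed per window day (daywise) and over the window (aggregate).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| geofence radius | 200 | m | presence radius for visit inference |
| minimum dwell | 900 | s | separates visits from pass-bys |
| monthly proximal-search cap | 15 | searches | removes staff/residents |
| monthly distinct-facility cap | 5 | facilities | removes couriers etc. |
| history requirement | 42 | search days | leaves 41 full window days |
| window length | 41 | search days | fixed analysis window |
| IRS weight $w$ | 0.1 | — | damps extreme interval ratios |
| session gap | 1800 | s | inactivity defining a session |
| enrichment alpha | 0.05 | — | family-wise (Bonferroni) level |
| enriched tokens / categories / name tokens | 100 / 53 / 113 | — | selection caps |
| coordinate rounding | 4 | decimal places | ~11 m cache granularity |
| conversion lookback / lookahead | 30 / 14 | days | "new visit" and attribution windows |
| bid-coefficient interval | [0.7, 1.3] | — | allowed ad-bid modulation |

At toy lexicon/gazetteer scale the selection caps are rarely binding: when
fewer items pass the Bonferroni bar than the cap, all significant items are
returned and the shortfall is messaged.

## The synthetic world

No public corpus of geotagged search logs exists at this granularity, so the
generator *is* the data source, and its defaults are the stated experimental
world rather than tunable knobs:

* 1000 users by default (500 patients, 500 controls), 60 search days each,
  with at least one search per day so search days and calendar days coincide
  in simulation; baseline 4 searches/user/day; baseline probability 0.12
  that a search is health-related; baseline probability 0.05 of searching
  from a health landmark. These magnitudes are unverifiable against any
  public source and were fixed once at values a field practitioner would
  call plausible for an engaged mobile-search user.
* Patient escalation is a linear ramp over the final 15 search days (the
  simplest monotone shape; nothing in the domain pins the functional form):
  health-search probability ×3, within-day health-search intervals shrink to
  1/3, term sampling drifts toward deeper (higher-IC) concepts, and
  health-landmark search probability ×4 at the ramp's end, all scaled by a
  per-user latent risk in (0.5, 1). Controls are stationary. Setting every
  multiplier to 1 yields an exchangeable null, which the test suite verifies
  by Kolmogorov–Smirnov.
* Search text is a bag of lexicon terms: Zipf-distributed non-medical filler
  plus, for health searches, 1–2 medical terms. The toy lexicon is a rooted
  DAG (root, one head per semantic group, a non-medical branch, a few
  cross-links producing multi-group concepts) with aggregated frequencies
  that guarantee IC monotonicity by construction. A configurable fraction of
  device-only terms is truly non-medical — the device-group misattribution
  phenomenon (common words mapping to obscure device concepts), which makes
  dropping the device group improve agreement with ground-truth
  categorization.
* Each patient ends in a single 1200 s dwell at one facility (one first
  visit; repeat visits would add nothing the pipeline tests). Controls are
  actively kept out of facility geofences so their ground-truth label is
  clean. Ad impressions convert with probability increasing in latent risk;
  costs are lognormal (positive, right-skewed; no cost model is otherwise
  implied).

What the generator does **not** emulate: real tokenized Chinese text and its
segmentation, road-network mobility and GPS error structure, label noise
from passers-by and non-searching visitors, seasonal/weekday structure, and
the long-tailed vocabulary of web-scale logs. A green parameter-recovery
test therefore establishes that the pipeline recovers *planted* signals of
realistic shape and size — not that it would attain any particular AUC on
production logs.

## Open choices and how they were decided

* **Endpoint.** The inclusion rule speaks of history before the *last*
  visit while windowing is defined from the *first*; first-visit is
  implemented (the first visit is the behaviourally interesting transition),
  with `endpoint = "last"` available in `geofence_policy()`.
* **IRS functional form.** Only the verbal properties of the score are
  specified (1 at ≤2 searches, neutral at equal intervals, below 1 under
  shortening, small $w$ best). The mean-of-damped-ratios form above
  satisfies all of them; interval ratios are clamped to [0.01, 100] so
  zero-length or enormous intervals cannot dominate, and a 0/0 ratio (two
  zero-length intervals) counts as no change.
* **Sessions.** Theme-linked sessionization would need search-result data;
  a 30-minute inactivity gap is the standard proxy.
* **"Month" and "search day".** Calendar months of the timestamp, and local
  calendar dates with ≥1 search under a single configured timezone offset —
  both chosen for reproducibility.
* **Proximity radius for the monthly caps** reuses the 200 m geofence
  radius; no second radius is defined anywhere.
* **Run continuation.** A visit run breaks when a search leaves the fence
  or more than 6 h passes between in-fence searches, preventing day-spanning
  phantom dwells.
* **Token-selection analysis 2.** The daywise "term frequency" comparison is
  implemented as the same Fisher machinery on user-day incidences (how many
  patient user-days used the token), for want of a named test; landmark
  categories and name tokens reuse both analyses unchanged.
* **Day specificity** uses the maximum of per-search IC maxima (the mean is
  available via `feature_config(day_specificity_stat = "mean")`), and IC
  uses the natural log (any base is order-preserving). Specificity considers
  only terms mapping into the four medical groups — a clinical terminology
  contains nothing else; the toy lexicon's non-medical branch exists only to
  give filler tokens realistic structure.
* **Score → coefficient map.** Only the target interval (0.7, 1.3) is
  specified; the linear map `0.7 + 0.6 s` is the default and any monotone
  map can be substituted.
* **Local-rate windows** truncate at the ends of the ranking; the window
  size T has no canonical value and is a required configuration parameter
  (`conversion_policy(window_T = ...)`).
* **Split stratification.** Whether the 80/20 split was stratified is
  unspecified; stratified is the default and configurable.

## Numerical and implementation notes

* Lasso/ridge/elastic net are fitted with `glmnet` under a shared,
  stratified, seeded fold assignment; the one-standard-error lambda is used
  (never weaker penalization than the CV minimum — asserted in tests). The
  elastic net grid is alpha ∈ {0.1, 0.3, 0.5, 0.7, 0.9} × a 50-point lambda
  path.
* No random-forest or SVM package can be assumed present, so both are
  implemented in-package: a bagged-CART forest with Gini splits, per-node
  `sqrt(p)` feature sampling and class-distribution leaves (C++, own
  xorshift RNG so forests are reproducible from an integer seed and leave
  R's RNG untouched); and a least-squares SVM with RBF kernel (one linear
  solve per fit), gamma = 1/p, cost by cross-validated AUC, Platt-style
  logistic calibration for probability output. Their correctness is
  checked behaviourally (separable data → AUC > 0.99, permuted labels →
  chance, reproducibility).
* ROC/AUC is computed by trapezoid over tie-grouped thresholds and equals
  the Mann–Whitney statistic exactly (tested to 1e-12); the Hand–Till
  multiclass AUC averages the two one-vs-one AUCs over class pairs and
  reduces exactly to the binary AUC for two classes.
* Per-stage seeds are derived by hashing (global seed, stage name), so a
  change in one stage's draw count cannot shift another stage's stream.
* Every enrichment selection is fitted on training users only; the test
  suite asserts invariance of the selection under perturbation of held-out
  users, and invariance of the feature matrices under perturbation of
  post-endpoint records.

## Known limitations

* Geofence labeling is inherently noisy in the real world (staff, visitors
  who do not search, urban-canyon GPS error); the simulator's clean labels
  mean the pipeline's robustness to label noise is untested here.
* The one-vs-rest leave-category-out ablation is a coarse attribution; at
  small cohort sizes its ordering is noisy, and it is only asserted under a
  world where a single category carries the planted signal.
* The conversion analysis is associational by design: nothing here
  establishes that showing the ad *causes* the visit, only that predicted
  risk and subsequent conversion move together.
* The least-squares SVM is a dense n × n solve — fine for cohort-scale data
  (thousands of users), unsuitable for millions.
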