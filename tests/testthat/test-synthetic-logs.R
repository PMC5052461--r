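test_that("world generation is deterministic and validates its config", {
  w1 <- generate_world(world_config(seed = 7))
  w2 <- generate_world(world_config(seed = 7))
  expect_identical(w1$facilities, w2$facilities)
  expect_identical(w1$landmarks, w2$landmarks)
  expect_identical(w1$lexicon, w2$lexicon)

  w3 <- generate_world(world_config(seed = 8))
  expect_false(identical(w1$facilities$lat, w3$facilities$lat))

  expect_error(generate_world(world_config(n_facilities = 0)), "positive")
  expect_error(generate_world(world_config(
    map_extent = c(lat_min = 30, lat_max = 30, lon_min = 120,
                   lon_max = 121))), "area")
  expect_error(world_config(n_landmark_categories = 1), ">= 2")
  expect_error(world_config(device_noise_rate = 1.5), "probability")
})

test_that("noiseless device group leaves every device term health-labeled", {
  w <- generate_world(world_config(seed = 3, device_noise_rate = 0))
  lex <- w$lexicon
  dev_terms <- lex$terms$term[
    lex$concepts$groups[match(lex$terms$concept,
                              lex$concepts$concept)] == "device"]
  lab <- lex$term_labels$health[match(dev_terms, lex$term_labels$term)]
  expect_true(all(lab))
})

test_that("lexicon frequency is monotone on every parent-child edge", {
  w <- generate_world(world_config(seed = 5, lexicon_size = 200))
  lex <- w$lexicon
  f <- setNames(lex$concepts$frequency, lex$concepts$concept)
  # brute force over every edge of the DAG
  expect_true(all(f[lex$edges$parent] >= f[lex$edges$child]))
  # and every concept is reachable from the root
  parents <- split(lex$edges$parent, lex$edges$child)
  reaches_root <- vapply(lex$concepts$concept, function(cid) {
    seen <- character()
    frontier <- cid
    while (length(frontier)) {
      if ("root" %in% frontier) return(TRUE)
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(parents[frontier]), seen)
    }
    FALSE
  }, logical(1))
  expect_true(all(reaches_root))
})

test_that("user streams honor planted escalation and degenerate cohorts", {
  fx <- fx_small()
  truth <- fx$sim$truth
  rec <- fx$sim$records

  # patients have exactly one visit dwell, inside the simulated period
  expect_true(all(!is.na(truth$first_visit_time[truth$class == "patient"])))
  expect_true(all(is.na(truth$first_visit_time[truth$class == "control"])))

  # planted signal: mean health searches/day higher in the last 5 pre-visit
  # days than in the first 5 window days, for patients
  lex <- fx$world$lexicon
  med <- lex$term_labels$term[lex$term_labels$health]
  rec2 <- data.table::copy(rec)
  rec2$is_med <- vapply(strsplit(rec2$tokens, " ", fixed = TRUE),
                        function(tt) any(tt %in% med), logical(1))
  rec2$date <- floor(rec2$ts / 86400)
  pat <- truth[truth$class == "patient", ]
  deltas <- vapply(seq_len(nrow(pat)), function(i) {
    r <- rec2[rec2$user_id == pat$user_id[i] &
                rec2$ts < pat$first_visit_time[i] - 86400 / 3, ]
    days <- sort(unique(r$date))
    per_day <- tapply(r$is_med, r$date, sum)
    late <- mean(per_day[as.character(utils::tail(days, 5))])
    early <- mean(per_day[as.character(utils::head(days, 5))])
    late - early
  }, numeric(1))
  expect_gt(mean(deltas), 0)

  # controls never produce a retained visit event
  vis <- detect_facility_visits(rec, fx$world$facilities, fx$policy)
  ctl <- truth$user_id[truth$class == "control"]
  expect_length(intersect(unique(vis$user_id), ctl), 0)

  # empty patient class
  sim0 <- generate_users(fx$world, cohort_config(n_patients = 0,
                                                 n_controls = 5,
                                                 days_per_user = 42,
                                                 seed = 9))
  expect_true(all(sim0$truth$class == "control"))
  vis0 <- detect_facility_visits(sim0$records, fx$world$facilities,
                                 fx$policy)
  expect_equal(nrow(vis0), 0)

  expect_error(cohort_config(days_per_user = 41), ">= 42")
})

test_that("null effect sizes make patient and control day counts exchangeable", {
  world <- generate_world(world_config(seed = 31))
  med <- world$lexicon$term_labels$term[world$lexicon$term_labels$health]
  null_effects <- list(health_rate = 1, interval = 1, specificity = 1,
                       location = 1)
  n_reject <- 0L
  for (s in 1:50) {
    sim <- generate_users(world, cohort_config(
      n_patients = 6, n_controls = 6, days_per_user = 42,
      effect_sizes = null_effects, seed = 1000 + s))
    rec <- sim$records
    rec$is_med <- vapply(strsplit(rec$tokens, " ", fixed = TRUE),
                         function(tt) any(tt %in% med), logical(1))
    rec$date <- floor(rec$ts / 86400)
    # pre-endpoint records only (drop the visit-day dwell searches)
    vt <- sim$truth$first_visit_time[match(rec$user_id, sim$truth$user_id)]
    rec <- rec[is.na(vt) | rec$ts < floor(vt / 86400) * 86400, ]
    cls <- sim$truth$class[match(rec$user_id, sim$truth$user_id)]
    cnt <- rec[, .(n = sum(is_med)), by = .(user_id, date)]
    cnt$cls <- sim$truth$class[match(cnt$user_id, sim$truth$user_id)]
    p <- suppressWarnings(
      stats::ks.test(cnt$n[cnt$cls == "patient"],
                     cnt$n[cnt$cls == "control"])$p.value)
    if (p < 0.01) n_reject <- n_reject + 1L
  }
  expect_lte(n_reject, 5L)  # at most 5/50 rejections at alpha = 0.01
})

test_that("ad stream ties conversions to latent risk", {
  world <- generate_world(world_config(seed = 41))
  truth <- data.table::data.table(
    user_id = sprintf("u%05d", 1:5000),
    latent_risk = stats::runif(5000),
    class = "control")

  # empty stream
  s0 <- generate_ad_stream(truth, world, n_impressions = 0)
  expect_equal(nrow(s0$impressions), 0)
  expect_named(s0$impressions,
               c("user_id", "facility_id", "shown_time", "cost"))

  # constant risk->visit function: flat across risk deciles
  sc <- generate_ad_stream(truth, world, n_impressions = 20000,
                           conv_fun = function(r) rep(0.2, length(r)),
                           seed = 42)
  conv <- label_conversions(sc$impressions, sc$visits)
  conv$risk <- truth$latent_risk[match(conv$user_id, truth$user_id)]
  dec <- cut(conv$risk, stats::quantile(conv$risk, 0:10 / 10),
             include.lowest = TRUE)
  rates_flat <- tapply(conv$converted, dec, mean)
  rho_flat <- stats::cor(seq_along(rates_flat), rates_flat,
                         method = "spearman")

  # monotone risk->visit function: decile conversion nondecreasing up to
  # sampling noise
  sm <- generate_ad_stream(truth, world, n_impressions = 20000,
                           conv_fun = function(r) 0.02 + 0.6 * r,
                           seed = 42)
  convm <- label_conversions(sm$impressions, sm$visits)
  convm$risk <- truth$latent_risk[match(convm$user_id, truth$user_id)]
  decm <- cut(convm$risk, stats::quantile(convm$risk, 0:10 / 10),
              include.lowest = TRUE)
  rates_mono <- tapply(convm$converted, decm, mean)
  rho_mono <- stats::cor(seq_along(rates_mono), rates_mono,
                         method = "spearman")
  expect_gt(rho_mono, 0.9)
  expect_lt(abs(rho_flat), rho_mono)

  # determinism
  sm2 <- generate_ad_stream(truth, world, n_impressions = 20000,
                            conv_fun = function(r) 0.02 + 0.6 * r,
                            seed = 42)
  expect_identical(sm$impressions, sm2$impressions)
})
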