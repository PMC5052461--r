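test_that("sessionization follows the inactivity-gap rule", {
  s <- sessionize(c(0, 600, 5000), session_gap_s = 1800)
  expect_equal(nrow(s), 2)
  expect_equal(s$duration_s, c(600, 0))
  expect_equal(s$n_searches, c(2L, 1L))

  s1 <- sessionize(42)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$duration_s, 0)

  s2 <- sessionize(c(0, 1000, 2000, 3000), session_gap_s = 1800)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$duration_s, 3000)

  expect_equal(nrow(sessionize(numeric())), 0)
  expect_error(sessionize(c(5, 1)), "sorted")
})

test_that("interval reduction score matches its defining properties", {
  # two or fewer searches: exactly 1
  expect_identical(interval_reduction_score(c(0, 300)), 1)
  expect_identical(interval_reduction_score(100), 1)
  expect_identical(interval_reduction_score(numeric()), 1)

  # equal intervals: exactly 1 for any w
  for (w in c(0.1, 0.5, 1)) {
    expect_equal(interval_reduction_score(c(0, 100, 200, 300), w), 1)
  }

  # hand computation: deltas 100, 50 -> 0.1 + 0.9 * 0.5 = 0.55
  expect_equal(interval_reduction_score(c(0, 100, 150), w = 0.1), 0.55)

  # shortening < 1 < lengthening
  expect_lt(interval_reduction_score(c(0, 1000, 1500, 1700)), 1)
  expect_gt(interval_reduction_score(c(0, 100, 400, 1300)), 1)

  # zero-length intervals are clamped, not infinite or NaN
  expect_true(is.finite(interval_reduction_score(c(0, 0, 100))))
  expect_true(is.finite(interval_reduction_score(c(0, 100, 100))))
  expect_error(interval_reduction_score(c(-5, 10, 20)), "negative")
})

test_that("information content is exact on a hand-built lexicon and monotone", {
  lex <- tiny_lexicon()
  # root has IC 0; a leaf with aggregated frequency 1 of 1000 has ln(1000)
  expect_equal(unname(-log(lex$concepts$frequency[1] / 1000)), 0)
  expect_equal(information_content("rare_syndrome", lex), log(1000))
  expect_equal(information_content("fever", lex), -log(100 / 1000))
  expect_true(is.na(information_content("unknown_term", lex)))

  # generated lexicon: IC nondecreasing along every root-to-leaf path,
  # checked by brute-force walk over all edges
  w <- generate_world(world_config(seed = 13))
  lx <- w$lexicon
  ic <- setNames(lx$concepts$ic, lx$concepts$concept)
  expect_true(all(ic[lx$edges$child] >= ic[lx$edges$parent] - 1e-12))
  expect_equal(unname(ic["root"]), 0)
})

test_that("day specificity takes the most specific mapped term", {
  lex <- tiny_lexicon()
  day <- make_records(c(0, 60, 120),
                      tokens = c("weather fever", "rare_syndrome weather",
                                 "weather"))
  expect_equal(day_specificity(day, lex), log(1000))
  expect_equal(day_specificity(day, lex, stat = "mean"),
               mean(c(-log(0.1), log(1000))))
  expect_equal(day_specificity(make_records(0, tokens = "weather"), lex), 0)
  expect_equal(day_specificity(make_records(0, tokens = "unmapped"), lex), 0)
})

test_that("semantic group counts allow multi-group membership", {
  lex <- tiny_lexicon()
  r <- make_records(0, tokens = "fever weather")
  expect_equal(semantic_group_counts(r, lex),
               c(disease = 1L, drug = 0L, device = 0L, procedure = 0L))
  # a term mapping to both drug and procedure increments both groups
  r2 <- make_records(0, tokens = "combo_item")
  expect_equal(semantic_group_counts(r2, lex),
               c(disease = 0L, drug = 1L, device = 0L, procedure = 1L))
  r3 <- make_records(c(0, 10), tokens = c("weather", "nonlexicon"))
  expect_equal(sum(semantic_group_counts(r3, lex)), 0)
})

test_that("categorization agreement responds to device-group noise", {
  lex <- tiny_lexicon()
  recs <- make_records(1:4 * 10,
                       tokens = c("fever", "combo_item", "weather",
                                  "weather fever"))
  # noiseless lexicon, all four groups: perfect agreement
  expect_equal(categorization_agreement(
    recs, lex, c("disease", "drug", "device", "procedure")), 1)
  # no groups at all: everything non-health, agreement = non-health share
  expect_equal(categorization_agreement(recs, lex, character(0)), 0.25)

  # with noisy device mappings, dropping the device group helps (direction
  # checked properly over many seeds in the acceptance suite)
  w <- generate_world(world_config(seed = 17, device_noise_rate = 0.5))
  sim <- generate_users(w, cohort_config(n_patients = 5, n_controls = 5,
                                         days_per_user = 42, seed = 18))
  a_all <- categorization_agreement(sim$records, w$lexicon,
                                    c("disease", "drug", "device",
                                      "procedure"))
  a_nodev <- categorization_agreement(sim$records, w$lexicon,
                                      c("disease", "drug", "procedure"))
  expect_gt(a_nodev, a_all)
})

test_that("general features and matrix aggregates agree with brute force", {
  lex <- tiny_lexicon()
  day <- 86400
  # 39 filler days, then a 5-search day (2 health-related) and a 2-search day
  filler <- make_records(day * (1:39) + 10, tokens = "x")
  d40 <- make_records(day * 40 + c(0, 600, 1200, 5000, 5600),
                      tokens = c("fever one", "plain words here",
                                 "combo_item", "a b c d", "weather"))
  d41 <- make_records(day * 41 + c(100, 200),
                      tokens = c("weather one", "weather two"))
  rec <- rbind(filler, d40, d41)
  w <- partition_window(rec, endpoint_time = day * 42, label = "control")
  gf <- general_features(w, lex)
  d2 <- gf$daywise[gf$daywise$day_index == 2, ]  # the 5-search day
  expect_equal(d2$n_searches, 5)
  expect_equal(d2$n_health_searches, 2)
  expect_equal(d2$mean_text_length, mean(c(2, 3, 1, 4, 1)))
  d1 <- gf$daywise[gf$daywise$day_index == 1, ]
  expect_equal(d1$n_searches, 2)
  expect_equal(d1$mean_text_length, mean(c(2, 2)))

  # window aggregates equal the brute-force re-count over all records
  expect_equal(gf$aggregate$n_searches, nrow(rec))
  expect_equal(gf$aggregate$n_health_searches, 2)
  expect_equal(gf$aggregate$mean_text_length,
               mean(lengths(strsplit(rec$tokens, " "))))

  # texts of token lengths 2 and 4 -> mean length 3
  r2 <- make_records(day * 41 + c(0, 60), tokens = c("a b", "a b c d"))
  sw <- partition_window(rbind(
    make_records(day * (1:40) + 10, tokens = "x"), r2), day * 42, "control")
  gf2 <- general_features(sw, lex)
  expect_equal(gf2$daywise$mean_text_length[gf2$daywise$day_index == 1], 3)
})

test_that("matrix assembly has the documented schema and is deterministic", {
  fxm <- fx_small_fm()
  fm <- fxm$fm
  k_tok <- length(fm$selections$tokens)
  k_cat <- length(fm$selections$categories)
  k_name <- length(fm$selections$name_tokens)
  # daywise: 41 x (5 general + 4 groups + 1 specificity + tokens + cats)
  expect_equal(ncol(fm$daywise), 41 * (5 + 4 + 1 + k_tok + k_cat))
  expect_equal(as.vector(table(fm$daywise_category)[c("general",
                                                      "semantic")]),
               c(5 * 41, (4 + 1 + k_tok) * 41))
  # aggregate: 4 general + 4 groups + tokens + cats + name-token binaries
  expect_equal(ncol(fm$aggregate), 8 + k_tok + k_cat + k_name)
  nm_cols <- grep("^locname_", colnames(fm$aggregate))
  if (length(nm_cols))
    expect_true(all(fm$aggregate[, nm_cols] %in% c(0, 1)))
  expect_false(any(is.na(fm$daywise)))
  expect_false(any(is.na(fm$aggregate)))

  # daywise counts summed over days equal the aggregate re-count
  for (f in c("n_searches", "n_health_searches", "n_disease", "n_drug")) {
    day_cols <- grep(paste0("^", f, "\\.d"), colnames(fm$daywise))
    expect_equal(unname(rowSums(fm$daywise[, day_cols])),
                 unname(fm$aggregate[, paste0("agg_", f)]))
  }

  # byte-identical on rebuild
  fx <- fx_small()
  fm2 <- build_matrices(fx$windows, fx$world$lexicon, fxm$selections)
  expect_identical(fm, fm2)
})

test_that("features leak nothing across users or from beyond the endpoint", {
  fx <- fx_small()
  fxm <- fx_small_fm()
  # perturb every user's records after the endpoint (the raw log keeps
  # post-endpoint visit-day searches) and rebuild: matrices are identical
  rec <- data.table::copy(fx$sim$records)
  ep <- fx$windows$cohort$endpoint_time[match(rec$user_id,
                                              fx$windows$cohort$user_id)]
  post <- !is.na(ep) & rec$ts >= ep
  expect_gt(sum(post), 0)
  # tokens only: coordinates of the post-endpoint dwell define the visit
  # label itself, which is the endpoint, not a feature
  rec$tokens[post] <- "poisoned token stream"
  win2 <- suppressMessages(build_cohort(rec, fx$world$facilities, fx$policy,
                                        seed = 103))
  win2 <- annotate_locations(win2, fx$world$landmarks)
  fm2 <- build_matrices(win2, fx$world$lexicon, fxm$selections)
  expect_identical(fxm$fm$daywise, fm2$daywise)
  expect_identical(fxm$fm$aggregate, fm2$aggregate)

  # no feature of user u depends on records of user v: dropping one user
  # leaves every other row unchanged
  keep <- fx$windows$cohort$user_id[-1]
  win3 <- fx$windows
  win3$records <- win3$records[win3$records$user_id %in% keep, ]
  win3$cohort <- win3$cohort[win3$cohort$user_id %in% keep, ]
  fm3 <- build_matrices(win3, fx$world$lexicon, fxm$selections)
  expect_equal(fm3$daywise, fxm$fm$daywise[rownames(fm3$daywise), ])
})
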