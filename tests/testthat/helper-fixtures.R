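# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small cohort with default effect sizes: 20 patients + 24 controls, 45 days
fx_small <- function() memo("small", function() {
  world <- generate_world(world_config(seed = 101))
  sim <- generate_users(world, cohort_config(n_patients = 20, n_controls = 24,
                                             days_per_user = 45, seed = 102))
  policy <- geofence_policy()
  windows <- suppressMessages(
    build_cohort(sim$records, world$facilities, policy, seed = 103))
  windows <- annotate_locations(windows, world$landmarks)
  list(world = world, sim = sim, policy = policy, windows = windows)
})

# feature matrices for the small cohort, selections fitted on a training split
fx_small_fm <- function() memo("small_fm", function() {
  fx <- fx_small()
  coh <- fx$windows$cohort
  labels <- as.integer(coh$label == "patient")
  sp <- split_train_test(matrix(0, nrow(coh), 1,
                                dimnames = list(coh$user_id)),
                         labels, 0.8, seed = 104)
  train_users <- coh$user_id[sp$train_idx]
  sel <- suppressMessages(list(
    tokens = select_enriched_tokens(fx$windows, train_users),
    categories = select_enriched_location_categories(fx$windows, train_users),
    name_tokens = select_enriched_name_tokens(fx$windows, train_users)))
  fm <- build_matrices(fx$windows, fx$world$lexicon, sel)
  list(fm = fm, train_users = train_users, selections = sel)
})

# hand-built toy lexicon with known structure and frequencies:
#   root(agg 1000) -> disease head -> d1 (multi-parent from drug head too)
# terms: one per ordinary concept; frequencies chosen for exact IC values
tiny_lexicon <- function() {
  concepts <- data.table::data.table(
    concept = c("root", "head_disease", "head_drug", "head_procedure",
                "head_device", "head_general", "c_dis", "c_dis_leaf",
                "c_drugproc", "c_gen"),
    depth = c(0L, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 2L, 2L),
    own_count = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    frequency = c(1000, 400, 200, 150, 50, 200, 100, 1, 60, 120),
    groups = c("", "disease", "drug", "procedure", "device", "",
               "disease", "disease", "drug,procedure", ""),
    ic = NA_real_
  )
  concepts$ic <- -log(concepts$frequency / 1000)
  terms <- data.table::data.table(
    term = c("fever", "rare_syndrome", "combo_item", "weather"),
    concept = c("c_dis", "c_dis_leaf", "c_drugproc", "c_gen"))
  edges <- data.table::data.table(
    child = c("head_disease", "head_drug", "head_procedure", "head_device",
              "head_general", "c_dis", "c_dis_leaf", "c_drugproc",
              "c_drugproc", "c_gen"),
    parent = c("root", "root", "root", "root", "root", "head_disease",
               "c_dis", "head_drug", "head_procedure", "head_general"))
  lex <- list(terms = terms, concepts = concepts, edges = edges,
              root = "root",
              term_labels = data.table::data.table(
                term = terms$term,
                health = c(TRUE, TRUE, TRUE, FALSE)))
  class(lex) <- "toy_lexicon"
  lex
}

# one-user records table helper
make_records <- function(ts, lat = 30, lon = 120, tokens = "weather",
                         user = "u1") {
  n <- length(ts)
  data.table::data.table(user_id = rep(user, n), ts = as.numeric(ts),
                         lat = rep_len(lat, n), lon = rep_len(lon, n),
                         tokens = rep_len(tokens, n))
}

# a synthetic analysis-window stack built directly from per-user day streams:
# `usage` is a named list user -> character vector of space-joined token
# strings, one per synthetic search (all placed on day 1)
windows_from_tokens <- function(usage, labels) {
  recs <- data.table::rbindlist(lapply(names(usage), function(u) {
    toks <- usage[[u]]
    data.table::data.table(user_id = u,
                           ts = 1000 + seq_along(toks) * 60,
                           lat = 30, lon = 120, tokens = toks,
                           date = 0L, day_index = 1L,
                           label = labels[[u]])
  }))
  out <- list(records = recs,
              cohort = data.table::data.table(
                user_id = names(usage),
                label = unlist(labels)[names(usage)],
                endpoint_time = 86400, n_search_days = 1L),
              n_days = 1L)
  class(out) <- "search_windows"
  out
}

# independent two-sided Fisher p-value oracle: exhaustive summation of
# hypergeometric point probabilities no larger than the observed one
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b        # patients
  n <- c + d        # controls
  k <- a + c        # users of the item
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
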