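#' Feature-engineering configuration
#'
#' @param irs_weight weight `w` of the interval reduction score, in (0, 1\];
#'   small values near 0.1 work best
#' @param session_gap_s inactivity gap that closes a search session
#' @param n_enriched_tokens maximum enriched search tokens kept
#' @param n_enriched_location_categories maximum enriched landmark categories
#' @param n_location_name_tokens maximum enriched location-name tokens
#' @param bonferroni_alpha family-wise significance level for enrichment
#' @param coord_round_places decimal places for coordinate rounding before
#'   landmark resolution (4 places is about 11 m of latitude)
#' @param health_groups semantic groups whose terms flag a search as
#'   health-related (device excluded by default: its mappings are noisy)
#' @param day_specificity_stat `"max"` (default) or `"mean"` of per-search
#'   maximum information content within a day
#' @return a `feature_config` list
#' @export
feature_config <- function(irs_weight = 0.1,
                           session_gap_s = 1800,
                           n_enriched_tokens = 100L,
                           n_enriched_location_categories = 53L,
                           n_location_name_tokens = 113L,
                           bonferroni_alpha = 0.05,
                           coord_round_places = 4L,
                           health_groups = c("disease", "drug", "procedure"),
                           day_specificity_stat = c("max", "mean")) {
  if (irs_weight <= 0 || irs_weight > 1)
    stop("irs_weight must lie in (0, 1]", call. = FALSE)
  counts <- c(n_enriched_tokens, n_enriched_location_categories,
              n_location_name_tokens)
  if (any(counts <= 0)) stop("enrichment counts must be > 0", call. = FALSE)
  cfg <- list(irs_weight = irs_weight, session_gap_s = session_gap_s,
              n_enriched_tokens = as.integer(n_enriched_tokens),
              n_enriched_location_categories =
                as.integer(n_enriched_location_categories),
              n_location_name_tokens = as.integer(n_location_name_tokens),
              bonferroni_alpha = bonferroni_alpha,
              coord_round_places = as.integer(coord_round_places),
              health_groups = health_groups,
              day_specificity_stat = match.arg(day_specificity_stat))
  class(cfg) <- "feature_config"
  cfg
}

#' Group searches into sessions by inactivity gap
#'
#' Consecutive searches no more than `session_gap_s` apart share a session;
#' a session's duration is its last minus first timestamp (0 for a
#' single-search session).
#'
#' @param ts numeric timestamps (epoch seconds), or a records table with a
#'   `ts` column; must be time-sorted
#' @param session_gap_s inactivity gap in seconds
#' @return `data.table` with one row per session: session, start, end,
#'   duration_s, n_searches
#' @export
sessionize <- function(ts, session_gap_s = 1800) {
  if (is.data.frame(ts)) ts <- ts$ts
  if (length(ts) == 0)
    return(data.table::data.table(session = integer(), start = numeric(),
                                  end = numeric(), duration_s = numeric(),
                                  n_searches = integer()))
  if (is.unsorted(ts)) stop("timestamps must be sorted", call. = FALSE)
  sess <- cumsum(c(1L, as.integer(diff(ts) > session_gap_s)))
  data.table::data.table(ts = ts, session = sess)[
    , .(start = ts[1], end = ts[.N], duration_s = ts[.N] - ts[1],
        n_searches = .N), by = "session"]
}

#' Interval reduction score of one search day
#'
#' Summarizes shortening (< 1) or lengthening (> 1) of the intervals between
#' consecutive health-related searches within a day. With intervals
#' \eqn{\Delta_i = t_{i+1} - t_i}, the score is the mean over successive
#' interval pairs of \eqn{w + (1 - w)\,\Delta_{i+1}/\Delta_i}; days with two
#' or fewer searches score exactly 1, and equal intervals give exactly 1.
#' Interval ratios are clamped to \[0.01, 100\] so zero-length or extreme
#' intervals cannot dominate the mean.
#'
#' @param ts time-sorted timestamps (seconds) of one day's health-related
#'   searches
#' @param w weight in (0, 1\]; the default 0.1 damps extreme ratios
#' @return the score (1 when fewer than three searches)
#' @export
interval_reduction_score <- function(ts, w = 0.1) {
  if (any(ts < 0)) stop("negative timestamps", call. = FALSE)
  n <- length(ts)
  if (n <= 2L) return(1)
  if (is.unsorted(ts)) stop("timestamps must be sorted", call. = FALSE)
  delta <- diff(ts)
  ratio <- delta[-1] / delta[-length(delta)]
  ratio[is.nan(ratio)] <- 1      # 0/0: two zero-length intervals, no change
  ratio <- pmin(pmax(ratio, 0.01), 100)
  mean(w + (1 - w) * ratio)
}

# per-term lookup tables used by the record annotator; `med_ic` is the IC of
# the term when it maps to a medical concept (member of at least one
# semantic group) and NA otherwise — specificity scores consider medical
# terminology only, as a clinical lexicon would contain nothing else
.lexicon_lookup <- function(lexicon) {
  terms <- lexicon$terms
  cinfo <- lexicon$concepts
  ci <- match(terms$concept, cinfo$concept)
  medical <- nzchar(cinfo$groups[ci])
  ic <- cinfo$ic[ci]
  list(term = terms$term,
       groups = strsplit(cinfo$groups[ci], ",", fixed = TRUE),
       ic = ic,
       med_ic = ifelse(medical, ic, NA_real_))
}

#' Information content of a lexicon term
#'
#' \eqn{IC(t) = -\ln(f(c_t)/f(root))} where \eqn{f} is the aggregated corpus
#' frequency of a concept (its own count plus all descendants'), so IC is 0
#' at the root and nondecreasing along every root-to-leaf path.
#'
#' @param term term string(s); unmapped terms give `NA`
#' @param lexicon a `toy_lexicon`
#' @return IC score(s), natural log scale
#' @export
information_content <- function(term, lexicon) {
  lk <- .lexicon_lookup(lexicon)
  lk$ic[match(term, lk$term)]
}

#' Daywise search specificity
#'
#' The specificity of a search is the information content of its most
#' specific term mapping to the medical terminology (terms outside the four
#' semantic groups are skipped); the day score is the maximum (or mean, via
#' `stat`) of per-search specificities. A day with no mapped medical term
#' scores 0.
#'
#' @param day_records one day's records (needs a `tokens` column)
#' @param lexicon a `toy_lexicon`
#' @param stat `"max"` or `"mean"`
#' @return the day score
#' @export
day_specificity <- function(day_records, lexicon, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  lk <- .lexicon_lookup(lexicon)
  toks <- split_tokens(day_records$tokens)
  per_search <- vapply(toks, function(tt) {
    ic <- lk$med_ic[match(tt, lk$term)]
    if (all(is.na(ic))) NA_real_ else max(ic, na.rm = TRUE)
  }, numeric(1))
  per_search <- per_search[!is.na(per_search)]
  if (length(per_search) == 0) return(0)
  if (stat == "max") max(per_search) else mean(per_search)
}

#' Per-day semantic group counts
#'
#' A search counts toward a group if any of its tokens maps to a concept in
#' that group; a single search can count in several groups.
#'
#' @param day_records one day's records (needs a `tokens` column)
#' @param lexicon a `toy_lexicon`
#' @return named integer vector: disease, drug, device, procedure
#' @export
semantic_group_counts <- function(day_records, lexicon) {
  lk <- .lexicon_lookup(lexicon)
  toks <- split_tokens(day_records$tokens)
  counts <- setNames(integer(4), SEMANTIC_GROUPS)
  for (tt in toks) {
    g <- unique(unlist(lk$groups[match(tt, lk$term)]))
    g <- g[!is.na(g) & nzchar(g)]
    counts[g] <- counts[g] + 1L
  }
  counts
}

#' Agreement between lexicon-based and reference health categorization
#'
#' Flags each search as health-related if any token maps to one of the
#' `included_groups`, and compares the flag with the reference (ground-truth)
#' health label of the search. Leaving the noisy device group out typically
#' improves agreement when device-mapped terms are contaminated with common
#' non-medical words.
#'
#' @param records search records (needs `tokens`)
#' @param lexicon a `toy_lexicon`
#' @param included_groups character subset of the four semantic groups (may
#'   be empty: then every search is categorized non-health)
#' @param reference_labels per-term truth, a table with columns `term` and
#'   logical `health` (defaults to the lexicon's ground truth)
#' @return fraction of searches on which the two categorizations agree
#' @export
categorization_agreement <- function(records, lexicon, included_groups,
                                     reference_labels = lexicon$term_labels) {
  stopifnot(all(included_groups %in% SEMANTIC_GROUPS))
  lk <- .lexicon_lookup(lexicon)
  toks <- split_tokens(records$tokens)
  in_grp <- vapply(lk$groups, function(g) any(g %in% included_groups),
                   logical(1))
  flag <- vapply(toks, function(tt)
    any(in_grp[match(tt, lk$term)], na.rm = TRUE), logical(1))
  truth_health <- setNames(reference_labels$health, reference_labels$term)
  ref <- vapply(toks, function(tt)
    any(truth_health[tt], na.rm = TRUE), logical(1))
  mean(flag == ref)
}
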