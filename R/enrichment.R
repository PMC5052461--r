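#' Case/control enrichment by Fisher's exact test with Bonferroni correction
#'
#' Generic machinery behind token, landmark-category and location-name-token
#' selection. For each item the 2x2 table (patients using / not, controls
#' using / not) is tested with a two-sided Fisher exact test; p-values are
#' Bonferroni-adjusted over the number of items tested. "Best performing"
#' items are those significant at `alpha`, ranked by adjusted p ascending
#' with ties broken by larger absolute log odds ratio and then item id.
#'
#' @param incidence table of unique (unit, item) pairs, columns `unit` and
#'   `item`; a unit is a user (or a user-day) of the *training split*
#' @param unit_labels table with columns `unit` and `label`
#'   ("patient"/"control") covering every training unit
#' @param k maximum number of items to select
#' @param alpha family-wise significance level
#' @return an `enrichment_result`: list with `table` (item, counts, p_value,
#'   p_adj, significant, direction) and `selected` (character vector,
#'   length <= k; fewer when fewer items pass the Bonferroni bar)
#' @export
fisher_enrichment <- function(incidence, unit_labels, k, alpha = 0.05) {
  inc <- unique(data.table::as.data.table(incidence)[, c("unit", "item")])
  lab <- data.table::as.data.table(unit_labels)
  n_pat <- sum(lab$label == "patient")
  n_ctl <- sum(lab$label == "control")
  inc$label <- lab$label[match(inc$unit, lab$unit)]

  counts <- inc[, .(a = sum(label == "patient"),
                    c = sum(label == "control")), by = "item"]
  counts$b <- n_pat - counts$a
  counts$d <- n_ctl - counts$c

  res <- counts[, {
    p <- vapply(seq_len(.N), function(i)
      stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2))$p.value,
      numeric(1))
    lo <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
    .(item = item, a = a, b = b, c = c, d = d, p_value = p,
      log_odds = lo)
  }]
  res$p_adj <- pmin(1, res$p_value * nrow(res))
  res$significant <- res$p_adj < alpha
  res$direction <- ifelse(res$log_odds > 0, "patient", "control")
  res$abs_lo <- abs(res$log_odds)
  data.table::setorder(res, p_adj, -abs_lo, item)
  res$abs_lo <- NULL

  selected <- head(res$item[res$significant], k)
  if (sum(res$significant) < k)
    message(sprintf(
      "fisher_enrichment: %d significant items for k = %d; returning all",
      sum(res$significant), k))
  out <- list(table = res[], selected = selected, k = as.integer(k),
              alpha = alpha)
  class(out) <- "enrichment_result"
  out
}

#' @export
#' @method print enrichment_result
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d items tested, %d significant, %d selected\n",
              nrow(x$table), sum(x$table$significant), length(x$selected)))
  invisible(x)
}

# unique (unit, item) incidence from window records; unit is the user or
# the user-day, item every token of the search text
.token_incidence <- function(records, per_day = FALSE) {
  toks <- split_tokens(records$tokens)
  n <- lengths(toks)
  unit <- if (per_day) paste(records$user_id, records$day_index, sep = "#")
  else records$user_id
  data.table::data.table(unit = rep(unit, n), item = unlist(toks))
}

#' Select enriched search tokens on the training split
#'
#' Two analyses are run and combined: (1) per token, a Fisher test on the
#' numbers of patients vs controls that used the token anywhere in their
#' window; (2) per token, the same test on user-day incidences (how many
#' patient user-days vs control user-days used the token), comparing daywise
#' term frequency between the classes. The union of significant tokens from
#' both analyses is ranked by the smaller adjusted p-value and the best `k`
#' are kept.
#'
#' @param windows a `search_windows` object
#' @param train_users users the selection may look at (training split);
#'   defaults to all users in `windows`
#' @param config a [feature_config()]
#' @return an `enrichment_result`; `table` carries an `analysis` column
#' @export
select_enriched_tokens <- function(windows, train_users = NULL,
                                   config = feature_config()) {
  windows <- as_search_windows(windows)
  rec <- windows$records
  coh <- windows$cohort
  if (!is.null(train_users)) {
    rec <- rec[rec$user_id %in% train_users, ]
    coh <- coh[coh$user_id %in% train_users, ]
  }
  .two_analysis_selection(.token_incidence(rec, per_day = FALSE),
                          .token_incidence(rec, per_day = TRUE),
                          coh, rec, config$n_enriched_tokens,
                          config$bonferroni_alpha)
}

# incidence of visited landmark categories / location name tokens, with the
# unit either the user or the user-day
.location_incidence <- function(records, what = c("category", "name_token"),
                                per_day = FALSE) {
  what <- match.arg(what)
  unit <- if (per_day) paste(records$user_id, records$day_index, sep = "#")
  else records$user_id
  if (what == "category") {
    data.table::data.table(unit = unit, item = records$landmark_category)
  } else {
    toks <- split_tokens(records$landmark_name)
    data.table::data.table(unit = rep(unit, lengths(toks)),
                           item = unlist(toks))
  }
}

# run the user-level and user-day-level Fisher analyses on a pair of
# incidence tables and combine them as select_enriched_tokens does
.two_analysis_selection <- function(inc_user, inc_day, coh, rec, k, alpha) {
  r1 <- fisher_enrichment(inc_user,
                          data.table::data.table(unit = coh$user_id,
                                                 label = coh$label),
                          k = k, alpha = alpha)
  day_units <- unique(rec[, .(unit = paste(user_id, day_index, sep = "#"),
                              label = label)])
  r2 <- fisher_enrichment(inc_day, day_units, k = k, alpha = alpha)
  t1 <- data.table::copy(r1$table)[, analysis := "users"]
  t2 <- data.table::copy(r2$table)[, analysis := "user_days"]
  both <- rbind(t1, t2)
  best <- both[, .SD[which.min(p_adj)], by = "item"]
  best$abs_lo <- abs(best$log_odds)
  data.table::setorder(best, p_adj, -abs_lo, item)
  selected <- head(best$item[best$significant], k)
  out <- list(table = both[], selected = selected, k = as.integer(k),
              alpha = alpha)
  class(out) <- "enrichment_result"
  out
}

#' Select enriched landmark categories and location-name tokens
#'
#' Reuses the token Fisher/Bonferroni machinery (both the user-level and the
#' user-day-level analyses) on incidence of, respectively, the landmark
#' category a search was mapped to and the word tokens of the mapped
#' landmark's name. Records must have been annotated with
#' [annotate_locations()] first.
#'
#' @param windows a `search_windows` whose records carry `landmark_category`
#'   and `landmark_name`
#' @param train_users training-split users (defaults to all)
#' @param config a [feature_config()]
#' @return an `enrichment_result`
#' @export
select_enriched_location_categories <- function(windows, train_users = NULL,
                                                config = feature_config()) {
  windows <- as_search_windows(windows)
  rec <- windows$records
  coh <- windows$cohort
  if (!is.null(train_users)) {
    rec <- rec[rec$user_id %in% train_users, ]
    coh <- coh[coh$user_id %in% train_users, ]
  }
  .two_analysis_selection(.location_incidence(rec, "category"),
                          .location_incidence(rec, "category",
                                              per_day = TRUE),
                          coh, rec, config$n_enriched_location_categories,
                          config$bonferroni_alpha)
}

#' @rdname select_enriched_location_categories
#' @export
select_enriched_name_tokens <- function(windows, train_users = NULL,
                                        config = feature_config()) {
  windows <- as_search_windows(windows)
  rec <- windows$records
  coh <- windows$cohort
  if (!is.null(train_users)) {
    rec <- rec[rec$user_id %in% train_users, ]
    coh <- coh[coh$user_id %in% train_users, ]
  }
  .two_analysis_selection(.location_incidence(rec, "name_token"),
                          .location_incidence(rec, "name_token",
                                              per_day = TRUE),
                          coh, rec, config$n_location_name_tokens,
                          config$bonferroni_alpha)
}
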