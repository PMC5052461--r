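# Daywise and aggregate feature assembly.
#
# All heavy lifting is vectorized over the stacked window records; the
# exported per-window helpers (general_features, location_features) are thin
# wrappers over the same internals so single-window results and full
# matrices cannot drift apart.

# per-record annotations: token count, semantic-group flags, health flag,
# maximum information content of mapped tokens
.annotate_records <- function(rec, lexicon, config) {
  lk <- .lexicon_lookup(lexicon)
  in_grp <- vapply(SEMANTIC_GROUPS, function(g)
    vapply(lk$groups, function(x) g %in% x, logical(1)),
    logical(length(lk$term)))  # term x group

  toks <- split_tokens(rec$tokens)
  n_tok <- lengths(toks)
  long <- data.table::data.table(rid = rep(seq_along(toks), n_tok),
                                 token = unlist(toks))
  ti <- match(long$token, lk$term)
  long$ic <- lk$med_ic[ti]   # specificity considers medical terms only
  for (g in SEMANTIC_GROUPS) {
    v <- in_grp[, g][ti]
    v[is.na(v)] <- FALSE
    long[[paste0("g_", g)]] <- v
  }
  hg <- paste0("g_", config$health_groups)
  long$healthy <- Reduce(`|`, lapply(hg, function(h) long[[h]]))

  agg <- long[, c(list(max_ic = if (all(is.na(ic))) 0 else max(ic, na.rm = TRUE),
                       is_health = any(healthy)),
                  lapply(.SD, any)),
              by = "rid", .SDcols = paste0("g_", SEMANTIC_GROUPS)]
  out <- data.table::data.table(rid = seq_along(toks), n_tokens = n_tok)
  out <- agg[out, on = "rid"]
  data.table::setorder(out, rid)
  out
}

# session ids over the whole record set, per user-day, by inactivity gap
.session_ids <- function(rec, gap) {
  newu <- c(TRUE, rec$user_id[-1] != rec$user_id[-nrow(rec)] |
              rec$day_index[-1] != rec$day_index[-nrow(rec)])
  cumsum(newu | c(TRUE, diff(rec$ts) > gap))
}

# base daywise features per (user_id, day_index); rec must carry label and
# be sorted by user, ts
.daywise_base <- function(rec, lexicon, config) {
  ann <- .annotate_records(rec, lexicon, config)
  r <- data.table::copy(rec)
  r$n_tokens <- ann$n_tokens
  r$is_health <- ann$is_health
  r$max_ic <- ann$max_ic
  for (g in SEMANTIC_GROUPS) r[[paste0("g_", g)]] <- ann[[paste0("g_", g)]]
  r$sess <- .session_ids(r, config$session_gap_s)

  sess_tab <- r[, .(user_id = user_id[1], day_index = day_index[1],
                    dur = ts[.N] - ts[1]), by = "sess"]
  sess_day <- sess_tab[, .(mean_session_duration = mean(dur)),
                       by = c("user_id", "day_index")]

  w <- config$irs_weight
  spec_stat <- config$day_specificity_stat
  base <- r[, .(
    n_searches = .N,
    n_health_searches = sum(is_health),
    mean_text_length = mean(n_tokens),
    irs = interval_reduction_score(sort(ts[is_health]), w),
    specificity = {
      ic <- max_ic[max_ic > 0]
      if (length(ic) == 0) 0
      else if (spec_stat == "max") max(ic) else mean(ic)
    },
    n_disease = sum(g_disease),
    n_drug = sum(g_drug),
    n_device = sum(g_device),
    n_procedure = sum(g_procedure)
  ), by = c("user_id", "day_index")]
  base <- sess_day[base, on = c("user_id", "day_index")]
  base
}

#' Daywise general features of one analysis window
#'
#' Per search day: number of searches, number of health-related searches,
#' mean session duration, mean search-text length and the interval reduction
#' score; plus the same quantities (without the IRS) aggregated over the
#' whole window.
#'
#' @param window an `analysis_window`
#' @param lexicon a `toy_lexicon`
#' @param config a [feature_config()]
#' @return list with `daywise` (one row per day index) and `aggregate`
#'   (one row)
#' @export
general_features <- function(window, lexicon, config = feature_config()) {
  sw <- as_search_windows(window)
  rec <- data.table::copy(sw$records)
  data.table::setorder(rec, user_id, ts)
  base <- .daywise_base(rec, lexicon, config)
  data.table::setorder(base, user_id, day_index)
  day <- base[, c("user_id", "day_index", "n_searches", "n_health_searches",
                  "mean_session_duration", "mean_text_length", "irs")]

  ann <- .annotate_records(rec, lexicon, config)
  sess <- sessionize(sort(rec$ts), config$session_gap_s)
  aggr <- data.table::data.table(
    user_id = rec$user_id[1],
    n_searches = nrow(rec),
    n_health_searches = sum(ann$is_health),
    mean_session_duration = mean(sess$duration_s),
    mean_text_length = mean(ann$n_tokens))
  list(daywise = day, aggregate = aggr)
}

#' Daywise location features of one analysis window
#'
#' Per-day counts of searches mapped to each enriched landmark category and
#' window-level binary indicators for enriched location-name tokens.
#'
#' @param window an `analysis_window` with location-annotated records (see
#'   [annotate_locations()])
#' @param landmarks gazetteer; used to annotate if not already done
#' @param enriched_categories character vector (or `enrichment_result`) of
#'   categories to count
#' @param name_tokens character vector (or `enrichment_result`) of location
#'   name tokens to indicate
#' @param config a [feature_config()]
#' @return list with `daywise` (user_id, day_index, one column per category)
#'   and `aggregate` (user_id, one 0/1 column per name token)
#' @export
location_features <- function(window, landmarks, enriched_categories,
                              name_tokens, config = feature_config()) {
  sw <- as_search_windows(window)
  if (is.null(sw$records$landmark_category))
    sw <- annotate_locations(sw, landmarks, config)
  cats <- if (inherits(enriched_categories, "enrichment_result"))
    enriched_categories$selected else enriched_categories
  nts <- if (inherits(name_tokens, "enrichment_result"))
    name_tokens$selected else name_tokens
  rec <- sw$records

  grid <- data.table::CJ(user_id = unique(rec$user_id),
                         day_index = seq_len(sw$n_days))
  day <- grid
  for (cc in cats) {
    cnt <- rec[rec$landmark_category == cc,
               .(v = .N), by = c("user_id", "day_index")]
    day <- cnt[day, on = c("user_id", "day_index")]
    data.table::setnames(day, "v", paste0("loccat_", cc))
  }
  for (j in names(day)) data.table::set(day, which(is.na(day[[j]])), j, 0)
  data.table::setorder(day, user_id, day_index)

  name_long <- data.table::data.table(
    user_id = rep(rec$user_id, lengths(split_tokens(rec$landmark_name))),
    item = unlist(split_tokens(rec$landmark_name)))
  aggr <- data.table::data.table(user_id = unique(rec$user_id))
  for (nt in nts)
    aggr[[paste0("locname_", nt)]] <-
      as.integer(aggr$user_id %in% name_long$user_id[name_long$item == nt])
  list(daywise = day[], aggregate = aggr)
}

# long (user, feature, day, value) -> users x (feature.day) matrix with the
# given feature order and days 1..n_days nested within feature
.wide_matrix <- function(long, users, features, n_days) {
  long$col <- paste0(long$feature, ".d", sprintf("%02d", long$day_index))
  cols <- as.vector(t(outer(features, sprintf(".d%02d", seq_len(n_days)),
                            paste0)))
  m <- matrix(0, nrow = length(users), ncol = length(cols),
              dimnames = list(users, cols))
  ri <- match(long$user_id, users)
  ci <- match(long$col, cols)
  ok <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[ok], ci[ok])] <- long$value[ok]
  m
}

#' Assemble model-ready daywise and aggregate feature matrices
#'
#' Builds the full Table-style schema: per day, 5 general features, 4
#' semantic-group counts, 1 specificity score, one count column per enriched
#' token and one per enriched landmark category; aggregates are the
#' window-level counterparts plus 0/1 location-name-token indicators. Every
#' column carries a feature-category tag (general/semantic/location) for the
#' ablation study. Selections must have been fitted on training users only;
#' the schema is fixed by the selections, so users outside the training set
#' simply receive columns for the selected items.
#'
#' @param windows a `search_windows`, location-annotated if location features
#'   are wanted
#' @param lexicon a `toy_lexicon`
#' @param selections list with elements `tokens`, `categories`,
#'   `name_tokens` (each an `enrichment_result` or character vector); any may
#'   be `NULL` to omit the corresponding columns
#' @param config a [feature_config()]
#' @return a `feature_matrices` object: list with `daywise` and `aggregate`
#'   numeric matrices (rownames = user ids), `daywise_category` /
#'   `aggregate_category` tag vectors, `labels` (0/1, patient = 1) and
#'   `users`
#' @export
build_matrices <- function(windows, lexicon, selections = list(),
                           config = feature_config()) {
  sw <- as_search_windows(windows)
  rec <- data.table::copy(sw$records)
  data.table::setorder(rec, user_id, ts)
  n_days <- sw$n_days
  users <- sort(unique(sw$cohort$user_id))

  sel <- lapply(selections, function(s)
    if (inherits(s, "enrichment_result")) s$selected else s)
  tokens <- sel$tokens %||% character()
  cats <- sel$categories %||% character()
  nts <- sel$name_tokens %||% character()

  base <- .daywise_base(rec, lexicon, config)
  base_feats <- c("n_searches", "n_health_searches", "mean_session_duration",
                  "mean_text_length", "irs", "n_disease", "n_drug",
                  "n_device", "n_procedure", "specificity")
  for (f in base_feats) base[[f]] <- as.numeric(base[[f]])
  long_base <- data.table::melt(base, id.vars = c("user_id", "day_index"),
                                measure.vars = base_feats,
                                variable.name = "feature",
                                value.name = "value")
  long_base$feature <- as.character(long_base$feature)

  # per-token daywise counts (searches containing the token)
  long_tok <- NULL
  if (length(tokens)) {
    toks <- split_tokens(rec$tokens)
    tl <- data.table::data.table(rid = rep(seq_along(toks), lengths(toks)),
                                 token = unlist(toks))
    tl <- unique(tl[tl$token %in% tokens, ])
    tl$user_id <- rec$user_id[tl$rid]
    tl$day_index <- rec$day_index[tl$rid]
    long_tok <- tl[, .(value = .N), by = c("user_id", "day_index", "token")]
    long_tok$feature <- paste0("tok_", long_tok$token)
    long_tok$token <- NULL
  }

  long_cat <- NULL
  if (length(cats)) {
    if (is.null(rec$landmark_category))
      stop("records lack landmark annotations; run annotate_locations()",
           call. = FALSE)
    cl <- rec[rec$landmark_category %in% cats,
              .(value = .N), by = c("user_id", "day_index",
                                    "landmark_category")]
    cl$feature <- paste0("loccat_", cl$landmark_category)
    cl$landmark_category <- NULL
    long_cat <- cl
  }

  prefix <- function(p, v) if (length(v)) paste0(p, v) else character(0)
  feat_order <- c(c("n_searches", "n_health_searches",
                    "mean_session_duration", "mean_text_length", "irs"),
                  c("n_disease", "n_drug", "n_device", "n_procedure"),
                  "specificity",
                  prefix("tok_", tokens), prefix("loccat_", cats))
  long <- data.table::rbindlist(list(
    long_base[, c("user_id", "day_index", "feature", "value")],
    long_tok, long_cat), use.names = TRUE)
  # IRS default is 1, not 0, for day cells never touched (cannot occur for
  # complete windows, but keep the fill faithful)
  daywise <- .wide_matrix(long, users, feat_order, n_days)

  cat_of <- function(f) {
    if (f %in% c("n_searches", "n_health_searches", "mean_session_duration",
                 "mean_text_length", "irs")) "general"
    else if (startsWith(f, "loccat_") || startsWith(f, "locname_")) "location"
    else "semantic"
  }
  daywise_category <- vapply(sub("\\.d[0-9]+$", "", colnames(daywise)),
                             cat_of, character(1))

  # ---- aggregate matrix ----
  ann <- .annotate_records(rec, lexicon, config)
  rec2 <- data.table::copy(rec)
  rec2$n_tokens <- ann$n_tokens
  rec2$is_health <- ann$is_health
  for (g in SEMANTIC_GROUPS) rec2[[paste0("g_", g)]] <- ann[[paste0("g_", g)]]
  rec2$sess <- .session_ids(rec2, config$session_gap_s)
  sess_dur <- rec2[, .(dur = ts[.N] - ts[1], user_id = user_id[1]),
                   by = "sess"]
  agg_gen <- rec2[, .(
    agg_n_searches = .N,
    agg_n_health_searches = sum(is_health),
    agg_mean_text_length = mean(n_tokens),
    agg_n_disease = sum(g_disease), agg_n_drug = sum(g_drug),
    agg_n_device = sum(g_device), agg_n_procedure = sum(g_procedure)
  ), by = "user_id"]
  agg_sess <- sess_dur[, .(agg_mean_session_duration = mean(dur)),
                       by = "user_id"]
  agg <- agg_sess[agg_gen, on = "user_id"]

  agg_feats <- c("agg_n_searches", "agg_n_health_searches",
                 "agg_mean_session_duration", "agg_mean_text_length",
                 "agg_n_disease", "agg_n_drug", "agg_n_device",
                 "agg_n_procedure")
  aggregate <- matrix(0, nrow = length(users),
                      ncol = length(agg_feats),
                      dimnames = list(users, agg_feats))
  ri <- match(agg$user_id, users)
  for (f in agg_feats) aggregate[ri, f] <- agg[[f]]

  if (length(tokens)) {
    toks <- split_tokens(rec$tokens)
    tl <- data.table::data.table(rid = rep(seq_along(toks), lengths(toks)),
                                 token = unlist(toks))
    tl <- unique(tl[tl$token %in% tokens, ])
    tl$user_id <- rec$user_id[tl$rid]
    cnt <- tl[, .(value = .N), by = c("user_id", "token")]
    tm <- matrix(0, length(users), length(tokens),
                 dimnames = list(users, paste0("agg_tok_", tokens)))
    tm[cbind(match(cnt$user_id, users),
             match(cnt$token, tokens))] <- cnt$value
    aggregate <- cbind(aggregate, tm)
  }
  if (length(cats)) {
    cl <- rec[rec$landmark_category %in% cats,
              .(value = .N), by = c("user_id", "landmark_category")]
    cm <- matrix(0, length(users), length(cats),
                 dimnames = list(users, paste0("agg_loccat_", cats)))
    cm[cbind(match(cl$user_id, users),
             match(cl$landmark_category, cats))] <- cl$value
    aggregate <- cbind(aggregate, cm)
  }
  if (length(nts)) {
    if (is.null(rec$landmark_name))
      stop("records lack landmark annotations; run annotate_locations()",
           call. = FALSE)
    nl <- data.table::data.table(
      user_id = rep(rec$user_id, lengths(split_tokens(rec$landmark_name))),
      item = unlist(split_tokens(rec$landmark_name)))
    nm <- matrix(0L, length(users), length(nts),
                 dimnames = list(users, paste0("locname_", nts)))
    for (i in seq_along(nts))
      nm[, i] <- as.integer(users %in% nl$user_id[nl$item == nts[i]])
    aggregate <- cbind(aggregate, nm)
  }
  agg_base <- sub("^agg_", "", colnames(aggregate))
  aggregate_category <- vapply(sub("\\.d[0-9]+$", "", agg_base), cat_of,
                               character(1))
  names(aggregate_category) <- colnames(aggregate)

  labels <- as.integer(
    sw$cohort$label[match(users, sw$cohort$user_id)] == "patient")
  out <- list(daywise = daywise, aggregate = aggregate,
              daywise_category = daywise_category,
              aggregate_category = aggregate_category,
              labels = labels, users = users,
              selections = list(tokens = tokens, categories = cats,
                                name_tokens = nts),
              config = config)
  class(out) <- "feature_matrices"
  out
}

#' @export
#' @method print feature_matrices
print.feature_matrices <- function(x, ...) {
  cat(sprintf("<feature_matrices> %d users; daywise %d cols, aggregate %d cols\n",
              length(x$users), ncol(x$daywise), ncol(x$aggregate)))
  invisible(x)
}

#' Write feature matrices as CSV with a JSON sidecar
#'
#' @param fm a `feature_matrices` object
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_matrices <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dw <- data.table::data.table(user_id = rownames(fm$daywise), fm$daywise)
  ag <- data.table::data.table(user_id = rownames(fm$aggregate),
                               fm$aggregate)
  dw$label <- fm$labels
  ag$label <- fm$labels
  data.table::fwrite(dw, file.path(dir, "daywise.csv"))
  data.table::fwrite(ag, file.path(dir, "aggregate.csv"))
  jsonlite::write_json(
    list(daywise_category = as.list(fm$daywise_category),
         aggregate_category = as.list(fm$aggregate_category),
         selections = fm$selections,
         config = unclass(fm$config)),
    file.path(dir, "features.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
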