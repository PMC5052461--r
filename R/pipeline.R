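#' Full-run configuration
#'
#' Bundles the per-stage configurations with a single global seed from which
#' every stage's seed is derived deterministically (hash of the global seed
#' and the stage name, so stages are insulated from each other's draw
#' counts), and an output directory.
#'
#' @param seed global integer seed
#' @param out_dir output directory for stage artifacts (`NULL` = keep
#'   everything in memory)
#' @param world a [world_config()]
#' @param cohort a [cohort_config()]
#' @param policy a [geofence_policy()]
#' @param features a [feature_config()]
#' @param model a [model_spec()] used for the headline fits and ablation
#' @param conversion a [conversion_policy()]
#' @param train_fraction training fraction of the user-level split
#' @param n_impressions size of the simulated ad stream
#' @return a `run_config` list
#' @export
run_config <- function(seed = 1L, out_dir = NULL,
                       world = world_config(),
                       cohort = cohort_config(),
                       policy = geofence_policy(),
                       features = feature_config(),
                       model = model_spec("random_forest"),
                       conversion = conversion_policy(),
                       train_fraction = 0.8,
                       n_impressions = 5000L) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, world = world,
              cohort = cohort, policy = policy, features = features,
              model = model, conversion = conversion,
              train_fraction = train_fraction,
              n_impressions = as.integer(n_impressions))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [run_config()]; each stage block
#' holds the arguments of the corresponding constructor. Unknown keys are an
#' error, so a config round-trips unchanged.
#'
#' @param path YAML (.yml/.yaml) or JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  ctors <- list(world = world_config, cohort = cohort_config,
                policy = geofence_policy, features = feature_config,
                model = model_spec, conversion = conversion_policy)
  args <- list()
  for (nm in names(raw)) {
    if (nm %in% names(ctors)) {
      blk <- raw[[nm]]
      if (nm == "world" && !is.null(blk$map_extent))
        blk$map_extent <- unlist(blk$map_extent)
      args[[nm]] <- do.call(ctors[[nm]], blk)
    } else if (nm %in% names(formals(run_config))) {
      args[[nm]] <- raw[[nm]]
    } else stop(sprintf("unknown run_config key '%s'", nm), call. = FALSE)
  }
  do.call(run_config, args)
}

# polynomial rolling hash of the serialized config, reported as hex; used
# only for provenance in the manifest
.config_hash <- function(x) {
  x$out_dir <- NULL   # identical analyses hash alike wherever they land
  s <- jsonlite::toJSON(rapply(x, unclass, how = "replace"), digits = NA,
                        auto_unbox = TRUE, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Executes simulate -> cohort -> features -> train/ablate -> ad evaluation
#' from one configuration and returns a manifest (metrics, per-stage seeds,
#' config hash). With an `out_dir`, stage outputs (logs TSV, world and truth
#' JSON, feature CSVs, ROC and conversion-curve CSVs, manifest JSON) are
#' written to disk; re-running with the same config reproduces them
#' byte-identically. Any stage failure aborts with the stage name and cause.
#'
#' @param config a [run_config()]
#' @return the manifest list, invisibly when written to disk
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seeds <- lapply(setNames(nm = c("world", "users", "cohort", "split",
                                  "model", "ads")),
                  function(s) derive_seed(config$seed, s))
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  world <- stage("simulate", {
    wc <- config$world
    wc$seed <- seeds$world
    generate_world(wc)
  })
  sim <- stage("simulate", {
    cc <- config$cohort
    cc$seed <- seeds$users
    generate_users(world, cc)
  })
  if (!is.null(out_dir)) {
    write_world(world, file.path(out_dir, "world.json"))
    write_search_logs(sim$records, file.path(out_dir, "logs.tsv"))
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }

  windows <- stage("cohort", {
    w <- build_cohort(sim$records, world$facilities, config$policy,
                      seed = seeds$cohort)
    annotate_locations(w, world$landmarks, config$features)
  })

  fm <- stage("features", {
    sp0 <- split_train_test(matrix(0, nrow(windows$cohort), 1,
                                   dimnames = list(windows$cohort$user_id)),
                            as.integer(windows$cohort$label == "patient"),
                            config$train_fraction, seeds$split)
    train_users <- windows$cohort$user_id[sp0$train_idx]
    selections <- list(
      tokens = select_enriched_tokens(windows, train_users,
                                      config$features),
      categories = select_enriched_location_categories(windows, train_users,
                                                       config$features),
      name_tokens = select_enriched_name_tokens(windows, train_users,
                                                config$features))
    fm <- build_matrices(windows, world$lexicon, selections,
                         config$features)
    attr(fm, "train_users") <- train_users
    fm
  })
  if (!is.null(out_dir)) write_matrices(fm, file.path(out_dir, "features"))

  models <- stage("train", {
    train_users <- attr(fm, "train_users")
    tr_idx <- which(fm$users %in% train_users)
    te_idx <- setdiff(seq_along(fm$users), tr_idx)
    mk <- function(x) list(
      train = list(x = x[tr_idx, , drop = FALSE], y = fm$labels[tr_idx]),
      test = list(x = x[te_idx, , drop = FALSE], y = fm$labels[te_idx]))
    spd <- mk(fm$daywise)
    spa <- mk(fm$aggregate)
    spec <- config$model
    spec$seed <- seeds$model
    list(daywise = fit_and_score(spd$train, spd$test, spec),
         aggregate = fit_and_score(spa$train, spa$test, spec),
         ablation = {
           ev <- lapply(
             c(full = "none", intersect(c("general", "semantic", "location"),
                                        unique(fm$daywise_category))),
             function(cc) {
               keep <- if (cc == "none") rep(TRUE, ncol(fm$daywise))
               else fm$daywise_category != cc
               fit_and_score(
                 list(x = spd$train$x[, keep, drop = FALSE], y = spd$train$y),
                 list(x = spd$test$x[, keep, drop = FALSE], y = spd$test$y),
                 spec)$test_auc
             })
           data.table::data.table(omitted = c("none", "general", "semantic",
                                              "location")[seq_along(ev)],
                                  test_auc = unlist(ev))
         },
         test_users = fm$users[te_idx],
         test_scores = NULL)
  })
  models$test_scores <- models$daywise$scores

  ads <- stage("evaluate", {
    stream <- generate_ad_stream(sim$truth, world,
                                 n_impressions = config$n_impressions,
                                 lookahead_days =
                                   config$conversion$lookahead_days,
                                 period_start = config$cohort$start_date,
                                 period_days = config$cohort$days_per_user,
                                 seed = seeds$ads)
    conv <- label_conversions(stream$impressions, stream$visits,
                              config$conversion)
    scored <- data.table::data.table(user_id = models$test_users,
                                     score = models$test_scores)
    scored <- scored[scored$user_id %in% conv$user_id, ]
    scored$converted <- conv$converted[match(scored$user_id, conv$user_id)]
    curve <- if (nrow(scored) >= 3)
      local_show_conversion_rate(scored, config$conversion$window_T)
    else NULL
    rho <- if (!is.null(curve) && length(unique(curve$local_rate)) > 1)
      suppressWarnings(cor(curve$percentile, curve$local_rate,
                           method = "spearman"))
    else NA_real_
    list(curve = curve, spearman = rho,
         global_rate = mean(conv$converted))
  })
  if (!is.null(out_dir) && !is.null(ads$curve))
    data.table::fwrite(ads$curve[, c("percentile", "local_rate")],
                       file.path(out_dir, "conversion_curve.csv"))

  manifest <- list(
    config_hash = .config_hash(config),
    seeds = seeds,
    n_patients = sum(windows$cohort$label == "patient"),
    n_controls = sum(windows$cohort$label == "control"),
    daywise_test_auc = models$daywise$test_auc,
    aggregate_test_auc = models$aggregate$test_auc,
    ablation = models$ablation,
    conversion_curve_spearman = ads$spearman,
    global_conversion_rate = ads$global_rate,
    paths = if (!is.null(out_dir))
      list(world = "world.json", logs = "logs.tsv", truth = "truth.json",
           features = "features", curve = "conversion_curve.csv")
    else NULL)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    return(invisible(manifest))
  }
  manifest
}
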