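#' World configuration for the synthetic-log simulator
#'
#' Describes the static "world" a simulated cohort lives in: medical
#' facilities, a landmark gazetteer, and a toy medical lexicon whose concepts
#' form a rooted DAG with corpus frequencies (the structure needed for an
#' information-content specificity score). The four semantic groups are fixed
#' to disease, drug, device and procedure. `device_noise_rate` is the
#' probability that a term mapped only to the device group is, in truth, a
#' common non-medical word — the misattribution phenomenon that makes the
#' device group noisy.
#'
#' @param n_facilities number of medical facilities (> 0)
#' @param n_landmarks number of non-facility landmarks in the gazetteer
#' @param n_landmark_categories number of landmark categories (>= 2; the
#'   first is always "health")
#' @param map_extent named numeric `c(lat_min, lat_max, lon_min, lon_max)`
#' @param lexicon_size number of terms in the toy lexicon
#' @param device_noise_rate probability in \[0, 1\] that a device-only term is
#'   truly non-medical
#' @param seed integer seed; identical seeds give byte-identical worlds
#' @return a `world_config` list
#' @export
world_config <- function(n_facilities = 5L,
                         n_landmarks = 120L,
                         n_landmark_categories = 8L,
                         map_extent = c(lat_min = 30, lat_max = 30.5,
                                        lon_min = 120, lon_max = 120.5),
                         lexicon_size = 240L,
                         device_noise_rate = 0.3,
                         seed = 1L) {
  if (n_landmark_categories < 2)
    stop("n_landmark_categories must be >= 2", call. = FALSE)
  stopifnot_scalar_prob(device_noise_rate, "device_noise_rate")
  cfg <- list(n_facilities = as.integer(n_facilities),
              n_landmarks = as.integer(n_landmarks),
              n_landmark_categories = as.integer(n_landmark_categories),
              map_extent = map_extent,
              lexicon_size = as.integer(lexicon_size),
              n_semantic_groups = 4L,
              device_noise_rate = device_noise_rate,
              seed = as.integer(seed))
  class(cfg) <- "world_config"
  cfg
}

SEMANTIC_GROUPS <- c("disease", "drug", "device", "procedure")
FACILITY_SPECIALTIES <- c("male", "female", "beauty", "other")

.category_words <- list(
  health = c("hospital", "clinic", "pharmacy", "medical", "dental"),
  education = c("university", "school", "college", "academy", "library"),
  restaurant = c("restaurant", "noodle", "teahouse", "grill", "bistro"),
  accommodation = c("hotel", "inn", "hostel", "lodge", "suites"),
  shopping = c("mall", "market", "plaza", "store", "bazaar"),
  transport = c("station", "terminal", "airport", "metro", "depot"),
  park = c("park", "garden", "lake", "hill", "riverside"),
  office = c("tower", "office", "centre", "headquarters", "exchange"),
  residential = c("apartments", "residence", "court", "villas", "estate")
)
.generic_words <- c("city", "north", "south", "east", "west", "central",
                    "grand", "new", "old", "golden")

# Build the toy lexicon: a rooted DAG of concepts (root -> one head concept
# per semantic group plus a general, non-medical branch), one term per
# ordinary concept, per-concept own corpus counts that shrink with depth, and
# aggregated frequencies own + sum(descendant aggregates) so every ancestor's
# frequency is >= any descendant's (monotone information content).
build_toy_lexicon <- function(lexicon_size, device_noise_rate) {
  branches <- c("general", SEMANTIC_GROUPS)
  n_general <- max(1L, round(0.4 * lexicon_size))
  n_med <- lexicon_size - n_general
  sizes <- c(general = n_general,
             setNames(rep(n_med %/% 4, 4), SEMANTIC_GROUPS))
  sizes[SEMANTIC_GROUPS[seq_len(n_med %% 4)]] <-
    sizes[SEMANTIC_GROUPS[seq_len(n_med %% 4)]] + 1L

  concept <- "root"
  depth <- c(root = 0L)
  parent_of <- list()    # concept -> character vector of parents
  branch_of <- c(root = "root")
  for (b in branches) {
    head_id <- paste0("head_", b)
    concept <- c(concept, head_id)
    depth[head_id] <- 1L
    parent_of[[head_id]] <- "root"
    branch_of[head_id] <- b
    members <- head_id
    for (i in seq_len(sizes[[b]])) {
      cid <- sprintf("c_%s_%03d", substr(b, 1, 3), i)
      par <- sample(members[depth[members] < 4L], 1L)
      concept <- c(concept, cid)
      depth[cid] <- depth[[par]] + 1L
      parent_of[[cid]] <- par
      branch_of[cid] <- b
      members <- c(members, cid)
    }
  }

  # a few cross links between medical branches -> multi-group concepts
  med <- names(branch_of)[branch_of %in% SEMANTIC_GROUPS &
                            !startsWith(names(branch_of), "head_")]
  n_cross <- max(1L, length(med) %/% 40L)
  for (cid in sample(med, n_cross)) {
    other <- setdiff(SEMANTIC_GROUPS, branch_of[[cid]])
    parent_of[[cid]] <- c(parent_of[[cid]], paste0("head_", sample(other, 1L)))
  }

  children_of <- list()
  for (cid in names(parent_of))
    for (par in parent_of[[cid]])
      children_of[[par]] <- c(children_of[[par]], cid)

  own <- setNames(1L + rpois(length(concept), 400 / 2^pmin(depth, 5)), concept)
  own["root"] <- own["root"] + 50L

  agg <- setNames(rep(NA_real_, length(concept)), concept)
  agg_of <- function(cid) {
    if (!is.na(agg[[cid]])) return(agg[[cid]])
    v <- own[[cid]] + sum(vapply(children_of[[cid]] %||% character(),
                                 agg_of, numeric(1)))
    agg[[cid]] <<- v
    v
  }
  agg_of("root")

  # group membership by reachability from the group head concepts
  groups_of <- function(cid) {
    seen <- character()
    frontier <- cid
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(parent_of[frontier]), seen)
    }
    SEMANTIC_GROUPS[paste0("head_", SEMANTIC_GROUPS) %in% seen]
  }
  grp <- vapply(concept, function(cid)
    paste(groups_of(cid), collapse = ","), character(1))

  ordinary <- concept[!(concept == "root" | startsWith(concept, "head_"))]
  terms <- data.table::data.table(
    term = paste0("t_", ordinary),
    concept = ordinary
  )

  ic <- -log(agg[concept] / agg[["root"]])
  concepts <- data.table::data.table(
    concept = concept,
    depth = as.integer(depth[concept]),
    own_count = as.integer(own[concept]),
    frequency = as.numeric(agg[concept]),
    groups = grp,
    ic = as.numeric(ic)
  )

  edges <- data.table::rbindlist(lapply(
    setdiff(concept, "root"),
    function(cid) data.table::data.table(child = cid,
                                         parent = parent_of[[cid]])))

  # ground-truth health label per term; device-only terms are mislabeled
  # non-medical words with probability device_noise_rate
  tg <- grp[terms$concept]
  health <- nzchar(tg)
  dev_only <- tg == "device"
  flip <- dev_only & runif(length(tg)) < device_noise_rate
  health[flip] <- FALSE

  lex <- list(terms = terms, concepts = concepts, edges = edges,
              root = "root",
              term_labels = data.table::data.table(term = terms$term,
                                                   health = health))
  class(lex) <- "toy_lexicon"
  lex
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a seeded synthetic world
#'
#' Places facilities and landmarks uniformly over the map extent, builds the
#' toy lexicon (see [world_config()]), and attaches ground-truth health
#' labels per term. Facilities are included in the landmark gazetteer under
#' the "health" category; non-facility landmarks are kept at least 250 m away
#' from every facility so that control users visiting them never enter a
#' facility geofence.
#'
#' @param config a [world_config()]
#' @return a `geoseek_world` list with elements `facilities`, `landmarks`,
#'   `lexicon`, `term_labels` and `config`
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  if (config$n_facilities <= 0)
    stop("n_facilities must be positive", call. = FALSE)
  ext <- config$map_extent
  if (ext[["lat_max"]] <= ext[["lat_min"]] ||
      ext[["lon_max"]] <= ext[["lon_min"]])
    stop("map_extent must have positive area", call. = FALSE)

  with_seed(config$seed, {
    nf <- config$n_facilities
    facilities <- data.table::data.table(
      facility_id = sprintf("F%03d", seq_len(nf)),
      name = paste(sample(.generic_words, nf, replace = TRUE), "hospital"),
      specialty = FACILITY_SPECIALTIES[((seq_len(nf) - 1L) %% 4L) + 1L],
      lat = runif(nf, ext[["lat_min"]], ext[["lat_max"]]),
      lon = runif(nf, ext[["lon_min"]], ext[["lon_max"]])
    )

    cats <- c("health", setdiff(names(.category_words), "health"))
    cats <- cats[seq_len(config$n_landmark_categories)]
    nl <- config$n_landmarks
    lm_cat <- sample(cats, nl, replace = TRUE)
    lm_lat <- runif(nl, ext[["lat_min"]], ext[["lat_max"]])
    lm_lon <- runif(nl, ext[["lon_min"]], ext[["lon_max"]])
    # keep non-facility landmarks out of facility geofences
    for (i in seq_len(20)) {
      d <- vapply(seq_len(nl), function(j)
        min(haversine_distance(lm_lat[j], lm_lon[j],
                               facilities$lat, facilities$lon)), numeric(1))
      bad <- d < 250
      if (!any(bad)) break
      lm_lat[bad] <- runif(sum(bad), ext[["lat_min"]], ext[["lat_max"]])
      lm_lon[bad] <- runif(sum(bad), ext[["lon_min"]], ext[["lon_max"]])
    }
    lm_name <- vapply(lm_cat, function(cc)
      paste(sample(.generic_words, 1L),
            sample(.category_words[[cc]], 1L)), character(1))
    landmarks <- data.table::data.table(
      landmark_id = sprintf("L%04d", seq_len(nl)),
      name = lm_name,
      category = lm_cat,
      lat = lm_lat,
      lon = lm_lon,
      is_facility = FALSE
    )
    landmarks <- rbind(
      landmarks,
      data.table::data.table(
        landmark_id = paste0("LF_", facilities$facility_id),
        name = facilities$name,
        category = "health",
        lat = facilities$lat,
        lon = facilities$lon,
        is_facility = TRUE
      )
    )

    lexicon <- build_toy_lexicon(config$lexicon_size,
                                 config$device_noise_rate)

    world <- list(facilities = facilities, landmarks = landmarks,
                  lexicon = lexicon, term_labels = lexicon$term_labels,
                  config = config)
    class(world) <- "geoseek_world"
    world
  })
}

#' @export
#' @method print geoseek_world
print.geoseek_world <- function(x, ...) {
  cat(sprintf("<geoseek_world> %d facilities, %d landmarks, %d lexicon terms\n",
              nrow(x$facilities), nrow(x$landmarks), nrow(x$lexicon$terms)))
  invisible(x)
}

#' Write / read a world as JSON
#'
#' @param world a `geoseek_world`
#' @param path file path
#' @return `read_world` returns a `geoseek_world`
#' @export
write_world <- function(world, path) {
  stopifnot(inherits(world, "geoseek_world"))
  out <- list(
    facilities = world$facilities,
    landmarks = world$landmarks,
    lexicon = list(terms = world$lexicon$terms,
                   concepts = world$lexicon$concepts,
                   edges = world$lexicon$edges,
                   root = world$lexicon$root,
                   term_labels = world$lexicon$term_labels),
    config = unclass(world$config)
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_world
#' @export
read_world <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lex <- lapply(raw$lexicon[c("terms", "concepts", "edges", "term_labels")],
                data.table::as.data.table)
  lex$root <- raw$lexicon$root
  class(lex) <- "toy_lexicon"
  cfg <- raw$config
  cfg$map_extent <- unlist(cfg$map_extent)
  class(cfg) <- "world_config"
  world <- list(facilities = data.table::as.data.table(raw$facilities),
                landmarks = data.table::as.data.table(raw$landmarks),
                lexicon = lex, term_labels = lex$term_labels, config = cfg)
  class(world) <- "geoseek_world"
  world
}
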