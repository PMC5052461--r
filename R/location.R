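#' Resolve coordinates to their nearest landmark
#'
#' Coordinates are rounded to `coord_round_places` decimal places (4 places
#' is about 11 m of latitude) and each unique rounded pair is resolved once:
#' the 10 closest landmarks are ranked by great-circle distance and the
#' nearest retained one supplies the category and name. The cache of unique
#' pairs is what makes batch annotation cheap.
#'
#' @param lat,lon coordinate vectors in degrees
#' @param landmarks gazetteer (landmark_id, name, category, lat, lon)
#' @param config a [feature_config()]
#' @return `data.table` aligned with the inputs: landmark_id, category, name,
#'   distance_m
#' @export
assign_landmark_category <- function(lat, lon, landmarks,
                                     config = feature_config()) {
  if (is.null(landmarks) || nrow(landmarks) == 0)
    stop("landmark gazetteer is empty", call. = FALSE)
  dp <- config$coord_round_places
  rlat <- round(lat, dp)
  rlon <- round(lon, dp)
  key <- paste(rlat, rlon, sep = ",")
  uk <- !duplicated(key)
  ulat <- rlat[uk]
  ulon <- rlon[uk]

  # distance from each unique pair to every landmark, tracking the minimum
  # (the nearest of the 10-closest shortlist is the overall nearest, so the
  # shortlist need not be materialized); vectorized over points per landmark
  m <- length(ulat)
  best_d <- rep(Inf, m)
  best_j <- rep(1L, m)
  for (j in seq_len(nrow(landmarks))) {
    d <- haversine_distance(ulat, ulon, landmarks$lat[j], landmarks$lon[j])
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_j[upd] <- j
  }
  res_id <- landmarks$landmark_id[best_j]
  res_cat <- landmarks$category[best_j]
  res_name <- landmarks$name[best_j]
  res_d <- best_d
  idx <- match(key, key[uk])
  data.table::data.table(landmark_id = res_id[idx],
                         category = res_cat[idx],
                         name = res_name[idx],
                         distance_m = res_d[idx])
}

#' Annotate window records with landmark categories and names
#'
#' Adds `landmark_category` and `landmark_name` columns to the records of a
#' `search_windows` (or single `analysis_window`) via
#' [assign_landmark_category()].
#'
#' @param windows a `search_windows` or `analysis_window`
#' @param landmarks gazetteer table
#' @param config a [feature_config()]
#' @return the `search_windows` with annotated records
#' @export
annotate_locations <- function(windows, landmarks,
                               config = feature_config()) {
  windows <- as_search_windows(windows)
  ann <- assign_landmark_category(windows$records$lat, windows$records$lon,
                                  landmarks, config)
  windows$records$landmark_category <- ann$category
  windows$records$landmark_name <- ann$name
  windows
}
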