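#' Load census-tract geometries from GeoJSON
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features, extracts the
#' tract identifier from a feature property, and computes each tract's
#' tight bounding box.
#'
#' @param path GeoJSON file.
#' @param id_property Name of the feature property holding the tract id
#'   (default `"GEOID"`).
#' @return A `tract_set`: a data.frame with `tract_id`, `min_lon`,
#'   `min_lat`, `max_lon`, `max_lat`, `bbox_area`, and a list column
#'   `rings` of 2-column (lon, lat) polygon-ring matrices.
#' @export
load_tracts <- function(path, id_property = "GEOID") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    id <- f$properties[[id_property]]
    if (is.null(id)) {
      stop("feature ", i, " has no '", id_property, "' property")
    }
    g <- f$geometry
    rings <- tryCatch(extract_rings(g), error = function(e) {
      stop("invalid geometry for feature '", id, "': ", conditionMessage(e))
    })
    xy <- do.call(rbind, rings)
    list(id = as.character(id), rings = rings,
         bbox = c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2])))
  })
  ids <- vapply(rows, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate tract id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bb <- do.call(rbind, lapply(rows, `[[`, "bbox"))
  out <- data.frame(tract_id = ids, min_lon = bb[, 1], min_lat = bb[, 2],
                    max_lon = bb[, 3], max_lat = bb[, 4],
                    stringsAsFactors = FALSE)
  if (any(out$min_lon >= out$max_lon | out$min_lat >= out$max_lat)) {
    bad <- out$tract_id[out$min_lon >= out$max_lon | out$min_lat >= out$max_lat]
    stop("degenerate bounding box for tract(s): ", paste(bad, collapse = ", "))
  }
  out$bbox_area <- (out$max_lon - out$min_lon) * (out$max_lat - out$min_lat)
  out$rings <- lapply(rows, `[[`, "rings")
  class(out) <- c("tract_set", "data.frame")
  out
}

# GeoJSON Polygon / MultiPolygon -> list of outer-ring matrices (holes are
# not modeled; census tracts are effectively simple polygons).
extract_rings <- function(geometry) {
  type <- geometry$type
  coords <- geometry$coordinates
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) < 4) stop("ring with fewer than 4 positions")
    m
  }
  if (identical(type, "Polygon")) {
    list(ring_mat(coords[[1]]))
  } else if (identical(type, "MultiPolygon")) {
    lapply(coords, function(poly) ring_mat(poly[[1]]))
  } else {
    stop("unsupported geometry type: ", type)
  }
}

#' Assign a point to a census tract
#'
#' The default mode follows the published point-to-bounding-box method:
#' candidate tracts are those whose bounding box contains the point (edges
#' inclusive); when boxes overlap, the smallest-area box wins and remaining
#' ties break by lexicographic tract id, making the assignment total and
#' deterministic. `mode = "polygon"` instead runs true point-in-polygon
#' (with the bounding-box test as a prefilter), the geometrically exact
#' alternative.
#'
#' @param lat,lon Point coordinates in degrees.
#' @param tracts A `tract_set`.
#' @param mode `"bbox"` (default) or `"polygon"`.
#' @return The assigned `tract_id`, or `NA_character_` when no tract
#'   contains the point.
#' @export
assign_tract <- function(lat, lon, tracts, mode = c("bbox", "polygon")) {
  mode <- match.arg(mode)
  cand <- which(lon >= tracts$min_lon & lon <= tracts$max_lon &
                  lat >= tracts$min_lat & lat <= tracts$max_lat)
  if (mode == "polygon" && length(cand) > 0) {
    inside <- vapply(cand, function(i) {
      point_in_rings(lon, lat, tracts$rings[[i]])
    }, logical(1))
    cand <- cand[inside]
  }
  if (length(cand) == 0) return(NA_character_)
  cand <- cand[order(tracts$bbox_area[cand], tracts$tract_id[cand])]
  tracts$tract_id[cand[1]]
}

point_in_rings <- function(lon, lat, rings) {
  pt <- matrix(c(lon, lat), ncol = 2)
  for (r in rings) {
    if (mgcv::in.out(r, pt)) return(TRUE)
  }
  FALSE
}

#' Map a geolocated corpus to census tracts
#'
#' Applies [assign_tract()] to every tweet. Unmapped tweets (outside every
#' tract) are reported separately rather than dropped silently.
#'
#' @param corpus A geolocated `tweet_corpus`.
#' @param tracts A `tract_set`.
#' @param mode Assignment mode, as in [assign_tract()].
#' @return A data.frame (`tweet_id`, `tract_id`) covering the mapped
#'   tweets, with the unmapped tweet ids in attribute `unmapped`.
#' @export
map_corpus <- function(corpus, tracts, mode = c("bbox", "polygon")) {
  mode <- match.arg(mode)
  n <- nrow(corpus)
  if (n == 0) {
    return(structure(data.frame(tweet_id = character(0),
                                tract_id = character(0)),
                     unmapped = character(0)))
  }
  # accumulate (point, tract) candidates tract-by-tract, vectorized over points
  pt_idx <- integer(0); tr_idx <- integer(0)
  for (i in seq_len(nrow(tracts))) {
    hit <- which(corpus$lon >= tracts$min_lon[i] & corpus$lon <= tracts$max_lon[i] &
                   corpus$lat >= tracts$min_lat[i] & corpus$lat <= tracts$max_lat[i])
    if (mode == "polygon" && length(hit) > 0) {
      pts <- cbind(corpus$lon[hit], corpus$lat[hit])
      inside <- rep(FALSE, length(hit))
      for (r in tracts$rings[[i]]) {
        inside <- inside | mgcv::in.out(r, pts)
      }
      hit <- hit[inside]
    }
    pt_idx <- c(pt_idx, hit)
    tr_idx <- c(tr_idx, rep.int(i, length(hit)))
  }
  ord <- order(pt_idx, tracts$bbox_area[tr_idx], tracts$tract_id[tr_idx])
  pt_idx <- pt_idx[ord]; tr_idx <- tr_idx[ord]
  first <- !duplicated(pt_idx)
  mapped <- data.frame(tweet_id = corpus$id[pt_idx[first]],
                       tract_id = tracts$tract_id[tr_idx[first]],
                       stringsAsFactors = FALSE)
  structure(mapped, unmapped = setdiff(corpus$id, mapped$tweet_id))
}
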