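#' Protected-area polygon collection
#'
#' A tibble of protected areas: one row per PA with its name, IUCN
#' management category and polygon geometry (a list column; each element is
#' a single closed ring as an n x 2 coordinate matrix, or a list of such
#' rings for multipolygons). Coordinates live in the same local metric CRS
#' as the rasters, tracked by a `crs` attribute.
#'
#' @param name character vector of PA names.
#' @param iucn_category character vector; each value must be one of the nine
#'   IUCN values (Ia, Ib, II, III, IV, V, VI, Not reported, Not applicable).
#' @param geometry list of n x 2 coordinate matrices (rings) or lists of
#'   rings.
#' @param crs CRS tag.
#' @return A tibble of class `pa_collection`.
#' @export
pa_collection <- function(name = character(), iucn_category = character(),
                          geometry = list(), crs = "LOCAL_METRIC") {
  stopifnot(length(name) == length(iucn_category),
            length(name) == length(geometry))
  bad <- setdiff(unique(iucn_category), iucn_categories())
  if (length(bad)) {
    stop("invalid IUCN category value(s): ", paste(bad, collapse = ", "))
  }
  geometry <- lapply(geometry, function(g) {
    rings <- if (is.matrix(g)) list(g) else g
    lapply(rings, function(ring) {
      ring <- as.matrix(ring)
      stopifnot(ncol(ring) == 2, nrow(ring) >= 3)
      # store rings unclosed; closure is re-imposed on write
      if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
      if (nrow(ring) < 3) stop("degenerate polygon ring")
      ring
    })
  })
  out <- tibble::tibble(name = name, iucn_category = iucn_category,
                        geometry = geometry)
  attr(out, "crs") <- crs
  class(out) <- c("pa_collection", class(out))
  out
}

pa_crs <- function(pas) attr(pas, "crs") %||% "LOCAL_METRIC"

# Signed area of a ring (shoelace); magnitude used for validity checks.
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon areas of a PA collection
#'
#' @param pas a [pa_collection()].
#' @return Numeric vector of areas in square metres (outer rings only; all
#'   generated PAs are single-ring).
#' @export
pa_areas <- function(pas) {
  vapply(pas$geometry, function(rings) sum(abs(vapply(rings, ring_area, 0))), 0)
}

#' Write / read protected areas as GeoJSON
#'
#' Standard GeoJSON FeatureCollection of Polygon features with `name` and
#' `iucn_category` properties. The CRS tag rides in a top-level `crs_tag`
#' member (GeoJSON proper is CRS-less).
#'
#' @param pas a [pa_collection()].
#' @param path file path.
#' @return `write_protected_areas()` returns `path` invisibly;
#'   `read_protected_areas()` returns a [pa_collection()].
#' @export
write_protected_areas <- function(pas, path) {
  stopifnot(inherits(pas, "pa_collection"))
  features <- purrr::pmap(
    list(pas$name, pas$iucn_category, pas$geometry),
    function(nm, cat, rings) {
      coords <- lapply(rings, function(ring) {
        closed <- rbind(ring, ring[1, ])
        lapply(seq_len(nrow(closed)), function(i) as.numeric(closed[i, ]))
      })
      list(type = "Feature",
           properties = list(name = nm, iucn_category = cat),
           geometry = list(type = "Polygon", coordinates = coords))
    })
  fc <- list(type = "FeatureCollection", crs_tag = pa_crs(pas),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protected_areas
#' @export
read_protected_areas <- function(path) {
  if (!file.exists(path)) stop("protected-area file does not exist: ", path)
  fc <- jsonlite::read_json(path)
  feats <- fc$features %||% list()
  geoms <- lapply(feats, function(f) {
    stopifnot(f$geometry$type %in% c("Polygon", "MultiPolygon"))
    polys <- if (f$geometry$type == "Polygon") list(f$geometry$coordinates)
             else f$geometry$coordinates
    unlist(lapply(polys, function(rings) {
      lapply(rings, function(ring) {
        do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
      })
    }), recursive = FALSE)
  })
  pa_collection(
    name = vapply(feats, function(f) f$properties$name %||% NA_character_, ""),
    iucn_category = vapply(feats, function(f) {
      f$properties$iucn_category %||% "Not reported"
    }, ""),
    geometry = geoms,
    crs = fc$crs_tag %||% "LOCAL_METRIC"
  )
}
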