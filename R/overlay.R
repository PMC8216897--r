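# Point-in-polygon membership for a set of points against one PA geometry
# (list of rings). Uses mgcv::in.out; multiple rings are passed as
# NA-separated loops so holes/multiparts follow the even-odd rule. Points
# exactly on a boundary segment follow in.out's convention (treated as
# inside on right/top edges); centroids sit on a half-cell offset lattice,
# so this only matters for deliberately degenerate geometries.
points_in_pa <- function(pts, rings) {
  bnd <- do.call(rbind, lapply(rings, function(ring) {
    rbind(ring, ring[1, ], c(NA, NA))
  }))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, pts)
}

#' Assign analysis locations to protected areas
#'
#' A location belongs to a PA iff its bin centroid falls inside the PA
#' polygon. Overlapping PAs are resolved in favour of the first-listed PA
#' (with a warning).
#'
#' @param pas a [pa_collection()].
#' @param cube the `st_cube` defining the analysis grid.
#' @return Integer matrix over analysis locations: the PA's row index in
#'   `pas`, or `NA` where no PA covers the centroid.
#' @export
rasterize_pa <- function(pas, cube) {
  stopifnot(inherits(pas, "pa_collection"), inherits(cube, "st_cube"))
  if (pa_crs(pas) != cube$crs) {
    stop(sprintf("CRS mismatch: protected areas are '%s', grid is '%s'",
                 pa_crs(pas), cube$crs))
  }
  cc <- cube_centroids(cube)
  d <- dim(cube$mask)
  pts <- cbind(rep(cc$x, each = d[1]), rep(cc$y, times = d[2]))
  out <- matrix(NA_integer_, d[1], d[2])
  overlap <- FALSE
  for (i in rev(seq_len(nrow(pas)))) {      # first-listed wins
    inside <- points_in_pa(pts, pas$geometry[[i]])
    if (any(!is.na(out[inside]))) overlap <- TRUE
    out[inside] <- i
  }
  if (overlap) {
    warning("overlapping protected areas: first-listed PA wins at shared locations")
  }
  out
}

#' Per-PA category shares and island-level inside/outside totals
#'
#' For each PA, the percentage of its covered analysis locations in each of
#' the eight hotspot categories plus "none" (shares sum to 100). PAs whose
#' polygons cover no analysis location get `NA` shares (undefined, not
#' zero). Island-level totals count category-bearing locations inside any PA
#' versus outside all PAs.
#'
#' @param result an `eha_result` from [run_eha()].
#' @param pa_raster integer PA-id matrix from [rasterize_pa()].
#' @param pas the [pa_collection()] used to build `pa_raster`.
#' @return A list of class `pa_shares`: `shares` tibble (`name`,
#'   `iucn_category`, `category`, `share_pct`, `n_locations`) and `island`
#'   tibble (`category`, `inside`, `outside`).
#' @export
pa_category_shares <- function(result, pa_raster, pas) {
  stopifnot(inherits(result, "eha_result"))
  cats <- c(eha_categories(), "none")
  loc <- result$locations
  pa_id <- pa_raster[cbind(loc$row, loc$col)]
  shares <- purrr::map_dfr(seq_len(nrow(pas)), function(i) {
    covered <- loc$category[!is.na(pa_id) & pa_id == i]
    n_cov <- length(covered)
    share <- if (n_cov == 0) {
      rep(NA_real_, length(cats))
    } else {
      100 * as.vector(table(factor(covered, levels = cats))) / n_cov
    }
    tibble::tibble(name = pas$name[i], iucn_category = pas$iucn_category[i],
                   category = cats, share_pct = share, n_locations = n_cov)
  })
  bearing <- loc$category %in% eha_categories()
  island <- tibble::tibble(
    category = eha_categories(),
    inside = as.vector(table(factor(loc$category[bearing & !is.na(pa_id)],
                                    levels = eha_categories()))),
    outside = as.vector(table(factor(loc$category[bearing & is.na(pa_id)],
                                     levels = eha_categories())))
  )
  structure(list(shares = shares, island = island), class = "pa_shares")
}

#' @export
print.pa_shares <- function(x, ...) {
  cat("<pa_shares>\n")
  print(x$shares, n = 20)
  invisible(x)
}

#' @export
tidy.pa_shares <- function(x, ...) x$shares

# Unsigned distance from points to the boundary (all ring segments) of a
# geometry; vectorized over points.
points_boundary_distance <- function(pts, rings) {
  dmin <- rep(Inf, nrow(pts))
  for (ring in rings) {
    closed <- rbind(ring, ring[1, ])
    for (s in seq_len(nrow(closed) - 1)) {
      dmin <- pmin(dmin,
                   point_segment_distance(pts, closed[s, ], closed[s + 1, ]))
    }
  }
  dmin
}

#' Category counts by distance to protected-area boundary
#'
#' Bins every masked analysis location by its signed distance to the nearest
#' PA boundary (negative inside a PA) into rings of width `ring_width`, and
#' counts locations per ring and category. Used to examine whether in-PA
#' hotspots concentrate near boundaries ("neighbourhood leakage").
#'
#' @param result an `eha_result`.
#' @param pas a [pa_collection()].
#' @param ring_width ring width in metres (> 0).
#' @return Tibble `ring_min`, `ring_max` (signed metres), `category`, `n`.
#' @export
boundary_distance_profile <- function(result, pas, ring_width) {
  stopifnot(inherits(result, "eha_result"), ring_width > 0, nrow(pas) >= 1)
  loc <- result$locations
  pts <- cbind(loc$x, loc$y)
  dist <- rep(Inf, nrow(pts))
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(pas))) {
    dist <- pmin(dist, points_boundary_distance(pts, pas$geometry[[i]]))
    inside <- inside | points_in_pa(pts, pas$geometry[[i]])
  }
  signed <- ifelse(inside, -dist, dist)
  ring <- floor(signed / ring_width)
  tb <- loc |>
    dplyr::mutate(ring = ring) |>
    dplyr::count(.data$ring, .data$category, name = "n") |>
    dplyr::mutate(ring_min = .data$ring * ring_width,
                  ring_max = (.data$ring + 1) * ring_width) |>
    dplyr::select("ring_min", "ring_max", "category", "n") |>
    dplyr::arrange(.data$ring_min, .data$category)
  tb
}
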