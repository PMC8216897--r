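#' Euclidean distance to the nearest feature
#'
#' Straight-line ("Near"-style) distance from every cell centroid to the
#' nearest feature. Point features measure point-to-point; polygon/polyline
#' features measure distance to the nearest vertex or edge.
#'
#' @param grid an `eha_raster` (or `st_cube`) defining the target grid.
#' @param features either a two-column matrix / data frame of point
#'   coordinates, or a list of n x 2 coordinate matrices treated as
#'   polylines/rings (closed if `closed = TRUE`).
#' @param closed treat list features as closed rings (default TRUE).
#' @return An `eha_raster` of distances in metres.
#' @export
euclidean_distance_map <- function(grid, features, closed = TRUE) {
  if (inherits(grid, "st_cube")) {
    cc <- cube_centroids(grid)
    template <- eha_raster(matrix(0, nrow(grid$mask), ncol(grid$mask)),
                           cell_size = grid$bin_size,
                           xll = grid$xll, yll = grid$yll, crs = grid$crs)
  } else {
    stopifnot(inherits(grid, "eha_raster"))
    cc <- raster_centroids(grid)
    template <- grid
  }
  nr <- length(cc$y); nc <- length(cc$x)
  pts <- cbind(rep(cc$x, each = nr), rep(cc$y, times = nc))
  if (is.data.frame(features)) features <- as.matrix(features[, c(1, 2)])
  if (is.matrix(features)) {
    if (nrow(features) == 0) stop("feature set is empty; distance is undefined")
    dmin <- rep(Inf, nrow(pts))
    for (i in seq_len(nrow(features))) {
      dmin <- pmin(dmin, sqrt((pts[, 1] - features[i, 1])^2 +
                              (pts[, 2] - features[i, 2])^2))
    }
  } else if (is.list(features)) {
    if (!length(features)) stop("feature set is empty; distance is undefined")
    dmin <- rep(Inf, nrow(pts))
    for (geom in features) {
      geom <- as.matrix(geom)
      seg <- if (closed && nrow(geom) >= 3) rbind(geom, geom[1, ]) else geom
      if (nrow(seg) == 1) {
        dmin <- pmin(dmin, sqrt((pts[, 1] - seg[1, 1])^2 +
                                (pts[, 2] - seg[1, 2])^2))
      } else {
        for (s in seq_len(nrow(seg) - 1)) {
          dmin <- pmin(dmin, point_segment_distance(pts, seg[s, ], seg[s + 1, ]))
        }
      }
    }
  } else stop("features must be a coordinate matrix or a list of geometries")
  out <- template
  out$values <- matrix(dmin, nr, nc)
  out$nodata <- -9999
  out
}

#' Slope from elevation (Horn's method)
#'
#' Horn's 3 x 3 finite-difference gradient with edge cells handled by
#' clamping the window to the grid; slope in degrees,
#' `atan(sqrt(p^2 + q^2))`.
#'
#' @param elevation an `eha_raster` of elevation in metres (>= 3 x 3).
#' @param cell_size optional override of the raster's cell size, metres.
#' @return An `eha_raster` of slope in degrees `[0, 90)`.
#' @export
slope_from_elevation <- function(elevation, cell_size = NULL) {
  stopifnot(inherits(elevation, "eha_raster"))
  z <- elevation$values
  stopifnot(nrow(z) >= 3, ncol(z) >= 3)
  cs <- cell_size %||% elevation$cell_size
  nr <- nrow(z); nc <- ncol(z)
  # clamped index helpers: replicate edge rows/cols
  up <- c(1, seq_len(nr - 1)); dn <- c(seq_len(nr - 1) + 1, nr)
  lf <- c(1, seq_len(nc - 1)); rt <- c(seq_len(nc - 1) + 1, nc)
  # Horn weights: p = dz/dx over the 3x3 window
  p <- ((z[up, rt] + 2 * z[, rt] + z[dn, rt]) -
        (z[up, lf] + 2 * z[, lf] + z[dn, lf])) / (8 * cs)
  q <- ((z[dn, lf] + 2 * z[dn, ] + z[dn, rt]) -
        (z[up, lf] + 2 * z[up, ] + z[up, rt])) / (8 * cs)
  slope <- atan(sqrt(p^2 + q^2)) * 180 / pi
  out <- elevation
  out$values <- slope
  out
}

#' Per-category covariate summaries
#'
#' Mean, standard error of the mean (sd / sqrt(n)) and n of each covariate
#' over the analysis locations of each hotspot category (the sampling unit
#' is one analysis location). Categories with no members are omitted;
#' single-member categories report SEM 0.
#'
#' @param result an `eha_result`.
#' @param covariates named list of `eha_raster`s aligned to the analysis
#'   grid (one value per analysis location), or a data frame with one row
#'   per masked location in `result$locations` order.
#' @param include_none include the "none" class (default FALSE).
#' @return Tibble `category`, `covariate`, `mean`, `sem`, `n`.
#' @export
category_summaries <- function(result, covariates, include_none = FALSE) {
  stopifnot(inherits(result, "eha_result"))
  loc <- result$locations
  df <- covariate_frame(covariates, loc)
  df$category <- loc$category
  keep <- if (include_none) c(eha_categories(), "none") else eha_categories()
  df |>
    dplyr::filter(.data$category %in% keep) |>
    tidyr::pivot_longer(-"category", names_to = "covariate",
                        values_to = "value") |>
    dplyr::group_by(.data$category, .data$covariate) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(factor(.data$category, levels = keep), .data$covariate)
}

# Extract per-location covariate values for the masked locations.
covariate_frame <- function(covariates, loc) {
  if (is.data.frame(covariates)) {
    stopifnot(nrow(covariates) == nrow(loc))
    return(tibble::as_tibble(covariates))
  }
  stopifnot(is.list(covariates), length(names(covariates)) == length(covariates))
  vals <- lapply(covariates, function(r) {
    stopifnot(inherits(r, "eha_raster"))
    r$values[cbind(loc$row, loc$col)]
  })
  tibble::as_tibble(vals)
}

#' Kruskal-Wallis rank test across category groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square approximation on k - 1
#' degrees of freedom. Accepts either a list of numeric vectors (one per
#' group) or a value vector plus grouping factor. Groups with no variation
#' at all (every pooled value identical) return H = 0, p = 1.
#'
#' @param groups list of numeric vectors, or a numeric vector when `g` is
#'   given.
#' @param g optional grouping factor/vector parallel to `groups`.
#' @return Object of class `eha_kw` with `H`, `df`, `p`; `tidy()` gives a
#'   one-row tibble.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (is.null(g)) {
    stopifnot(is.list(groups), length(groups) >= 2)
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
  } else {
    x <- as.numeric(groups)
    g <- factor(g)
  }
  stopifnot(nlevels(g) >= 2, length(x) >= 3, all(tabulate(g) >= 1))
  if (length(unique(x)) == 1L) {
    res <- list(H = 0, df = nlevels(g) - 1L, p = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value)
  }
  structure(c(res, list(n = length(x), k = nlevels(g))), class = "eha_kw")
}

#' @export
print.eha_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %d, k = %d)\n",
              x$H, x$df, x$p, x$n, x$k))
  invisible(x)
}

#' @export
tidy.eha_kw <- function(x, ...) {
  tibble::tibble(H = x$H, df = x$df, p = x$p, n = x$n, k = x$k)
}

#' Kruskal-Wallis per covariate across hotspot categories
#'
#' Runs [kruskal_wallis()] once per covariate with the hotspot category as
#' the grouping variable (the per-variable testing layout used to compare
#' driver distributions across categories).
#'
#' @inheritParams category_summaries
#' @return Tibble `covariate`, `H`, `df`, `p`.
#' @export
kruskal_wallis_by_category <- function(result, covariates) {
  loc <- result$locations
  df <- covariate_frame(covariates, loc)
  keep <- loc$category %in% eha_categories()
  g <- loc$category[keep]
  purrr::map_dfr(names(df), function(v) {
    kw <- kruskal_wallis(df[[v]][keep], g)
    tibble::tibble(covariate = v, H = kw$H, df = kw$df, p = kw$p)
  })
}
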