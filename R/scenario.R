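#' Planted patch description
#'
#' A spatial footprint (axis-aligned rectangle or disc in pixel coordinates)
#' carrying one intensity template and an amplitude: the added probability of
#' first loss in a fully "on" year.
#'
#' @param template template name, see [template_profile()].
#' @param amplitude added per-pixel per-year loss probability when the
#'   template is fully on (`[0, 1)`).
#' @param rows,cols for a rectangle: inclusive pixel index ranges
#'   `c(first, last)`.
#' @param center,radius for a disc: pixel `c(row, col)` centre and radius in
#'   pixels.
#' @return An object of class `planted_patch`.
#' @export
planted_patch <- function(template, amplitude, rows = NULL, cols = NULL,
                          center = NULL, radius = NULL) {
  template_profile(template, 2)  # validates the name
  stopifnot(is.numeric(amplitude), amplitude >= 0, amplitude < 1)
  if (!is.null(rows)) {
    stopifnot(length(rows) == 2, length(cols) == 2,
              rows[1] <= rows[2], cols[1] <= cols[2])
    fp <- list(type = "rect", rows = as.integer(rows), cols = as.integer(cols))
  } else {
    stopifnot(length(center) == 2, is.numeric(radius), radius > 0)
    fp <- list(type = "disc", center = as.numeric(center),
               radius = as.numeric(radius))
  }
  structure(list(template = template, amplitude = amplitude, footprint = fp),
            class = "planted_patch")
}

# Logical pixel mask of a patch footprint on an nr x nc grid.
patch_mask <- function(patch, nr, nc) {
  fp <- patch$footprint
  m <- matrix(FALSE, nr, nc)
  if (fp$type == "rect") {
    if (fp$rows[1] < 1 || fp$rows[2] > nr || fp$cols[1] < 1 || fp$cols[2] > nc)
      stop("patch footprint extends outside the grid")
    m[fp$rows[1]:fp$rows[2], fp$cols[1]:fp$cols[2]] <- TRUE
  } else {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    m <- (rr - fp$center[1])^2 + (cc - fp$center[2])^2 <= fp$radius^2
    if (fp$center[1] - fp$radius < 0.5 || fp$center[1] + fp$radius > nr + 0.5 ||
        fp$center[2] - fp$radius < 0.5 || fp$center[2] + fp$radius > nc + 0.5)
      stop("patch footprint extends outside the grid")
  }
  m
}

#' Synthetic study scenario
#'
#' Describes a complete synthetic study region: grid geometry, number of
#' annual steps, background first-loss probability, planted patches and the
#' RNG seed. The scenario is the single source of truth for all simulated
#' layers, so identical scenarios reproduce byte-identical outputs.
#'
#' @param grid_rows,grid_cols grid size in pixels.
#' @param cell_size pixel edge in metres.
#' @param n_years number of annual steps (>= 2, default 18).
#' @param background_rate per-pixel per-year probability of first loss
#'   outside patches, `[0, 1)`.
#' @param patches list of [planted_patch()] objects (non-overlapping).
#' @param seed integer RNG seed.
#' @param neighborhood_distance metres; used to check that the grid is large
#'   enough (each dimension at least 3 neighbourhood radii) for the
#'   downstream space-time statistics to be meaningful.
#' @param crs CRS tag for all generated layers.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(grid_rows = 120, grid_cols = 120, cell_size = 1000,
                          n_years = 18, background_rate = 0.005,
                          patches = list(), seed = 1,
                          neighborhood_distance = 10000,
                          crs = "LOCAL_METRIC") {
  stopifnot(grid_rows >= 1, grid_cols >= 1, cell_size > 0, n_years >= 2,
            background_rate >= 0, background_rate < 1,
            neighborhood_distance > 0)
  radius_px <- neighborhood_distance / cell_size
  if (min(grid_rows, grid_cols) < 3 * radius_px) {
    stop(sprintf(
      "grid dimensions (%d x %d px) must be at least 3 neighbourhood radii (%.0f px)",
      grid_rows, grid_cols, 3 * radius_px))
  }
  amps <- vapply(patches, function(p) p$amplitude, 0)
  if (length(amps) && background_rate + max(amps) > 1)
    stop("background_rate plus the largest patch amplitude exceeds 1")
  # footprints must lie within the grid and not overlap: with overlapping
  # planted processes the per-template loss targets would not be identifiable
  cover <- matrix(0L, grid_rows, grid_cols)
  for (p in patches) cover <- cover + patch_mask(p, grid_rows, grid_cols)
  if (any(cover > 1L)) stop("planted patch footprints overlap")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_size = as.numeric(cell_size), n_years = as.integer(n_years),
         background_rate = background_rate, patches = patches,
         seed = as.integer(seed),
         neighborhood_distance = as.numeric(neighborhood_distance),
         crs = crs),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %d x %d px @ %.0f m, %d years, p0 = %g, %d patches, seed %d\n",
    x$grid_rows, x$grid_cols, x$cell_size, x$n_years, x$background_rate,
    length(x$patches), x$seed))
  invisible(x)
}

#' Demonstration scenario with one patch per hotspot template
#'
#' The package's reference validation scenario: a 1120 x 1120 pixel grid of
#' 500-m cells (a 560-km square, island scale), 18 annual steps, background
#' first-loss probability 0.0075 per pixel-year, and eight well-separated
#' 50 x 50-pixel (5 x 5 analysis-bin) planted patches, one per hotspot
#' template. Patch amplitudes were chosen from the detection power analysis
#' in the methods vignette so that "on" years clear the Gi* hot threshold by
#' a wide margin and suppressed years can produce cold bins.
#'
#' @param seed RNG seed (default 42, the canonical demo seed).
#' @param scale linear down-scaling factor for quicker runs: `scale = 2`
#'   halves the grid and patch sizes (minimum patch 3 x 3 bins).
#' @return A [scenario_spec()].
#' @export
demo_scenario <- function(seed = 42, scale = 1) {
  stopifnot(scale %in% c(1, 2))
  px <- 1120L %/% scale
  half <- 25L %/% scale    # patch half-width in pixels (5x5 or 3x3 bins)
  centers_bins <- rbind(
    c(16, 16), c(16, 56), c(16, 96),
    c(56, 16),            c(56, 96),
    c(96, 16), c(96, 56), c(96, 96)) %/% scale
  amps <- c(new = 0.30, consecutive = 0.12, intensifying = 0.09,
            persistent = 0.03, diminishing = 0.09, sporadic = 0.08,
            oscillating = 0.07, historical = 0.03)
  patches <- purrr::map2(names(amps), seq_along(amps), function(tpl, i) {
    ctr <- centers_bins[i, ] * 10L - 5L   # bin centre -> pixel centre
    planted_patch(tpl, amps[[i]],
                  rows = c(ctr[1] - half + 1L, ctr[1] + half),
                  cols = c(ctr[2] - half + 1L, ctr[2] + half))
  })
  scenario_spec(grid_rows = px, grid_cols = px, cell_size = 500,
                n_years = 18, background_rate = 0.0075,
                patches = patches, seed = seed)
}

#' Serialize / restore a scenario as YAML
#'
#' @param spec a [scenario_spec()].
#' @param path YAML file path.
#' @return `write_scenario_yaml()` returns `path`; `read_scenario_yaml()`
#'   returns a [scenario_spec()].
#' @export
write_scenario_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  x <- unclass(spec)
  x$patches <- lapply(spec$patches, function(p) {
    c(list(template = p$template, amplitude = p$amplitude), p$footprint)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  patches <- lapply(x$patches, function(p) {
    if (p$type == "rect") {
      planted_patch(p$template, p$amplitude,
                    rows = unlist(p$rows), cols = unlist(p$cols))
    } else {
      planted_patch(p$template, p$amplitude,
                    center = unlist(p$center), radius = p$radius)
    }
  })
  scenario_spec(grid_rows = x$grid_rows, grid_cols = x$grid_cols,
                cell_size = x$cell_size, n_years = x$n_years,
                background_rate = x$background_rate, patches = patches,
                seed = x$seed,
                neighborhood_distance = x$neighborhood_distance,
                crs = x$crs)
}
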