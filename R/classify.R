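#' Minimum number of hot steps for "persistent-class" categories
#'
#' Operationalizes the "ninety percent of the time step intervals"
#' persistence clause as `floor(hot_fraction * T)`: with 18 annual steps and
#' the default 0.90 this gives 16, i.e. "16 of the 18 years".
#'
#' @param T number of time steps (>= 2).
#' @param hot_fraction persistence threshold, default 0.90.
#' @return Integer threshold.
#' @examples
#' min_hot_steps(18)        # 16
#' @export
min_hot_steps <- function(T, hot_fraction = 0.90) {
  stopifnot(T >= 2, hot_fraction > 0, hot_fraction <= 1)
  as.integer(floor(hot_fraction * T))
}

# Category decision given per-location diagnostics (vectorized).
# Rule order (first match wins):
#   new, consecutive, intensifying, diminishing, historical, persistent,
#   oscillating, sporadic, none.
# historical is tested before persistent so that a >=90%-hot location whose
# final step is NOT hot is historical regardless of trend, matching the
# category's "most recent time period is not hot" definition.
classify_from_diag <- function(final_hot, hot_count, cold_count,
                               terminal_run, direction, min_hot) {
  dplyr::case_when(
    final_hot & hot_count == 1L ~ "new",
    final_hot & terminal_run >= 2L & hot_count == terminal_run &
      hot_count < min_hot ~ "consecutive",
    final_hot & hot_count >= min_hot & direction == "increasing" ~ "intensifying",
    final_hot & hot_count >= min_hot & direction == "decreasing" ~ "diminishing",
    !final_hot & hot_count >= min_hot ~ "historical",
    hot_count >= min_hot & direction == "none" ~ "persistent",
    final_hot & cold_count >= 1L & hot_count < min_hot ~ "oscillating",
    final_hot & cold_count == 0L & hot_count < min_hot ~ "sporadic",
    TRUE ~ "none"
  )
}

#' Classify one location's hot/cold label sequence
#'
#' Assigns one of the eight emerging-hotspot categories (or "none") from a
#' location's per-year hot / cold / neither labels and its intensity trend,
#' applying the category rules in a fixed specific-to-general order (new,
#' consecutive, intensifying, diminishing, historical, persistent,
#' oscillating, sporadic). Only hotspot categories are emitted; cold labels
#' enter solely through the oscillating rule's cold-history clause.
#'
#' @param labels character vector over `{"hot", "cold", "neither"}`, one per
#'   time step.
#' @param trend an `eha_mk` object (or list with `direction`) for the
#'   location's intensity trend.
#' @param params an [eha_params()]; supplies `hot_fraction`.
#' @return Single category string.
#' @export
classify_location <- function(labels, trend, params = eha_params()) {
  if (!all(labels %in% c("hot", "cold", "neither"))) {
    stop("labels must be 'hot', 'cold' or 'neither'; got: ",
         paste(unique(setdiff(labels, c("hot", "cold", "neither"))),
               collapse = ", "))
  }
  Tn <- length(labels)
  hot <- labels == "hot"
  run <- 0L
  for (t in rev(seq_len(Tn))) {
    if (!hot[t]) break
    run <- run + 1L
  }
  classify_from_diag(
    final_hot = hot[Tn],
    hot_count = sum(hot),
    cold_count = sum(labels == "cold"),
    terminal_run = run,
    direction = trend$direction,
    min_hot = min_hot_steps(Tn, params$hot_fraction)
  )
}

#' Run the full emerging hotspot analysis on a cube
#'
#' Composes the pipeline's statistical core: Gi* z-scores over the
#' space-time neighbourhood, per-location hot/cold label sequences, a
#' Mann-Kendall trend per location, and the eight-category classification.
#' The trend series is the location's raw annual count series by default
#' (`trend_on = "counts"`); `trend_on = "zscore"` uses the Gi* z series (the
#' "intensity of clustering") instead - the two readings and the reason for
#' the default are discussed in the methods vignette.
#'
#' @param cube an `st_cube`.
#' @param params an [eha_params()].
#' @param trend_on "counts" or "zscore".
#' @return Object of class `eha_result`: `category` character matrix over
#'   analysis locations (NA outside the mask), a `locations` diagnostics
#'   tibble, the `gi` field, `params` and `trend_on`.
#' @export
run_eha <- function(cube, params = eha_params(),
                    trend_on = c("counts", "zscore")) {
  trend_on <- match.arg(trend_on)
  stopifnot(inherits(cube, "st_cube"))
  d <- dim(cube$counts)
  Tn <- d[3]
  category <- matrix(NA_character_, d[1], d[2])
  empty <- tibble::tibble(
    row = integer(), col = integer(), x = numeric(), y = numeric(),
    category = character(), hot_count = integer(), cold_count = integer(),
    final_hot = logical(), terminal_run = integer(),
    trend_s = integer(), trend_z = numeric(), trend_p = numeric(),
    trend_direction = character())
  if (!any(cube$mask)) {
    return(structure(list(category = category, locations = empty, gi = NULL,
                          params = params, trend_on = trend_on,
                          bin_size = cube$bin_size, n_years = Tn,
                          mask = cube$mask),
                     class = "eha_result"))
  }
  gi <- gi_star(cube, params)
  idx <- which(cube$mask)                      # column-major location ids
  m <- length(idx)
  # m x T matrices of labels and series
  lab <- matrix(gi$label, nrow = d[1] * d[2])[idx, , drop = FALSE]
  hot <- lab == 1L
  cold <- lab == -1L
  series <- if (trend_on == "counts") {
    matrix(cube$counts, nrow = d[1] * d[2])[idx, , drop = FALSE]
  } else {
    matrix(gi$z, nrow = d[1] * d[2])[idx, , drop = FALSE]
  }
  trend <- mk_stats(series, alpha = params$alpha)
  run <- integer(m)
  alive <- rep(TRUE, m)
  for (t in rev(seq_len(Tn))) {
    alive <- alive & hot[, t]
    run <- run + alive
  }
  diag <- tibble::tibble(
    row = (idx - 1L) %% d[1] + 1L,
    col = (idx - 1L) %/% d[1] + 1L,
    hot_count = rowSums(hot),
    cold_count = rowSums(cold),
    final_hot = hot[, Tn],
    terminal_run = run,
    trend_s = trend$S, trend_z = trend$z, trend_p = trend$p,
    trend_direction = trend$direction
  )
  diag$category <- classify_from_diag(
    diag$final_hot, diag$hot_count, diag$cold_count, diag$terminal_run,
    diag$trend_direction, min_hot_steps(Tn, params$hot_fraction))
  cc <- cube_centroids(cube)
  diag$x <- cc$x[diag$col]
  diag$y <- cc$y[diag$row]
  diag <- diag[, names(empty)]
  category[cbind(diag$row, diag$col)] <- diag$category
  structure(
    list(category = category, locations = diag, gi = gi, params = params,
         trend_on = trend_on, bin_size = cube$bin_size, n_years = Tn,
         mask = cube$mask),
    class = "eha_result"
  )
}

#' @export
print.eha_result <- function(x, ...) {
  tb <- table(factor(x$locations$category, levels = c(eha_categories(), "none")))
  cat(sprintf("<eha_result> %d analysis locations (%s trend series)\n",
              nrow(x$locations), x$trend_on))
  print(tb)
  invisible(x)
}

#' Tidy an EHA result into its per-location table
#'
#' @param x an `eha_result`.
#' @param ... unused.
#' @return The per-location diagnostics tibble (one row per masked
#'   location): position, category, hot/cold counts, terminal run and trend
#'   statistics.
#' @export
tidy.eha_result <- function(x, ...) x$locations

#' One-row summary of an EHA result
#'
#' @param x an `eha_result`.
#' @param ... unused.
#' @return Tibble with the number of masked locations, hotspot locations,
#'   categories present and parameter echo.
#' @export
glance.eha_result <- function(x, ...) {
  hs <- x$locations$category != "none"
  tibble::tibble(
    n_locations = nrow(x$locations),
    n_hotspot = sum(hs),
    n_categories = length(intersect(unique(x$locations$category),
                                    eha_categories())),
    alpha = x$params$alpha,
    neighborhood_distance = x$params$neighborhood_distance,
    tau = x$params$tau,
    hot_fraction = x$params$hot_fraction,
    trend_on = x$trend_on
  )
}
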