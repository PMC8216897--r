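#' Hotspot composition of a category map
#'
#' Percentage of category-bearing locations per category (locations
#' labelled "none" are excluded from the denominator), the composition
#' style used for headline reporting (e.g. "oscillating 58.8%, sporadic
#' 29.8%"). With zero hotspot locations an empty tibble is returned rather
#' than a division error.
#'
#' @param result an `eha_result` (or a character vector of per-location
#'   categories).
#' @return Tibble `category`, `n`, `pct`; `pct` sums to 100 over the
#'   categories present.
#' @export
category_composition <- function(result) {
  cats <- if (inherits(result, "eha_result")) result$locations$category
          else as.character(result)
  cats <- cats[cats %in% eha_categories()]
  if (!length(cats)) {
    return(tibble::tibble(category = character(), n = integer(),
                          pct = numeric()))
  }
  tb <- table(factor(cats, levels = eha_categories()))
  tb <- tb[tb > 0]
  tibble::tibble(category = names(tb), n = as.integer(tb),
                 pct = 100 * as.integer(tb) / length(cats)) |>
    dplyr::arrange(dplyr::desc(.data$pct),
                   factor(.data$category, levels = eha_categories()))
}

#' Pipeline run configuration
#'
#' Assembles and validates the configuration of an end-to-end run. Inputs
#' are either a synthetic scenario (a [scenario_spec()], a scenario YAML
#' path, or `"demo"`) or a loss-raster file, plus an optional
#' protected-area GeoJSON and covariate rasters. Every analysis parameter
#' of the method is surfaced here; nothing is hard-coded downstream.
#'
#' @param scenario a [scenario_spec()], path to a scenario YAML, or "demo".
#' @param loss_raster path to a loss-year `.asc` (alternative to
#'   `scenario`).
#' @param protected_areas path to a PA GeoJSON; for synthetic runs `NULL`
#'   means "simulate `n_pas` PAs".
#' @param n_pas number of PAs to simulate when none are supplied.
#' @param n_years annual steps of the loss coding.
#' @param bin_size analysis bin edge (m).
#' @param mask_mode "any-loss" or "all" (see [build_cube()]).
#' @param params an [eha_params()].
#' @param trend_on "counts" or "zscore" (see [run_eha()]).
#' @param cart_max_depth,cart_min_leaf,cart_criterion tree controls
#'   (see [fit_cart()]).
#' @param out_dir output directory (created); `NULL` disables artifact
#'   files.
#' @param seed integer; every source of randomness in the run flows from
#'   it.
#' @return A validated list of class `eha_config`.
#' @export
eha_config <- function(scenario = NULL, loss_raster = NULL,
                       protected_areas = NULL, n_pas = 3, n_years = 18,
                       bin_size = 5000, mask_mode = "any-loss",
                       params = eha_params(), trend_on = "counts",
                       cart_max_depth = 4, cart_min_leaf = 0.05,
                       cart_criterion = "gini", out_dir = NULL, seed = 1) {
  if (is.null(scenario) && is.null(loss_raster)) {
    stop("config needs either a scenario or a loss_raster path")
  }
  if (!is.null(loss_raster) && !file.exists(loss_raster)) {
    stop("loss raster file does not exist: ", loss_raster)
  }
  structure(
    list(scenario = scenario, loss_raster = loss_raster,
         protected_areas = protected_areas, n_pas = n_pas,
         n_years = as.integer(n_years), bin_size = bin_size,
         mask_mode = mask_mode, params = params, trend_on = trend_on,
         cart_max_depth = cart_max_depth, cart_min_leaf = cart_min_leaf,
         cart_criterion = cart_criterion, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "eha_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> cube -> Gi* + Mann-Kendall ->
#' classification -> protected-area overlay -> driver attribution, writes
#' the artifact files (category map, per-location diagnostics, annual loss
#' series, PA shares, Kruskal-Wallis table, decision tree) when `out_dir`
#' is set, and returns a machine-readable report. Identical config and seed
#' reproduce an identical report.
#'
#' @param config an [eha_config()].
#' @return A list of class `eha_report` (invisible config echo, per-stage
#'   records, category composition, PA shares, KW results, tree summary).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "eha_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  art <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)

  # --- simulate / load ------------------------------------------------
  sim_out <- stage("simulate", {
    if (!is.null(config$scenario)) {
      spec <- config$scenario
      if (identical(spec, "demo")) spec <- demo_scenario(seed = config$seed)
      if (is.character(spec)) spec <- read_scenario_yaml(spec)
      spec$seed <- config$seed
      sim <- generate_loss_raster(spec)
      cv <- generate_covariates(spec, seed = config$seed + 1L)
      pas <- if (is.null(config$protected_areas)) {
        generate_protected_areas(spec, config$n_pas, seed = config$seed + 2L)
      }
      list(raster = sim$raster, sim = sim,
           covs = list(elevation = cv$elevation, footprint = cv$footprint,
                       plantations = cv$plantations),
           pas = pas)
    } else {
      list(raster = read_loss_raster(config$loss_raster,
                                     n_years = config$n_years),
           sim = NULL, covs = NULL, pas = NULL)
    }
  })
  raster <- sim_out$raster
  sim <- sim_out$sim
  covs <- sim_out$covs
  pas <- sim_out$pas

  # --- cube -----------------------------------------------------------
  cube <- stage("cube", build_cube(raster, bin_size = config$bin_size,
                                   mask_mode = config$mask_mode))
  annual <- stage("cube", annual_loss_series(cube))

  # --- stats + classification -----------------------------------------
  result <- stage("eha", run_eha(cube, params = config$params,
                                 trend_on = config$trend_on))
  composition <- category_composition(result)

  # --- overlay --------------------------------------------------------
  shares <- NULL
  if (!is.null(config$protected_areas)) {
    pas <- stage("overlay", read_protected_areas(config$protected_areas))
  }
  if (!is.null(pas) && nrow(pas) > 0 && nrow(result$locations) > 0) {
    shares <- stage("overlay", {
      pa_raster <- rasterize_pa(pas, cube)
      pa_category_shares(result, pa_raster, pas)
    })
  }

  # --- drivers --------------------------------------------------------
  drivers <- NULL
  if (!is.null(covs) && nrow(result$locations) > 0 &&
      length(unique(result$locations$category[
        result$locations$category != "none"])) >= 2) {
    drivers <- stage("drivers", {
      elev_bin <- aggregate_to_bins(covs$elevation, cube)
      slope_bin <- slope_from_elevation(elev_bin)
      fp_bin <- aggregate_to_bins(covs$footprint, cube, fun = "nearest")
      pl <- covs$plantations
      cov_list <- list(
        elevation = elev_bin, slope = slope_bin, human_footprint = fp_bin,
        dist_oil_palm = euclidean_distance_map(
          cube, as.matrix(pl[pl$type == "oil_palm", c("x", "y")])),
        dist_wood_fiber = euclidean_distance_map(
          cube, as.matrix(pl[pl$type == "wood_fiber", c("x", "y")]))
      )
      summaries <- category_summaries(result, cov_list)
      kw <- kruskal_wallis_by_category(result, cov_list)
      loc <- result$locations
      hs <- loc$category %in% eha_categories()
      tree <- fit_cart(covariate_frame(cov_list, loc)[hs, ],
                       loc$category[hs],
                       max_depth = config$cart_max_depth,
                       min_leaf = config$cart_min_leaf,
                       criterion = config$cart_criterion)
      list(covariates = cov_list, summaries = summaries, kw = kw,
           tree = tree)
    })
  }

  # --- artifacts ------------------------------------------------------
  stage("report", {
    if (!is.null(out_dir)) {
      write_category_map(result, art("category_map.asc"))
      utils::write.csv(result$locations, art("locations.csv"),
                       row.names = FALSE)
      utils::write.csv(cbind(annual, year_label = 2000 + annual$year),
                       art("annual_loss.csv"), row.names = FALSE)
      if (!is.null(shares)) {
        utils::write.csv(shares$shares, art("pa_shares.csv"), row.names = FALSE)
        utils::write.csv(shares$island, art("pa_island_summary.csv"),
                         row.names = FALSE)
      }
      if (!is.null(drivers)) {
        utils::write.csv(drivers$summaries, art("category_summaries.csv"),
                         row.names = FALSE)
        utils::write.csv(drivers$kw, art("kruskal_wallis.csv"),
                         row.names = FALSE)
        write_cart_json(drivers$tree, art("decision_tree.json"))
        writeLines(utils::capture.output(print(drivers$tree)),
                   art("decision_tree.txt"))
      }
      if (!is.null(pas)) write_protected_areas(pas, art("protected_areas.geojson"))
    }
  })

  report <- list(
    config = config_echo(config),
    stages = list(
      cube = list(locations = sum(cube$mask), n_bins = cube$n,
                  bin_size = cube$bin_size, n_years = cube$n_years),
      eha = c(as.list(glance.eha_result(result))),
      annual_loss = list(total_km2 = attr(annual, "total_km2"),
                         mean_km2_yr = attr(annual, "mean_km2_yr"))
    ),
    composition = composition,
    pa_shares = if (!is.null(shares)) shares$shares,
    pa_island = if (!is.null(shares)) shares$island,
    kruskal_wallis = if (!is.null(drivers)) drivers$kw,
    tree = if (!is.null(drivers)) as.list(glance.eha_cart(drivers$tree)),
    truth_legend = if (!is.null(sim)) sim$legend,
    version = as.character(utils::packageVersion("ehacube"))
  )
  class(report) <- "eha_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_json(report), art("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(report, "result") <- result
  attr(report, "cube") <- cube
  attr(report, "drivers") <- drivers
  attr(report, "pas") <- pas
  report
}

config_echo <- function(config) {
  ce <- unclass(config)
  ce$out_dir <- NULL   # artifact location, not an analysis input
  if (inherits(ce$scenario, "scenario_spec")) {
    ce$scenario <- list(
      grid = c(ce$scenario$grid_rows, ce$scenario$grid_cols),
      cell_size = ce$scenario$cell_size, n_years = ce$scenario$n_years,
      background_rate = ce$scenario$background_rate,
      n_patches = length(ce$scenario$patches), seed = ce$scenario$seed)
  }
  ce$params <- unclass(ce$params)
  ce
}

report_json <- function(report) {
  r <- unclass(report)
  r$composition <- as.list(as.data.frame(r$composition))
  if (!is.null(r$pa_shares)) r$pa_shares <- as.list(as.data.frame(r$pa_shares))
  if (!is.null(r$pa_island)) r$pa_island <- as.list(as.data.frame(r$pa_island))
  if (!is.null(r$kruskal_wallis)) {
    r$kruskal_wallis <- as.list(as.data.frame(r$kruskal_wallis))
  }
  if (!is.null(r$truth_legend)) {
    r$truth_legend <- as.list(as.data.frame(r$truth_legend))
  }
  r
}

#' @export
print.eha_report <- function(x, ...) {
  cat("<eha_report>\n")
  cat(sprintf("  locations: %d masked, %d hotspot categories present\n",
              x$stages$cube$locations, x$stages$eha$n_categories))
  cat(sprintf("  mean annual loss: %s km^2/yr\n",
              format(x$stages$annual_loss$mean_km2_yr)))
  if (nrow(x$composition)) {
    cat("  composition: ",
        paste(sprintf("%s %.1f%%", x$composition$category, x$composition$pct),
              collapse = "; "), "\n")
  }
  invisible(x)
}

# Nearest-neighbour / mean aggregation of a pixel raster to the analysis
# bin grid (coarse covariates are resampled by nearest neighbour, smooth
# fields by the bin mean).
aggregate_to_bins <- function(r, cube, fun = c("mean", "nearest")) {
  fun <- match.arg(fun)
  k <- as.integer(round(cube$bin_size / r$cell_size))
  stopifnot(k >= 1)
  v <- r$values
  d <- dim(cube$mask)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    rows <- ((i - 1L) * k + 1L):min(i * k, nrow(v))
    for (j in seq_len(d[2])) {
      cols <- ((j - 1L) * k + 1L):min(j * k, ncol(v))
      out[i, j] <- if (fun == "mean") mean(v[rows, cols]) else
        v[rows[ceiling(length(rows) / 2)], cols[ceiling(length(cols) / 2)]]
    }
  }
  eha_raster(out, cell_size = cube$bin_size, xll = cube$xll, yll = cube$yll,
             crs = cube$crs)
}

#' Write a category map as an ASCII grid + JSON legend
#'
#' Integer codes 1-8 follow the standard category order (new, consecutive,
#' intensifying, persistent, diminishing, sporadic, oscillating,
#' historical), 0 = analysed but no category, nodata = outside the mask.
#'
#' @param result an `eha_result`.
#' @param path `.asc` output path; the legend goes to `<path>.legend.json`.
#' @return `path`, invisibly.
#' @export
write_category_map <- function(result, path) {
  stopifnot(inherits(result, "eha_result"))
  codes <- matrix(-9999L, nrow(result$category), ncol(result$category))
  codes[!is.na(result$category)] <- 0L
  for (i in seq_along(eha_categories())) {
    codes[!is.na(result$category) & result$category == eha_categories()[i]] <- i
  }
  r <- eha_raster(codes, cell_size = result$bin_size, nodata = -9999L)
  write_raster_asc(r, path)
  jsonlite::write_json(
    c(list(none = 0), setNames(as.list(seq_along(eha_categories())),
                               eha_categories())),
    paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Polygonized category map as GeoJSON
#'
#' One MultiPolygon feature per category present, assembled from the bin
#' squares of its member locations (squares are not dissolved across shared
#' edges; consumers that need dissolved outlines can union downstream).
#'
#' @param result an `eha_result`.
#' @param path GeoJSON output path.
#' @return `path`, invisibly.
#' @export
write_category_geojson <- function(result, path) {
  loc <- result$locations
  half <- result$bin_size / 2
  feats <- lapply(intersect(eha_categories(), unique(loc$category)),
                  function(cat) {
    sub <- loc[loc$category == cat, ]
    polys <- lapply(seq_len(nrow(sub)), function(i) {
      x <- sub$x[i]; y <- sub$y[i]
      ring <- rbind(c(x - half, y - half), c(x + half, y - half),
                    c(x + half, y + half), c(x - half, y + half),
                    c(x - half, y - half))
      list(lapply(seq_len(nrow(ring)), function(r) as.numeric(ring[r, ])))
    })
    list(type = "Feature", properties = list(category = cat),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
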