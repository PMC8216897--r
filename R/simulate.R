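# Per-year target fresh-loss fractions and the hazards that deliver them.
#
# The template profile is a target for the EXPECTED fraction of the bin's
# original pixels newly lost in year t:
#   r_t = p0 (1 - p0)^(t-1) * (1 - suppressed_t) + amplitude * profile_t
# Because a pixel can be lost only once, the per-year hazards applied to the
# surviving pixels are solved recursively: h_t = r_t / s_{t-1},
# s_t = s_{t-1} - r_t. Off years therefore match the background process
# exactly, suppressed years have zero loss, and sustained templates do not
# drift "diminishing" through depletion of the susceptible pool.
patch_loss_targets <- function(p0, amplitude, profile) {
  n <- length(profile)
  supp <- attr(profile, "suppressed") %||% logical(n)
  r <- p0 * (1 - p0)^(seq_len(n) - 1) * as.numeric(!supp) +
    amplitude * as.numeric(profile)
  s <- 1
  for (t in seq_len(n)) {
    if (r[t] > s + 1e-12) {
      stop(sprintf(
        "loss probability exceeds 1 in year %d: cumulative planted loss targets exhaust the pixel pool",
        t))
    }
    s <- s - r[t]
  }
  r
}

#' Simulate a loss-year raster with planted space-time hotspots
#'
#' Draws, for every pixel, the first year in which loss occurs (or 0 for
#' never), under a background Bernoulli process plus planted patch
#' processes. Each patch's intensity template is delivered as the expected
#' fraction of original pixels newly lost per year (see the methods
#' vignette for why the hazards are depletion-compensated). The result is
#' reproducible: identical scenario (including seed) gives an identical
#' raster.
#'
#' @param spec a [scenario_spec()].
#' @return A list with elements `raster` (a `loss_raster`), `truth` (an
#'   `eha_raster` of integer patch ids, 0 = background) and `legend` (a
#'   tibble mapping patch id to template name).
#' @export
generate_loss_raster <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  nr <- spec$grid_rows; nc <- spec$grid_cols; n <- spec$n_years
  p0 <- spec$background_rate
  group <- matrix(0L, nr, nc)
  for (i in seq_along(spec$patches)) {
    group[patch_mask(spec$patches[[i]], nr, nc)] <- i
  }
  # loss-fraction targets per group (row = year)
  targets <- cbind(p0 * (1 - p0)^(seq_len(n) - 1))
  for (p in spec$patches) {
    targets <- cbind(targets,
                     patch_loss_targets(p0, p$amplitude,
                                        template_profile(p$template, n)))
  }
  set.seed(spec$seed)
  codes <- matrix(0L, nr, nc)
  for (g in 0:length(spec$patches)) {
    idx <- which(group == g)
    if (!length(idx)) next
    cum <- cumsum(targets[, g + 1])
    u <- runif(length(idx))
    yr <- findInterval(u, cum, left.open = TRUE) + 1L
    yr[yr > n] <- 0L  # survived the whole record
    codes[idx] <- yr
  }
  raster <- as_loss_raster(
    eha_raster(codes, cell_size = spec$cell_size, crs = spec$crs),
    n_years = n)
  truth <- eha_raster(group, cell_size = spec$cell_size, crs = spec$crs)
  legend <- tibble::tibble(
    id = seq_along(spec$patches),
    template = vapply(spec$patches, function(p) p$template, ""))
  list(raster = raster, truth = truth, legend = legend)
}

#' Simulate covariate layers, plantation features and roads
#'
#' Generates the driver layers the study design expects, georeferenced
#' identically to the loss grid: a smooth elevation field (sum of Gaussian
#' bumps), a human-footprint index decaying exponentially with distance from
#' synthetic straight roads and clipped to the 0-50 index range, and Poisson
#' point sets standing in for oil-palm and wood-fiber plantation locations.
#'
#' @param spec a [scenario_spec()].
#' @param seed RNG seed (defaults to the scenario seed).
#' @param n_bumps number of Gaussian elevation bumps (0 gives a flat field).
#' @param relief maximum bump height in metres.
#' @param n_roads number of straight roads crossing the extent.
#' @param footprint_max footprint value on a road (clipped to 50).
#' @param footprint_lambda e-folding distance of footprint decay, metres
#'   (`Inf` gives a constant field).
#' @param plantation_mean expected number of plantation points per type.
#' @return A list with `elevation` and `footprint` rasters, a `plantations`
#'   tibble (`x`, `y`, `type`), and `roads` (list of two-column coordinate
#'   matrices).
#' @export
generate_covariates <- function(spec, seed = spec$seed, n_bumps = 5,
                                relief = 800, n_roads = 2,
                                footprint_max = 40,
                                footprint_lambda = 10000,
                                plantation_mean = 30) {
  stopifnot(inherits(spec, "scenario_spec"))
  nr <- spec$grid_rows; nc <- spec$grid_cols; cs <- spec$cell_size
  W <- nc * cs; H <- nr * cs
  set.seed(seed)
  xs <- (seq_len(nc) - 0.5) * cs
  ys <- (nr - seq_len(nr) + 0.5) * cs
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)

  elev <- matrix(0, nr, nc)
  if (n_bumps > 0) {
    bx <- runif(n_bumps, 0, W); by <- runif(n_bumps, 0, H)
    bh <- runif(n_bumps, 0.25, 1) * relief
    bw <- runif(n_bumps, 0.1, 0.3) * min(W, H)
    for (k in seq_len(n_bumps)) {
      elev <- elev + bh[k] * exp(-((X - bx[k])^2 + (Y - by[k])^2) / (2 * bw[k]^2))
    }
  }

  roads <- lapply(seq_len(n_roads), function(k) {
    if (runif(1) < 0.5) {  # west-east chord
      rbind(c(0, runif(1, 0.2, 0.8) * H), c(W, runif(1, 0.2, 0.8) * H))
    } else {               # south-north chord
      rbind(c(runif(1, 0.2, 0.8) * W, 0), c(runif(1, 0.2, 0.8) * W, H))
    }
  })
  pts <- cbind(as.vector(X), as.vector(Y))
  if (length(roads)) {
    d_road <- do.call(pmin, lapply(roads, function(seg) {
      point_segment_distance(pts, seg[1, ], seg[2, ])
    }))
  } else {
    d_road <- rep(Inf, nrow(pts))
  }
  fp_val <- if (is.infinite(footprint_lambda)) {
    rep(footprint_max, length(d_road))
  } else {
    footprint_max * exp(-d_road / footprint_lambda)
  }
  footprint <- matrix(pmin(pmax(fp_val, 0), 50), nr, nc)

  plantations <- purrr::map_dfr(c("oil_palm", "wood_fiber"), function(type) {
    npts <- rpois(1, plantation_mean)
    tibble::tibble(x = runif(npts, 0, W), y = runif(npts, 0, H), type = type)
  })

  list(
    elevation = eha_raster(elev, cell_size = cs, crs = spec$crs),
    footprint = eha_raster(footprint, cell_size = cs, crs = spec$crs),
    plantations = plantations,
    roads = roads
  )
}

# Distance from points (n x 2 matrix) to segment a-b.
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  tt <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((pts[, 1] - (a[1] + tt * ab[1]))^2 + (pts[, 2] - (a[2] + tt * ab[2]))^2)
}

#' Simulate a protected-area polygon collection
#'
#' Draws `n_pas` non-degenerate rectangles or discs inside the scenario
#' extent, each with a name and an IUCN management category drawn from the
#' nine standard values (Ia, Ib, II, III, IV, V, VI, Not reported,
#' Not applicable).
#'
#' @param spec a [scenario_spec()].
#' @param n_pas number of protected areas (>= 0).
#' @param seed RNG seed (defaults to the scenario seed).
#' @return A `pa_collection` tibble with columns `name`, `iucn_category` and
#'   a `geometry` list column of closed-ring coordinate matrices.
#' @export
generate_protected_areas <- function(spec, n_pas, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"), n_pas >= 0)
  W <- spec$grid_cols * spec$cell_size
  H <- spec$grid_rows * spec$cell_size
  set.seed(seed)
  geoms <- vector("list", n_pas)
  iucn <- character(n_pas)
  boxes <- matrix(numeric(0), 0, 4)
  for (i in seq_len(n_pas)) {
    # rejection-sample centres so PA bounding boxes do not overlap (give up
    # after 100 tries on crowded extents and accept the overlap)
    for (try in 1:100) {
      cx <- runif(1, 0.15, 0.85) * W; cy <- runif(1, 0.15, 0.85) * H
      half_w <- runif(1, 0.04, 0.12) * W; half_h <- runif(1, 0.04, 0.12) * H
      box <- c(cx - half_w, cx + half_w, cy - half_h, cy + half_h)
      clear <- !any(box[1] < boxes[, 2] & box[2] > boxes[, 1] &
                    box[3] < boxes[, 4] & box[4] > boxes[, 3])
      if (clear) break
    }
    boxes <- rbind(boxes, box)
    if (runif(1) < 0.5) {
      ring <- rbind(c(cx - half_w, cy - half_h), c(cx + half_w, cy - half_h),
                    c(cx + half_w, cy + half_h), c(cx - half_w, cy + half_h))
    } else {
      th <- seq(0, 2 * pi, length.out = 37)[-37]
      rr <- min(half_w, half_h)
      ring <- cbind(cx + rr * cos(th), cy + rr * sin(th))
    }
    geoms[[i]] <- ring
    iucn[i] <- sample(iucn_categories(), 1)
  }
  pa_collection(
    name = sprintf("PA-%02d", seq_len(n_pas)),
    iucn_category = iucn,
    geometry = geoms,
    crs = spec$crs
  )
}
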