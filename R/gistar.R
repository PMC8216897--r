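#' Emerging hotspot analysis parameters
#'
#' The tunable parameters of the space-time statistics: the spatial
#' neighbourhood distance (10 km in the reference analysis), the
#' neighbourhood time-step interval tau (bins from the current and the tau
#' preceding years are neighbours), the two-sided significance level for
#' both Gi* and the trend test, and the persistence threshold used by the
#' category rules (fraction of steps that must be hot; 0.90 with 18 annual
#' steps operationalizes to 16 of 18).
#'
#' @param neighborhood_distance metres (> 0), default 10000.
#' @param tau temporal neighbourhood in steps (>= 0), default 1.
#' @param alpha significance level in (0, 1), default 0.05.
#' @param hot_fraction persistence threshold in (0, 1], default 0.90.
#' @return Object of class `eha_params`.
#' @export
eha_params <- function(neighborhood_distance = 10000, tau = 1, alpha = 0.05,
                       hot_fraction = 0.90) {
  stopifnot(neighborhood_distance > 0, tau >= 0, alpha > 0, alpha < 1,
            hot_fraction > 0, hot_fraction <= 1)
  structure(list(neighborhood_distance = as.numeric(neighborhood_distance),
                 tau = as.integer(tau), alpha = alpha,
                 hot_fraction = hot_fraction),
            class = "eha_params")
}

# Spatial offsets (dr, dc) whose bin-centroid distance is within d.
spatial_offsets <- function(bin_size, distance) {
  m <- floor(distance / bin_size)
  dr <- rep(-m:m, each = 2 * m + 1)
  dc <- rep(-m:m, times = 2 * m + 1)
  keep <- (dr^2 + dc^2) * bin_size^2 <= distance^2 + 1e-9
  cbind(dr = dr[keep], dc = dc[keep])
}

# Shift a matrix by (dr, dc) with zero fill: result[r, c] = M[r + dr, c + dc].
mat_shift <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0, nr, nc)
  r0 <- max(1, 1 + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1, 1 + dc); c1 <- min(nc, nc + dc)
  if (r0 > r1 || c0 > c1) return(out)
  out[(r0:r1) - dr, (c0:c1) - dc] <- M[r0:r1, c0:c1, drop = FALSE]
  out
}

#' Space-time neighbours of a bin
#'
#' The neighbour set of a focal bin: all masked bins whose location centroid
#' lies within the neighbourhood distance and whose year falls in the
#' current-or-previous window `t - tau .. t` (clipped at the start of the
#' record), the focal bin included. Weights are binary.
#'
#' @param cube an `st_cube`.
#' @param loc integer `c(row, col)` of the focal location (must be masked).
#' @param t focal year index (1..T).
#' @param params an [eha_params()].
#' @return Tibble of neighbours: `row`, `col`, `year`.
#' @export
spacetime_neighbors <- function(cube, loc, t, params = eha_params()) {
  stopifnot(inherits(cube, "st_cube"), length(loc) == 2,
            t >= 1, t <= cube$n_years)
  if (!cube$mask[loc[1], loc[2]]) {
    stop(sprintf("location (%d, %d) is outside the analysis mask", loc[1], loc[2]))
  }
  off <- spatial_offsets(cube$bin_size, params$neighborhood_distance)
  d <- dim(cube$counts)
  rr <- loc[1] + as.vector(off[, "dr"]); cc <- loc[2] + as.vector(off[, "dc"])
  ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
  rr <- rr[ok]; cc <- cc[ok]
  ok <- cube$mask[cbind(rr, cc)]
  rr <- rr[ok]; cc <- cc[ok]
  years <- max(1L, t - params$tau):t
  tibble::tibble(
    row = rep(rr, times = length(years)),
    col = rep(cc, times = length(years)),
    year = rep(years, each = length(rr))
  )
}

#' Getis-Ord Gi* over a space-time cube
#'
#' For every masked bin i, computes the local statistic
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
#'   {S \sqrt{(n W_i - W_i^2)/(n - 1)}}}
#' with binary weights over the space-time neighbourhood (see
#' [spacetime_neighbors()]), \eqn{W_i = \sum_j w_{ij}}, and the global mean
#' \eqn{\bar{X}} and standard deviation
#' \eqn{S = \sqrt{\sum_j x_j^2 / n - \bar{X}^2}} taken over all `n` masked
#' space-time bins of the cube. Two-sided normal p-values and hot / cold /
#' neither labels at the `alpha` threshold are attached; a constant cube
#' (S = 0) yields all-zero z and all-neither labels.
#'
#' @param cube an `st_cube` with at least 2 masked locations.
#' @param params an [eha_params()].
#' @return Object of class `gi_star_field`: arrays `z`, `p` and integer
#'   `label` (-1 cold, 0 neither, 1 hot; NA outside the mask), plus the
#'   critical z and inputs.
#' @export
gi_star <- function(cube, params = eha_params()) {
  stopifnot(inherits(cube, "st_cube"))
  if (sum(cube$mask) < 2) stop("Gi* requires at least 2 masked locations")
  d <- dim(cube$counts)
  Tn <- d[3]
  x <- cube$counts
  maskM <- cube$mask
  x[array(!maskM, dim = d)] <- 0  # recycle mask over years
  n <- cube$n
  xs <- x[array(maskM, dim = d)]
  xbar <- sum(xs) / n
  S <- sqrt(max(sum(xs^2) / n - xbar^2, 0))
  off <- spatial_offsets(cube$bin_size, params$neighborhood_distance)

  # spatial neighbour sums per year slice and spatial neighbour counts
  NW <- matrix(0, d[1], d[2])
  NS <- array(0, dim = d)
  mask_num <- maskM * 1
  for (k in seq_len(nrow(off))) {
    NW <- NW + mat_shift(mask_num, off[k, 1], off[k, 2])
    for (t in seq_len(Tn)) {
      NS[, , t] <- NS[, , t] + mat_shift(x[, , t], off[k, 1], off[k, 2])
    }
  }
  # accumulate the backward temporal window
  Wi <- array(0, dim = d)
  Sx <- array(0, dim = d)
  for (t in seq_len(Tn)) {
    window <- max(1L, t - params$tau):t
    Sx[, , t] <- apply(NS[, , window, drop = FALSE], c(1, 2), sum)
    Wi[, , t] <- NW * length(window)
  }

  z <- array(NA_real_, dim = d)
  if (S > 0) {
    denom <- S * sqrt(pmax(n * Wi - Wi^2, 0) / (n - 1))
    zv <- (Sx - xbar * Wi) / denom
    zv[!is.finite(zv)] <- 0
    z <- zv
  } else {
    z <- array(0, dim = d)
  }
  z[array(!maskM, dim = d)] <- NA_real_
  p <- 2 * pnorm(-abs(z))
  z_crit <- qnorm(1 - params$alpha / 2)
  label <- array(0L, dim = d)
  label[!is.na(z) & z > z_crit] <- 1L
  label[!is.na(z) & z < -z_crit] <- -1L
  label[array(!maskM, dim = d)] <- NA_integer_
  structure(
    list(z = z, p = p, label = label, z_crit = z_crit, params = params,
         mask = maskM, n = n, xbar = xbar, S = S, n_years = Tn),
    class = "gi_star_field"
  )
}

#' @export
print.gi_star_field <- function(x, ...) {
  cat(sprintf(
    "<gi_star_field> %d x %d x %d bins, n = %d, z_crit = %.3f; hot %d, cold %d\n",
    dim(x$z)[1], dim(x$z)[2], dim(x$z)[3], x$n, x$z_crit,
    sum(x$label == 1L, na.rm = TRUE), sum(x$label == -1L, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a Gi* field
#'
#' @param x a `gi_star_field`.
#' @param ... unused.
#' @return Tibble `row`, `col`, `year`, `z`, `p`, `label` ("hot", "cold",
#'   "neither"), masked bins only.
#' @export
tidy.gi_star_field <- function(x, ...) {
  d <- dim(x$z)
  keep <- as.vector(!is.na(x$z))
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2] * d[3])[keep],
    col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3])[keep],
    year = rep(seq_len(d[3]), each = d[1] * d[2])[keep],
    z = as.vector(x$z)[keep],
    p = as.vector(x$p)[keep],
    label = c("cold", "neither", "hot")[as.vector(x$label)[keep] + 2L]
  )
}
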