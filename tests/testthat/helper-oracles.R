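# Shared fixtures and independent brute-force oracles for the test suite.

CATS8 <- c("new", "consecutive", "intensifying", "persistent",
           "diminishing", "sporadic", "oscillating", "historical")

# Build an st_cube directly from a counts array (bypassing raster I/O), the
# way build_cube() would: mask = any loss (or all).
cube_from_counts <- function(counts, bin_size = 1000, cell_size = 1000,
                             mask_mode = c("any-loss", "all"),
                             xll = 0, yll = 0) {
  mask_mode <- match.arg(mask_mode)
  d <- dim(counts)
  k <- as.integer(bin_size / cell_size)
  total <- apply(counts, c(1, 2), sum)
  mask <- if (mask_mode == "any-loss") total >= 1 else matrix(TRUE, d[1], d[2])
  structure(
    list(counts = counts, mask = mask,
         pixels_per_bin = matrix(k^2, d[1], d[2]),
         bin_size = bin_size, n_years = d[3], pixel_area = cell_size^2,
         cell_size = cell_size, pixel_rows = d[1] * k, pixel_cols = d[2] * k,
         xll = xll, yll = yll, crs = "LOCAL_METRIC", n = sum(mask) * d[3]),
    class = "st_cube")
}

# Direct evaluation of the Gi* formula by exhaustive neighbour enumeration.
gi_star_brute <- function(cube, params = eha_params()) {
  d <- dim(cube$counts)
  Tn <- d[3]
  mask <- cube$mask
  n <- sum(mask) * Tn
  xs <- numeric(0)
  for (t in seq_len(Tn)) xs <- c(xs, cube$counts[, , t][mask])
  xbar <- sum(xs) / n
  S <- sqrt(sum(xs^2) / n - xbar^2)
  z <- array(NA_real_, dim = d)
  locs <- which(mask, arr.ind = TRUE)
  for (t in seq_len(Tn)) {
    tt <- max(1, t - params$tau):t
    for (i in seq_len(nrow(locs))) {
      r <- locs[i, 1]; c <- locs[i, 2]
      W <- 0; sx <- 0
      for (j in seq_len(nrow(locs))) {
        r2 <- locs[j, 1]; c2 <- locs[j, 2]
        dist <- sqrt((r - r2)^2 + (c - c2)^2) * cube$bin_size
        if (dist <= params$neighborhood_distance + 1e-9) {
          for (t2 in tt) {
            W <- W + 1
            sx <- sx + cube$counts[r2, c2, t2]
          }
        }
      }
      denom <- S * sqrt((n * W - W^2) / (n - 1))
      z[r, c, t] <- if (S > 0) (sx - xbar * W) / denom else 0
    }
  }
  z
}

# Even-odd ray-casting point-in-polygon (independent of mgcv::in.out).
point_in_ring_raycast <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Kruskal-Wallis H from first-principles rank arithmetic (tie-corrected).
kw_brute <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / tabulate(g)) -
    3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

# Gini / cross-entropy impurity of a label vector.
impurity_of <- function(y, criterion = "gini") {
  p <- as.numeric(table(y)) / length(y)
  p <- p[p > 0]
  if (criterion == "gini") 1 - sum(p^2) else -sum(p * log(p))
}

# Exhaustive search over all feature/threshold pairs for the best first
# CART split (midpoint candidate thresholds, weighted child impurity).
cart_root_brute <- function(X, y, criterion = "gini", min_leaf = 1) {
  best <- NULL
  for (j in seq_along(X)) {
    uv <- sort(unique(X[[j]]))
    if (length(uv) < 2) next
    for (thr in (uv[-1] + uv[-length(uv)]) / 2) {
      left <- X[[j]] < thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      imp <- (sum(left) * impurity_of(y[left], criterion) +
              sum(!left) * impurity_of(y[!left], criterion)) / length(y)
      if (is.null(best) || imp < best$imp - 1e-12) {
        best <- list(var = j, threshold = thr, imp = imp)
      }
    }
  }
  best
}

# Small deterministic label-sequence generator for classifier property tests.
random_label_seq <- function(Tn) {
  sample(c("hot", "cold", "neither"), Tn, replace = TRUE,
         prob = c(0.4, 0.15, 0.45))
}
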