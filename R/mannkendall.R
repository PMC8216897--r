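#' Mann-Kendall trend test
#'
#' Non-parametric trend test based on the sign of all pairwise differences:
#' \eqn{S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)}, with the tie-corrected
#' variance
#' \eqn{\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_g t_g (t_g-1)(2t_g+5)]/18}
#' over tie groups g, the continuity-corrected normal deviate
#' (\eqn{z = (S-1)/\sqrt{\mathrm{Var}(S)}} for S > 0,
#' \eqn{(S+1)/\sqrt{\mathrm{Var}(S)}} for S < 0, 0 otherwise) and a
#' two-sided normal p-value. Under no trend E(z) = 0. The trend direction is
#' reported only when p < `alpha`.
#'
#' @param series numeric vector, length >= 4 (the normal approximation is
#'   unreliable below that).
#' @param alpha significance level for calling a direction.
#' @return Object of class `eha_mk` with fields `S`, `var_s`, `z`, `p`,
#'   `direction` ("increasing", "decreasing" or "none") and `n`.
#' @examples
#' mann_kendall(1:18)   # S = 153, z = 152 / sqrt(697)
#' @export
mann_kendall <- function(series, alpha = 0.05) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 4 || anyNA(x)) {
    stop("mann_kendall requires a complete series of length >= 4")
  }
  res <- mk_stats(matrix(x, nrow = 1), alpha = alpha)
  structure(list(S = res$S, var_s = res$var_s, z = res$z, p = res$p,
                 direction = res$direction, n = n, alpha = alpha),
            class = "eha_mk")
}

#' @export
print.eha_mk <- function(x, ...) {
  cat(sprintf("Mann-Kendall: n = %d, S = %d, Var(S) = %.1f, z = %.3f, p = %.4g (%s)\n",
              x$n, x$S, x$var_s, x$z, x$p, x$direction))
  invisible(x)
}

#' @export
tidy.eha_mk <- function(x, ...) {
  tibble::tibble(S = x$S, var_s = x$var_s, z = x$z, p = x$p,
                 direction = x$direction, n = x$n)
}

# Vectorized Mann-Kendall over the rows of a matrix (one series per row).
# Returns a tibble with one row per input row.
mk_stats <- function(X, alpha = 0.05) {
  n <- ncol(X)
  m <- nrow(X)
  S <- integer(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(X[, j] - X[, i])
    }
  }
  base_var <- n * (n - 1) * (2 * n + 5)
  tie_term <- vapply(seq_len(m), function(r) {
    tg <- table(X[r, ])
    tg <- as.numeric(tg[tg > 1])
    if (!length(tg)) 0 else sum(tg * (tg - 1) * (2 * tg + 5))
  }, 0)
  var_s <- (base_var - tie_term) / 18
  z <- numeric(m)
  pos <- S > 0 & var_s > 0
  neg <- S < 0 & var_s > 0
  z[pos] <- (S[pos] - 1) / sqrt(var_s[pos])
  z[neg] <- (S[neg] + 1) / sqrt(var_s[neg])
  p <- 2 * pnorm(-abs(z))
  p[S == 0 | var_s == 0] <- 1
  direction <- rep("none", m)
  direction[p < alpha & S > 0] <- "increasing"
  direction[p < alpha & S < 0] <- "decreasing"
  tibble::tibble(S = as.integer(S), var_s = var_s, z = z, p = p,
                 direction = direction)
}

#' Trend in the intensity of clustering at one location
#'
#' Applies the Mann-Kendall test to a location's time series of Gi*
#' z-scores - the "intensity of clustering" reading of the per-location
#' trend. (The pipeline's default trend series is the location's raw count
#' series; see [run_eha()] and the methods vignette.)
#'
#' @param gi_field a `gi_star_field` from [gi_star()].
#' @param location integer `c(row, col)`, must be masked.
#' @param params an [eha_params()]; its `alpha` is used for the direction.
#' @return An `eha_mk` object.
#' @export
intensity_trend <- function(gi_field, location, params = eha_params()) {
  stopifnot(inherits(gi_field, "gi_star_field"), length(location) == 2)
  if (!gi_field$mask[location[1], location[2]]) {
    stop(sprintf("location (%d, %d) is outside the analysis mask",
                 location[1], location[2]))
  }
  mann_kendall(gi_field$z[location[1], location[2], ], alpha = params$alpha)
}
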