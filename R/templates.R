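#' Planted hotspot intensity templates
#'
#' Deterministic per-year intensity profiles used by the scenario generator
#' to plant each of the eight emerging-hotspot patterns (plus a pure cold
#' template). The returned vector scales the patch amplitude per year; a
#' `suppressed` attribute flags years in which the background loss process
#' is switched off inside the patch so that Gi* cold bins can arise
#' (oscillating and cold templates only).
#'
#' Profiles, for a series of `n_years` steps:
#' \describe{
#'   \item{new}{0 everywhere except 1 in the final year.}
#'   \item{consecutive}{0, then a final uninterrupted run of
#'     `floor(0.3 * n_years)` ones.}
#'   \item{intensifying}{linear ramp `t / n_years`, all years > 0.}
#'   \item{persistent}{1 every year.}
#'   \item{diminishing}{linear ramp `(n_years - t) / (n_years - 1)`; every
#'     year but the last > 0.}
#'   \item{sporadic}{on/off blocks covering well under 90% of years, final
#'     year on, never suppressed.}
#'   \item{oscillating}{on blocks alternating with suppressed blocks, final
#'     year on.}
#'   \item{historical}{on for an initial run covering at least 90% of years
#'     (per the floor-based operationalization: 16 of 18), then off for the
#'     final years.}
#'   \item{cold}{never on; every year suppressed.}
#' }
#'
#' @param category_template template name, one of
#'   `r paste(c(eha_categories(), "cold"), collapse = ", ")`.
#' @param n_years series length (>= 2).
#' @return Numeric vector of length `n_years` with values in `[0, 1]` and a
#'   logical attribute `"suppressed"` of the same length.
#' @examples
#' template_profile("new", 18)
#' template_profile("consecutive", 18)  # final run of 5 ones
#' @export
template_profile <- function(category_template, n_years) {
  valid <- c(eha_categories(), "cold")
  if (!is.character(category_template) || length(category_template) != 1 ||
      !category_template %in% valid) {
    stop("unknown template '", category_template, "'; valid templates are: ",
         paste(valid, collapse = ", "))
  }
  n <- as.integer(n_years)
  stopifnot(n >= 2)
  t <- seq_len(n)
  prof <- numeric(n)
  supp <- logical(n)
  switch(category_template,
    new = { prof[n] <- 1 },
    persistent = { prof[] <- 1 },
    consecutive = {
      run <- max(2L, min(n - 1L, floor(0.3 * n)))
      prof[(n - run + 1L):n] <- 1
    },
    intensifying = { prof <- t / n },
    diminishing = { prof <- (n - t) / (n - 1) },
    sporadic = {
      prof[(t %% 7L) %in% c(2L, 3L, 4L)] <- 1
      prof[n] <- 1
    },
    oscillating = {
      on <- ((t - 1L) %% 6L) < 3L
      on[n] <- TRUE
      prof[on] <- 1
      supp <- !on
    },
    historical = {
      # on-run covering the 90% persistence threshold (16 of 18), with an
      # off-tail of 2 years where possible so the final step is clearly
      # not hot even under a 1-step temporal neighbourhood
      k <- max(floor(0.9 * n), n - 2L)
      prof[seq_len(min(k, n - 1L))] <- 1
    },
    cold = { supp[] <- TRUE }
  )
  attr(prof, "suppressed") <- supp
  prof
}
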