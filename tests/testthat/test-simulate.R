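small_spec <- function(..., seed = 11) {
  scenario_spec(grid_rows = 40, grid_cols = 40, cell_size = 1000,
                n_years = 18, neighborhood_distance = 8000, seed = seed, ...)
}

test_that("degenerate loss processes behave in closed form", {
  none <- generate_loss_raster(small_spec(background_rate = 0))
  expect_true(all(none$raster$values == 0L))

  # background_rate below 1 but certain first-year loss via a patch at 0.999
  sure <- generate_loss_raster(
    scenario_spec(grid_rows = 30, grid_cols = 30, cell_size = 1000,
                  n_years = 2, background_rate = 0.9999,
                  neighborhood_distance = 5000, seed = 3))
  expect_gt(mean(sure$raster$values == 1L), 0.99)
})

test_that("identical scenario and seed reproduce identical outputs", {
  sp <- small_spec(background_rate = 0.01,
                   patches = list(planted_patch("sporadic", 0.05,
                                                rows = c(10, 19), cols = c(10, 19))))
  a <- generate_loss_raster(sp)
  b <- generate_loss_raster(sp)
  expect_identical(a$raster$values, b$raster$values)
  expect_identical(a$truth$values, b$truth$values)
  ca <- generate_covariates(sp)
  cb <- generate_covariates(sp)
  expect_identical(ca$elevation$values, cb$elevation$values)
  expect_identical(ca$footprint$values, cb$footprint$values)
  expect_identical(ca$plantations, cb$plantations)
  pa <- generate_protected_areas(sp, 3)
  pb <- generate_protected_areas(sp, 3)
  expect_identical(pa$geometry, pb$geometry)
})

test_that("background survival matches the closed form", {
  # outside-patch never-lost fraction ~ (1 - p0)^18 within 3 Monte-Carlo SE
  sp <- scenario_spec(grid_rows = 100, grid_cols = 100, cell_size = 1000,
                      n_years = 18, background_rate = 0.005,
                      patches = list(planted_patch("persistent", 0.04,
                                                   rows = c(40, 59),
                                                   cols = c(40, 59))),
                      seed = 1, neighborhood_distance = 10000)
  g <- generate_loss_raster(sp)
  outside <- g$raster$values[g$truth$values == 0L]
  p_surv <- (1 - 0.005)^18
  se <- sqrt(p_surv * (1 - p_surv) / length(outside))
  expect_lt(abs(mean(outside == 0L) - p_surv), 3 * se)
})

test_that("patch-free yearly totals are binomial within 4 SE", {
  p0 <- 0.02
  sp <- scenario_spec(grid_rows = 32, grid_cols = 32, cell_size = 1000,
                      n_years = 18, background_rate = p0, seed = 5,
                      neighborhood_distance = 8000)
  g <- generate_loss_raster(sp)
  npix <- 32 * 32
  counts <- tabulate(g$raster$values[g$raster$values > 0], nbins = 18)
  for (t in 1:18) {
    expected <- npix * p0 * (1 - p0)^(t - 1)
    se <- sqrt(expected * (1 - p0 * (1 - p0)^(t - 1)))
    expect_lt(abs(counts[t] - expected), 4 * se)
  }
})

test_that("infeasible loss probabilities are rejected", {
  sp <- small_spec(background_rate = 0.01,
                   patches = list(planted_patch("persistent", 0.08,
                                                rows = c(5, 10), cols = c(5, 10))))
  expect_error(generate_loss_raster(sp), "exceeds 1")
  expect_error(
    scenario_spec(grid_rows = 40, grid_cols = 40, background_rate = 0.5,
                  neighborhood_distance = 8000,
                  patches = list(planted_patch("new", 0.6,
                                               rows = c(1, 5), cols = c(1, 5)))),
    "exceeds 1")
})

test_that("scenario validation enforces its invariants", {
  expect_error(scenario_spec(grid_rows = 10, grid_cols = 10,
                             cell_size = 1000), "3 neighbourhood radii")
  expect_error(
    small_spec(patches = list(
      planted_patch("new", 0.1, rows = c(1, 10), cols = c(1, 10)),
      planted_patch("sporadic", 0.1, rows = c(5, 12), cols = c(5, 12)))),
    "overlap")
  expect_error(
    small_spec(patches = list(planted_patch("new", 0.1,
                                            rows = c(30, 45), cols = c(1, 5)))),
    "outside the grid")
})

test_that("covariate limit cases are exact", {
  sp <- small_spec(background_rate = 0.01)
  flat <- generate_covariates(sp, n_bumps = 0)
  expect_true(all(flat$elevation$values == 0))
  expect_true(all(slope_from_elevation(flat$elevation)$values == 0))

  const <- generate_covariates(sp, footprint_lambda = Inf, footprint_max = 40)
  expect_true(all(const$footprint$values == 40))

  clipped <- generate_covariates(sp, footprint_max = 80, footprint_lambda = Inf)
  expect_true(all(clipped$footprint$values == 50))  # clipped to index range
})

test_that("protected-area generation is valid and bounded", {
  sp <- small_spec(background_rate = 0.01)
  p0 <- generate_protected_areas(sp, 0)
  expect_s3_class(p0, "pa_collection")
  expect_equal(nrow(p0), 0)

  p3 <- generate_protected_areas(sp, 3)
  expect_equal(nrow(p3), 3)
  expect_true(all(pa_areas(p3) > 0))
  W <- 40 * 1000
  for (g in p3$geometry) {
    expect_true(all(g[[1]][, 1] >= 0 & g[[1]][, 1] <= W))
  }

  p25 <- generate_protected_areas(sp, 25, seed = 99)
  valid <- c("Ia", "Ib", "II", "III", "IV", "V", "VI",
             "Not reported", "Not applicable")
  expect_true(all(p25$iucn_category %in% valid))
})
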