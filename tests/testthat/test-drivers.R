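test_that("distance maps match direct computation and min composition", {
  r <- eha_raster(matrix(0, 8, 10), cell_size = 1000)
  # feature exactly on a cell centroid
  one <- euclidean_distance_map(r, cbind(2500, 3500))
  expect_equal(one$values[5, 3], 0)  # y = 8000 - 4500 = 3500 at row 5
  # single corner feature: field equals the analytic distance everywhere
  corner <- euclidean_distance_map(r, cbind(0, 0))
  cc <- ehacube:::raster_centroids(r)
  for (i in 1:8) for (j in 1:10) {
    expect_equal(corner$values[i, j], sqrt(cc$x[j]^2 + cc$y[i]^2))
  }
  # two features: elementwise min of the single-feature fields
  f1 <- euclidean_distance_map(r, cbind(1000, 1000))
  f2 <- euclidean_distance_map(r, cbind(9000, 7000))
  both <- euclidean_distance_map(r, rbind(c(1000, 1000), c(9000, 7000)))
  expect_equal(both$values, pmin(f1$values, f2$values))
  # triangle property: adding a feature never increases any distance
  more <- euclidean_distance_map(r, rbind(c(1000, 1000), c(9000, 7000),
                                          c(5000, 4000)))
  expect_true(all(more$values <= both$values + 1e-12))
  expect_error(euclidean_distance_map(r, cbind(numeric(0), numeric(0))),
               "empty")
})

test_that("polygon features measure distance to nearest edge", {
  r <- eha_raster(matrix(0, 6, 6), cell_size = 1000)
  square <- list(rbind(c(2000, 2000), c(4000, 2000), c(4000, 4000),
                       c(2000, 4000)))
  d <- euclidean_distance_map(r, square)
  # centroid (2500, 3500) sits inside-ish near edges; nearest edge x = 2000
  expect_equal(d$values[3, 3], 500)
  # far corner cell (5500, 500): nearest point is polygon corner (4000, 2000)
  expect_equal(d$values[6, 6], sqrt(1500^2 + 1500^2))
})

test_that("Horn slope reproduces analytic gradients", {
  flat <- eha_raster(matrix(7, 5, 5), cell_size = 30)
  expect_true(all(slope_from_elevation(flat)$values == 0))

  # inclined plane z = x with 1 m cells: 45 degrees at interior cells
  nr <- 7; nc <- 7
  xplane <- eha_raster(matrix(rep(1:nc, each = nr), nr, nc), cell_size = 1)
  s <- slope_from_elevation(xplane)
  expect_equal(s$values[2:(nr - 1), 2:(nc - 1)],
               matrix(45, nr - 2, nc - 2), tolerance = 1e-10)
  # isotropy: the transposed plane has the same slope magnitudes
  yplane <- eha_raster(t(xplane$values), cell_size = 1)
  s2 <- slope_from_elevation(yplane)
  expect_equal(s2$values, t(s$values), tolerance = 1e-10)
  expect_true(all(s$values >= 0 & s$values < 90))
})

drivers_fixture <- function() {
  # deterministic 6-location result standing in for a category map
  loc <- tibble::tibble(
    row = c(1, 1, 2, 2, 3, 3), col = c(1, 2, 1, 2, 1, 2),
    x = 0, y = 0,
    category = c("sporadic", "sporadic", "oscillating", "oscillating",
                 "oscillating", "none"),
    hot_count = 0L, cold_count = 0L, final_hot = FALSE, terminal_run = 0L,
    trend_s = 0L, trend_z = 0, trend_p = 1, trend_direction = "none")
  res <- structure(list(locations = loc, category = NULL), class = "eha_result")
  covs <- tibble::tibble(
    elevation = c(100, 120, 80, 90, 85, 200),
    footprint = c(10, 12, 6, 7, 8, 1))
  list(res = res, covs = covs)
}

test_that("category summaries equal hand arithmetic", {
  fx <- drivers_fixture()
  tab <- category_summaries(fx$res, fx$covs)
  spo_el <- tab[tab$category == "sporadic" & tab$covariate == "elevation", ]
  expect_equal(spo_el$mean, 110)
  expect_equal(spo_el$sem, sd(c(100, 120)) / sqrt(2))
  expect_equal(spo_el$n, 2L)
  osc_fp <- tab[tab$category == "oscillating" & tab$covariate == "footprint", ]
  expect_equal(osc_fp$mean, 7)
  expect_equal(osc_fp$sem, sd(c(6, 7, 8)) / sqrt(3))
  # "none" excluded by default, included on demand
  expect_false("none" %in% tab$category)
  tab2 <- category_summaries(fx$res, fx$covs, include_none = TRUE)
  none_el <- tab2[tab2$category == "none" & tab2$covariate == "elevation", ]
  expect_equal(none_el$mean, 200)
  expect_equal(none_el$sem, 0)  # single member
  # constant covariate: SEM 0 everywhere
  tab3 <- category_summaries(fx$res, tibble::tibble(c5 = rep(5, 6)))
  expect_true(all(tab3$sem == 0))
})

test_that("Kruskal-Wallis H matches exhaustive rank arithmetic", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, kw_brute(g), tolerance = 1e-12)
  expect_equal(kw$H, 3.857142857, tolerance = 1e-8)
  expect_equal(kw$df, 1)

  # tied data
  gt <- list(c(1, 1, 2, 3), c(2, 2, 4), c(3, 3, 3, 5))
  kwt <- kruskal_wallis(gt)
  expect_equal(kwt$H, kw_brute(gt), tolerance = 1e-12)
  expect_equal(kwt$p, stats::pchisq(kwt$H, kwt$df, lower.tail = FALSE))

  # identical groups: no variation
  same <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  # rank-based invariance under strictly monotone transforms
  g2 <- list(exp(c(1, 2, 3)), exp(c(4, 5, 6)))
  expect_equal(kruskal_wallis(g2)$H, kw$H, tolerance = 1e-12)
})

test_that("Kruskal-Wallis chi-square p agrees with a permutation check", {
  set.seed(88)
  g <- list(c(3.1, 4.5, 2.2, 5.0), c(4.0, 6.1, 5.5), c(1.0, 2.5, 3.3, 2.8))
  kw <- kruskal_wallis(g)
  x <- unlist(g)
  sizes <- lengths(g)
  lab <- rep(seq_along(g), sizes)
  nperm <- 10000
  exceed <- 0
  for (i in seq_len(nperm)) {
    perm <- sample(lab)
    exceed <- exceed + (kw_brute(split(x, perm)) >= kw$H - 1e-12)
  }
  p_perm <- exceed / nperm
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(p_perm - kw$p), 4 * se + 0.02)
})

test_that("per-covariate KW layout returns one test per variable", {
  fx <- drivers_fixture()
  kt <- kruskal_wallis_by_category(fx$res, fx$covs)
  expect_equal(kt$covariate, c("elevation", "footprint"))
  expect_equal(kt$df, c(1, 1))
  expect_equal(kt$H[1],
               kw_brute(list(c(100, 120), c(80, 90, 85))), tolerance = 1e-12)
})
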