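# A deterministic little landscape: 10x10 bins of 2x2 pixels, every
# location masked, a hot block in the north-west.
overlay_fixture <- function(seed = 77) {
  set.seed(seed)
  counts <- array(rpois(10 * 10 * 12, 1) + 1L, dim = c(10, 10, 12))
  counts[2:4, 2:4, ] <- counts[2:4, 2:4, ] + 10L
  cube <- cube_from_counts(counts, bin_size = 2000, cell_size = 1000)
  res <- run_eha(cube, eha_params(neighborhood_distance = 3000))
  list(cube = cube, res = res)
}

rect_pa <- function(x0, y0, x1, y1, name = "PA", iucn = "II",
                    reverse = FALSE) {
  ring <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  if (reverse) ring <- ring[4:1, ]
  pa_collection(name = name, iucn_category = iucn, geometry = list(ring))
}

test_that("rasterize_pa matches a brute-force point-in-polygon oracle", {
  fx <- overlay_fixture()
  set.seed(5)
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  blob <- cbind(9000 + 4500 * cos(th) * runif(8, 0.6, 1),
                11000 + 4500 * sin(th) * runif(8, 0.6, 1))
  pas <- pa_collection(name = c("rect", "blob"),
                       iucn_category = c("Ia", "IV"),
                       geometry = list(rbind(c(2000, 2000), c(10900, 2000),
                                             c(10900, 8900), c(2000, 8900)),
                                       blob))
  ids <- rasterize_pa(pas, fx$cube)
  cc <- ehacube:::cube_centroids(fx$cube)
  for (r in 1:10) for (c in 1:10) {
    in1 <- point_in_ring_raycast(cc$x[c], cc$y[r], pas$geometry[[1]][[1]])
    in2 <- point_in_ring_raycast(cc$x[c], cc$y[r], pas$geometry[[2]][[1]])
    expected <- if (in1) 1L else if (in2) 2L else NA_integer_
    expect_identical(ids[r, c], expected)
  }
})

test_that("whole-grid and empty collections are trivial", {
  fx <- overlay_fixture()
  all_pa <- rect_pa(-1, -1, 20001, 20001)
  ids <- rasterize_pa(all_pa, fx$cube)
  expect_true(all(ids == 1L))
  empty <- pa_collection()
  attr(empty, "crs") <- "LOCAL_METRIC"
  ids0 <- rasterize_pa(empty, fx$cube)
  expect_true(all(is.na(ids0)))
  mismatch <- rect_pa(0, 0, 1, 1)
  attr(mismatch, "crs") <- "EPSG:32648"
  expect_error(rasterize_pa(mismatch, fx$cube), "CRS mismatch")
})

test_that("per-PA shares sum to 100 and undefined shares stay NA", {
  fx <- overlay_fixture()
  pas <- dplyr::bind_rows(
    rect_pa(0, 12000, 8000, 20000, name = "north-west", iucn = "II"),
    rect_pa(12000, 0, 20000, 6000, name = "south-east", iucn = "VI"),
    rect_pa(30000, 30000, 40000, 40000, name = "off-grid", iucn = "Ia"))
  class(pas) <- c("pa_collection", class(pas))
  attr(pas, "crs") <- "LOCAL_METRIC"
  ids <- rasterize_pa(pas, fx$cube)
  sh <- pa_category_shares(fx$res, ids, pas)
  sums <- tapply(sh$shares$share_pct, sh$shares$name, sum)
  expect_equal(as.numeric(sums[c("north-west", "south-east")]), c(100, 100),
               tolerance = 1e-6)
  expect_true(all(is.na(sh$shares$share_pct[sh$shares$name == "off-grid"])))
  expect_true(all(sh$shares$share_pct >= 0, na.rm = TRUE))
})

test_that("inside + outside counts conserve the category totals", {
  fx <- overlay_fixture()
  pas <- rect_pa(1100, 9100, 8900, 18900)
  ids <- rasterize_pa(pas, fx$cube)
  sh <- pa_category_shares(fx$res, ids, pas)
  totals <- table(factor(fx$res$locations$category, levels = CATS8))
  expect_equal(sh$island$inside + sh$island$outside,
               as.integer(totals), ignore_attr = TRUE)
})

test_that("shares are invariant to polygon vertex order and winding", {
  fx <- overlay_fixture()
  a <- rect_pa(2000, 2000, 12000, 12000)
  b <- rect_pa(2000, 2000, 12000, 12000, reverse = TRUE)
  ida <- rasterize_pa(a, fx$cube)
  idb <- rasterize_pa(b, fx$cube)
  expect_identical(ida, idb)
})

test_that("a half-covered hot core yields ~50% category share", {
  # hot block spans bins rows 2:4, cols 2:4 (x in [2,8] km, y in [12,18] km);
  # a PA covering its left half plus background should see ~half its
  # locations category-bearing
  fx <- overlay_fixture()
  core_cats <- fx$res$category[2:4, 2:4]
  main_cat <- names(sort(table(core_cats), decreasing = TRUE))[1]
  expect_true(main_cat %in% CATS8)
  # PA holding exactly 6 core bins and 6 background bins south of the block
  pa <- rect_pa(2000, 3900, 8000, 16100)
  ids <- rasterize_pa(pa, fx$cube)
  expect_equal(sum(!is.na(ids)), 18)
  sh <- pa_category_shares(fx$res, ids, pa)
  got <- sh$shares$share_pct[sh$shares$category == main_cat]
  block_share <- 100 * sum(fx$res$category[ids == 1L & !is.na(ids)] == main_cat) / 18
  expect_equal(got, block_share)
  expect_gt(got, 25)
  expect_lt(got, 75)
})

test_that("overlapping PAs resolve to the first listed with a warning", {
  fx <- overlay_fixture()
  pas <- dplyr::bind_rows(rect_pa(900, 900, 9100, 9100, name = "first"),
                          rect_pa(5100, 5100, 15100, 15100, name = "second"))
  class(pas) <- c("pa_collection", class(pas))
  attr(pas, "crs") <- "LOCAL_METRIC"
  expect_warning(ids <- rasterize_pa(pas, fx$cube), "first-listed")
  # shared centroids belong to PA 1
  cc <- ehacube:::cube_centroids(fx$cube)
  for (r in 1:10) for (c in 1:10) {
    if (point_in_ring_raycast(cc$x[c], cc$y[r], pas$geometry[[1]][[1]])) {
      expect_equal(ids[r, c], 1L)
    }
  }
})

test_that("boundary profile partitions locations and flags edge hotspots", {
  fx <- overlay_fixture()
  # PA sharing its eastern boundary with the hot block's western edge
  pa <- rect_pa(100, 11900, 3900, 17900)
  prof <- boundary_distance_profile(fx$res, pa, ring_width = 2000)
  expect_equal(sum(prof$n), nrow(fx$res$locations))  # partition
  inner <- prof[prof$ring_min < 0, ]
  # the block pokes into the PA near its boundary: innermost ring counts
  # must dominate the deep interior
  innermost <- sum(inner$n[inner$ring_min == -2000 & inner$category %in% CATS8])
  deep <- sum(inner$n[inner$ring_min < -2000 & inner$category %in% CATS8])
  expect_gte(innermost, deep)

  # a PA with no interior hotspots has all-"none" interior rings
  far <- rect_pa(12100, 100, 19900, 7900)
  prof2 <- boundary_distance_profile(fx$res, far, ring_width = 2000)
  expect_true(all(prof2$category[prof2$ring_min < 0] == "none"))
})
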