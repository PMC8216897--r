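mk_stub <- function(direction) list(direction = direction)

test_that("min_hot_steps reproduces the 16-of-18 operationalization", {
  expect_equal(min_hot_steps(18, 0.90), 16L)
  expect_equal(min_hot_steps(10, 1.0), 10L)
  # exhaustive check: smallest k with floor semantics
  expect_equal(min_hot_steps(18, 0.90), as.integer(floor(0.9 * 18)))
  expect_equal(min_hot_steps(20, 0.90), 18L)
})

test_that("category rules fire per their definitions", {
  Tn <- 18
  lab <- function(hot_at = integer(), cold_at = integer()) {
    l <- rep("neither", Tn)
    l[hot_at] <- "hot"; l[cold_at] <- "cold"
    l
  }
  none_trend <- mk_stub("none")

  # a final-step-only hotspot that has never been hot before is new
  expect_equal(classify_location(lab(hot_at = 18), none_trend), "new")
  # an uninterrupted final run with no prior history is consecutive
  expect_equal(classify_location(lab(hot_at = 14:18), none_trend), "consecutive")
  # a run of 1 with prior isolated history is neither new nor consecutive
  expect_equal(classify_location(lab(hot_at = c(3, 18)), none_trend), "sporadic")
  # >= 16 hot steps: trend splits intensifying / diminishing / persistent
  expect_equal(classify_location(lab(hot_at = 1:18), none_trend), "persistent")
  expect_equal(classify_location(lab(hot_at = 1:18), mk_stub("increasing")),
               "intensifying")
  expect_equal(classify_location(lab(hot_at = 1:18), mk_stub("decreasing")),
               "diminishing")
  # final step not hot with >= 16 hot steps is historical, whatever the trend
  expect_equal(classify_location(lab(hot_at = 1:16), none_trend), "historical")
  expect_equal(classify_location(lab(hot_at = 1:16), mk_stub("decreasing")),
               "historical")
  # cold history + final hot below the persistence threshold is oscillating
  osc <- lab(hot_at = c(1, 17, 18), cold_at = 2)
  expect_equal(classify_location(osc, none_trend), "oscillating")
  # on-again off-again with no cold history is sporadic
  expect_equal(classify_location(lab(hot_at = c(2, 3, 9, 10, 18)), none_trend),
               "sporadic")
  # no hot steps at all can never earn a category
  expect_equal(classify_location(lab(), none_trend), "none")
  expect_equal(classify_location(lab(cold_at = 1:18), none_trend), "none")

  expect_error(classify_location(c("hot", "tepid"), none_trend), "tepid")
})

test_that("exactly one rule fires for every sequence (exhaustive + random)", {
  all_cats <- c(CATS8, "none")
  # exhaustive over all 3^8 sequences of length 8, both trend directions
  seqs <- expand.grid(rep(list(c("hot", "cold", "neither")), 8),
                      stringsAsFactors = FALSE)
  for (dir in c("none", "increasing", "decreasing")) {
    got <- apply(seqs, 1, function(s) {
      classify_location(unname(unlist(s)), mk_stub(dir))
    })
    expect_true(all(got %in% all_cats))
    expect_length(got, nrow(seqs))  # one label per sequence, never an error
  }
  # random longer sequences
  set.seed(55)
  for (i in 1:200) {
    s <- random_label_seq(18)
    out <- classify_location(s, mk_stub(sample(c("none", "increasing",
                                                 "decreasing"), 1)))
    expect_length(out, 1)
    expect_true(out %in% all_cats)
    if (!"hot" %in% s) expect_equal(out, "none")
    if (out %in% setdiff(CATS8, "historical")) {
      expect_true(s[18] == "hot" || sum(s == "hot") >= 16)
    }
  }
})

test_that("all eight categories (and only they) are reachable", {
  Tn <- 18
  fixtures <- list(
    new = list(hot = 18, cold = integer(), dir = "none"),
    consecutive = list(hot = 15:18, cold = integer(), dir = "none"),
    intensifying = list(hot = 1:18, cold = integer(), dir = "increasing"),
    persistent = list(hot = 1:18, cold = integer(), dir = "none"),
    diminishing = list(hot = 1:18, cold = integer(), dir = "decreasing"),
    sporadic = list(hot = c(2, 3, 10, 18), cold = integer(), dir = "none"),
    oscillating = list(hot = c(2, 3, 18), cold = 7, dir = "none"),
    historical = list(hot = 1:16, cold = integer(), dir = "none")
  )
  got <- vapply(names(fixtures), function(nm) {
    f <- fixtures[[nm]]
    l <- rep("neither", Tn); l[f$hot] <- "hot"; l[f$cold] <- "cold"
    classify_location(l, mk_stub(f$dir))
  }, "")
  expect_equal(unname(got), names(fixtures))
  expect_setequal(names(fixtures), CATS8)
})

test_that("stricter alpha never adds category-bearing locations", {
  set.seed(66)
  counts <- array(rpois(12 * 12 * 18, 2), dim = c(12, 12, 18))
  counts[5:7, 5:7, 10:18] <- counts[5:7, 5:7, 10:18] + 8L
  cube <- cube_from_counts(counts, bin_size = 1000, cell_size = 1000)
  n_cat <- vapply(c(0.05, 0.01), function(a) {
    res <- run_eha(cube, eha_params(neighborhood_distance = 2000, alpha = a))
    sum(res$locations$category != "none")
  }, 0)
  expect_lte(n_cat[2], n_cat[1])
})

test_that("run_eha handles empty and degenerate cubes", {
  empty <- cube_from_counts(array(0L, dim = c(4, 4, 4)))
  res <- run_eha(empty)
  expect_equal(nrow(res$locations), 0)
  expect_true(all(is.na(res$category)))
  expect_equal(nrow(category_composition(res)), 0)
})
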