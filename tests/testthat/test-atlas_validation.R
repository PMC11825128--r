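test_that("top-fraction thresholding keeps exact counts with stable ties", {
  set.seed(1)
  for (n in c(100, 1000)) {
    p <- runif(n)
    keep <- threshold_top_fraction(p, 0.05)
    expect_equal(sum(keep), ceiling(0.05 * n))
    expect_true(min(p[keep]) >= max(p[!keep]))
  }
  # strictly increasing probabilities: the top-index block is retained
  p <- seq(0, 1, length.out = 100)
  expect_equal(which(threshold_top_fraction(p, 0.05)), 96:100)
  # all equal: lowest-index voxels win the tie
  expect_equal(which(threshold_top_fraction(rep(0.5, 100), 0.05)), 1:5)
  expect_error(threshold_top_fraction(p, 0), "between 0 and 1")
  expect_error(threshold_top_fraction(p, 1), "between 0 and 1")
})

test_that("retained sets grow monotonically with the fraction", {
  set.seed(2)
  p <- rnorm(500)
  f <- c(0.02, 0.05, 0.1, 0.3, 0.7)
  sets <- lapply(f, function(fr) which(threshold_top_fraction(p, fr)))
  for (q in seq_along(f)[-1]) {
    expect_true(all(sets[[q - 1]] %in% sets[[q]]))
  }
})

test_that("maximum probability map assigns argmax among retaining regions", {
  atlas <- structure(list(region_names = c("CM", "LB", "SF"),
                          prob = rbind(c(0.2, 0.7, 0.1),
                                       c(0.9, 0.1, 0.0),
                                       c(0.3, 0.3, 0.1),
                                       c(0.1, 0.2, 0.05))),
                     class = "prob_atlas")
  masks <- cbind(c(TRUE, TRUE, TRUE, FALSE),
                 c(TRUE, TRUE, TRUE, FALSE),
                 c(TRUE, FALSE, FALSE, FALSE))
  expect_message(lab <- maximum_probability_map(atlas, masks), "tie")
  expect_equal(as.integer(lab), c(2L, 1L, 1L, NA))  # tie at voxel 3 -> CM
  expect_equal(attr(lab, "region_names"), c("CM", "LB", "SF"))
  one <- structure(list(region_names = "CM", prob = atlas$prob[, 1,
                                                               drop = FALSE]),
                   class = "prob_atlas")
  expect_error(maximum_probability_map(one, masks[, 1, drop = FALSE]),
               "at least 2")
})

test_that("a hard axis tiling is recovered exactly", {
  mask <- make_ellipsoid_mask(c(18, 18, 18), c(7, 6, 6))
  atlas <- make_tiled_atlas(mask, axis = "inferior-superior", n_regions = 3,
                            softness = 1e-6)
  masks <- lapply(1:3, function(g) atlas$prob[, g] > 0.5)
  lab <- maximum_probability_map(atlas, masks)
  expect_equal(as.integer(lab), as.integer(attr(atlas, "truth_band")))
  # each region's top-5% core lies inside its own generative band
  soft <- make_tiled_atlas(mask, n_regions = 3, softness = 1.5)
  for (g in 1:3) {
    core <- threshold_top_fraction(soft$prob[, g], 0.05)
    expect_true(all(attr(soft, "truth_band")[core] == g))
  }
})

test_that("component_by_region groups values and conserves counts", {
  lab <- structure(c(1L, 1L, 2L, 2L, NA, 3L, 3L),
                   region_names = c("A", "B", "C"), class = "label_map")
  comp <- c(1, 2, 10, 12, 99, 5, 7)
  out <- component_by_region(comp, lab)
  expect_equal(out$summary$n, c(2L, 2L, 2L))
  expect_equal(out$summary$mean, c(1.5, 11, 6))
  expect_equal(sum(out$summary$n), sum(!is.na(lab)))
  expect_equal(out$values$B, c(10, 12))
})

test_that("ANOVA F matches the textbook oracle", {
  lab <- structure(rep(1:3, each = 3), region_names = c("A", "B", "C"),
                   class = "label_map")
  comp <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  ens <- permutation_surrogates(comp, n_surrogates = 99, seed = 1)
  res <- anova_with_surrogate_null(comp, lab, ens)
  expect_equal(res$F, 27)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  # identical group means: F = 0
  res0 <- anova_with_surrogate_null(rep(c(1, 2, 3), times = 3), lab,
                                    permutation_surrogates(rep(c(1, 2, 3), 3),
                                                           99, 1))
  expect_equal(res0$F, 0)
  # random groups vs oracle and vs stats::oneway.test
  set.seed(3)
  for (rep_i in 1:5) {
    vals <- rnorm(30)
    g <- sample(1:3, 30, replace = TRUE)
    while (min(tabulate(g, 3)) < 2) g <- sample(1:3, 30, replace = TRUE)
    labr <- structure(g, region_names = c("A", "B", "C"),
                      class = "label_map")
    r <- anova_with_surrogate_null(vals, labr,
                                   permutation_surrogates(vals, 19, rep_i))
    expect_equal(r$F, oracle_oneway_F(vals, g), tolerance = 1e-10)
    expect_equal(r$F,
                 unname(stats::oneway.test(vals ~ factor(g),
                                           var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("surrogate-null ANOVA is insensitive to label-independent maps", {
  mask <- make_ellipsoid_mask(c(14, 14, 14), c(5, 5, 4))
  tab <- voxel_table(masked_volume(array(0, dim(mask)), mask, 100))
  atlas <- make_tiled_atlas(mask, n_regions = 3, softness = 1e-6)
  lab <- maximum_probability_map(atlas, lapply(1:3, function(g)
    atlas$prob[, g] > 0.5))
  hits <- vapply(1:10, function(i) {
    f <- make_smooth_field(mask, 1.5, seed = 100 + i)
    ens <- variogram_surrogates(f, tab, n_surrogates = 99, seed = 200 + i)
    anova_with_surrogate_null(f, lab, ens)$p_null < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.3)
})

test_that("degenerate groupings are rejected", {
  lab <- structure(c(1L, 1L, 1L, 2L), region_names = c("A", "B"),
                   class = "label_map")
  ens <- permutation_surrogates(1:4, 9, 1)
  expect_error(anova_with_surrogate_null(1:4, lab, ens), ">= 2")
})
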