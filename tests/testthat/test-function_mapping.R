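test_that("quantile subregions keep exact disjoint counts", {
  set.seed(1)
  for (n in c(100, 1000)) {
    comp <- rnorm(n)
    sp <- quantile_subregions(comp, 0.25)
    expect_equal(sum(sp$high_mask), ceiling(0.25 * n))
    expect_equal(sum(sp$low_mask), ceiling(0.25 * n))
    expect_false(any(sp$high_mask & sp$low_mask))
    expect_true(min(comp[sp$high_mask]) >= max(comp[!sp$high_mask]))
  }
  comp <- seq_len(100)
  expect_equal(which(quantile_subregions(comp, 0.25)$high_mask), 76:100)
  expect_error(quantile_subregions(comp, 0.6), "0.5")
  # odd n at fraction 0.5: 51 + 51 > 101 voxels cannot be disjoint
  expect_error(quantile_subregions(rnorm(101), 0.5), "overlap")
})

test_that("seed time series averages masked voxels", {
  set.seed(2)
  ts <- matrix(rnorm(50 * 20), 50, 20)
  one <- logical(50); one[7] <- TRUE
  expect_equal(seed_timeseries(ts, one), ts[7, ])
  # cancellation
  two <- logical(50); two[c(1, 2)] <- TRUE
  ts2 <- ts; ts2[2, ] <- -ts2[1, ]
  expect_equal(seed_timeseries(ts2, two), rep(0, 20))
  # brute-force loop oracle on a random 10-voxel mask
  m <- logical(50); m[sample(50, 10)] <- TRUE
  manual <- rep(0, 20)
  for (t in 1:20) manual[t] <- mean(ts[which(m), t])
  expect_equal(seed_timeseries(ts, m), manual, tolerance = 1e-12)
  expect_error(seed_timeseries(ts, logical(50)), "empty")
  # 4D array path
  arr <- array(rnorm(4 * 4 * 4 * 9), c(4, 4, 4, 9))
  msk <- array(FALSE, c(4, 4, 4)); msk[2, 3, 1] <- TRUE
  expect_equal(seed_timeseries(arr, msk), arr[2, 3, 1, ])
})

test_that("seed connectivity clamps, transforms and guards degenerate input", {
  set.seed(3)
  seed <- rnorm(80)
  cortex <- rbind(seed,                       # r = 1 -> clamped
                  rnorm(80),                  # noise
                  rep(1, 80))                 # zero variance
  expect_warning(pr <- seed_connectivity(seed, cortex), "zero-variance")
  expect_equal(pr$z_values[1], atanh(1 - 1e-7))
  expect_equal(pr$z_values[3], 0)
  expect_true(all(is.finite(pr$z_values)))
  # orthogonal series: z = 0
  s2 <- c(1, -1, 1, -1)
  c2 <- matrix(c(1, 1, -1, -1), 1)
  expect_equal(seed_connectivity(s2, c2)$z_values, 0)
  expect_error(seed_connectivity(1:2, matrix(1:2, 1)), "3 timepoints")
})

test_that("Fisher z agrees with arctanh on a grid and at r = 0.5", {
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(r), atanh(r), tolerance = 1e-12)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
})

test_that("identical high/low profiles give zero t and no detections", {
  set.seed(4)
  z <- matrix(rnorm(10 * 40), 10, 40)
  res <- contrast_subregions(list(high = z, low = z), n_permutations = 99,
                             seed = 5)
  expect_true(all(res$t_values == 0))
  expect_false(any(res$significant_mask))
})

test_that("permutation p-values follow the plus-one arithmetic", {
  set.seed(6)
  high <- matrix(rnorm(8 * 30), 8, 30)
  low <- matrix(rnorm(8 * 30), 8, 30)
  res <- contrast_subregions(list(high = high, low = low),
                             n_permutations = 999, seed = 7)
  grid <- seq_len(1000) / 1000
  expect_true(all(abs(outer(res$p_fwe, grid, "-")) |>
                    apply(1, min) < 1e-12))
  expect_true(all(res$p_fwe > 0 & res$p_fwe <= 1))
})

test_that("a planted subregion-by-network effect is detected", {
  mask <- make_ellipsoid_mask(c(16, 16, 16), c(6, 6, 5))
  vol <- masked_volume(array(0, dim(mask)), mask, 100)
  tab <- voxel_table(vol)
  comp <- axis_coordinate(tab, "inferior-superior")
  profs <- list()
  for (s in 1:6) {
    sim <- make_coupled_timeseries(comp, coupling_spec(effect = 0.5,
                                                       seed = 40 + s))
    sp <- quantile_subregions(comp, 0.25, subject_id = s)
    hi <- seed_timeseries(sim$voxel_ts, sp$high_mask)
    lo <- seed_timeseries(sim$voxel_ts, sp$low_mask)
    profs <- c(profs,
               list(seed_connectivity(hi, sim$cortex_ts, "high", s),
                    seed_connectivity(lo, sim$cortex_ts, "low", s)))
  }
  res <- contrast_subregions(profs, n_permutations = 499, seed = 8)
  sim <- make_coupled_timeseries(comp, coupling_spec())
  net1 <- sim$networks == 1
  sens <- mean(res$significant_mask[net1])
  fp <- mean(res$significant_mask[!net1])
  expect_gt(sens, 0.5)
  expect_lt(fp, 0.05)
  # missing seed errors
  expect_error(contrast_subregions(profs[-1], n_permutations = 99, seed = 1),
               "exactly one")
})

test_that("covariate residualization preserves the paired contrast", {
  set.seed(9)
  S <- 12; V <- 25
  effect <- c(rep(0.8, 5), rep(0, V - 5))
  high <- matrix(rnorm(S * V), S, V) + rep(effect, each = S)
  low <- matrix(rnorm(S * V), S, V)
  cov <- data.frame(age = rnorm(S), sex = rbinom(S, 1, 0.5))
  res <- contrast_subregions(list(high = high, low = low), covariates = cov,
                             n_permutations = 499, seed = 10)
  expect_equal(res$df, S - 3L)
  expect_gt(mean(res$t_values[1:5]), mean(res$t_values[-(1:5)]))
})

test_that("network stratification recovers block structure exactly", {
  networks <- rep(1:7, each = 10)
  z <- rep(c(0.1, 0.5, -0.2, 0.9, 0, 0.3, -0.7), each = 10)
  out <- network_stratify(z, networks)
  expect_equal(out$mean_z, c(0.1, 0.5, -0.2, 0.9, 0, 0.3, -0.7))
  expect_equal(out$n, rep(10L, 7))
  # constant profile: every network mean equals it
  out1 <- network_stratify(rep(1, 70), networks)
  expect_true(all(out1$mean_z == 1))
  # single network: mean equals the global mean
  out2 <- network_stratify(z, rep(1, 70))
  expect_equal(out2$mean_z, mean(z))
})

test_that("term decoding ranks by correlation, invariant to affine rescaling", {
  set.seed(11)
  V <- 60
  input <- rnorm(V)
  terms <- rbind(fear = input,                     # identical: r = 1
                 noise1 = rnorm(V),
                 noise2 = rnorm(V))
  out <- decode_terms(input, terms)
  expect_equal(out$term[1], "fear")
  expect_equal(out$r[1], 1)
  out2 <- decode_terms(input * 3.7 - 12, terms)
  expect_equal(out2$term, out$term)
  expect_equal(out2$r, out$r, tolerance = 1e-12)
})
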