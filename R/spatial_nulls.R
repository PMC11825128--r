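#' Empirical variogram of a per-voxel scalar map
#'
#' Semivariance `gamma(h) = mean over voxel pairs at distance ~h of
#' 0.5 * (v_i - v_j)^2`, in equal-width distance bins up to a fraction of the
#' maximum pairwise distance (the masked bounding-box diagonal is used as the
#' deterministic upper bound of the pair distance). Above the pair budget,
#' pairs are subsampled uniformly at random (seeded).
#'
#' @param values numeric, one value per masked voxel.
#' @param table the matching [voxel_table()].
#' @param n_bins number of distance bins.
#' @param max_distance_fraction fraction of the maximum pair distance up to
#'   which semivariance is evaluated; pairs beyond it are dropped.
#' @param pair_budget maximum number of sampled pairs.
#' @param seed seed for pair subsampling.
#' @return An object of class `variogram`: list with `bin_centers` (um),
#'   `gamma`, `counts`.
#' @export
empirical_variogram <- function(values, table, n_bins = 25,
                                max_distance_fraction = 0.5,
                                pair_budget = 1e5, seed = 1L) {
  n <- nrow(table)
  if (n < 2) stop("need at least 2 voxels for a variogram", call. = FALSE)
  stopifnot(length(values) == n)
  xyz <- as.matrix(table[, c("x_um", "y_um", "z_um")])
  set.seed(as.integer(seed))
  pr <- .sample_pairs(n, pair_budget)
  d <- sqrt(rowSums((xyz[pr$i, , drop = FALSE] -
                     xyz[pr$j, , drop = FALSE])^2))
  dmax <- sqrt(sum((apply(xyz, 2, max) - apply(xyz, 2, min))^2))
  cutoff <- max_distance_fraction * dmax
  keep <- d <= cutoff & d > 0
  if (!any(keep)) {  # degenerate geometry: single bin over all pairs
    keep <- rep(TRUE, length(d))
    cutoff <- max(d) + .Machine$double.eps
  }
  breaks <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d[keep], breaks, rightmost.closed = TRUE),
                   1L), n_bins)
  sq <- 0.5 * (values[pr$i[keep]] - values[pr$j[keep]])^2
  counts <- tabulate(bin, nbins = n_bins)
  sums <- rep(0, n_bins)
  agg <- tapply(sq, bin, sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  gamma <- ifelse(counts > 0, sums / pmax(counts, 1L), NaN)
  structure(list(bin_centers = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                 gamma = gamma, counts = counts),
            class = "variogram")
}

# uniform random sample of unordered voxel pairs (all pairs when they fit
# the budget)
.sample_pairs <- function(n, budget) {
  total <- n * (n - 1) / 2
  if (total <= budget) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(list(i = idx[, 1], j = idx[, 2]))
  }
  i <- sample.int(n, budget, replace = TRUE)
  j <- sample.int(n - 1L, budget, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)
  list(i = i, j = j)
}

#' Precompute the smoothing kernels for variogram-matched surrogates
#'
#' Builds, once per voxel table, everything [variogram_surrogates()] needs
#' that does not depend on the map being randomized: the pairwise distance
#' matrix, and per candidate smoothing scale the k-nearest-neighbor
#' truncation radii and (optionally cached) dense row-normalized
#' distance-decay kernel matrices. Reuse one model across many maps on the
#' same table -- e.g. both embedding components, or many simulated fields --
#' to amortize the n^2 work.
#'
#' @param table a [voxel_table()].
#' @param fractions candidate smoothing scales, as fractions of the voxel
#'   count defining k-nearest-neighbor kernels.
#' @param kernel distance-decay shape over the kernel radius: `"gaussian"`
#'   (default) or `"exp"`. The Gaussian kernel's lighter tail keeps the
#'   surrogates' long-range correlation closer to that of smooth fields,
#'   which improves the calibration of the null (the exponential kernel
#'   yields a more conservative test).
#' @param cache_kernels "auto" caches dense kernels when they fit in about
#'   2 GB; TRUE/FALSE force the choice. Uncached kernels are rebuilt on the
#'   fly at each [variogram_surrogates()] call.
#' @return An object of class `surrogate_model`.
#' @export
surrogate_model <- function(table, fractions = c(0.005, 0.01, 0.02, 0.05, seq(0.1, 0.9, by = 0.1)),
                            kernel = c("gaussian", "exp"),
                            cache_kernels = "auto") {
  kernel <- match.arg(kernel)
  n <- nrow(table)
  if (n < 10) stop("need at least 10 voxels", call. = FALSE)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  xyz <- as.matrix(table[, c("x_um", "y_um", "z_um")])
  D <- as.matrix(stats::dist(xyz))
  ks <- pmax(3L, pmin(n, as.integer(round(fractions * n))))
  thr <- cpp_knn_threshold(D, ks)
  cache <- if (identical(cache_kernels, "auto")) {
    length(fractions) * n^2 * 8 < 2e9
  } else isTRUE(cache_kernels)
  kernels <- if (cache) {
    lapply(seq_along(ks), function(q) .build_kernel(D, thr[, q], kernel))
  } else NULL
  structure(list(n = n, D = D, fractions = fractions, ks = ks,
                 thresholds = thr, kernel = kernel, kernels = kernels),
            class = "surrogate_model")
}

# dense kNN smoothing kernel, truncated row-wise at the k-th neighbor (self
# included at d = 0) and row-normalized; exponential or Gaussian distance
# decay over the kernel radius
.build_kernel <- function(D, dk, kernel = "gaussian") {
  if (!kernel %in% c("gaussian", "exp")) {
    stop("unknown kernel '", kernel, "'", call. = FALSE)
  }
  cpp_build_kernel(D, pmax(dk, .Machine$double.eps),
                   identical(kernel, "gaussian"))
}

#' Variogram-matched surrogate maps
#'
#' Generates spatial-autocorrelation-preserving null maps for one scalar map:
#' each surrogate is a random permutation of the values, smoothed with the
#' k-nearest-neighbor distance-decay kernel whose variogram -- after a free
#' linear (scale + offset) adjustment -- best matches the empirical variogram
#' of the original map; the fitted scale is applied and the offset realized
#' by adding rescaled white noise. The surrogates keep the map's spatial
#' smoothness structure while destroying any alignment with external
#' variables, making them a valid null for spatial correlation tests.
#'
#' @param values numeric map, one value per masked voxel.
#' @param table the matching [voxel_table()].
#' @param n_surrogates number of null maps.
#' @param seed integer seed; the ensemble is fully reproducible.
#' @param precomputed optional [surrogate_model()] for this table; built on
#'   the fly when NULL.
#' @param fractions candidate smoothing scales (ignored when `precomputed`
#'   is given).
#' @param n_bins,max_distance_fraction variogram binning (see
#'   [empirical_variogram()]).
#' @param pair_budget pairs sampled for the variogram-matching fit. The fit
#'   only needs a coarse variogram, so this default is deliberately smaller
#'   than the [empirical_variogram()] reporting default.
#' @param resample if TRUE (default), each finished surrogate is rank-mapped
#'   onto the original value set, so every null map is a monotone transform
#'   of its permutation-smoothing and the marginal distribution is preserved
#'   exactly; FALSE keeps the raw rescaled maps.
#' @return An object of class `surrogate_ensemble`: list with `maps`
#'   (n_surrogates x voxels matrix), `seed`, `smoothing_scale` (chosen
#'   fraction per surrogate) and `fit_sse` (variogram fit error per
#'   surrogate).
#' @references Viladomat et al. (2014) Assessing the significance of global
#'   and local correlations under spatial autocorrelation: a nonparametric
#'   approach. Biometrics 70(2), 409-418.
#' @export
variogram_surrogates <- function(values, table, n_surrogates = 1000,
                                 seed = 1L, precomputed = NULL,
                                 fractions = c(0.005, 0.01, 0.02, 0.05, seq(0.1, 0.9, by = 0.1)),
                                 n_bins = 25, max_distance_fraction = 0.5,
                                 pair_budget = 1e4, resample = TRUE) {
  n <- nrow(table)
  stopifnot(length(values) == n)
  if (n_surrogates < 1) stop("n_surrogates must be >= 1", call. = FALSE)
  if (n < 10) stop("need at least 10 voxels", call. = FALSE)
  model <- precomputed %||% surrogate_model(table, fractions)
  stopifnot(model$n == n)
  set.seed(as.integer(seed))
  S <- as.integer(n_surrogates)

  # fixed pair sample and bins shared by the empirical and surrogate
  # variograms, so fit errors are comparable
  pr <- .sample_pairs(n, pair_budget)
  d <- model$D[cbind(pr$i, pr$j)]
  cutoff <- max_distance_fraction * max(model$D)
  keep <- d <= cutoff & d > 0
  pi <- pr$i[keep]; pj <- pr$j[keep]
  breaks <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d[keep], breaks, rightmost.closed = TRUE),
                   1L), n_bins)
  g0 <- cpp_batch_variogram(matrix(values, ncol = 1), pi, pj, bin, n_bins)
  ok_bin <- is.finite(g0[, 1])
  g0v <- g0[ok_bin, 1]

  X <- vapply(seq_len(S), function(s) values[sample.int(n)], numeric(n))
  best_sse <- rep(Inf, S)
  best_scale <- numeric(S)
  best_alpha <- numeric(S)
  best_beta <- numeric(S)
  bestY <- matrix(0, n, S)
  for (q in seq_along(model$fractions)) {
    W <- if (!is.null(model$kernels)) model$kernels[[q]]
         else .build_kernel(model$D, model$thresholds[, q],
                            model$kernel %||% "gaussian")
    Y <- W %*% X
    G <- cpp_batch_variogram(Y, pi, pj, bin, n_bins)[ok_bin, , drop = FALSE]
    # per-column OLS of the empirical variogram on the surrogate variogram
    gm <- colMeans(G)
    g0m <- mean(g0v)
    sxy <- colSums(G * g0v) - length(g0v) * gm * g0m
    sxx <- colSums(G^2) - length(g0v) * gm^2
    alpha <- ifelse(sxx > 0, sxy / sxx, 0)
    beta <- g0m - alpha * gm
    resid <- g0v - sweep(sweep(G, 2, alpha, "*"), 2, beta, "+")
    sse <- colSums(resid^2)
    better <- sse < best_sse
    if (any(better)) {
      best_sse[better] <- sse[better]
      best_scale[better] <- model$fractions[q]
      best_alpha[better] <- alpha[better]
      best_beta[better] <- beta[better]
      bestY[, better] <- Y[, better]
    }
  }
  noise <- matrix(rnorm(n * S), n, S)
  maps <- sweep(bestY, 2, sqrt(abs(best_alpha)), "*") +
    sweep(noise, 2, sqrt(abs(best_beta)), "*")
  if (resample) {
    sorted <- sort(values)
    maps <- apply(maps, 2, function(col) sorted[rank(col, ties.method = "first")])
  }
  structure(list(maps = t(maps), seed = as.integer(seed),
                 smoothing_scale = best_scale, fit_sse = best_sse),
            class = "surrogate_ensemble")
}

#' Plain permutation surrogates
#'
#' Null maps that shuffle values over voxels with no regard for spatial
#' autocorrelation. Provided as the naive comparator to
#' [variogram_surrogates()]: on smooth fields it understates the null
#' variance of spatial correlations and inflates false positives.
#'
#' @inheritParams variogram_surrogates
#' @return a `surrogate_ensemble` (with `smoothing_scale` and `fit_sse` NA).
#' @export
permutation_surrogates <- function(values, n_surrogates = 1000, seed = 1L) {
  if (n_surrogates < 1) stop("n_surrogates must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(values)
  maps <- t(vapply(seq_len(n_surrogates), function(s) values[sample.int(n)],
                   numeric(n)))
  structure(list(maps = maps, seed = as.integer(seed),
                 smoothing_scale = rep(NA_real_, n_surrogates),
                 fit_sse = rep(NA_real_, n_surrogates)),
            class = "surrogate_ensemble")
}

#' @exportS3Method base::print
print.surrogate_ensemble <- function(x, ...) {
  cat("<surrogate_ensemble> ", nrow(x$maps), " surrogates x ",
      ncol(x$maps), " voxels (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Axis correlation test with a spatial null
#'
#' Pearson correlation between a per-voxel map (typically an embedding
#' component) and one anatomical axis coordinate, with significance assessed
#' against the surrogate ensemble: the same correlation is computed for every
#' null map and the empirical two-sided p-value is
#' `(1 + #{|r_null| >= |r_obs|}) / (n_surrogates + 1)`, never exactly 0.
#'
#' @param component numeric map, one value per masked voxel.
#' @param table the matching [voxel_table()].
#' @param axis axis name to correlate against.
#' @param ensemble a [variogram_surrogates()] (or
#'   [permutation_surrogates()]) ensemble built from `component`.
#' @param alpha significance threshold.
#' @return An object of class `spatial_test`: list with `axis`, `r_observed`,
#'   `r_null`, `p_null`, `alpha`, `significant`, `n_surrogates`.
#' @export
axis_correlation_test <- function(component, table, axis, ensemble,
                                  alpha = 0.05) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"),
            length(component) == ncol(ensemble$maps))
  coord <- axis_coordinate(table, axis)
  r_obs <- cor(component, coord)
  r_null <- as.numeric(cor(t(ensemble$maps), coord))
  p <- (1 + sum(abs(r_null) >= abs(r_obs), na.rm = TRUE)) /
    (length(r_null) + 1)
  structure(list(axis = axis, r_observed = r_obs, r_null = r_null,
                 p_null = p, alpha = alpha, significant = p < alpha,
                 n_surrogates = length(r_null)),
            class = "spatial_test")
}

#' @exportS3Method base::print
print.spatial_test <- function(x, ...) {
  cat(sprintf("<spatial_test> axis %s: r = %.4f, p_null = %.4g (%s, %d surrogates)\n",
              x$axis, x$r_observed, x$p_null,
              if (x$significant) "significant" else "n.s.", x$n_surrogates))
  invisible(x)
}

#' Serialize a spatial test result to JSON
#' @param x a [axis_correlation_test()] result.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
spatial_test_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "spatial_test"))
  obj <- list(axis = x$axis, r_observed = x$r_observed, p_null = x$p_null,
              n_surrogates = x$n_surrogates, alpha = x$alpha,
              significant = x$significant)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
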