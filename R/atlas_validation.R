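#' Load a probabilistic subregion atlas
#'
#' Reads one probability volume per subregion (already aligned to the
#' structure's grid; no registration is performed here) and gathers the
#' masked-voxel probabilities into an atlas object.
#'
#' @param paths NIfTI paths, one per subregion.
#' @param region_names labels, same length as `paths`.
#' @param volume the [masked_volume()] defining the grid and voxel order.
#' @return An object of class `prob_atlas`: list with `region_names` and
#'   `prob` (voxels x regions matrix of probabilities in `[0, 1]`).
#' @export
load_atlas <- function(paths, region_names, volume) {
  stopifnot(length(paths) == length(region_names), length(paths) >= 1)
  prob <- vapply(paths, function(p) read_scalar_map(p, volume),
                 numeric(sum(volume$mask)))
  prob <- as.matrix(prob)
  colnames(prob) <- region_names
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    stop("atlas probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(region_names = region_names, prob = prob),
            class = "prob_atlas")
}

#' Retain the top fraction of voxels by probability
#'
#' Keeps exactly `ceiling(fraction * n)` voxels with the highest
#' probabilities (a count-based reading of "highest 5% probability values",
#' giving conservative subregion cores). Ties at the cut are broken by voxel
#' index ascending, so the result is deterministic.
#'
#' @param prob_map numeric probabilities, one per masked voxel.
#' @param fraction proportion in (0, 1).
#' @return logical vector marking retained voxels.
#' @export
threshold_top_fraction <- function(prob_map, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- length(prob_map)
  m <- ceiling(fraction * n)
  ord <- order(-prob_map, seq_len(n))
  keep <- logical(n)
  keep[ord[seq_len(m)]] <- TRUE
  keep
}

#' Maximum probability parcellation
#'
#' Labels every voxel retained by at least one region's thresholded core with
#' the retaining region of highest probability there; ties go to the lowest
#' region index (logged via message). Voxels retained by no region stay
#' unassigned (NA).
#'
#' @param atlas a `prob_atlas`.
#' @param thresholded_masks list (or matrix) of per-region logical masks,
#'   e.g. from [threshold_top_fraction()] applied to each column of
#'   `atlas$prob`.
#' @return An integer vector of region ids (NA = unassigned) with the region
#'   names as attribute `region_names`; class `label_map`.
#' @export
maximum_probability_map <- function(atlas, thresholded_masks) {
  stopifnot(inherits(atlas, "prob_atlas"))
  M <- if (is.list(thresholded_masks)) do.call(cbind, thresholded_masks)
       else as.matrix(thresholded_masks)
  R <- length(atlas$region_names)
  if (R < 2) stop("need at least 2 regions", call. = FALSE)
  stopifnot(ncol(M) == R, nrow(M) == nrow(atlas$prob))
  p <- atlas$prob
  p[!M] <- -Inf  # only retaining regions may claim a voxel
  lab <- max.col(p, ties.method = "first")
  lab[rowSums(M) == 0] <- NA_integer_
  nties <- sum(apply(p, 1, function(x) {
    fx <- is.finite(x); sum(fx) > 1 && sum(x[fx] == max(x[fx])) > 1
  }))
  if (nties > 0) message(nties, " voxel(s) had tied probabilities; ",
                         "assigned to the lowest region index")
  structure(as.integer(lab), region_names = atlas$region_names,
            class = "label_map")
}

#' Group a component by parcellation label
#'
#' @param component numeric, one value per masked voxel.
#' @param labels a [maximum_probability_map()] result.
#' @return list with `values` (named list of per-region value vectors) and
#'   `summary` (data.frame region, n, mean, sd).
#' @export
component_by_region <- function(component, labels) {
  stopifnot(inherits(labels, "label_map"),
            length(component) == length(labels))
  names <- attr(labels, "region_names")
  assigned <- !is.na(labels)
  if (!any(assigned)) stop("no assigned voxels", call. = FALSE)
  groups <- split(component[assigned],
                  factor(names[labels[assigned]], levels = names))
  groups <- groups[vapply(groups, length, 1L) > 0]
  summ <- data.frame(
    region = names(groups),
    n = vapply(groups, length, 1L),
    mean = vapply(groups, mean, 1),
    sd = vapply(groups, sd, 1),
    row.names = NULL
  )
  list(values = groups, summary = summ)
}

# one-way ANOVA F over a label vector; vectorized over the rows of a
# value matrix (each row one map)
.oneway_F <- function(V, g) {
  g <- as.integer(g)
  ng <- tabulate(g)
  used <- ng > 0
  k <- sum(used)
  n <- length(g)
  ind <- outer(g, which(used), "==") * 1
  gm <- (V %*% ind) / rep(ng[used], each = nrow(V))
  grand <- rowMeans(V)
  ssb <- rowSums(sweep(gm, 1, grand, "-")^2 * rep(ng[used], each = nrow(V)))
  sst <- rowSums(sweep(V, 1, grand, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  df_b <- k - 1
  df_w <- n - k
  list(F = (ssb / df_b) / (ssw / df_w), df_between = df_b, df_within = df_w)
}

#' One-way ANOVA of a component across subregions, with a spatial null
#'
#' The observed F statistic compares component values across parcellation
#' labels. Because neighboring voxels are strongly autocorrelated, the
#' nominal F distribution is far too liberal; significance is instead
#' assessed by recomputing F on each surrogate map (labels held fixed):
#' `p_null = (1 + #{F_surrogate >= F_observed}) / (n_surrogates + 1)`.
#'
#' @param component numeric, one value per masked voxel.
#' @param labels a [maximum_probability_map()] result.
#' @param ensemble a [variogram_surrogates()] ensemble built from
#'   `component` (pass a [permutation_surrogates()] ensemble for a plain
#'   permutation null).
#' @return An object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p_null`, `F_null`.
#' @export
anova_with_surrogate_null <- function(component, labels, ensemble) {
  stopifnot(inherits(labels, "label_map"),
            inherits(ensemble, "surrogate_ensemble"),
            length(component) == length(labels),
            ncol(ensemble$maps) == length(labels))
  assigned <- which(!is.na(labels))
  g <- as.integer(factor(labels[assigned]))
  sizes <- tabulate(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 voxels each", call. = FALSE)
  }
  obs <- .oneway_F(matrix(component[assigned], nrow = 1), g)
  Fn <- .oneway_F(ensemble$maps[, assigned, drop = FALSE], g)$F
  p <- (1 + sum(Fn >= obs$F)) / (length(Fn) + 1)
  structure(list(F = obs$F, df_between = obs$df_between,
                 df_within = obs$df_within, p_null = p, F_null = Fn),
            class = "anova_result")
}

#' @exportS3Method base::print
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.1f, p_null = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_null))
  invisible(x)
}
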