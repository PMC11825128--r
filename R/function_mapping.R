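#' Quantile-based subregion pair
#'
#' Splits the structure into its two anchors of maximal microstructural
#' dissociation: the voxels in the top and bottom quantile of an embedding
#' component. Each mask contains exactly `ceiling(fraction * n)` voxels, with
#' ties broken deterministically by voxel index; the two masks must be
#' disjoint, so fractions whose rounded counts would overlap are an error.
#'
#' @param component numeric, one value per masked voxel.
#' @param fraction quantile fraction in (0, 0.5].
#' @param subject_id optional label carried through to connectivity profiles.
#' @return An object of class `subregion_pair`: list with `high_mask`,
#'   `low_mask` (logical), `fraction`, `subject_id`.
#' @export
quantile_subregions <- function(component, fraction = 0.25,
                                subject_id = NULL) {
  if (fraction <= 0 || fraction > 0.5) {
    stop("fraction must lie in (0, 0.5]", call. = FALSE)
  }
  n <- length(component)
  m <- ceiling(fraction * n)
  if (2 * m > n) {
    stop(sprintf("top and bottom masks of %d voxels each would overlap on %d voxels",
                 m, n), call. = FALSE)
  }
  idx <- seq_len(n)
  high <- logical(n); high[order(-component, idx)[seq_len(m)]] <- TRUE
  low <- logical(n); low[order(component, idx)[seq_len(m)]] <- TRUE
  structure(list(high_mask = high, low_mask = low, fraction = fraction,
                 subject_id = subject_id),
            class = "subregion_pair")
}

#' Mean time series within a seed mask
#'
#' @param ts either a voxels x time matrix (rows in [voxel_table()] order) or
#'   a 4D array whose first three dimensions match the mask grid.
#' @param mask logical vector over masked voxels (matrix input) or logical 3D
#'   array (4D input).
#' @return numeric vector, one value per timepoint.
#' @export
seed_timeseries <- function(ts, mask) {
  if (is.array(ts) && length(dim(ts)) == 4L) {
    stopifnot(is.array(mask), identical(dim(ts)[1:3], dim(mask)))
    if (!any(mask)) stop("empty seed mask", call. = FALSE)
    m <- matrix(ts, ncol = dim(ts)[4])
    return(colMeans(m[as.logical(mask), , drop = FALSE]))
  }
  ts <- as.matrix(ts)
  mask <- as.logical(mask)
  stopifnot(length(mask) == nrow(ts))
  if (!any(mask)) stop("empty seed mask", call. = FALSE)
  colMeans(ts[mask, , drop = FALSE])
}

#' Seed-to-cortex connectivity profile
#'
#' Pearson correlation between the seed time series and every cortical
#' vertex's series, clamped to +/-(1 - 1e-7) and Fisher R-to-Z transformed
#' (`atanh`), so all values are finite. Zero-variance vertices (or a
#' zero-variance seed) yield z = 0 with a warning.
#'
#' @param seed numeric time series.
#' @param cortex vertices x time matrix.
#' @param seed_label one of "high", "low", "whole" (free-form allowed).
#' @param subject_id optional label.
#' @return An object of class `connectivity_profile`: list with `z_values`
#'   (per vertex), `seed_label`, `subject_id`.
#' @export
seed_connectivity <- function(seed, cortex, seed_label = "whole",
                              subject_id = NULL) {
  cortex <- as.matrix(cortex)
  Tt <- length(seed)
  stopifnot(ncol(cortex) == Tt)
  if (Tt < 3) stop("need at least 3 timepoints", call. = FALSE)
  sv <- sd(seed)
  vv <- apply(cortex, 1, sd)
  bad <- vv == 0 | !is.finite(vv)
  if (sv == 0) {
    warning("zero-variance seed series; all z set to 0", call. = FALSE)
    r <- rep(0, nrow(cortex))
  } else {
    r <- suppressWarnings(as.numeric(cor(t(cortex), seed)))
    if (any(bad)) {
      warning(sum(bad), " zero-variance vertex series; z set to 0",
              call. = FALSE)
      r[bad] <- 0
    }
  }
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  structure(list(z_values = atanh(r), seed_label = seed_label,
                 subject_id = subject_id),
            class = "connectivity_profile")
}

#' Fisher R-to-Z transform
#' @param r correlations; clamped to +/-(1 - 1e-7) before `atanh`.
#' @return z values.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))

# assemble list of connectivity_profile objects into high/low matrices
.pair_profiles <- function(profiles) {
  labs <- vapply(profiles, function(p) p$seed_label, "")
  subj <- vapply(profiles, function(p) as.character(p$subject_id %||% NA), "")
  subjects <- unique(subj)
  get <- function(id, lab) {
    hit <- which(subj == id & labs == lab)
    if (length(hit) != 1) {
      stop("subject '", id, "' must have exactly one '", lab, "' profile",
           call. = FALSE)
    }
    profiles[[hit]]$z_values
  }
  high <- t(vapply(subjects, get, numeric(length(profiles[[1]]$z_values)),
                   lab = "high"))
  low <- t(vapply(subjects, get, numeric(length(profiles[[1]]$z_values)),
                  lab = "low"))
  list(high = high, low = low, subjects = subjects)
}

#' Contrast high- vs low-component subregion connectivity across subjects
#'
#' Paired high-minus-low contrast of Fisher-z connectivity profiles, with
#' optional nuisance covariates (e.g. age, sex) residualized out of the
#' paired differences, and family-wise error control by max-statistic
#' sign-flip permutation: each permutation flips the sign of whole subjects'
#' difference maps, the maximum |t| over vertices is recorded, and each
#' vertex's `p_fwe` is the proportion of permutation maxima reaching its
#' observed |t| (plus-one rule). This controls the probability of any false
#' positive across vertices without distributional assumptions.
#'
#' @param profiles list of [seed_connectivity()] profiles: one "high" and
#'   one "low" per subject. Alternatively a list with `high` and `low`
#'   subjects x vertices matrices.
#' @param covariates optional subjects x p data.frame/matrix of nuisance
#'   covariates (centered internally; an intercept is always included).
#' @param n_permutations number of sign-flip permutations.
#' @param seed integer seed.
#' @param fwe_alpha significance threshold on `p_fwe`.
#' @return An object of class `contrast_result`: list with `t_values`,
#'   `p_fwe`, `significant_mask`, `df`, `n_permutations`, `subjects`.
#' @export
contrast_subregions <- function(profiles, covariates = NULL,
                                n_permutations = 999, seed = 1L,
                                fwe_alpha = 0.05) {
  if (!is.null(profiles$high)) {
    high <- as.matrix(profiles$high); low <- as.matrix(profiles$low)
    subjects <- rownames(high) %||% as.character(seq_len(nrow(high)))
  } else {
    pp <- .pair_profiles(profiles)
    high <- pp$high; low <- pp$low; subjects <- pp$subjects
  }
  stopifnot(identical(dim(high), dim(low)))
  S <- nrow(high)
  if (S < 2) stop("need at least 2 subjects", call. = FALSE)
  D <- high - low
  p_cov <- 0L
  if (!is.null(covariates)) {
    X <- scale(as.matrix(covariates), center = TRUE, scale = FALSE)
    p_cov <- ncol(X)
    if (S <= p_cov + 1) stop("too few subjects for the covariates",
                             call. = FALSE)
    D <- stats::lm.fit(x = X, y = D)$residuals
  }
  df <- S - 1L - p_cov
  ss <- colSums(D^2)
  tstat <- function(colsums_flip) {
    m <- colsums_flip / S
    v <- pmax(ss - S * m^2, 0) / (S - 1)
    se <- sqrt(v / S)
    ifelse(se > 0, m / se, 0)
  }
  t_obs <- tstat(colSums(D))
  set.seed(as.integer(seed))
  flips <- matrix(sample(c(-1, 1), n_permutations * S, replace = TRUE),
                  n_permutations, S)
  msums <- flips %*% D  # permutations x vertices
  max_t <- apply(msums, 1, function(cs) max(abs(tstat(cs))))
  p_fwe <- (1 + colSums(outer(max_t, abs(t_obs), ">="))) /
    (n_permutations + 1)
  structure(list(t_values = t_obs, p_fwe = p_fwe,
                 significant_mask = p_fwe < fwe_alpha, df = df,
                 n_permutations = as.integer(n_permutations),
                 subjects = subjects),
            class = "contrast_result")
}

#' Average a connectivity profile within functional networks
#'
#' @param profile a [seed_connectivity()] profile, or a numeric per-vertex
#'   map.
#' @param networks integer/factor label per vertex (e.g. the customary seven
#'   intrinsic communities).
#' @return data.frame with `network`, `mean_z`, `n`.
#' @export
network_stratify <- function(profile, networks) {
  z <- if (inherits(profile, "connectivity_profile")) profile$z_values
       else as.numeric(profile)
  stopifnot(length(z) == length(networks))
  f <- factor(networks)
  data.frame(network = levels(f),
             mean_z = as.numeric(tapply(z, f, mean)),
             n = as.integer(table(f)),
             row.names = NULL)
}

#' Decode a cortical map against term activation maps
#'
#' Pearson correlation between an input per-vertex map (a connectivity
#' profile or statistic map) and each user-supplied meta-analytic term map,
#' ranked by correlation. Rankings are invariant to affine rescaling of the
#' input.
#'
#' @param profile_or_t per-vertex map, or a `connectivity_profile`.
#' @param term_maps terms x vertices matrix with term names as rownames.
#' @return data.frame with `term`, `r`, sorted by `r` descending.
#' @export
decode_terms <- function(profile_or_t, term_maps) {
  z <- if (inherits(profile_or_t, "connectivity_profile"))
         profile_or_t$z_values else as.numeric(profile_or_t)
  term_maps <- as.matrix(term_maps)
  stopifnot(ncol(term_maps) == length(z))
  r <- as.numeric(cor(t(term_maps), z))
  out <- data.frame(term = rownames(term_maps) %||%
                      paste0("term", seq_len(nrow(term_maps))),
                    r = r)
  out[order(-out$r), , drop = FALSE]
}
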