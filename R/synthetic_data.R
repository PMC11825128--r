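#' Ellipsoidal structure mask
#'
#' Builds the compact, roughly amygdala-shaped binary mask used throughout
#' the synthetic fixtures: all voxels whose centre satisfies
#' `sum(((ijk - centre)/semiaxes)^2) <= 1`. Deterministic.
#'
#' @param shape integer(3) grid dimensions. Default 40^3, which with the
#'   default semiaxes gives a mask of roughly 8000 voxels -- large enough for
#'   stable variograms while keeping feature extraction fast.
#' @param semiaxes numeric(3) ellipsoid semiaxes in voxel units.
#' @param center voxel-centre of the ellipsoid (0-based, defaults to the grid
#'   centre).
#' @return logical 3D array.
#' @export
make_ellipsoid_mask <- function(shape = c(40L, 40L, 40L),
                                semiaxes = c(16, 13, 9), center = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(semiaxes) == 3L, all(semiaxes > 0))
  if (is.null(center)) center <- (shape - 1) / 2
  i <- (seq_len(shape[1]) - 1 - center[1]) / semiaxes[1]
  j <- (seq_len(shape[2]) - 1 - center[2]) / semiaxes[2]
  k <- (seq_len(shape[3]) - 1 - center[3]) / semiaxes[3]
  d2 <- outer(outer(i^2, j^2, "+"), k^2, "+")
  mask <- d2 <= 1
  if (!any(mask)) stop("ellipsoid mask is empty", call. = FALSE)
  mask
}

#' Specification of a planted microstructural gradient
#'
#' Describes a synthetic intensity field in which the *local* mean increases
#' linearly along one anatomical axis while the local skewness (and with it
#' kurtosis, since both are driven by one skew-normal shape parameter)
#' increases along a second, distinct axis. This is the ground-truth analogue
#' of a structure whose staining intensity rises along one anatomical
#' direction while a different direction carries increasingly heavy-tailed
#' texture.
#'
#' @param mean_axis axis carrying the linear mean gradient.
#' @param mean_slope intensity units per voxel along `mean_axis`. The default
#'   (0.3 intensity units per voxel against texture SD 2) keeps the mean
#'   gradient strong at map level -- the windowed mean spans many multiples
#'   of its standard error across the mask -- while leaving the local value
#'   distribution texture-dominated, so higher-moment features reflect the
#'   planted asymmetry rather than within-window mean drift.
#' @param skew_axis axis carrying the asymmetry gradient; must differ from
#'   `mean_axis`.
#' @param skew_range length-2 range of the target marginal *skewness* mapped
#'   linearly along `skew_axis`; realized by inverting the skew-normal
#'   skewness formula for the shape parameter. The skew-normal family caps
#'   skewness just below 1, so values must lie in (-0.995, 0.995).
#' @param texture_sd SD of the standardized skew-normal texture component.
#' @param noise_sd SD of additive Gaussian noise on top of the texture.
#' @param base baseline intensity.
#' @param seed integer seed; every generated volume is a pure function of its
#'   spec.
#' @return An object of class `gradient_spec`.
#' @export
gradient_spec <- function(mean_axis = "inferior-superior", mean_slope = 0.3,
                          skew_axis = "medial-lateral",
                          skew_range = c(-0.9, 0.9), texture_sd = 2,
                          noise_sd = 0.5, base = 100, seed = 1L) {
  if (identical(mean_axis, skew_axis)) {
    stop("mean_axis and skew_axis must be distinct", call. = FALSE)
  }
  stopifnot(noise_sd > 0, texture_sd >= 0, length(skew_range) == 2L,
            all(abs(skew_range) < 0.995))
  structure(list(mean_axis = mean_axis, mean_slope = mean_slope,
                 skew_axis = skew_axis, skew_range = skew_range,
                 texture_sd = texture_sd, noise_sd = noise_sd,
                 base = base, seed = as.integer(seed)),
            class = "gradient_spec")
}

# marginal skewness of a skew-normal with delta = alpha / sqrt(1 + alpha^2)
.sn_skewness <- function(delta) {
  b <- delta * sqrt(2 / pi)
  (4 - pi) / 2 * b^3 / (1 - b^2)^1.5
}

# shape parameter alpha whose skew-normal has the requested marginal
# skewness (monotone inversion on a dense delta grid)
.alpha_for_skewness <- function(gamma) {
  grid_d <- seq(0, 0.9985, length.out = 2000)
  grid_g <- .sn_skewness(grid_d)
  d <- sign(gamma) * approx(grid_g, grid_d, xout = pmin(abs(gamma),
                                                        max(grid_g)))$y
  d / sqrt(pmax(1 - d^2, 1e-8))
}

# standardized skew-normal draws: shape alpha varies per draw; mean 0, SD 1
.rskewnorm_std <- function(alpha) {
  n <- length(alpha)
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- abs(rnorm(n)); z1 <- rnorm(n)
  x <- delta * z0 + sqrt(1 - delta^2) * z1
  mu <- delta * sqrt(2 / pi)
  sg <- sqrt(1 - 2 * delta^2 / pi)
  (x - mu) / sg
}

#' Generate a volume with planted mean and skewness gradients
#'
#' @param mask logical 3D array (e.g. from [make_ellipsoid_mask()]); voxels
#'   outside the mask are filled with background noise around the baseline so
#'   mask-locality can be tested.
#' @param spec a [gradient_spec()].
#' @param voxel_size_um physical voxel size (um).
#' @return A [masked_volume()]. The generative per-voxel mean-axis and
#'   skew-axis coordinates are attached as attribute `truth` (a list with
#'   `mean_coord`, `skew_coord`, in [voxel_table()] order).
#' @export
make_gradient_volume <- function(mask, spec = gradient_spec(),
                                 voxel_size_um = 100) {
  stopifnot(inherits(spec, "gradient_spec"), is.array(mask))
  set.seed(spec$seed)
  dm <- dim(mask)
  vol <- masked_volume(array(0, dm), mask, voxel_size_um)
  tab <- voxel_table(vol)
  axes <- attr(tab, "axis_names")
  mean_coord <- tab[[c("i", "j", "k")[.match_axis(spec$mean_axis, axes)]]]
  skew_coord <- tab[[c("i", "j", "k")[.match_axis(spec$skew_axis, axes)]]]
  rng <- range(skew_coord)
  u <- if (diff(rng) > 0) (skew_coord - rng[1]) / diff(rng) else rep(0, nrow(tab))
  target_skew <- spec$skew_range[1] + u * diff(spec$skew_range)
  alpha <- .alpha_for_skewness(target_skew)
  vals <- spec$base + spec$mean_slope * mean_coord +
    spec$texture_sd * .rskewnorm_std(alpha) +
    rnorm(nrow(tab), sd = spec$noise_sd)
  data <- array(rnorm(prod(dm), mean = spec$base, sd = spec$noise_sd), dm)
  data[mask] <- vals
  out <- masked_volume(data, mask, voxel_size_um)
  attr(out, "truth") <- list(mean_coord = mean_coord, skew_coord = skew_coord)
  out
}

#' Smooth Gaussian random field on a mask
#'
#' White noise on the full grid, smoothed with a separable (circular)
#' Gaussian kernel and standardized over the masked voxels. Used as the
#' spatially autocorrelated but axis-independent field in null-calibration
#' experiments.
#'
#' @param mask logical 3D array.
#' @param sigma_voxels Gaussian smoothing SD in voxels.
#' @param seed integer seed.
#' @return numeric vector of field values at the masked voxels, in
#'   [voxel_table()] order, standardized to mean 0 / SD 1.
#' @export
make_smooth_field <- function(mask, sigma_voxels = 2, seed = 1L) {
  set.seed(as.integer(seed))
  dm <- dim(mask)
  half <- max(1L, ceiling(3 * sigma_voxels))
  # pad by the kernel half-width so no correlation wraps across grid edges,
  # then crop back: the masked field is a patch of a stationary random field
  ext <- dm + 2L * half
  arr <- array(rnorm(prod(ext)), ext)
  w <- exp(-0.5 * ((-half):half / sigma_voxels)^2)
  w <- w / sum(w)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    m <- apply_filter_circular(m, w)
    arr <- aperm(array(m, da), order(perm))
  }
  core <- arr[half + seq_len(dm[1]), half + seq_len(dm[2]),
              half + seq_len(dm[3])]
  v <- core[mask]
  as.numeric(scale(v))
}

# circular convolution of each column of m with kernel w (odd length)
apply_filter_circular <- function(m, w) {
  out <- stats::filter(m, w, method = "convolution", sides = 2,
                       circular = TRUE)
  matrix(out, nrow = nrow(m))
}

#' Axis-tiled probabilistic atlas
#'
#' Builds a synthetic probabilistic atlas whose subregions tile one
#' anatomical axis: the axis range over the mask is split into `n_regions`
#' equal-width bands and each region's probability is a smooth plateau over
#' its band, decaying logistically with distance from the band edges.
#' Probabilities are deliberately not normalized across regions, matching
#' real probabilistic atlases (and exercising the maximum-probability
#' overlap logic).
#'
#' @param mask logical 3D array.
#' @param axis axis being tiled.
#' @param n_regions number of subregions (>= 2).
#' @param softness logistic decay width at the band edges, in voxels;
#'   `softness -> 0` gives a hard tiling.
#' @param region_names labels; defaults to the three classical amygdala
#'   subdivision names when `n_regions` is 3.
#' @param voxel_size_um voxel size used to build the coordinate table.
#' @return An object of class `prob_atlas`: list with `region_names` and
#'   `prob`, an n_voxels x n_regions matrix of probabilities in [0, 1]
#'   aligned to the [voxel_table()] of the mask. The generative band id per
#'   voxel is attached as attribute `truth_band`.
#' @export
make_tiled_atlas <- function(mask, axis = "inferior-superior", n_regions = 3,
                             softness = 1.5, region_names = NULL,
                             voxel_size_um = 100) {
  stopifnot(n_regions >= 2)
  if (is.null(region_names)) {
    region_names <- if (n_regions == 3) c("CM", "LB", "SF")
                    else paste0("R", seq_len(n_regions))
  }
  vol <- masked_volume(array(0, dim(mask)), mask, voxel_size_um)
  tab <- voxel_table(vol)
  axes <- attr(tab, "axis_names")
  coord <- tab[[c("i", "j", "k")[.match_axis(axis, axes)]]]
  rng <- range(coord)
  breaks <- seq(rng[1], rng[2], length.out = n_regions + 1)
  softness <- max(softness, 1e-6)
  prob <- vapply(seq_len(n_regions), function(g) {
    lo <- breaks[g]; hi <- breaks[g + 1]
    p <- plogis((coord - lo) / softness) * plogis((hi - coord) / softness)
    if (g == 1) p <- plogis((hi - coord) / softness)
    if (g == n_regions) p <- plogis((coord - lo) / softness)
    p
  }, numeric(nrow(tab)))
  band <- pmin(findInterval(coord, breaks, rightmost.closed = TRUE),
               n_regions)
  structure(list(region_names = region_names, prob = prob),
            class = "prob_atlas", truth_band = band)
}

#' Specification of coupled seed/cortex time series
#'
#' Describes synthetic resting-state-like signals in which cortical vertices
#' load on the latent signal of their functional network, and structure
#' voxels load on the *designated* network's latent with a weight that grows
#' with the voxel's embedding-component value. The contrast between high- and
#' low-component seed connectivity to that network is therefore known by
#' construction, with strength `effect`.
#'
#' @param n_vertices cortical vertex count.
#' @param n_networks number of functional communities (vertices are split
#'   evenly; default 7, the customary intrinsic-network count).
#' @param n_timepoints series length (>= 50).
#' @param effect differential coupling strength in correlation units, in
#'   `[0, 0.9)`; 0 plants no effect.
#' @param base_coupling coupling of every voxel to the designated network
#'   before the component-dependent part.
#' @param bg_coupling loading of every structure voxel on a shared
#'   structure-internal latent that is independent of all cortical networks.
#'   Without it, averaging many voxels into a seed would cancel the
#'   independent voxel noise and both seeds would collapse onto the
#'   designated network's latent, erasing the planted contrast; a shared
#'   background keeps the seed time series mixed, as in real data where
#'   regional fluctuations are common to neighbouring voxels.
#' @param vertex_coupling loading of each cortical vertex on its own
#'   network's latent.
#' @param seed integer seed.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(n_vertices = 500L, n_networks = 7L,
                          n_timepoints = 200L, effect = 0.4,
                          base_coupling = 0.1, bg_coupling = 0.6,
                          vertex_coupling = 0.7, seed = 1L) {
  if (effect < 0 || effect >= 0.9) {
    stop("effect must lie in [0, 0.9)", call. = FALSE)
  }
  stopifnot(n_timepoints >= 50, bg_coupling >= 0, bg_coupling < 1)
  structure(list(n_vertices = as.integer(n_vertices),
                 n_networks = as.integer(n_networks),
                 n_timepoints = as.integer(n_timepoints),
                 effect = effect, base_coupling = base_coupling,
                 bg_coupling = bg_coupling,
                 vertex_coupling = vertex_coupling,
                 seed = as.integer(seed)),
            class = "coupling_spec")
}

#' Generate coupled voxel and cortical time series
#'
#' @param component per-voxel scalar (e.g. an embedding component); its rank
#'   determines each voxel's coupling to the designated network.
#' @param spec a [coupling_spec()].
#' @return list with `voxel_ts` (voxels x time), `cortex_ts` (vertices x
#'   time), `networks` (integer label per vertex), and `designated_network`
#'   (always 1).
#' @export
make_coupled_timeseries <- function(component, spec = coupling_spec()) {
  stopifnot(inherits(spec, "coupling_spec"))
  set.seed(spec$seed)
  nv <- length(component)
  Tt <- spec$n_timepoints
  L <- matrix(rnorm(spec$n_networks * Tt), spec$n_networks, Tt)
  L <- L / sqrt(rowMeans(L^2))  # unit-RMS latents
  networks <- rep(seq_len(spec$n_networks), length.out = spec$n_vertices)
  networks <- sort(networks)
  a <- spec$vertex_coupling
  cortex_ts <- a * L[networks, , drop = FALSE] +
    sqrt(1 - a^2) * matrix(rnorm(spec$n_vertices * Tt), spec$n_vertices, Tt)
  u <- (rank(component, ties.method = "first") - 1) / max(nv - 1, 1)
  w <- spec$base_coupling + spec$effect * u
  b <- spec$bg_coupling
  w <- pmin(w, sqrt(pmax(0.999 - b^2, 0)))
  bg <- matrix(rnorm(Tt), 1, Tt)  # structure-internal latent
  bg <- bg / sqrt(mean(bg^2))
  voxel_ts <- outer(w, rep(1, Tt)) * L[rep(1L, nv), , drop = FALSE] +
    b * bg[rep(1L, nv), , drop = FALSE] +
    sqrt(pmax(1 - w^2 - b^2, 0)) * matrix(rnorm(nv * Tt), nv, Tt)
  list(voxel_ts = voxel_ts, cortex_ts = cortex_ts, networks = networks,
       designated_network = 1L)
}
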