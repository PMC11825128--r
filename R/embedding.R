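#' Embedding configuration
#'
#' Hyperparameters of the nonlinear voxel embedding. The manifold-graph
#' neighborhood size and minimum embedding distance default to the reducer's
#' standard settings (15 and 0.1); the output is two-dimensional. The seed
#' fixes all stochastic steps so a given bank always yields the same
#' coordinates.
#'
#' @param n_neighbors manifold graph neighborhood size.
#' @param min_dist minimum distance between embedded points.
#' @param n_components output dimensionality.
#' @param seed integer random seed.
#' @param budget maximum number of voxels embedded directly; above it a
#'   uniform random subsample is embedded and the remaining voxels are placed
#'   by out-of-sample projection. The default is high enough that typical
#'   structure masks (and all synthetic fixtures) are embedded in full.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(n_neighbors = 15L, min_dist = 0.1,
                             n_components = 2L, seed = 42L,
                             budget = 50000L) {
  structure(list(n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed), budget = as.integer(budget)),
            class = "embedding_config")
}

#' Embed a normalized feature bank into two dimensions
#'
#' Projects the voxels-by-features matrix to `n_components` dimensions with
#' UMAP (called as an external numerical primitive; the reproducibility
#' harness -- fixed seed, single-threaded optimization, stable row order and
#' the [orient_embedding()] sign convention -- is what this package adds on
#' top). Components are named U1 and U2 in the order the reducer emits them.
#'
#' @param bank a normalized [feature_bank][build_feature_bank()].
#' @param config an [embedding_config()].
#' @return An object of class `voxel_embedding`: list with `coords` (voxels x
#'   n_components matrix, columns U1, U2, ...), `config`, and `orientation`
#'   (per-component flip flags, all FALSE until [orient_embedding()]).
#' @export
embed_bank <- function(bank, config = embedding_config()) {
  stopifnot(inherits(bank, "feature_bank"),
            inherits(config, "embedding_config"))
  if (!bank$normalized) {
    stop("bank must be normalized before embedding (see normalize_bank())",
         call. = FALSE)
  }
  n <- nrow(bank$values)
  if (n <= config$n_neighbors) {
    stop("too few voxels (", n, ") for n_neighbors = ", config$n_neighbors,
         call. = FALSE)
  }
  set.seed(config$seed)
  if (n > config$budget) {
    sub <- sort(sample.int(n, config$budget))
    fit <- uwot::umap(bank$values[sub, , drop = FALSE],
                      n_neighbors = config$n_neighbors,
                      min_dist = config$min_dist,
                      n_components = config$n_components,
                      n_threads = 1, n_sgd_threads = 1, ret_model = TRUE,
                      verbose = FALSE)
    coords <- matrix(NA_real_, n, config$n_components)
    coords[sub, ] <- fit$embedding
    coords[-sub, ] <- uwot::umap_transform(
      bank$values[-sub, , drop = FALSE], fit, n_threads = 1,
      n_sgd_threads = 1, verbose = FALSE)
  } else {
    coords <- uwot::umap(bank$values, n_neighbors = config$n_neighbors,
                         min_dist = config$min_dist,
                         n_components = config$n_components,
                         n_threads = 1, n_sgd_threads = 1, verbose = FALSE)
  }
  if (anyNA(coords)) stop("embedding produced NAs", call. = FALSE)
  colnames(coords) <- paste0("U", seq_len(ncol(coords)))
  orientation <- stats::setNames(rep(FALSE, ncol(coords)), colnames(coords))
  structure(list(coords = coords, config = config, orientation = orientation),
            class = "voxel_embedding")
}

#' @exportS3Method base::print
print.voxel_embedding <- function(x, ...) {
  cat("<voxel_embedding> ", nrow(x$coords), " voxels x ", ncol(x$coords),
      " components (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Fix the rotation and sign of the embedding
#'
#' Embedding coordinates are only defined up to rotation and sign: the
#' reducer's optimizer can emit the same layout rotated arbitrarily in the
#' (U1, U2) plane, so per-component statistics are not comparable across
#' runs without a convention. This applies the package's orientation
#' convention in two steps. With `rotate = TRUE` (recommended for the full
#' pipeline) the centred coordinate cloud is first rotated to its own
#' principal axes -- an intrinsic, deterministic choice that uses nothing
#' but the embedding itself and leaves all pairwise structure untouched.
#' Then each component is flipped, independently, so its Pearson correlation
#' with the chosen reference axis coordinate is non-negative. Flips are
#' recorded in the `orientation` flags, the rotation (if any) in `rotation`.
#' Applying the convention twice is a no-op.
#'
#' @param embedding a [voxel_embedding][embed_bank()].
#' @param table the matching [voxel_table()].
#' @param reference_axis one of the table's axis names.
#' @param rotate if TRUE, align components with the principal axes of the
#'   embedding cloud before sign-fixing; FALSE (default) keeps the reducer's
#'   raw axes and only fixes signs.
#' @return The embedding with oriented `coords`.
#' @export
orient_embedding <- function(embedding, table,
                             reference_axis = "inferior-superior",
                             rotate = FALSE) {
  stopifnot(inherits(embedding, "voxel_embedding"))
  coord <- axis_coordinate(table, reference_axis)
  if (rotate) {
    ctr <- scale(embedding$coords, center = TRUE, scale = FALSE)
    sv <- svd(ctr, nu = 0)
    embedding$coords <- ctr %*% sv$v
    colnames(embedding$coords) <- paste0("U", seq_len(ncol(ctr)))
    embedding$rotation <- sv$v
  }
  for (cc in seq_len(ncol(embedding$coords))) {
    r <- suppressWarnings(cor(embedding$coords[, cc], coord))
    if (!is.na(r) && r < 0) {
      embedding$coords[, cc] <- -embedding$coords[, cc]
      embedding$orientation[cc] <- !embedding$orientation[cc]
    }
  }
  embedding
}

#' Reorder a feature bank by an embedding component
#'
#' Sorting the bank's rows by U1 or U2 reveals which features each component
#' tracks (monotone columns follow the component).
#'
#' @param bank a [feature_bank][build_feature_bank()].
#' @param embedding a [voxel_embedding][embed_bank()] with matching rows.
#' @param component component name (`"U1"`, `"U2"`, ...).
#' @return list with `values` (rows sorted ascending by the component) and
#'   `permutation` (the ordering applied).
#' @export
sort_bank_by_component <- function(bank, embedding, component = "U1") {
  stopifnot(inherits(bank, "feature_bank"),
            inherits(embedding, "voxel_embedding"),
            nrow(bank$values) == nrow(embedding$coords))
  if (!component %in% colnames(embedding$coords)) {
    stop("unknown component '", component, "'", call. = FALSE)
  }
  perm <- order(embedding$coords[, component], seq_len(nrow(bank$values)))
  list(values = bank$values[perm, , drop = FALSE], permutation = perm)
}

#' Two-dimensional colormap over the embedding plane
#'
#' Maps each voxel's (U1, U2) position -- min-max scaled per component -- to
#' an RGB color by bilinear interpolation between four fixed corner colors.
#' Deterministic, and invariant to affine rescaling of the coordinates.
#'
#' @param embedding a [voxel_embedding][embed_bank()].
#' @param corners 4 hex colors for the (low,low), (high,low), (low,high) and
#'   (high,high) corners of the (U1, U2) plane.
#' @return character vector of hex colors, one per voxel.
#' @export
embedding_colors <- function(embedding,
                             corners = c("#2166AC", "#D1E5F0",
                                         "#B2182B", "#FDDBC7")) {
  stopifnot(inherits(embedding, "voxel_embedding"), length(corners) == 4)
  sc <- function(v) {
    rng <- range(v)
    if (diff(rng) <= 0) return(rep(0.5, length(v)))
    (v - rng[1]) / diff(rng)
  }
  u <- sc(embedding$coords[, 1])
  v <- sc(embedding$coords[, 2])
  cr <- t(grDevices::col2rgb(corners)) / 255
  rgbm <- outer((1 - u) * (1 - v), cr[1, ]) + outer(u * (1 - v), cr[2, ]) +
    outer((1 - u) * v, cr[3, ]) + outer(u * v, cr[4, ])
  rgbm <- pmin(pmax(rgbm, 0), 1)
  grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3])
}

#' Persist an embedding as a delimited table plus YAML sidecar
#' @param embedding a [voxel_embedding][embed_bank()].
#' @param path output TSV path; sidecar written as `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(index = seq_len(nrow(embedding$coords)),
                   embedding$coords, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    n_neighbors = embedding$config$n_neighbors,
    min_dist = embedding$config$min_dist,
    n_components = embedding$config$n_components,
    seed = embedding$config$seed,
    orientation = as.list(embedding$orientation)
  ), paste0(path, ".yaml"))
  invisible(path)
}
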