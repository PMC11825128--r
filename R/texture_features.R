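.moment_names <- c("mean", "variance", "skewness", "kurtosis")

#' Masked neighborhood of a voxel
#'
#' Intensities of all masked voxels inside the cubic window of edge
#' `2 * radius + 1` centred on a masked voxel, clipped at the grid border.
#' The centre voxel is always included.
#'
#' @param volume a [masked_volume()].
#' @param center voxel-table index (row of [voxel_table()]) of the centre.
#' @param radius_voxels positive integer kernel radius.
#' @param spherical if TRUE, restrict the window to voxels within Euclidean
#'   distance `radius_voxels` of the centre.
#' @return numeric vector of intensities.
#' @export
neighborhood <- function(volume, center, radius_voxels, spherical = FALSE) {
  stopifnot(inherits(volume, "masked_volume"), radius_voxels >= 1)
  lin <- which(volume$mask)
  center <- as.integer(center)
  if (center < 1L || center > length(lin)) {
    stop("center is not a masked voxel index", call. = FALSE)
  }
  cpp_neighborhood(as.numeric(volume$data), as.logical(volume$mask),
                   dim(volume$data), lin[center], as.integer(radius_voxels),
                   spherical)
}

#' Robust first-order moment with outlier exclusion
#'
#' Computes one central moment of a value set after excluding outliers:
#' values whose absolute deviation from the set's own mean exceeds
#' `outlier_sd` times the set's (population) SD are dropped, and the moment
#' is computed on the survivors with population (denominator n) estimators.
#' Kurtosis is raw (normal is about 3), not excess. Degenerate survivor sets
#' (fewer than 2 values, or zero variance) give variance, skewness and
#' kurtosis 0 by convention, keeping feature banks dense.
#'
#' @param values non-empty numeric vector.
#' @param moment one of `"mean"`, `"variance"`, `"skewness"`, `"kurtosis"`.
#' @param outlier_sd exclusion threshold in SD units; `Inf` disables
#'   exclusion.
#' @return scalar moment value.
#' @examples
#' robust_moment(c(1, 2, 3, 4, 100), "mean", outlier_sd = 1)  # 2.5
#' @export
robust_moment <- function(values, moment, outlier_sd = 1) {
  if (length(values) == 0) stop("values is empty", call. = FALSE)
  moment <- match.arg(moment, .moment_names)
  values <- as.numeric(values)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  thr <- outlier_sd * s
  keep <- if (!is.finite(thr) || s == 0) rep(TRUE, length(values))
          else abs(values - m) <= thr
  if (!any(keep)) keep <- seq_along(values) == which.min(abs(values - m))
  x <- values[keep]
  mu <- mean(x)
  if (moment == "mean") return(mu)
  if (length(x) < 2) return(0)
  m2 <- mean((x - mu)^2)
  if (m2 <= 0) return(0)
  switch(moment,
         variance = m2,
         skewness = mean((x - mu)^3) / m2^1.5,
         kurtosis = mean((x - mu)^4) / m2^2)
}

#' Build the multiscale texture feature bank
#'
#' For every masked voxel and every (moment, radius) pair, computes the
#' robust windowed moment of the voxel's masked neighborhood. Columns are
#' ordered moment-major, radius ascending within moment, and named
#' `<moment>_r<radius>`. At 100 um voxels the default histology radii
#' 2,4,...,10 give physical windows of 500-2100 um in 400 um steps; an
#' in vivo schedule at 500 um voxels uses radii 1-5 (1500-5500 um windows).
#' Only masked intensities ever enter a window.
#'
#' @param volume a [masked_volume()].
#' @param radii integer kernel radii (voxels).
#' @param moments subset of mean/variance/skewness/kurtosis.
#' @param outlier_sd per-window outlier exclusion threshold in SD units
#'   (see [robust_moment()]); the window's own mean/SD is the reference by
#'   default.
#' @param spherical use spherical instead of cubic kernels.
#' @param global_reference if TRUE, outlier exclusion uses the global
#'   mean/SD over all masked voxels instead of each window's own (sensitivity
#'   variant).
#' @return An object of class `feature_bank`: list with `values` (voxels x
#'   features matrix), `specs` (data.frame of moment, radius, window_um),
#'   `normalized` (FALSE) and `outlier_sd`.
#' @export
build_feature_bank <- function(volume, radii = c(2L, 4L, 6L, 8L, 10L),
                               moments = .moment_names, outlier_sd = 1,
                               spherical = FALSE, global_reference = FALSE) {
  stopifnot(inherits(volume, "masked_volume"),
            length(radii) > 0, length(moments) > 0, all(radii >= 1))
  moments <- match.arg(moments, .moment_names, several.ok = TRUE)
  radii <- sort(as.integer(radii))
  lin <- which(volume$mask)
  gvals <- volume$data[volume$mask]
  gmean <- mean(gvals)
  gsd <- sqrt(mean((gvals - gmean)^2))
  full <- cpp_feature_bank(as.numeric(volume$data), as.logical(volume$mask),
                           dim(volume$data), lin, radii, outlier_sd,
                           spherical, global_reference, gmean, gsd)
  nr <- length(radii)
  keep_cols <- unlist(lapply(match(moments, .moment_names),
                             function(m) (m - 1) * nr + seq_len(nr)))
  values <- full[, keep_cols, drop = FALSE]
  specs <- data.frame(
    moment = rep(moments, each = nr),
    radius = rep(radii, times = length(moments)),
    window_um = rep((2 * radii + 1) * volume$voxel_size_um[1],
                    times = length(moments))
  )
  colnames(values) <- paste0(specs$moment, "_r", specs$radius)
  structure(list(values = values, specs = specs, normalized = FALSE,
                 outlier_sd = outlier_sd),
            class = "feature_bank")
}

#' @exportS3Method base::print
print.feature_bank <- function(x, ...) {
  cat("<feature_bank> ", nrow(x$values), " voxels x ", ncol(x$values),
      " features (", if (x$normalized) "normalized" else "raw", ")\n",
      sep = "")
  invisible(x)
}

#' Z-score every feature column
#'
#' Each column is standardized independently over voxels. Zero-variance
#' columns are mapped to all zeros with a warning. Normalizing twice is an
#' error.
#'
#' @param bank an unnormalized [build_feature_bank()] result.
#' @return The bank with standardized `values` and `normalized = TRUE`.
#' @export
normalize_bank <- function(bank) {
  stopifnot(inherits(bank, "feature_bank"))
  if (bank$normalized) stop("bank is already normalized", call. = FALSE)
  v <- bank$values
  mu <- colMeans(v)
  sdv <- apply(v, 2, sd)
  flat <- sdv <= 0 | !is.finite(sdv)
  if (any(flat)) {
    warning("zero-variance feature column(s) set to 0: ",
            paste(colnames(v)[flat], collapse = ", "), call. = FALSE)
    sdv[flat] <- 1
  }
  z <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  z[, flat] <- 0
  bank$values <- z
  bank$normalized <- TRUE
  bank
}

#' Persist a feature bank as a delimited table plus YAML sidecar
#'
#' @param bank a [build_feature_bank()] result.
#' @param path output TSV path; the sidecar is written as `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_feature_bank <- function(bank, path) {
  stopifnot(inherits(bank, "feature_bank"))
  df <- data.frame(index = seq_len(nrow(bank$values)), bank$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    radii = unique(bank$specs$radius),
    moments = unique(bank$specs$moment),
    window_um = unique(bank$specs$window_um),
    outlier_sd = bank$outlier_sd,
    normalized = bank$normalized
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a feature bank written by [write_feature_bank()]
#' @param path TSV path with `<path>.yaml` sidecar.
#' @return a `feature_bank`.
#' @export
read_feature_bank <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  values <- as.matrix(df[, setdiff(colnames(df), "index"), drop = FALSE])
  nr <- length(meta$radii)
  specs <- data.frame(moment = rep(meta$moments, each = nr),
                      radius = rep(meta$radii, times = length(meta$moments)),
                      window_um = rep(meta$window_um,
                                      times = length(meta$moments)))
  structure(list(values = values, specs = specs,
                 normalized = isTRUE(meta$normalized),
                 outlier_sd = meta$outlier_sd),
            class = "feature_bank")
}
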