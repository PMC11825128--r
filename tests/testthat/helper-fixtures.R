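# shared in-code fixtures: everything is generated, nothing read from disk

# small masked volume with reproducible random intensities and an irregular
# random mask (~density of trues given by p_mask)
random_volume <- function(shape = c(16L, 16L, 16L), p_mask = 0.5,
                          seed = 1L, voxel_size_um = 100) {
  set.seed(seed)
  mask <- array(runif(prod(shape)) < p_mask, shape)
  if (!any(mask)) mask[1] <- TRUE
  data <- array(rnorm(prod(shape), mean = 10, sd = 3), shape)
  masked_volume(data, mask, voxel_size_um)
}

# brute-force windowed robust moment for one voxel: explicit loops, no reuse
# of package internals beyond robust_moment (itself oracle-checked against
# hand-computed examples)
brute_force_window <- function(volume, v, radius) {
  tab <- voxel_table(volume)
  ijk <- as.integer(tab[v, c("i", "j", "k")])
  dm <- dim(volume$data)
  vals <- c()
  for (di in -radius:radius) for (dj in -radius:radius)
    for (dk in -radius:radius) {
      p <- ijk + c(di, dj, dk)
      if (any(p < 0) || any(p >= dm)) next
      if (volume$mask[p[1] + 1, p[2] + 1, p[3] + 1]) {
        vals <- c(vals, volume$data[p[1] + 1, p[2] + 1, p[3] + 1])
      }
    }
  vals
}

# plain one-way ANOVA F via explicit sums of squares (textbook form)
oracle_oneway_F <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  k <- nlevels(groups); n <- length(values)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# mean silhouette width for known labels from a plain distance matrix
silhouette_score <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(tapply(D[i, !own], labels[!own], mean))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
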