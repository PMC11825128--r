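test_that("embedding enforces preconditions and the shape contract", {
  vol <- random_volume(c(8, 8, 8), p_mask = 0.7, seed = 71)
  bank <- build_feature_bank(vol, radii = c(1, 2))
  expect_error(embed_bank(bank), "normalized")
  nb <- normalize_bank(bank)
  emb <- embed_bank(nb, embedding_config(seed = 1))
  expect_equal(dim(emb$coords), c(nrow(nb$values), 2))
  expect_equal(colnames(emb$coords), c("U1", "U2"))
  expect_false(anyNA(emb$coords))
  # too few voxels
  tiny <- nb
  tiny$values <- tiny$values[1:10, ]
  expect_error(embed_bank(tiny), "too few voxels")
})

test_that("embedding is deterministic for a fixed seed", {
  vol <- random_volume(c(8, 8, 8), p_mask = 0.7, seed = 72)
  nb <- normalize_bank(build_feature_bank(vol, radii = c(1, 2)))
  e1 <- embed_bank(nb, embedding_config(seed = 9))
  e2 <- embed_bank(nb, embedding_config(seed = 9))
  expect_identical(e1$coords, e2$coords)
})

test_that("well-separated feature clusters stay separated in the embedding", {
  set.seed(81)
  n <- 150
  labels <- rep(c(1, 2), each = n)
  X <- rbind(matrix(rnorm(n * 8, mean = 0), n, 8),
             matrix(rnorm(n * 8, mean = 6), n, 8))
  bank <- structure(list(values = X,
                         specs = data.frame(moment = "mean", radius = 1,
                                            window_um = 300),
                         normalized = TRUE, outlier_sd = 1),
                    class = "feature_bank")
  emb <- embed_bank(bank, embedding_config(seed = 2))
  expect_gt(silhouette_score(emb$coords, labels), 0.5)
})

test_that("orientation convention flips components to positive axis correlation", {
  vol <- random_volume(c(8, 8, 8), p_mask = 0.7, seed = 73)
  tab <- voxel_table(vol)
  coords <- cbind(U1 = -tab$z_um + rnorm(nrow(tab), sd = 50),
                  U2 = tab$z_um + rnorm(nrow(tab), sd = 50))
  emb <- structure(list(coords = coords, config = embedding_config(),
                        orientation = c(U1 = FALSE, U2 = FALSE)),
                   class = "voxel_embedding")
  or <- orient_embedding(emb, tab, "inferior-superior")
  expect_gte(cor(or$coords[, 1], tab$z_um), 0)
  expect_gte(cor(or$coords[, 2], tab$z_um), 0)
  expect_true(or$orientation[["U1"]])
  expect_false(or$orientation[["U2"]])
  # idempotent
  or2 <- orient_embedding(or, tab, "inferior-superior")
  expect_identical(or$coords, or2$coords)
  # sign symmetry: the correlation magnitude is preserved
  expect_equal(abs(cor(or$coords[, 1], tab$z_um)),
               abs(cor(coords[, 1], tab$z_um)))
})

test_that("PCA rotation preserves geometry and decorrelates components", {
  vol <- random_volume(c(8, 8, 8), p_mask = 0.7, seed = 75)
  tab <- voxel_table(vol)
  set.seed(76)
  n <- nrow(tab)
  raw <- cbind(U1 = rnorm(n), U2 = rnorm(n) * 3)
  emb <- structure(list(coords = raw, config = embedding_config(),
                        orientation = c(U1 = FALSE, U2 = FALSE)),
                   class = "voxel_embedding")
  rot <- orient_embedding(emb, tab, rotate = TRUE)
  # rigid motion: all pairwise distances unchanged
  expect_equal(as.numeric(dist(rot$coords)), as.numeric(dist(raw)),
               tolerance = 1e-12)
  # principal axes: components uncorrelated, variance-ordered
  expect_equal(cor(rot$coords)[1, 2], 0, tolerance = 1e-10)
  expect_gte(var(rot$coords[, 1]), var(rot$coords[, 2]))
  # applying the full convention twice changes nothing
  rot2 <- orient_embedding(rot, tab, rotate = TRUE)
  expect_equal(rot2$coords, rot$coords, tolerance = 1e-8)
})

test_that("sorting the bank by a component returns rows and permutation", {
  vol <- random_volume(c(8, 8, 8), p_mask = 0.7, seed = 74)
  nb <- normalize_bank(build_feature_bank(vol, radii = c(1, 2)))
  n <- nrow(nb$values)
  mk <- function(u1) structure(
    list(coords = cbind(U1 = u1, U2 = rnorm(n)),
         config = embedding_config(), orientation = c(U1 = FALSE, U2 = FALSE)),
    class = "voxel_embedding")
  expect_equal(sort_bank_by_component(nb, mk(seq_len(n)), "U1")$permutation,
               seq_len(n))
  expect_equal(sort_bank_by_component(nb, mk(rev(seq_len(n))), "U1")$permutation,
               rev(seq_len(n)))
  # sorted rows match the permutation applied to the original matrix
  emb <- mk(rnorm(n))
  srt <- sort_bank_by_component(nb, emb, "U1")
  expect_equal(srt$values, nb$values[srt$permutation, ])
})

test_that("mean features are monotone along the component that tracks them", {
  mask <- make_ellipsoid_mask(c(20, 20, 20), c(8, 7, 6))
  vol <- make_gradient_volume(mask, gradient_spec(seed = 5))
  nb <- normalize_bank(build_feature_bank(vol, radii = c(2, 4)))
  emb <- embed_bank(nb, embedding_config(seed = 3))
  tr <- attr(vol, "truth")
  # pick the component that recovered the planted mean axis
  comp <- which.max(abs(cor(emb$coords, tr$mean_coord)))
  srt <- sort_bank_by_component(nb, emb, paste0("U", comp))
  rho <- cor(srt$values[, "mean_r4"], seq_len(nrow(srt$values)),
             method = "spearman")
  expect_gt(abs(rho), 0.8)
})

test_that("embedding colors are deterministic anchors of the 2D colormap", {
  n <- 50
  set.seed(91)
  coords <- cbind(U1 = runif(n, -3, 7), U2 = runif(n, 0, 1))
  coords[1, ] <- c(-3, 0)  # force the (min, min) corner
  emb <- structure(list(coords = coords, config = embedding_config(),
                        orientation = c(U1 = FALSE, U2 = FALSE)),
                   class = "voxel_embedding")
  cols <- embedding_colors(emb)
  expect_equal(cols[1], "#2166AC")
  # identical coordinates get identical colors
  emb$coords[2, ] <- emb$coords[3, ]
  cols2 <- embedding_colors(emb)
  expect_equal(cols2[2], cols2[3])
  # affine rescaling leaves colors unchanged
  emb2 <- emb
  emb2$coords[, 1] <- emb$coords[, 1] * 13 - 5
  emb2$coords[, 2] <- emb$coords[, 2] * 0.2 + 40
  expect_equal(embedding_colors(emb2), cols2)
})
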