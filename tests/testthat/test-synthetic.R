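test_that("edge vectorization is lower-triangle row-major and invertible", {
  m <- matrix(0, 4, 4)
  m[lower.tri(m)] <- 1:6
  m <- m + t(m)
  ep <- edge_pairs(4)
  expect_equal(ep[, "i"], c(2L, 3L, 3L, 4L, 4L, 4L))
  expect_equal(ep[, "j"], c(1L, 1L, 2L, 1L, 2L, 3L))
  v <- vectorize_edges(m)
  expect_equal(edge_matrix(v, 4), m)
  expect_equal(n_edges(4), 6L)
})

test_that("same seed gives bit-identical datasets", {
  cfg <- synth_config(n_subjects = 60, n_parcels_cortical = 20,
                      n_parcels_subcortical = 4, n_items = 15, seed = 5L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset$modality_blocks, b$dataset$modality_blocks)
  expect_identical(a$dataset$behavior, b$dataset$behavior)
  expect_identical(a$truth, b$truth)
})

test_that("ordinal items live in {0,1,2} with a modal zero and monotone
           threshold response", {
  base <- list(n_subjects = 400, n_parcels_cortical = 16,
               n_parcels_subcortical = 2, n_items = 20, seed = 8L)
  lo <- do.call(synth_config, c(base, list(item_thresholds = c(0.3, 1.2))))
  hi <- do.call(synth_config, c(base, list(item_thresholds = c(1.0, 2.0))))
  bl <- generate_dataset(lo)$dataset$behavior
  bh <- generate_dataset(hi)$dataset$behavior
  expect_true(all(bl %in% 0:2))
  tab <- tabulate(generate_dataset(do.call(synth_config, base))$
                    dataset$behavior + 1L, 3L)
  expect_true(which.max(tab) == 1L)
  ## raising thresholds shifts mass toward zero
  expect_gt(mean(bh == 0), mean(bl == 0))
  expect_lt(mean(bh == 2), mean(bl == 2))
})

test_that("planted truth satisfies its structural invariants", {
  tr <- small_strong()$truth
  L <- ncol(tr$behavior_saliences)
  expect_equal(crossprod(tr$behavior_saliences), diag(L),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(tr$imaging_saliences), diag(L),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(abs(mean(tr$planted_gradient)), 1e-10)
})

test_that("per-subject connectivity matrices are positive semi-definite", {
  ds <- small_strong()$dataset
  p <- nrow(ds$assets$coords)
  for (i in c(1L, 7L, 33L)) {
    C <- edge_matrix(ds$modality_blocks$rsfc[i, ], p)
    diag(C) <- ds$rsfc_diagonal[i, ]
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("connectivity similarity decays along the planted gradient", {
  g <- small_strong()
  gc <- group_connectivity(g$dataset)
  ctx <- g$dataset$assets$coords$hemisphere != "SC"
  sim <- stats::cor(t(gc[ctx, ctx]))
  gd <- -abs(outer(g$truth$planted_gradient[ctx],
                   g$truth$planted_gradient[ctx], "-"))
  lt <- lower.tri(sim)
  expect_gt(stats::cor(sim[lt], gd[lt], method = "spearman"), 0.2)
})

test_that("zero latent strength decouples imaging from behavior", {
  cfg <- synth_config(n_subjects = 500, n_parcels_cortical = 20,
                      n_parcels_subcortical = 4, n_items = 25,
                      latent_strength = c(0, 0, 0),
                      confound_strength = 0, seed = 13L)
  g <- generate_dataset(cfg)
  ds <- g$dataset
  blocks <- lapply(ds$modality_blocks, scale)
  y <- scale(ds$behavior)
  ## behavior totals against imaging means: no association beyond noise
  r <- stats::cor(rowMeans(y), rowMeans(blocks$area))
  expect_lt(abs(r), 3 / sqrt(cfg$n_subjects))
  ## and the leading cross-covariance singular value is null-scale
  pt <- permutation_test(blocks$area, y, ds$covariates$site,
                         n_perm = 99, k_test = 1, seed = 2L)
  expect_gt(pt$p_values[1L], 0.05)
})

test_that("parcellation assets partition all parcels with unit centroids", {
  cfg <- synth_config(n_subjects = 10, n_parcels_cortical = 400,
                      n_parcels_subcortical = 19, n_items = 5, seed = 2L)
  as <- generate_parcellation_assets(cfg, n_networks = 18)
  expect_equal(nrow(as$coords), 419L)
  expect_equal(length(as$partition), 419L)
  expect_false(anyNA(as$partition))
  expect_equal(nlevels(as$partition), 18L)
  expect_equal(sum(as$partition == "subcortical"), 19L)
  nrm <- sqrt(rowSums(as$coords[, c("x", "y", "z")]^2))
  expect_equal(nrm, rep(1, 419), tolerance = 1e-12, ignore_attr = TRUE)
  ## nearest-centroid lookup of each centroid is the identity
  xyz <- as.matrix(as$coords[, c("x", "y", "z")])
  expect_equal(max.col(tcrossprod(xyz), ties.method = "first"),
               seq_len(419L))
  ## mirrored hemispheres
  nL <- sum(as$coords$hemisphere == "L")
  expect_equal(as$coords$x[201:400], -as$coords$x[1:200])
  expect_error(generate_parcellation_assets(cfg, n_networks = 1000),
               "configuration error")
})

test_that("smooth maps gain spatial autocorrelation with fwhm", {
  cfg <- synth_config(n_subjects = 10, n_parcels_cortical = 80,
                      n_parcels_subcortical = 0, n_items = 5, seed = 3L)
  coords <- generate_parcellation_assets(cfg, 4)$coords
  ang <- matrix(acos(pmin(1, tcrossprod(
    as.matrix(coords[, c("x", "y", "z")])))), nrow(coords))
  near <- ang < 0.35; diag(near) <- FALSE
  far <- ang > 2.5
  basis <- smooth_map_basis(coords, 40)
  prods_near0 <- prods_near <- prods_far <- numeric(100)
  for (s in 1:100) {
    m0 <- generate_smooth_map(coords, 0, seed = s)
    m1 <- generate_smooth_map(coords, 40, seed = s, basis = basis)
    pn0 <- outer(m0, m0)
    pn1 <- outer(m1, m1)
    prods_near0[s] <- mean(pn0[near]) / mean(m0^2)
    prods_near[s] <- mean(pn1[near]) / mean(m1^2)
    prods_far[s] <- mean(pn1[far]) / mean(m1^2)
  }
  expect_lt(abs(mean(prods_near0)), 0.1)   # fwhm 0: no neighbor coupling
  expect_gt(mean(prods_near), mean(prods_far))
  expect_gt(mean(prods_near), 0.3)
  expect_identical(generate_smooth_map(coords, 40, seed = 9, basis = basis),
                   generate_smooth_map(coords, 40, seed = 9, basis = basis))
})

test_that("infeasible latent dimension is a configuration error", {
  expect_error(synth_config(n_subjects = 50, n_parcels_cortical = 4,
                            n_parcels_subcortical = 0, n_items = 2,
                            n_latent = 5,
                            latent_strength = rep(1, 5)),
               "configuration error")
  expect_error(synth_config(item_thresholds = c(2, 1)), "increasing")
})
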