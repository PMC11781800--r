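test_that("within-site permutations stay within site", {
  site <- factor(c("a", "a", "a", "b", "b", "b", "b"))
  for (s in 1:20) {
    perm <- permute_within_site(site, seed = s)
    expect_true(all(site[perm] == site))
    expect_setequal(perm, 1:7)
  }
  ## singleton sites force the identity
  ones <- factor(letters[1:6])
  expect_identical(permute_within_site(ones, seed = 1L), 1:6)
  ## single site: full permutation support; 2 sites of sizes 3 and 4
  ## reach essentially all 3!*4! = 144 permutations
  seen <- character()
  with_seed(3L, {
    for (i in 1:10000)
      seen[i] <- paste(permute_within_site(site), collapse = ",")
  })
  expect_gt(length(unique(seen)), 0.95 * 144)
})

test_that("permutation p-values hit the attainable floor on strong signal
           and respect the add-one convention", {
  with_seed(14L, {
    n <- 400
    f <- stats::rnorm(n)
    x <- 2 * outer(f, c(rep(1, 3), rep(0, 5)) / sqrt(3)) +
      matrix(stats::rnorm(n * 8), n)
    y <- 2 * outer(f, rep(1, 6) / sqrt(6)) +
      matrix(stats::rnorm(n * 6), n)
    site <- factor(sample(c("s1", "s2", "s3"), n, TRUE))
    pt <- permutation_test(x, y, site, n_perm = 199, k_test = 3, seed = 5L)
    expect_equal(pt$p_values[1L], 1 / 200)
    expect_true(all(pt$p_values > 0 & pt$p_values <= 1))
    ## null singular values for LC1 dominate those for LC3 pointwise
    expect_true(all(pt$null_distribution[, 1L] >=
                      pt$null_distribution[, 3L]))
    ## Procrustes-aligned null variant runs and is no less conservative
    ptp <- permutation_test(x, y, site, n_perm = 99, k_test = 2,
                            seed = 5L, procrustes = TRUE)
    expect_true(all(ptp$p_values > 0 & ptp$p_values <= 1))
  })
})

test_that("site restriction protects against site-driven false positives", {
  ## strong site mean shifts in X and Y, no true subject-level signal:
  ## unrestricted permutation mistakes site structure for signal
  p_restricted <- p_unrestricted <- numeric(10)
  for (s in 1:10) {
    with_seed(200 + s, {
      n <- 200
      site <- factor(rep(sprintf("s%d", 1:4), each = n / 4))
      shift_x <- matrix(stats::rnorm(4 * 6, 0, 1.5), 4)
      shift_y <- matrix(stats::rnorm(4 * 5, 0, 1.5), 4)
      x <- matrix(stats::rnorm(n * 6), n) + shift_x[as.integer(site), ]
      y <- matrix(stats::rnorm(n * 5), n) + shift_y[as.integer(site), ]
      p_restricted[s] <- permutation_test(x, y, site, 99, 1,
                                          seed = s)$p_values[1L]
      one_site <- factor(rep("all", n))
      p_unrestricted[s] <- permutation_test(x, y, one_site, 99, 1,
                                            seed = s)$p_values[1L]
    })
  }
  expect_gte(sum(p_unrestricted < 0.05), 8)
  expect_lte(sum(p_restricted < 0.05), 3)
})

test_that("network block averaging matches hand-computed cases", {
  ## constant loadings give constant blocks
  part <- factor(rep(c("n1", "n2", "n3"), times = c(3, 3, 2)))
  L <- matrix(0.4, 8, 8); diag(L) <- 0
  ba <- block_average_edges(L, part)
  expect_equal(as.numeric(ba), rep(0.4, 9))
  ## checkerboard two-network toy: within +1, between -1
  part2 <- factor(rep(c("a", "b"), each = 3))
  L2 <- matrix(-1, 6, 6)
  L2[1:3, 1:3] <- 1; L2[4:6, 4:6] <- 1; diag(L2) <- 0
  ba2 <- block_average_edges(L2, part2)
  expect_equal(unname(diag(ba2)), c(1, 1))
  expect_equal(ba2["a", "b"], -1)
  ## a singleton network has no within-network edges
  part3 <- factor(c("a", "a", "b"))
  ba3 <- block_average_edges(matrix(0.2, 3, 3) - 0.2 * diag(3), part3)
  expect_true(is.na(ba3["b", "b"]))
  expect_false(anyNA(ba3[lower.tri(ba3)]))
  ## 18 networks produce 18 + 153 = 171 distinct blocks
  part18 <- factor(rep(sprintf("n%02d", 1:18), each = 2))
  ba18 <- block_average_edges(matrix(1, 36, 36) - diag(36), part18)
  expect_equal(length(block_vector(ba18)), 171L)
})

test_that("BH step-up matches hand-worked examples", {
  f1 <- fdr_bh(rep(0.001, 10), 0.05)
  expect_true(all(f1$mask))
  expect_true(fdr_bh(0.04, 0.05)$mask)
  f3 <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), 0.05)
  expect_equal(unname(f3$mask), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(f3$adjusted, stats::p.adjust(c(0.01, 0.02, 0.03, 0.5),
                                            "BH"))
})

test_that("bootstrap reports stable loadings with sensible intervals", {
  d <- planted_loading_data(500, seed = 15L)
  bt <- bootstrap_within_site(
    d$X, d$Y, d$site, n_boot = 80,
    targets = list(items = list(data = d$Y, arm = "behavior")),
    seed = 6L, k = 2L)
  it <- bt$targets$items
  expect_equal(dim(it$loading), c(30L, 2L))
  expect_true(all(it$sd[, 1L] > 0))
  expect_true(all(it$ci_lo <= it$ci_hi))
  ## the planted item's interval covers its population loading
  expect_gt(d$true_loading, it$ci_lo[1L, 1L] - 0.05)
  expect_lt(d$true_loading, it$ci_hi[1L, 1L] + 0.05)
  ## strong loadings are flagged, and Z = loading / sd
  expect_true(it$mask[1L, 1L])
  expect_equal(it$z, it$loading / it$sd, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a degenerate always-unit loading yields infinite Z flagged
           significant", {
  with_seed(16L, {
    n <- 120
    x <- matrix(stats::rnorm(n), n, 1)
    y <- cbind(x[, 1L] + 0.01 * stats::rnorm(n))
    site <- factor(rep(c("a", "b"), n / 2))
    bt <- bootstrap_within_site(
      x, y, site, n_boot = 30,
      targets = list(self = list(data = x, arm = "imaging")),
      seed = 7L, k = 1L)
    s <- bt$targets$self
    expect_true(s$zero_sd[1L, 1L])
    expect_true(is.infinite(s$z[1L, 1L]))
    expect_true(s$mask[1L, 1L])
  })
})

test_that("pure-noise loadings rarely pass the FDR mask", {
  empty <- logical(10)
  for (s in 1:10) {
    d <- with_seed(300 + s, {
      n <- 150
      list(X = matrix(stats::rnorm(n * 6), n),
           Y = matrix(stats::rnorm(n * 8), n),
           noise = matrix(stats::rnorm(n * 10), n),
           site = factor(sample(c("a", "b"), n, TRUE)))
    })
    bt <- bootstrap_within_site(
      d$X, d$Y, d$site, n_boot = 60,
      targets = list(noise = list(data = d$noise, arm = "imaging")),
      seed = s, k = 1L)
    empty[s] <- !any(bt$targets$noise$mask)
  }
  expect_gte(sum(empty), 7)
})

test_that("edge targets are block-averaged before Z-scoring", {
  g <- small_strong()
  ds <- g$dataset
  part <- ds$assets$partition
  B <- nlevels(part)
  bt <- bootstrap_within_site(
    ds$modality_blocks$area, ds$behavior, ds$covariates$site,
    n_boot = 20,
    targets = list(rsfc = list(data = ds$modality_blocks$rsfc,
                               arm = "imaging", partition = part)),
    seed = 8L, k = 1L)
  expect_equal(nrow(bt$targets$rsfc$loading), B + B * (B - 1L) / 2L)
})
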