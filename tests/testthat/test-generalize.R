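## Two same-truth cohorts: one generated draw split in half, so both
## halves share the planted structure but have independent subjects.
same_truth_halves <- function() {
  if (is.null(fixture_env$halves)) {
    cfg <- synth_config(n_subjects = 1200, n_sites = 4,
                        n_parcels_cortical = 40,
                        n_parcels_subcortical = 4, n_items = 30,
                        latent_strength = c(6, 3, 2),
                        confound_strength = 0, seed = 77L)
    g <- generate_dataset(cfg)
    idx_a <- 1:600; idx_b <- 601:1200
    take <- function(idx) list(
      blocks = lapply(g$dataset$modality_blocks, function(b)
        b[idx, , drop = FALSE]),
      behavior = g$dataset$behavior[idx, , drop = FALSE],
      site = g$dataset$covariates$site[idx])
    fixture_env$halves <- list(a = take(idx_a), b = take(idx_b),
                               truth = g$truth)
  }
  fixture_env$halves
}

test_that("self-transfer reproduces within-sample composite scores", {
  h <- same_truth_halves()
  tm <- fit_transfer_model(h$a$blocks, h$a$behavior)
  xp <- concatenate_scores(tm$reduction, h$a$blocks)
  fit <- pls_decompose(xp, h$a$behavior)
  ts <- transfer_scores(tm, h$a$blocks, h$a$behavior)
  expect_equal(ts$LX[, 1:3], fit$LX[, 1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ts$LY[, 1:3], fit$LY[, 1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ts$r[1:3], fit$lc_correlations[1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("discovery weights are untouched by replication data", {
  h <- same_truth_halves()
  tm <- fit_transfer_model(h$a$blocks, h$a$behavior)
  before <- serialize(tm, NULL)
  invisible(transfer_scores(tm, h$b$blocks, h$b$behavior))
  invisible(transfer_scores(tm, lapply(h$b$blocks, function(b)
    b[-1, , drop = FALSE]), h$b$behavior[-1, , drop = FALSE]))
  expect_identical(serialize(tm, NULL), before)
})

test_that("same-truth transfer attains near within-sample correlation,
           null transfer does not", {
  h <- same_truth_halves()
  tm <- fit_transfer_model(h$a$blocks, h$a$behavior)
  within_r <- tm$lc_correlations_within[1L]
  ts <- transfer_scores(tm, h$b$blocks, h$b$behavior)
  expect_gt(ts$r[1L], 0)
  expect_lt(abs(ts$r[1L] - within_r), 0.1)
  ## independent truth: out-of-sample correlation at noise level
  cfg0 <- synth_config(n_subjects = 600, n_sites = 4,
                       n_parcels_cortical = 40, n_parcels_subcortical = 4,
                       n_items = 30, latent_strength = c(0, 0, 0),
                       confound_strength = 0, seed = 99L)
  g0 <- generate_dataset(cfg0)
  ts0 <- transfer_scores(tm, g0$dataset$modality_blocks,
                         g0$dataset$behavior)
  expect_lt(abs(ts0$r[1L]), 2 / sqrt(600) + 0.05)
})

test_that("transfer significance separates signal from permuted nulls", {
  h <- same_truth_halves()
  tm <- fit_transfer_model(h$a$blocks, h$a$behavior)
  sig <- transfer_significance(tm, h$b$blocks, h$b$behavior, h$b$site,
                               n_perm = 99, seed = 12L, k_test = 3)
  expect_equal(sig$p_values[1L], 1 / 100)
  expect_true(all(sig$fdr_q <= 1))
  expect_error(transfer_significance(tm, h$b$blocks, h$b$behavior,
                                     h$b$site, n_perm = 0), "n_perm")
})

test_that("replication-invariant items are dropped with renormalization", {
  h <- same_truth_halves()
  tm <- fit_transfer_model(h$a$blocks, h$a$behavior)
  yb <- h$b$behavior
  yb[, 3L] <- 0L
  expect_message(ts <- transfer_scores(tm, h$b$blocks, yb),
                 "replication-invariant")
  expect_equal(length(ts$kept_items), ncol(yb) - 1L)
  expect_gt(ts$r[1L], 0.5)  # one item barely matters
})

test_that("full replication of identical data reproduces loadings", {
  g <- small_strong()
  ds <- g$dataset
  prep <- small_strong_prepped()
  disc_load <- project_loadings_back(prep$pls, prep$blocks)
  disc_load$behavior <- prep$pls$behavior_loadings
  rep <- suppressMessages(replicate_full(
    ds$modality_blocks, ds$behavior, ds$covariates, disc_load, k = 2))
  r1 <- rep$comparison$r[rep$comparison$lc == 1L]
  expect_true(all(abs(r1) > 0.999))
})

test_that("held-out association recovers planted effects and stays quiet
           on noise", {
  p <- small_strong_prepped()
  n <- nrow(p$xp)
  site <- p$dataset$covariates$site
  with_seed(23L, {
    tracts <- cbind(p$pls$LX[, 1L],
                    0.4 * scale(p$truth$subject_scores[, 1L]) +
                      stats::rnorm(n),
                    matrix(stats::rnorm(n * 3), n))
    ha <- heldout_association(tracts, p$pls$LX, p$pls$LY, site,
                              n_boot = 60, seed = 13L, k = 2L)
    expect_equal(ha$imaging$loading[1L, 1L], 1, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(ha$imaging$mask[2L, 1L])
    expect_false(any(ha$imaging$mask[3:5, 2L]))
  })
  expect_error(heldout_association(matrix(1, 2, 2), p$pls$LX[1:2, ],
                                   p$pls$LY[1:2, ], site[1:2],
                                   n_boot = 10), "overlap")
})

test_that("demographic post hoc tests flag only real structure", {
  with_seed(24L, {
    n <- 500
    cov <- data.frame(age = stats::runif(n, 9, 11),
                      sex = factor(sample(c("F", "M"), n, TRUE)))
    ## score driven by age: age test fires, sex does not
    sc <- list(imaging = cbind(scale(cov$age) + stats::rnorm(n, 0, 0.5)))
    out <- demographic_posthoc(sc, cov)
    expect_true(out$significant[out$test == "age_r"])
    expect_false(out$significant[out$test == "sex_t"])
    ## equal means, unequal variances: Welch statistic near zero
    s2 <- stats::rnorm(n, 0, ifelse(cov$sex == "F", 1, 3))
    out2 <- demographic_posthoc(list(b = cbind(s2)), cov)
    expect_lt(abs(out2$statistic[out2$test == "sex_t"]), 3)
    ## one sex absent: skipped with flag
    cov1 <- cov; cov1$sex <- factor(rep("F", n))
    out3 <- demographic_posthoc(sc, cov1)
    expect_true(out3$skipped[out3$test == "sex_t"])
  })
})
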