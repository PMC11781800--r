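## Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

## Strong-signal three-component cohort, modest size: used by several
## module tests for recovery and invariance checks.
small_strong <- function() {
  if (is.null(fixture_env$strong)) {
    cfg <- synth_config(n_subjects = 600, n_sites = 4,
                        n_parcels_cortical = 50, n_parcels_subcortical = 6,
                        n_items = 40, latent_strength = c(5, 3, 2),
                        seed = 42L)
    fixture_env$strong <- generate_dataset(cfg)
  }
  fixture_env$strong
}

## Residualized blocks + behavior for the strong fixture.
small_strong_prepped <- function() {
  if (is.null(fixture_env$strong_prep)) {
    g <- small_strong()
    ds <- g$dataset
    blocks <- lapply(names(ds$modality_blocks), function(nm)
      residualize(ds$modality_blocks[[nm]], ds$covariates,
                  modality_covariates(nm)))
    names(blocks) <- names(ds$modality_blocks)
    behavior <- residualize(ds$behavior, ds$covariates,
                            modality_covariates("behavior"))
    red <- reduce_fit(blocks, 0.5)
    xp <- concatenate_scores(red, blocks)
    fixture_env$strong_prep <- list(
      dataset = ds, truth = g$truth, blocks = blocks,
      behavior = behavior, reduction = red, xp = xp,
      pls = pls_decompose(xp, behavior))
  }
  fixture_env$strong_prep
}

## Exact-variance orthogonal design: columns with prescribed sample
## variances, mutually orthogonal after centering.
orthogonal_columns <- function(n, variances, seed = 1L) {
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * length(variances)), n)
    z <- sweep(z, 2L, colMeans(z), "-")
    q <- qr.Q(qr(z))
    sweep(q, 2L, sqrt(variances * (n - 1)), "*")
  })
}

## Fisher-Lee circular correlation (offset- and rotation-invariant).
circular_correlation <- function(a, b) {
  sa <- outer(a, a, function(x, y) sin(x - y))
  sb <- outer(b, b, function(x, y) sin(x - y))
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

## Single-latent-factor continuous dataset with a known population item
## loading. The composite LY is a c-weighted item sum, so the target
## item's own noise enters it; c1 is solved so that the population
## correlation between item 1 and the composite is exactly `loading`.
planted_loading_data <- function(n, n_items = 30, n_x = 20,
                                 loading = 0.6, n_sites = 4, seed = 1L) {
  c_rest <- rep(0.6, n_items - 1L)
  pop_loading <- function(c1) {
    ## composite weights follow the z-scored cross-covariance, w ~ c/(1+c^2)
    cj <- c(c1, c_rest)
    w <- cj / (1 + cj^2)
    s <- sum(w * cj)
    (c1 * s + w[1L]) / sqrt((1 + c1^2) * (s^2 + sum(w^2)))
  }
  c1 <- stats::uniroot(function(c) pop_loading(c) - loading,
                       c(0.1, 2))$root
  with_seed(seed, {
    f <- stats::rnorm(n)
    cj <- c(c1, c_rest)
    Y <- outer(f, cj) + matrix(stats::rnorm(n * n_items), n)
    v <- stats::rnorm(n_x); v <- v / sqrt(sum(v^2))
    X <- 3 * outer(f, v) + matrix(stats::rnorm(n * n_x), n)
    site <- factor(sample(sprintf("s%d", seq_len(n_sites)), n, TRUE))
    list(X = X, Y = Y, site = site, f = f, true_loading = loading)
  })
}
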