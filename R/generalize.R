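#' Fit a discovery-cohort transfer model
#'
#' Captures every weight needed to score an unseen replication cohort:
#' the per-modality PCA models, the discovery means and SDs of the
#' concatenated PCA scores and of the behavior items, and the discovery
#' PLS saliences. All statistics are computed from discovery subjects
#' only.
#'
#' @param blocks Named list of discovery imaging blocks (residualized).
#' @param behavior Discovery behavior matrix (residualized items).
#' @param variance_threshold PCA retention threshold (default 0.5).
#' @param standardize Standardize features before PCA.
#' @return Object of class \code{transfer_model}.
#' @export
fit_transfer_model <- function(blocks, behavior, variance_threshold = 0.5,
                               standardize = FALSE) {
  red <- reduce_fit(blocks, variance_threshold, standardize)
  xp <- concatenate_scores(red, blocks)
  pls <- pls_decompose(xp, behavior)
  structure(list(
    reduction = red,
    x_mean = colMeans(xp), x_sd = apply(xp, 2L, stats::sd),
    y_mean = colMeans(as.matrix(behavior)),
    y_sd = apply(as.matrix(behavior), 2L, stats::sd),
    U = pls$U, V = pls$V, singular_values = pls$singular_values,
    item_names = colnames(behavior),
    lc_correlations_within = pls$lc_correlations,
    blocks_attr = attr(xp, "blocks")), class = "transfer_model")
}

## Drop items invariant in the replication sample from U and Y, with
## renormalization of the remaining salience columns.
align_items <- function(model, behavior) {
  behavior <- as.matrix(behavior)
  v <- apply(behavior, 2L, stats::var)
  keep <- which(v > 0)
  if (length(keep) < 2L) stop("replication behavior nearly invariant")
  if (length(keep) < ncol(behavior)) {
    dropped <- colnames(behavior)[-keep] %||% as.character(setdiff(
      seq_len(ncol(behavior)), keep))
    message("dropping ", ncol(behavior) - length(keep),
            " replication-invariant item(s): ",
            paste(dropped, collapse = ", "),
            "; salience columns renormalized")
  }
  U <- model$U[keep, , drop = FALSE]
  U <- sweep(U, 2L, sqrt(colSums(U^2)), "/")
  list(keep = keep, U = U)
}

#' Out-of-sample composite scores via discovery weight transfer
#'
#' Projects replication data through the discovery PCA coefficients,
#' normalizes PCA scores and items by the discovery means and SDs, and
#' multiplies by the discovery saliences to obtain cross-validated
#' composite scores. Out-of-sample loadings correlate these scores with
#' the normalized replication data.
#'
#' @param model A \code{\link{fit_transfer_model}} object.
#' @param blocks Named list of replication imaging blocks (same feature
#'   spaces as discovery).
#' @param behavior Replication behavior matrix (same items as
#'   discovery; items invariant in replication are dropped from both
#'   sides with salience renormalization).
#' @return List: \code{LX}, \code{LY} (cross-validated composites),
#'   \code{r} (per-LC correlation), \code{behavior_loadings},
#'   \code{imaging_pc_loadings} (out-of-sample, in normalized spaces),
#'   \code{kept_items}.
#' @export
transfer_scores <- function(model, blocks, behavior) {
  stopifnot(inherits(model, "transfer_model"))
  xp <- reduce_transform(model$reduction, blocks)
  if (ncol(xp) != length(model$x_mean)) stop("feature mismatch")
  xn <- sweep(sweep(xp, 2L, model$x_mean, "-"), 2L, model$x_sd, "/")
  ai <- align_items(model, behavior)
  yn <- as.matrix(behavior)[, ai$keep, drop = FALSE]
  yn <- sweep(sweep(yn, 2L, model$y_mean[ai$keep], "-"), 2L,
              model$y_sd[ai$keep], "/")
  LX <- xn %*% model$V
  LY <- yn %*% ai$U
  colnames(LX) <- colnames(LY) <-
    paste0("LC", seq_len(ncol(LX)))
  cc <- cor_columns(LX, LY)
  list(LX = LX, LY = LY, r = diag(cc),
       behavior_loadings = cor_columns(yn, LY),
       imaging_pc_loadings = cor_columns(xn, LX),
       kept_items = ai$keep)
}

#' Permutation significance of transferred components
#'
#' Permutes replication behavior within site, recomputes the
#' cross-validated per-LC correlation, and compares the observed
#' correlations against their same-index nulls (add-one p, BH-FDR over
#' the tested components).
#'
#' @param model A \code{transfer_model}.
#' @param blocks,behavior Replication data as in
#'   \code{\link{transfer_scores}}.
#' @param site_labels Replication site labels.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param k_test Leading components tested (default 5).
#' @return List: \code{r}, \code{null_r}, \code{p_values}, \code{fdr_q}.
#' @export
transfer_significance <- function(model, blocks, behavior, site_labels,
                                  n_perm, seed = 1L, k_test = 5) {
  if (is.null(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  ts <- transfer_scores(model, blocks, behavior)
  k_test <- min(k_test, ncol(ts$LX))
  obs <- ts$r[seq_len(k_test)]
  null <- matrix(NA_real_, n_perm, k_test)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- permute_within_site(site_labels)
      cc <- cor_columns(ts$LX[, seq_len(k_test), drop = FALSE],
                        ts$LY[perm, seq_len(k_test), drop = FALSE])
      null[b, ] <- diag(cc)
    }
  })
  p <- vapply(seq_len(k_test), function(k)
    (1 + sum(null[, k] >= obs[k])) / (1 + n_perm), 1.0)
  list(r = obs, null_r = null, p_values = p,
       fdr_q = stats::p.adjust(p, "BH"))
}

#' Independent re-analysis of a replication cohort
#'
#' Re-runs residualization, PCA reduction and PLS from scratch on the
#' replication subjects and correlates the resulting loadings, component
#' by component, with the discovery loadings. Parcel-map comparisons use
#' spin-permutation p-values when spins are supplied; item loadings use a
#' parametric correlation test.
#'
#' @param blocks Named list of replication imaging blocks (raw).
#' @param behavior Replication behavior matrix (raw items).
#' @param covariates Replication covariate table.
#' @param discovery_loadings Named list of discovery loading matrices
#'   (features x K), e.g. from \code{\link{project_loadings_back}}, plus
#'   an element \code{behavior}.
#' @param variance_threshold PCA retention threshold.
#' @param k Components compared (default 3).
#' @param spins Optional spin matrix for cortical parcel maps (applied to
#'   modalities whose loading length matches \code{ncol(spins)}).
#' @param q FDR level for the comparison table.
#' @return List: \code{pls} (replication fit), \code{loadings}
#'   (replication loadings per modality + behavior), \code{comparison}
#'   (data.frame modality x LC with r and p).
#' @export
replicate_full <- function(blocks, behavior, covariates,
                           discovery_loadings, variance_threshold = 0.5,
                           k = 3, spins = NULL, q = 0.05) {
  stopifnot(nrow(behavior) >= 10)
  resid_blocks <- lapply(names(blocks), function(nm)
    residualize(blocks[[nm]], covariates, modality_covariates(nm)))
  names(resid_blocks) <- names(blocks)
  beh_kept <- drop_invariant_items(behavior)
  yb <- residualize(beh_kept$behavior, covariates,
                    modality_covariates("behavior"))
  red <- reduce_fit(resid_blocks, variance_threshold)
  xp <- concatenate_scores(red, resid_blocks)
  pls <- pls_decompose(xp, yb)
  k <- min(k, length(pls$singular_values))
  loadings <- project_loadings_back(pls, resid_blocks)
  loadings$behavior <- pls$behavior_loadings
  rows <- list()
  for (nm in names(discovery_loadings)) {
    if (is.null(loadings[[nm]])) next
    for (lc in seq_len(k)) {
      a <- discovery_loadings[[nm]][, lc]
      b <- loadings[[nm]][, lc]
      if (length(a) != length(b)) next
      r <- stats::cor(a, b)
      p <- if (!is.null(spins) && length(a) == ncol(spins))
        spin_correlation(a, b, spins)$p_spin
      else stats::cor.test(a, b)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        modality = nm, lc = lc, r = r, p = p)
    }
  }
  comparison <- do.call(rbind, rows)
  fdr <- fdr_bh(comparison$p, q)
  comparison$q_adj <- fdr$adjusted
  comparison$significant <- fdr$mask
  list(pls = pls, loadings = loadings, comparison = comparison)
}

#' Associate held-out features with existing composite scores
#'
#' Correlates features measured in a subject subset (e.g. diffusion
#' tract metrics, task connectivity) with composite scores from the main
#' analysis, reusing the existing scores on the overlapping subjects.
#' Stability is assessed by a site-restricted bootstrap; edge features
#' are averaged within and between networks before Z-scoring.
#'
#' @param heldout Subjects x features matrix (overlap subjects only).
#' @param LX,LY Composite score matrices for the same overlap subjects.
#' @param site_labels Site labels for the overlap subjects.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param partition Optional network factor marking \code{heldout} as
#'   vectorized edges.
#' @param seed Integer seed.
#' @param k Components (default min(5, ncol(LX))).
#' @param q FDR level.
#' @return List with elements \code{imaging} and \code{behavior}, each a
#'   loading-stability table as in \code{\link{bootstrap_within_site}}.
#' @export
heldout_association <- function(heldout, LX, LY, site_labels,
                                n_boot = 1000, partition = NULL,
                                seed = 1L, k = NULL, q = 0.05) {
  heldout <- as.matrix(heldout)
  n <- nrow(heldout)
  if (n < 3L) stop("empty (or near-empty) subject overlap")
  stopifnot(nrow(LX) == n, nrow(LY) == n, length(site_labels) == n,
            n_boot >= 2)
  if (is.null(k)) k <- min(5L, ncol(LX))
  f <- factor(site_labels)
  summarize <- function(ld) {
    if (is.null(partition)) return(ld)
    p_reg <- length(partition)
    apply(ld, 2L, function(v)
      block_vector(block_average_edges(edge_matrix(v, p_reg), partition)))
  }
  obs <- list(
    imaging = summarize(cor_columns(heldout, LX[, seq_len(k),
                                                drop = FALSE])),
    behavior = summarize(cor_columns(heldout, LY[, seq_len(k),
                                                 drop = FALSE])))
  boots <- lapply(obs, function(o) array(NA_real_,
                                         c(nrow(o), ncol(o), n_boot)))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(levels(f), function(lv) {
        members <- which(f == lv)
        sample(members, length(members), replace = TRUE)
      }), use.names = FALSE)
      boots$imaging[, , b] <- summarize(cor_columns(
        heldout[idx, , drop = FALSE], LX[idx, seq_len(k), drop = FALSE]))
      boots$behavior[, , b] <- summarize(cor_columns(
        heldout[idx, , drop = FALSE], LY[idx, seq_len(k), drop = FALSE]))
    }
  })
  out <- lapply(names(obs), function(arm) {
    sds <- apply(boots[[arm]], c(1L, 2L), stats::sd)
    zero_sd <- sds < 1e-12
    z <- obs[[arm]] / sds
    z[zero_sd] <- sign(obs[[arm]][zero_sd]) * Inf
    p <- 2 * stats::pnorm(-abs(z)); p[zero_sd] <- 0
    fdr <- fdr_bh(as.numeric(p), q)
    list(loading = obs[[arm]], sd = sds, z = z, p = p,
         q_adj = matrix(fdr$adjusted, nrow(p), ncol(p)),
         mask = matrix(fdr$mask, nrow(p), ncol(p)),
         ci_lo = apply(boots[[arm]], c(1L, 2L), stats::quantile,
                       probs = 0.025),
         ci_hi = apply(boots[[arm]], c(1L, 2L), stats::quantile,
                       probs = 0.975))
  })
  names(out) <- names(obs)
  out
}

#' Demographic post hoc tests on composite scores
#'
#' Welch t-tests for sex differences and Pearson correlations with age
#' and age squared for each latent component score, BH-FDR corrected
#' across all tests.
#'
#' @param scores Named list of score matrices (e.g. imaging = LX,
#'   behavior = LY), columns = components.
#' @param covariates Covariate table with \code{sex} and \code{age}.
#' @param q FDR level.
#' @return Data.frame: arm, lc, test, statistic, p, q_adj, significant,
#'   skipped.
#' @export
demographic_posthoc <- function(scores, covariates, q = 0.05) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  sex <- factor(covariates$sex)
  one_sex <- nlevels(droplevels(sex)) < 2L
  rows <- list()
  for (arm in names(scores)) {
    sc <- as.matrix(scores[[arm]])
    for (k in seq_len(ncol(sc))) {
      if (one_sex) {
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, lc = k, test = "sex_t", statistic = NA_real_,
          p = NA_real_, skipped = TRUE)
      } else {
        tt <- stats::t.test(sc[, k] ~ sex)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, lc = k, test = "sex_t", statistic = tt$statistic,
          p = tt$p.value, skipped = FALSE)
      }
      for (trm in c("age", "age2")) {
        x <- if (trm == "age") covariates$age else covariates$age^2
        ct <- stats::cor.test(sc[, k], x)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, lc = k, test = paste0(trm, "_r"),
          statistic = ct$estimate, p = ct$p.value, skipped = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p[!out$skipped], q)
  out$q_adj <- NA_real_; out$significant <- FALSE
  out$q_adj[!out$skipped] <- fdr$adjusted
  out$significant[!out$skipped] <- fdr$mask
  rownames(out) <- NULL
  out
}
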