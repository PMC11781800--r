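#' Site-restricted subject permutation
#'
#' Draws a permutation of subject indices that maps each acquisition
#' site's members onto positions of that same site, so that shuffling the
#' behavior rows by it preserves site composition. Sites of size one are
#' left fixed.
#'
#' @param site_labels Factor or vector of site labels, one per subject.
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   used (so callers drawing many permutations seed once).
#' @return Integer permutation vector.
#' @export
permute_within_site <- function(site_labels, seed = NULL) {
  f <- factor(site_labels)
  draw <- function() {
    perm <- seq_along(f)
    for (lv in levels(f)) {
      members <- which(f == lv)
      if (length(members) > 1L) perm[members] <- sample(members)
    }
    perm
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Permutation significance of the latent components
#'
#' Re-runs the PLS singular value decomposition with behavior rows
#' permuted within site and compares the observed singular values of the
#' first \code{k_test} components against their same-index permutation
#' nulls. P-values use add-one smoothing,
#' \code{p = (1 + #\{perm >= obs\}) / (1 + n_perm)}, and are BH-FDR
#' corrected across the tested components.
#'
#' @param X Imaging matrix (subjects x dims).
#' @param Y Behavior matrix (subjects x items).
#' @param site_labels Site labels, one per subject.
#' @param n_perm Number of permutations (>= 1).
#' @param k_test Number of leading components tested (default 5, capped
#'   at the available rank).
#' @param seed Integer seed.
#' @param procrustes Align each permuted solution to the observed
#'   singular vectors before extracting null singular values (sensitivity
#'   variant; default FALSE compares raw same-index singular values).
#' @param covariates,terms Optional confound design. When supplied,
#'   \code{Y} is taken to be confound residuals and every permuted draw
#'   is re-residualized against the same design before the null
#'   decomposition (permutation of residuals with re-projection). Without
#'   this, permuted rows lose the observed data's exact orthogonality to
#'   the design and the test becomes slightly anticonservative.
#' @return Object of class \code{permutation_result}: \code{observed},
#'   \code{null_distribution} (n_perm x k_test), \code{p_values},
#'   \code{fdr_q}, \code{n_perm}.
#' @export
permutation_test <- function(X, Y, site_labels, n_perm, k_test = 5,
                             seed = 1L, procrustes = FALSE,
                             covariates = NULL, terms = NULL) {
  stopifnot(n_perm >= 1)
  Xz <- zscore_columns(X, "X")
  Yz <- zscore_columns(Y, "Y")
  sv <- svd(crossprod(Yz, Xz))
  k_test <- min(k_test, length(sv$d))
  obs <- sv$d[seq_len(k_test)]
  U0 <- sv$u
  refit <- !is.null(covariates) && length(terms) > 0
  Ym <- as.matrix(Y)
  null <- matrix(NA_real_, n_perm, k_test)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- permute_within_site(site_labels)
      Yp <- if (refit)
        zscore_columns(residualize(Ym[perm, , drop = FALSE],
                                   covariates, terms), "Y")
      else Yz[perm, , drop = FALSE]
      svp <- svd(crossprod(Yp, Xz))
      if (procrustes) {
        ## rotate the permuted solution onto the observed singular
        ## vectors, then take column norms as aligned singular values
        m <- svd(crossprod(U0, svp$u))
        rot <- m$v %*% t(m$u)
        us <- svp$u %*% diag(svp$d, length(svp$d)) %*% rot
        dp <- sqrt(colSums(us^2))
      } else dp <- svp$d
      null[b, ] <- dp[seq_len(k_test)]
    }
  })
  p <- vapply(seq_len(k_test), function(k)
    (1 + sum(null[, k] >= obs[k])) / (1 + n_perm), 1.0)
  structure(list(observed = obs, null_distribution = null,
                 p_values = p, fdr_q = stats::p.adjust(p, "BH"),
                 n_perm = n_perm), class = "permutation_result")
}

#' Average edge loadings within and between networks
#'
#' Entry (a, b) of the output is the mean loading over all edges with one
#' endpoint in network a and the other in network b; the diagonal blocks
#' average within-network edges (region-pair diagonal excluded). A
#' network with fewer than two regions has an undefined within block,
#' returned as NA.
#'
#' @param edge_loadings Region x region symmetric matrix of loadings.
#' @param partition Factor of network labels, one per region.
#' @return B x B symmetric matrix of block means (B = number of
#'   networks).
#' @export
block_average_edges <- function(edge_loadings, partition) {
  L <- as.matrix(edge_loadings)
  p <- nrow(L)
  stopifnot(ncol(L) == p, length(partition) == p)
  if (max(abs(L - t(L))) > 1e-8) stop("edge loading matrix not symmetric")
  f <- factor(partition)
  A <- stats::model.matrix(~ f - 1)
  diag(L) <- 0
  sums <- crossprod(A, L %*% A)
  cnt <- table(f)
  counts <- outer(as.numeric(cnt), as.numeric(cnt))
  diag(counts) <- as.numeric(cnt) * (as.numeric(cnt) - 1)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  dimnames(out) <- list(levels(f), levels(f))
  out
}

## lower triangle (incl. diagonal) of a block matrix as a labelled vector
block_vector <- function(bm) {
  idx <- which(lower.tri(bm, diag = TRUE), arr.ind = TRUE)
  v <- bm[idx]
  names(v) <- paste0(rownames(bm)[idx[, 1L]], "|", colnames(bm)[idx[, 2L]])
  v
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' @param p_values Vector of p-values in [0, 1] (NAs tolerated).
#' @param q FDR level (default 0.05).
#' @return List with \code{adjusted} (BH-adjusted p-values) and
#'   \code{mask} (logical rejections at level q).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, mask = !is.na(adj) & adj < q)
}

#' Site-restricted bootstrap of loading stability
#'
#' Resamples subjects with replacement within each site (site sizes
#' preserved), refits the PLS decomposition, sign-aligns each bootstrap
#' component to the original solution, and records the loadings of the
#' requested targets. Z-scores divide each original loading by its
#' bootstrapped standard deviation; p-values are two-sided standard
#' normal, BH-FDR masked at level \code{q}; percentile confidence
#' intervals use the 2.5/97.5 quantiles. Edge targets are averaged within
#' and between networks before Z-scoring.
#'
#' @param X Imaging matrix (subjects x dims).
#' @param Y Behavior matrix (subjects x items).
#' @param site_labels Site labels.
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param targets Named list; each element is a list with \code{data}
#'   (subjects x features matrix), \code{arm} ("imaging" correlates with
#'   LX, "behavior" with LY), and optionally \code{partition} (network
#'   factor marking \code{data} as vectorized edges to be
#'   block-averaged).
#' @param seed Integer seed.
#' @param k Components tracked (default min(5, rank)).
#' @param q FDR level (default 0.05).
#' @return Object of class \code{bootstrap_result}: per target a list
#'   with \code{loading}, \code{sd}, \code{z}, \code{p}, \code{q_adj},
#'   \code{mask}, \code{ci_lo}, \code{ci_hi} (features x k matrices),
#'   plus \code{n_boot_used} and \code{zero_sd} flags.
#' @export
bootstrap_within_site <- function(X, Y, site_labels, n_boot, targets,
                                  seed = 1L, k = NULL, q = 0.05) {
  stopifnot(n_boot >= 2, is.list(targets), length(targets) >= 1L,
            !is.null(names(targets)))
  orig <- pls_decompose(X, Y)
  K <- length(orig$singular_values)
  if (is.null(k)) k <- min(5L, K) else k <- min(k, K)
  f <- factor(site_labels)
  n <- nrow(as.matrix(X))

  target_loadings <- function(res, rows) {
    lapply(targets, function(tg) {
      scores <- if (identical(tg$arm, "behavior")) res$LY else res$LX
      ld <- cor_columns(as.matrix(tg$data)[rows, , drop = FALSE],
                        scores[, seq_len(k), drop = FALSE])
      if (!is.null(tg$partition)) {
        p_reg <- length(tg$partition)
        ld <- apply(ld, 2L, function(v)
          block_vector(block_average_edges(edge_matrix(v, p_reg),
                                           tg$partition)))
      }
      ld
    })
  }

  obs <- target_loadings(orig, seq_len(n))
  boots <- lapply(obs, function(o)
    array(NA_real_, c(nrow(o), k, n_boot)))
  used <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(levels(f), function(lv) {
        members <- which(f == lv)
        sample(members, length(members), replace = TRUE)
      }), use.names = FALSE)
      res <- tryCatch(
        pls_decompose(as.matrix(X)[idx, , drop = FALSE],
                      as.matrix(Y)[idx, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(res)) next
      ## sign-align bootstrap components to the original solution
      flip <- sign(diag(crossprod(
        res$U[, seq_len(k), drop = FALSE],
        orig$U[, seq_len(k), drop = FALSE])))
      flip[flip == 0] <- 1
      res$LX[, seq_len(k)] <- sweep(res$LX[, seq_len(k), drop = FALSE],
                                    2L, flip, "*")
      res$LY[, seq_len(k)] <- sweep(res$LY[, seq_len(k), drop = FALSE],
                                    2L, flip, "*")
      bl <- target_loadings(res, idx)
      used <- used + 1L
      for (tg in names(targets)) boots[[tg]][, , used] <- bl[[tg]]
    }
  })
  if (used < 2L) stop("fewer than two successful bootstrap resamples")
  out <- list()
  for (tg in names(targets)) {
    arr <- boots[[tg]][, , seq_len(used), drop = FALSE]
    sds <- apply(arr, c(1L, 2L), stats::sd)
    zero_sd <- sds < 1e-12
    z <- obs[[tg]] / sds
    z[zero_sd] <- sign(obs[[tg]][zero_sd]) * Inf
    p <- 2 * stats::pnorm(-abs(z))
    p[zero_sd] <- 0
    fdr <- fdr_bh(as.numeric(p), q)
    out[[tg]] <- list(
      loading = obs[[tg]], sd = sds, z = z, p = p,
      q_adj = matrix(fdr$adjusted, nrow(p), ncol(p),
                     dimnames = dimnames(p)),
      mask = matrix(fdr$mask, nrow(p), ncol(p), dimnames = dimnames(p)),
      ci_lo = apply(arr, c(1L, 2L), stats::quantile, probs = 0.025),
      ci_hi = apply(arr, c(1L, 2L), stats::quantile, probs = 0.975),
      zero_sd = zero_sd)
  }
  structure(list(targets = out, n_boot = n_boot, n_boot_used = used,
                 k = k), class = "bootstrap_result")
}
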