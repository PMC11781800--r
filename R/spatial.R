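## Uniform random rotation in SO(3) via QR of a Gaussian matrix.
random_rotation <- function() {
  qd <- qr(matrix(stats::rnorm(9L), 3L))
  q <- qr.Q(qd)
  q <- q %*% diag(sign(diag(qr.R(qd))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Spin permutations of cortical parcels
#'
#' Generates autocorrelation-preserving null permutations by rotating the
#' parcel centroids on the sphere: each spin draws a uniform random
#' rotation, applies it to the left hemisphere and its x-mirrored
#' counterpart to the right, and reassigns each parcel the value of the
#' nearest rotated centroid within its hemisphere (greedy
#' nearest-neighbor, duplicates allowed). Subcortical parcels must be
#' excluded before calling.
#'
#' @param coords Data.frame of cortical parcels with columns
#'   \code{hemisphere} ("L"/"R") and unit-sphere \code{x}, \code{y},
#'   \code{z}.
#' @param n_spin Number of spins.
#' @param seed Integer seed.
#' @return \code{n_spin x P} integer matrix; row s maps parcel i to the
#'   source parcel whose value it receives, i.e.
#'   \code{spun_map <- map[spins[s, ]]}.
#' @export
spin_permutation <- function(coords, n_spin, seed = 1L) {
  stopifnot(n_spin >= 1)
  hemi <- coords$hemisphere
  if (!all(hemi %in% c("L", "R")))
    stop("spin_permutation expects cortical parcels only (hemisphere L/R)")
  p <- nrow(coords)
  if (p < 3L) stop("need at least 3 parcels to spin")
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  mirror <- diag(c(-1, 1, 1))
  out <- matrix(NA_integer_, n_spin, p)
  with_seed(seed, {
    for (s in seq_len(n_spin)) {
      rot <- random_rotation()
      rot_r <- mirror %*% rot %*% mirror
      for (h in c("L", "R")) {
        idx <- which(hemi == h)
        if (!length(idx)) next
        r <- if (h == "L") rot else rot_r
        rotated <- xyz[idx, , drop = FALSE] %*% t(r)
        ## nearest rotated centroid (max inner product on the sphere)
        sim <- tcrossprod(xyz[idx, , drop = FALSE], rotated)
        out[s, idx] <- idx[max.col(sim, ties.method = "first")]
      }
    }
  })
  out
}

#' Spatial correlation with spin-permutation significance
#'
#' Pearson correlation between two parcel maps, with a null distribution
#' obtained by spinning \code{map_a} against the fixed \code{map_b};
#' p-values use add-one smoothing.
#'
#' @param map_a,map_b Numeric parcel maps over the same cortical parcels.
#' @param spins Spin matrix from \code{\link{spin_permutation}}.
#' @param two_sided Two-sided test on |r| (default TRUE).
#' @return Object of class \code{spin_test_result}: \code{observed_r},
#'   \code{null_r}, \code{p_spin}, \code{n_spin}.
#' @export
spin_correlation <- function(map_a, map_b, spins, two_sided = TRUE) {
  stopifnot(length(map_a) == length(map_b), ncol(spins) == length(map_a))
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("zero-variance map")
  obs <- stats::cor(map_a, map_b)
  null_r <- apply(spins, 1L, function(pr) stats::cor(map_a[pr], map_b))
  n_spin <- nrow(spins)
  p <- if (two_sided) (1 + sum(abs(null_r) >= abs(obs))) / (1 + n_spin)
       else (1 + sum(null_r >= obs)) / (1 + n_spin)
  structure(list(observed_r = obs, null_r = null_r, p_spin = p,
                 n_spin = n_spin), class = "spin_test_result")
}

#' Per-parcel within- and between-network connectivity loading summaries
#'
#' Reduces a region x region edge-loading matrix to two cortical parcel
#' maps: the mean loading over each parcel's edges to parcels of its own
#' network, and over its edges to parcels outside it. Signed means by
#' default; absolute means available as a sensitivity variant.
#'
#' @param edge_loadings Region x region symmetric loading matrix.
#' @param partition Network factor, one level per region.
#' @param absolute Use absolute loadings before averaging.
#' @return List with numeric vectors \code{within} and \code{between}.
#' @export
network_loading_maps <- function(edge_loadings, partition,
                                 absolute = FALSE) {
  L <- as.matrix(edge_loadings)
  p <- nrow(L)
  stopifnot(length(partition) == p)
  if (absolute) L <- abs(L)
  diag(L) <- NA
  fi <- as.integer(factor(partition))
  same <- outer(fi, fi, "==")
  within <- vapply(seq_len(p), function(i)
    mean(L[i, same[i, ]], na.rm = TRUE), 1.0)
  between <- vapply(seq_len(p), function(i)
    mean(L[i, !same[i, ]], na.rm = TRUE), 1.0)
  list(within = within, between = between)
}

#' Spatial contextualization of loading maps against a gradient
#'
#' Correlates a set of cortical loading maps (structural modalities,
#' within/between-network connectivity summaries, one per latent
#' component) with a gradient map, assessing each with the spin test and
#' applying BH-FDR across the table.
#'
#' @param maps Named list of numeric cortical parcel maps.
#' @param gradient Numeric gradient map over the same parcels.
#' @param spins Spin matrix from \code{\link{spin_permutation}}.
#' @param q FDR level (default 0.05).
#' @param two_sided Two-sided spin tests (default TRUE).
#' @return Data.frame with columns target, r, p_spin, q_adj, significant.
#' @export
gradient_contextualize <- function(maps, gradient, spins, q = 0.05,
                                   two_sided = TRUE) {
  stopifnot(is.list(maps), length(maps) >= 1L, !is.null(names(maps)))
  rows <- lapply(names(maps), function(nm) {
    st <- spin_correlation(maps[[nm]], gradient, spins, two_sided)
    data.frame(target = nm, r = st$observed_r, p_spin = st$p_spin)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p_spin, q)
  out$q_adj <- fdr$adjusted
  out$significant <- fdr$mask
  rownames(out) <- NULL
  out
}
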