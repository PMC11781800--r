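#' Row-thresholded cosine affinity of a connectivity matrix
#'
#' For each region, keeps only its strongest connections (the top
#' \code{row_top_fraction} of off-diagonal entries per row, ties by first
#' occurrence), zeroes the rest, then computes cosine similarity between
#' the thresholded connectivity profiles. Negative similarities are
#' clamped to zero so the result is a valid diffusion affinity.
#'
#' @param connectivity Square symmetric matrix.
#' @param row_top_fraction Fraction of entries kept per row, in (0, 1];
#'   default 0.1.
#' @return Symmetric nonnegative affinity matrix with unit diagonal.
#' @export
build_affinity <- function(connectivity, row_top_fraction = 0.1) {
  m <- as.matrix(connectivity)
  p <- nrow(m)
  if (ncol(m) != p) stop("connectivity must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("connectivity must be symmetric")
  if (!(row_top_fraction > 0 && row_top_fraction <= 1))
    stop("row_top_fraction must be in (0, 1]")
  keep <- min(p - 1L, ceiling(row_top_fraction * p))
  thr <- matrix(0, p, p)
  for (i in seq_len(p)) {
    row <- m[i, ]
    row[i] <- -Inf
    top <- order(row, decreasing = TRUE)[seq_len(keep)]
    thr[i, top] <- m[i, top]
  }
  nrm <- sqrt(rowSums(thr^2))
  if (any(nrm == 0)) stop("a row has no retained connections")
  aff <- tcrossprod(thr / nrm)
  aff[aff < 0] <- 0
  aff <- (aff + t(aff)) / 2
  dimnames(aff) <- dimnames(m)
  aff
}

#' Diffusion map embedding of an affinity matrix
#'
#' Anisotropic normalization \code{W' = D^-alpha W D^-alpha} followed by
#' the random-walk operator \code{P = D'^-1 W'}, whose nontrivial
#' eigenvectors are the connectivity gradients. \code{alpha} controls the
#' influence of sampling density (0.5 recovers Fokker-Planck
#' normalization); \code{t} scales gradient k by its eigenvalue to the
#' power t (t = 0 leaves eigenvectors unscaled). The trivial constant
#' eigenvector is discarded, and each gradient's sign is fixed so its
#' largest-magnitude entry is positive. The eigenproblem is solved
#' densely on the symmetrically conjugated operator, so results are
#' deterministic.
#'
#' @param affinity Symmetric nonnegative matrix.
#' @param alpha Density-normalization exponent in [0, 1] (default 0.5).
#' @param t Diffusion-time eigenvalue scaling (default 0).
#' @param n_gradients Number of gradients returned (default 10).
#' @return Object of class \code{gradient_result}: \code{embedding}
#'   (parcels x n_gradients), \code{eigenvalues} (full nontrivial
#'   spectrum, nonincreasing, clipped at 0), \code{variance_explained}
#'   (eigenvalue fractions), \code{alignment_rotation} (identity until
#'   aligned), \code{reference_id}.
#' @export
diffusion_embed <- function(affinity, alpha = 0.5, t = 0,
                            n_gradients = 10) {
  w <- as.matrix(affinity)
  p <- nrow(w)
  stopifnot(ncol(w) == p, n_gradients >= 1, alpha >= 0, alpha <= 1)
  if (any(w < 0)) stop("affinity must be nonnegative")
  if (max(abs(w - base::t(w))) > 1e-8) stop("affinity must be symmetric")
  ## connectivity check (warn only): breadth-first search on the graph
  reach <- logical(p); reach[1L] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(w[frontier, , drop = FALSE] > 0) > 0 & !reach)
    reach[nb] <- TRUE
    frontier <- nb
  }
  if (!all(reach)) warning("affinity graph is disconnected; embedding ",
                           "mixes per-component structure")
  d <- rowSums(w)
  if (any(d == 0)) stop("isolated node in affinity")
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  s <- w1 / outer(sqrt(d1), sqrt(d1))
  e <- eigen((s + base::t(s)) / 2, symmetric = TRUE)
  psi <- e$vectors / sqrt(d1)       # random-walk eigenvectors
  psi <- sweep(psi, 2L, sqrt(colSums(psi^2)), "/")
  lam <- e$values
  n_gradients <- min(n_gradients, p - 1L)
  ev <- pmax(lam[-1L], 0)           # drop trivial lambda = 1
  grads <- fix_signs(psi[, 1L + seq_len(n_gradients), drop = FALSE])
  if (t > 0) grads <- sweep(grads, 2L,
                            ev[seq_len(n_gradients)]^t, "*")
  rownames(grads) <- rownames(w)
  colnames(grads) <- paste0("g", seq_len(n_gradients))
  structure(list(embedding = grads, eigenvalues = ev,
                 variance_explained = gradient_variance_explained(ev),
                 alignment_rotation = diag(n_gradients),
                 reference_id = "unaligned"),
            class = "gradient_result")
}

#' Fraction of connectivity variance carried by each gradient
#'
#' Eigenvalue of each diffusion component divided by the sum of the
#' retained spectrum.
#'
#' @param eigenvalues Nonnegative eigenvalues.
#' @return Fractions summing to one.
#' @export
gradient_variance_explained <- function(eigenvalues) {
  stopifnot(all(eigenvalues >= -1e-12))
  eigenvalues <- pmax(eigenvalues, 0)
  tot <- sum(eigenvalues)
  if (tot == 0) stop("all eigenvalues are zero")
  eigenvalues / tot
}

#' Procrustes alignment of gradients to a reference set
#'
#' Finds the orthogonal rotation (reflections allowed, no scaling, no
#' translation beyond column centering) minimizing the Frobenius distance
#' between the source embedding and a reference, and applies it. The
#' unaligned embedding remains available in the input object.
#'
#' @param source A \code{gradient_result}.
#' @param reference Parcels x G matrix of reference gradients
#'   (G <= computed gradients).
#' @param reference_id Label stored with the aligned result.
#' @return New \code{gradient_result} with rotated embedding (first G
#'   columns) and \code{alignment_rotation} set.
#' @export
procrustes_align <- function(source, reference,
                             reference_id = "reference") {
  stopifnot(inherits(source, "gradient_result"))
  ref <- as.matrix(reference)
  G <- ncol(ref)
  src <- source$embedding[, seq_len(G), drop = FALSE]
  if (nrow(ref) != nrow(src)) stop("parcel count mismatch")
  if (G > ncol(source$embedding)) stop("reference has too many gradients")
  src_c <- sweep(src, 2L, colMeans(src), "-")
  ref_c <- sweep(ref, 2L, colMeans(ref), "-")
  m <- svd(crossprod(src_c, ref_c))
  rot <- m$u %*% t(m$v)
  out <- source
  out$embedding <- src_c %*% rot
  colnames(out$embedding) <- paste0("g", seq_len(G))
  rownames(out$embedding) <- rownames(src)
  out$alignment_rotation <- rot
  out$reference_id <- reference_id
  out
}
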