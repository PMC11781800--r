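#' Number of unique edges in a symmetric matrix of a given order
#'
#' Counts the off-diagonal, unordered region pairs of a \code{p x p}
#' connectivity matrix, i.e. \code{p * (p - 1) / 2}.
#'
#' @param p Number of regions (positive integer).
#' @return Integer edge count.
#' @examples
#' n_edges(419)  # 87571 unique connections
#' @export
n_edges <- function(p) {
  stopifnot(length(p) == 1L, p >= 1)
  as.integer(p * (p - 1) / 2)
}

#' Edge index table for a symmetric matrix
#'
#' The canonical vectorization order used throughout the package:
#' lower triangle, row-major, diagonal excluded. Edge \code{e} connects
#' regions \code{i[e] > j[e]}.
#'
#' @param p Number of regions.
#' @return Two-column integer matrix with columns \code{i}, \code{j}.
#' @export
edge_pairs <- function(p) {
  stopifnot(p >= 2)
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Vectorize the unique edges of a symmetric matrix
#'
#' @param m Square symmetric matrix.
#' @return Numeric vector of length \code{n_edges(nrow(m))} in
#'   \code{\link{edge_pairs}} order.
#' @export
vectorize_edges <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[edge_pairs(nrow(m))]
}

#' Rebuild a symmetric matrix from vectorized edges
#'
#' Inverse of \code{\link{vectorize_edges}}; the diagonal is filled with
#' \code{diag_value} (edges carry no diagonal information).
#'
#' @param v Edge vector in \code{\link{edge_pairs}} order.
#' @param p Number of regions.
#' @param diag_value Value placed on the diagonal (default 0).
#' @return \code{p x p} symmetric matrix.
#' @export
edge_matrix <- function(v, p, diag_value = 0) {
  stopifnot(length(v) == n_edges(p))
  m <- matrix(diag_value, p, p)
  ep <- edge_pairs(p)
  m[ep] <- v
  m[ep[, c(2L, 1L)]] <- v
  m
}

## Column z-scoring with the sample (n - 1) SD. Errors on zero-variance
## columns, naming them, because downstream cross-covariances are undefined.
zscore_columns <- function(x, name = "matrix") {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in ", name)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  bad <- which(sd == 0 | !is.finite(sd))
  if (length(bad)) {
    lab <- colnames(x)[bad]
    if (is.null(lab)) lab <- as.character(bad)
    stop("zero-variance column(s) in ", name, ": ",
         paste(utils::head(lab, 5L), collapse = ", "))
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
}

## Fast column-wise Pearson correlation between all columns of a and b.
## Zero-variance columns yield 0 with the "undefined" attribute set.
cor_columns <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  stopifnot(nrow(b) == n, n >= 3L)
  ac <- sweep(a, 2L, colMeans(a), "-")
  bc <- sweep(b, 2L, colMeans(b), "-")
  sa <- sqrt(colSums(ac^2))
  sb <- sqrt(colSums(bc^2))
  num <- crossprod(ac, bc)
  den <- outer(sa, sb)
  out <- num / den
  undef <- den == 0
  if (any(undef)) out[undef] <- 0
  attr(out, "undefined") <- undef
  out
}

## Gram-Schmidt orthonormalization of columns, optionally under a metric G
## (inner product t(a) %*% G %*% b). Used to plant exactly orthogonal
## salience directions.
gram_schmidt <- function(v, G = NULL) {
  v <- as.matrix(v)
  ip <- if (is.null(G)) function(a, b) sum(a * b) else
    function(a, b) as.numeric(crossprod(a, G %*% b))
  out <- v
  for (k in seq_len(ncol(v))) {
    w <- v[, k]
    if (k > 1L) for (j in seq_len(k - 1L)) {
      w <- w - ip(out[, j], w) * out[, j]
    }
    nrm <- sqrt(ip(w, w))
    if (nrm < 1e-12) stop("gram_schmidt: columns are linearly dependent")
    out[, k] <- w / nrm
  }
  out
}

## Deterministic sign convention: flip each column so its largest-magnitude
## entry is positive.
fix_signs <- function(v) {
  v <- as.matrix(v)
  s <- apply(v, 2L, function(x) sign(x[which.max(abs(x))]))
  s[s == 0] <- 1
  sweep(v, 2L, s, "*")
}

## Geodesic (great-circle) angle matrix between unit-sphere points, radians.
geodesic_angles <- function(xyz) {
  g <- tcrossprod(as.matrix(xyz))
  g[g > 1] <- 1; g[g < -1] <- -1
  acos(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
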