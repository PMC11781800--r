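#' PLS correlation between an imaging matrix and behavior items
#'
#' Symmetric partial least squares: both matrices are z-scored across
#' subjects (sample SD), the cross-covariance \code{R = t(Y) \%*\% X} is
#' formed and decomposed by SVD \code{R = U S t(V)}. Each latent component
#' (LC) is a singular-vector pair (behavioral and imaging saliences) with
#' its singular value; composite scores are the projections
#' \code{LX = X V}, \code{LY = Y U}. Loadings are Pearson correlations of
#' the original variables with the matching composite score. Component
#' signs are fixed so the largest-magnitude behavior loading of each LC is
#' positive.
#'
#' @param X Subjects x imaging-dimensions matrix (typically a
#'   \code{reduced_matrix} of concatenated PCA scores).
#' @param Y Subjects x items matrix (ordinal items are used as numeric).
#' @return Object of class \code{pls_result}: \code{U}, \code{V},
#'   \code{singular_values}, \code{LX}, \code{LY},
#'   \code{covariance_explained}, \code{behavior_loadings},
#'   \code{lc_correlations}, \code{lc_correlation_defined}, plus the
#'   z-scored inputs (\code{Xz}, \code{Yz}) and the modality column
#'   ranges of \code{X} when present.
#' @export
pls_decompose <- function(X, Y) {
  blocks <- attr(X, "blocks")
  Xz <- zscore_columns(X, "X")
  Yz <- zscore_columns(Y, "Y")
  if (nrow(Xz) != nrow(Yz)) stop("X and Y disagree on subject count")
  R <- crossprod(Yz, Xz)
  sv <- svd(R)
  U <- sv$u; V <- sv$v; d <- sv$d
  LX <- Xz %*% V
  LY <- Yz %*% U
  bl <- cor_columns(Y, LY)
  ## joint sign flip per component: dominant behavior loading positive
  for (k in seq_along(d)) {
    m <- which.max(abs(bl[, k]))
    if (bl[m, k] < 0) {
      U[, k] <- -U[, k]; V[, k] <- -V[, k]
      LX[, k] <- -LX[, k]; LY[, k] <- -LY[, k]
      bl[, k] <- -bl[, k]
    }
  }
  cc <- cor_columns(LX, LY)
  lc_r <- diag(cc)
  defined <- !diag(attr(cc, "undefined"))
  rownames(U) <- colnames(Y); rownames(V) <- colnames(X)
  colnames(LX) <- colnames(LY) <- paste0("LC", seq_along(d))
  structure(list(
    U = U, V = V, singular_values = d,
    LX = LX, LY = LY,
    covariance_explained = covariance_explained(d),
    behavior_loadings = bl,
    lc_correlations = lc_r,
    lc_correlation_defined = defined,
    Xz = Xz, Yz = Yz, blocks = blocks), class = "pls_result")
}

#' Covariance explained by each latent component
#'
#' Squared singular value divided by the sum of squared singular values.
#'
#' @param singular_values Nonnegative singular values.
#' @return Fractions summing to one.
#' @export
covariance_explained <- function(singular_values) {
  stopifnot(all(singular_values >= 0))
  tot <- sum(singular_values^2)
  if (tot == 0) stop("all singular values are zero")
  singular_values^2 / tot
}

#' Relative contribution of one modality to the imaging composites
#'
#' Correlates the full imaging composite scores \code{X V} with
#' modality-specific composites \code{X V_mod}, where \code{V_mod} keeps
#' only the salience rows belonging to the modality and zeroes the rest.
#'
#' @param result A \code{\link{pls_decompose}} result whose \code{X}
#'   carried modality column ranges.
#' @param modality Modality name.
#' @return Numeric vector of per-component correlations; components whose
#'   modality-specific composite has no variance are reported as 0 with
#'   attribute \code{undefined}.
#' @export
modality_contribution <- function(result, modality) {
  stopifnot(inherits(result, "pls_result"))
  if (is.null(result$blocks)) stop("result carries no modality ranges")
  if (!modality %in% names(result$blocks))
    stop("unknown modality: ", modality)
  keep <- result$blocks[[modality]]
  Vmod <- result$V * 0
  Vmod[keep, ] <- result$V[keep, , drop = FALSE]
  Lmod <- result$Xz %*% Vmod
  cc <- cor_columns(result$LX, Lmod)
  out <- diag(cc)
  attr(out, "undefined") <- diag(attr(cc, "undefined"))
  out
}

#' Loadings of original features on the latent components
#'
#' Pearson correlation of every original variable with the matching
#' composite score: imaging blocks against the imaging composites
#' \code{LX}, behavior against \code{LY}.
#'
#' @param result A \code{pls_result}.
#' @param blocks Named list of subjects x features matrices in original
#'   feature space (same subjects as the fit).
#' @param arm "imaging" (correlate with LX, default) or "behavior"
#'   (correlate with LY).
#' @return Named list of features x K loading matrices.
#' @export
project_loadings_back <- function(result, blocks,
                                  arm = c("imaging", "behavior")) {
  stopifnot(inherits(result, "pls_result"))
  arm <- match.arg(arm)
  scores <- if (arm == "imaging") result$LX else result$LY
  lapply(blocks, function(b) {
    b <- as.matrix(b)
    if (nrow(b) != nrow(scores)) stop("subject count mismatch")
    cor_columns(b, scores)
  })
}
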