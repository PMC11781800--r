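#' Per-modality PCA with variance-threshold retention
#'
#' Principal components analysis on a column-centered (optionally
#' standardized) residual block, retaining the smallest number of
#' components whose cumulative explained-variance ratio reaches
#' \code{variance_threshold}. Everything needed to project unseen data is
#' stored. Computed via eigendecomposition of the smaller of the two Gram
#' matrices, so wide blocks (edges) stay tractable.
#'
#' @param block Subjects x features numeric matrix.
#' @param variance_threshold Cumulative explained-variance target in
#'   (0, 1]; default 0.5.
#' @param standardize Scale features to unit variance before PCA
#'   (default FALSE: features within a modality share units).
#' @param modality Optional modality name stored with the model.
#' @return Object of class \code{pca_model}: \code{means}, \code{sds}
#'   (NULL unless standardized), \code{loadings} (features x k),
#'   \code{evr} (explained-variance ratios, full spectrum), \code{k},
#'   \code{modality}.
#' @export
fit_pca <- function(block, variance_threshold = 0.5, standardize = FALSE,
                    modality = NULL) {
  block <- as.matrix(block)
  n <- nrow(block); p <- ncol(block)
  if (n < 2L) stop("need more than one subject")
  if (!(variance_threshold > 0 && variance_threshold <= 1))
    stop("variance_threshold must be in (0, 1]")
  mu <- colMeans(block)
  xc <- sweep(block, 2L, mu, "-")
  sds <- NULL
  if (standardize) {
    sds <- apply(block, 2L, stats::sd)
    if (any(sds == 0)) stop("zero-variance feature; cannot standardize")
    xc <- sweep(xc, 2L, sds, "/")
  }
  if (p <= n) {
    e <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
    vals <- pmax(e$values, 0)
    vecs <- e$vectors
  } else {
    e <- eigen(tcrossprod(xc) / (n - 1), symmetric = TRUE)
    vals <- pmax(e$values, 0)
    pos <- vals > max(vals) * 1e-12
    vecs <- crossprod(xc, e$vectors[, pos, drop = FALSE])
    vecs <- sweep(vecs, 2L, sqrt(colSums(vecs^2)), "/")
    vals <- vals[pos]
  }
  tot <- sum(vals)
  if (tot == 0) stop("block has no variance")
  evr <- vals / tot
  k <- which(cumsum(evr) >= variance_threshold - 1e-12)[1L]
  w <- fix_signs(vecs[, seq_len(k), drop = FALSE])
  rownames(w) <- colnames(block)
  structure(list(means = mu, sds = sds, loadings = w, evr = evr, k = k,
                 n_features = p, modality = modality,
                 variance_threshold = variance_threshold),
            class = "pca_model")
}

#' Project data onto a fitted PCA model
#'
#' Applies the stored centering (and scaling) and loading matrix; no
#' re-fitting, so discovery-fit models transfer unchanged to replication
#' data.
#'
#' @param model A \code{\link{fit_pca}} model.
#' @param block Subjects x features matrix with the same feature count.
#' @return Subjects x k score matrix.
#' @export
pca_transform <- function(model, block) {
  stopifnot(inherits(model, "pca_model"))
  block <- as.matrix(block)
  if (ncol(block) != model$n_features)
    stop("feature count mismatch: got ", ncol(block), ", expected ",
         model$n_features)
  xc <- sweep(block, 2L, model$means, "-")
  if (!is.null(model$sds)) xc <- sweep(xc, 2L, model$sds, "/")
  sc <- xc %*% model$loadings
  colnames(sc) <- paste0(model$modality %||% "pc", ":PC",
                         seq_len(model$k))
  sc
}

#' Fit per-modality PCA models over all blocks
#'
#' @param blocks Named list of subjects x features matrices.
#' @param variance_threshold Cumulative explained-variance target.
#' @param standardize Standardize features before PCA.
#' @return Named list of \code{pca_model}s (class \code{reduction_model})
#'   in block order.
#' @export
reduce_fit <- function(blocks, variance_threshold = 0.5,
                       standardize = FALSE) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  models <- mapply(function(b, nm) fit_pca(b, variance_threshold,
                                           standardize, modality = nm),
                   blocks, names(blocks), SIMPLIFY = FALSE)
  structure(models, class = "reduction_model")
}

#' Concatenate per-modality PCA scores into one imaging matrix
#'
#' Horizontal concatenation in fixed modality order with column labels
#' \code{"modality:PCk"}; the per-modality column ranges are kept as the
#' \code{"blocks"} attribute so saliences can later be split by modality.
#'
#' @param models A \code{reduction_model} (or list of \code{pca_model}s).
#' @param blocks Named list of matrices matching the models; score blocks
#'   are computed via \code{\link{pca_transform}}.
#' @return Subjects x total-components matrix (class
#'   \code{reduced_matrix}) with attribute \code{blocks}: named list of
#'   column index vectors.
#' @export
concatenate_scores <- function(models, blocks) {
  stopifnot(length(models) >= 1L, all(names(models) %in% names(blocks)))
  ns <- vapply(blocks, nrow, 1L)
  if (length(unique(ns)) != 1L) stop("blocks disagree on subject count")
  score_list <- lapply(names(models), function(nm)
    pca_transform(models[[nm]], blocks[[nm]]))
  out <- do.call(cbind, score_list)
  widths <- vapply(score_list, ncol, 1L)
  ends <- cumsum(widths)
  ranges <- mapply(function(a, b) seq.int(a, b), ends - widths + 1L, ends,
                   SIMPLIFY = FALSE)
  names(ranges) <- names(models)
  attr(out, "blocks") <- ranges
  class(out) <- c("reduced_matrix", class(out))
  out
}

#' Transform new data through a fitted reduction model
#'
#' @param models A \code{reduction_model}.
#' @param blocks Named list of matrices (replication data).
#' @return \code{reduced_matrix} of scores.
#' @export
reduce_transform <- function(models, blocks) concatenate_scores(models, blocks)
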