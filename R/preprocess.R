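#' Covariate terms used to residualize each modality
#'
#' Every block is adjusted for age, age squared, sex, site and ethnicity.
#' Cortical thickness and volume are additionally adjusted for total
#' intracranial volume, surface area for total surface area, and
#' (rest or task) functional connectivity for head motion (mean FD) and
#' image intensity (mean DVARS). Diffusion metrics (FA/MD) use the base
#' terms, optionally with motion.
#'
#' @param modality One of "area", "thickness", "volume", "rsfc",
#'   "taskfc" (or any name starting with "taskfc"), "fa", "md",
#'   "behavior".
#' @param include_motion_for_dwi Add mean FD/DVARS for fa/md (control
#'   analysis variant).
#' @return Character vector of covariate names understood by
#'   \code{\link{residualize}}.
#' @export
modality_covariates <- function(modality, include_motion_for_dwi = FALSE) {
  base <- c("age", "age2", "sex", "site", "ethnicity")
  if (startsWith(modality, "taskfc")) modality <- "taskfc"
  switch(modality,
    area = c(base, "total_area"),
    thickness = c(base, "icv"),
    volume = c(base, "icv"),
    rsfc = c(base, "mean_fd", "mean_dvars"),
    taskfc = c(base, "mean_fd", "mean_dvars"),
    fa = ,
    md = if (include_motion_for_dwi) c(base, "mean_fd", "mean_dvars")
         else base,
    behavior = base,
    stop("unknown modality: ", modality))
}

## Build the residualization design matrix (intercept + encoded terms).
build_design <- function(covariates, terms) {
  n <- nrow(covariates)
  if (length(terms) == 0L) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "intercept")))
  cols <- list(intercept = rep(1, n))
  for (tm in terms) {
    if (tm == "age2") {
      cols[["age2"]] <- covariates$age^2
    } else if (is.factor(covariates[[tm]]) ||
               is.character(covariates[[tm]])) {
      f <- droplevels(factor(covariates[[tm]]))
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(mm) <- paste0(tm, levels(f)[-1L])
        for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
      }
    } else {
      if (is.null(covariates[[tm]])) stop("unknown covariate term: ", tm)
      cols[[tm]] <- covariates[[tm]]
    }
  }
  do.call(cbind, cols)
}

#' Regress confounds out of a data block
#'
#' Per-feature ordinary least squares residuals against an intercept plus
#' the requested covariate terms. Categorical terms are dummy-coded
#' (first-level reference); \code{"age2"} adds the square of age.
#'
#' @param block Subjects x features numeric matrix.
#' @param covariates Data.frame with one row per subject.
#' @param terms Character vector of covariate names (see
#'   \code{\link{modality_covariates}}); empty means intercept-only
#'   (column centering).
#' @return Residual matrix of the same dimension; residuals are orthogonal
#'   to every design column.
#' @export
residualize <- function(block, covariates, terms) {
  block <- as.matrix(block)
  stopifnot(nrow(block) == nrow(covariates))
  D <- build_design(covariates, terms)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    bad <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qd, block)
  dimnames(res) <- dimnames(block)
  res
}

#' Drop items with no variance within a subject subset
#'
#' Symptom items on which every subject in \code{idx} gives the same
#' response carry no information and break z-scoring; they are removed,
#' mirroring the removal of an all-zero item from a discovery cohort.
#'
#' @param behavior Subjects x items matrix.
#' @param idx Subject indices defining the subset (default: all).
#' @return List with \code{behavior} (filtered matrix, all subjects) and
#'   \code{dropped} (character vector of removed item names).
#' @export
drop_invariant_items <- function(behavior, idx = NULL) {
  behavior <- as.matrix(behavior)
  if (is.null(idx)) idx <- seq_len(nrow(behavior))
  v <- apply(behavior[idx, , drop = FALSE], 2L, stats::var)
  drop <- which(v == 0)
  if (length(drop) == ncol(behavior))
    stop("all items are invariant in the given subset")
  dropped <- colnames(behavior)[drop]
  if (is.null(dropped)) dropped <- as.character(drop)
  if (length(drop)) {
    message("dropping ", length(drop), " invariant item(s): ",
            paste(dropped, collapse = ", "))
    behavior <- behavior[, -drop, drop = FALSE]
  }
  list(behavior = behavior, dropped = dropped)
}

#' Overall psychopathology score
#'
#' First principal-component score of the centered item matrix, signed so
#' that it correlates positively with the item total; used as a matching
#' variable for the discovery/replication split.
#'
#' @param behavior Subjects x items matrix.
#' @return Numeric subject-length vector.
#' @export
overall_psychopathology <- function(behavior) {
  behavior <- as.matrix(behavior)
  stopifnot(ncol(behavior) >= 2L)
  pc <- stats::prcomp(behavior, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1L]
  tot <- rowSums(behavior)
  if (stats::sd(tot) > 0 && stats::cor(score, tot) < 0) score <- -score
  as.numeric(score)
}

## quartile bin labels (ties collapsed)
quartile_bins <- function(x) {
  qs <- unique(stats::quantile(x, probs = c(0.25, 0.5, 0.75)))
  cut(x, breaks = c(-Inf, qs, Inf), labels = FALSE)
}

#' Matched discovery/replication split
#'
#' Stratified randomization: subjects are binned by site, sex, ethnicity,
#' age quartile and overall-psychopathology quartile, and each cell is
#' split as close to \code{fraction} as integer counts allow. Cells
#' smaller than \code{min_cell} are merged upward by dropping
#' stratification variables (psychopathology, then age, then ethnicity,
#' then sex) until every cell is large enough.
#'
#' @param covariates Covariate data.frame (columns sex, site, ethnicity,
#'   age).
#' @param overall_psy Overall psychopathology score vector.
#' @param fraction Target discovery fraction, in (0, 1); default 2/3.
#' @param seed Integer seed.
#' @param min_cell Smallest allowed stratum (default 3).
#' @return List (class \code{split_result}) with \code{discovery_idx},
#'   \code{replication_idx}, \code{balance_report} (standardized mean
#'   differences), and \code{merge_log}.
#' @export
matched_split <- function(covariates, overall_psy, fraction = 2 / 3,
                          seed = 1L, min_cell = 3L) {
  stopifnot(fraction > 0, fraction < 1,
            nrow(covariates) == length(overall_psy))
  n <- nrow(covariates)
  vars <- list(site = factor(covariates$site),
               sex = factor(covariates$sex),
               ethnicity = factor(covariates$ethnicity),
               age_q = quartile_bins(covariates$age),
               psy_q = quartile_bins(overall_psy))
  level <- length(vars)
  labels <- interaction(vars[seq_len(level)], drop = TRUE)
  merge_log <- character()
  while (level > 1L && min(table(labels)) < min_cell) {
    level <- level - 1L
    merge_log <- c(merge_log, paste0(
      "merged strata upward: dropped ", names(vars)[level + 1L]))
    labels <- interaction(vars[seq_len(level)], drop = TRUE)
  }
  disc <- logical(n)
  with_seed(seed, {
    for (cell in levels(labels)) {
      members <- which(labels == cell)
      m <- length(members)
      nd <- floor(fraction * m)
      if (stats::runif(1) < fraction * m - nd) nd <- nd + 1L
      nd <- min(nd, m)
      disc[sample(members, nd)] <- TRUE
    }
  })
  smd <- function(x) {
    a <- x[disc]; b <- x[!disc]
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (!is.finite(sp) || sp == 0) return(0)
    (mean(a) - mean(b)) / sp
  }
  report <- data.frame(variable = character(), smd = numeric())
  for (v in c("age")) report <- rbind(report, data.frame(
    variable = v, smd = smd(covariates[[v]])))
  report <- rbind(report, data.frame(variable = "overall_psy",
                                     smd = smd(overall_psy)))
  for (v in c("sex", "site", "ethnicity")) {
    f <- factor(covariates[[v]])
    for (lv in levels(f)) report <- rbind(report, data.frame(
      variable = paste0(v, ":", lv), smd = smd(as.numeric(f == lv))))
  }
  structure(list(discovery_idx = which(disc),
                 replication_idx = which(!disc),
                 balance_report = report, merge_log = merge_log),
            class = "split_result")
}
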