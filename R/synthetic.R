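#' Configuration for the synthetic multi-site cohort generator
#'
#' Defines the study conditions emulated by \code{\link{generate_dataset}}:
#' a multi-site pediatric cohort with per-parcel structural measures
#' (surface area, cortical thickness, cortical volume), vectorized
#' region-pair functional connectivity, and parent-rated ordinal symptom
#' items (0/1/2) whose covariance with imaging is carried by a small number
#' of planted latent components.
#'
#' @param n_subjects Number of subjects.
#' @param n_sites Number of acquisition sites.
#' @param n_parcels_cortical Cortical parcels (default 400).
#' @param n_parcels_subcortical Subcortical parcels (default 19).
#' @param n_items Ordinal symptom items (default 118).
#' @param n_latent Number of planted latent components (default 3).
#' @param latent_strength Per-component signal-to-noise: the SD of the
#'   planted signal along each salience direction relative to unit noise
#'   on the matching composite. Default \code{c(5, 3, 2)}.
#' @param item_thresholds Two increasing cut-points per item mapping the
#'   continuous symptom propensity (unit variance) to ordinal 0/1/2.
#'   Either a length-2 vector recycled across items or an
#'   \code{n_items x 2} matrix. The default \code{c(0.8, 1.8)} makes "0"
#'   the modal response, as in right-skewed community symptom scales.
#' @param confound_strength Magnitude of age/sex/site/ethnicity (and, for
#'   connectivity, motion) effects injected into imaging and behavior.
#' @param spatial_smoothing_fwhm FWHM (degrees on the sphere) of the
#'   spatial autocorrelation of cortical maps.
#' @param gradient_strength Relative strength of the planted connectivity
#'   gradient versus network-block structure.
#' @param seed Integer RNG seed; the full dataset is reproducible from it.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects = 500, n_sites = 5,
                         n_parcels_cortical = 400,
                         n_parcels_subcortical = 19,
                         n_items = 118, n_latent = 3,
                         latent_strength = c(5, 3, 2),
                         item_thresholds = c(0.8, 1.8),
                         confound_strength = 0.3,
                         spatial_smoothing_fwhm = 25,
                         gradient_strength = 1,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, n_sites >= 1, n_parcels_cortical >= 4,
            n_parcels_subcortical >= 0, n_items >= 2, n_latent >= 1,
            confound_strength >= 0, spatial_smoothing_fwhm >= 0,
            gradient_strength >= 0)
  if (length(latent_strength) != n_latent || any(latent_strength < 0))
    stop("latent_strength must hold ", n_latent, " nonnegative values")
  th <- item_thresholds
  if (is.null(dim(th))) {
    if (length(th) != 2L) stop("item_thresholds must have two cut-points")
    th <- matrix(th, n_items, 2L, byrow = TRUE)
  }
  th <- as.matrix(th)
  if (nrow(th) != n_items || ncol(th) != 2L)
    stop("item_thresholds must be n_items x 2")
  if (any(th[, 2L] <= th[, 1L]))
    stop("item_thresholds must be strictly increasing per item")
  p_total <- 3L * n_parcels_cortical +
    n_edges(n_parcels_cortical + n_parcels_subcortical)
  if (n_latent > min(n_items, p_total))
    stop("configuration error: n_latent exceeds min(n_items, features)")
  structure(list(
    n_subjects = as.integer(n_subjects), n_sites = as.integer(n_sites),
    n_parcels_cortical = as.integer(n_parcels_cortical),
    n_parcels_subcortical = as.integer(n_parcels_subcortical),
    n_items = as.integer(n_items), n_latent = as.integer(n_latent),
    latent_strength = as.numeric(latent_strength),
    item_thresholds = th,
    confound_strength = confound_strength,
    spatial_smoothing_fwhm = spatial_smoothing_fwhm,
    gradient_strength = gradient_strength,
    seed = as.integer(seed)), class = "synth_config")
}

#' Parcel sphere coordinates and network partition
#'
#' Builds deterministic parcellation assets for a synthetic cohort:
#' unit-sphere parcel centroids with left-hemisphere points mirrored to the
#' right, and an assignment of every cortical parcel to one of
#' \code{n_networks - 1} spatially contiguous cortical networks (mirrored
#' across hemispheres) with all subcortical parcels collected in one
#' subcortical group.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @param n_networks Total number of networks including the subcortical
#'   group (default 18, i.e. 17 cortical networks + subcortex).
#' @return List with \code{coords} (data.frame: parcel_id, hemisphere,
#'   x, y, z) and \code{partition} (factor of network labels named by
#'   parcel_id), class \code{parcellation_assets}.
#' @export
generate_parcellation_assets <- function(cfg, n_networks = 18) {
  stopifnot(inherits(cfg, "synth_config"), n_networks >= 2)
  nc <- cfg$n_parcels_cortical; ns <- cfg$n_parcels_subcortical
  n_cort_net <- n_networks - 1L
  if (n_cort_net > nc)
    stop("configuration error: n_networks exceeds cortical parcel count")
  nL <- as.integer(ceiling(nc / 2)); nR <- nc - nL
  ## Fibonacci-style low-discrepancy lattice restricted to the x < 0
  ## half-sphere; the right hemisphere is its x-mirror.
  i <- seq_len(nL)
  z <- -1 + 2 * (i - 0.5) / nL
  az <- pi / 2 + pi * ((i * (sqrt(5) - 1) / 2) %% 1)
  r <- sqrt(pmax(0, 1 - z^2))
  left <- cbind(x = r * cos(az), y = r * sin(az), z = z)
  right <- left[seq_len(nR), , drop = FALSE]
  right[, "x"] <- -right[, "x"]
  ids_L <- sprintf("ctx_L_%03d", seq_len(nL))
  ids_R <- sprintf("ctx_R_%03d", seq_len(nR))
  coords <- data.frame(
    parcel_id = c(ids_L, ids_R),
    hemisphere = c(rep("L", nL), rep("R", nR)),
    rbind(left, right), stringsAsFactors = FALSE)
  if (ns > 0) {
    ## Subcortical centroids on a tight polar cap; excluded from spins.
    j <- seq_len(ns)
    zz <- -cos(0.08 + 0.02 * j)
    aa <- 2 * pi * j / ns
    rr <- sqrt(pmax(0, 1 - zz^2))
    coords <- rbind(coords, data.frame(
      parcel_id = sprintf("sc_%03d", j), hemisphere = "SC",
      x = rr * cos(aa), y = rr * sin(aa), z = zz,
      stringsAsFactors = FALSE))
  }
  rownames(coords) <- NULL
  ## Mirror-symmetric cortical networks: cluster left-hemisphere centroids,
  ## assign each right parcel the network of its mirrored left counterpart.
  net_left <- with_seed(cfg$seed + 101L, {
    if (n_cort_net == 1L) rep(1L, nL)
    else stats::kmeans(left, centers = n_cort_net, nstart = 5L,
                       iter.max = 50L)$cluster
  })
  labels <- c(sprintf("net%02d", net_left),
              sprintf("net%02d", net_left[seq_len(nR)]))
  if (ns > 0) labels <- c(labels, rep("subcortical", ns))
  partition <- factor(labels)
  names(partition) <- coords$parcel_id
  structure(list(coords = coords, partition = partition,
                 n_networks = if (ns > 0) n_cort_net + 1L else n_cort_net),
            class = "parcellation_assets")
}

#' Basis for spatially autocorrelated maps on parcel centroids
#'
#' Square-root factor of a Gaussian geodesic covariance kernel; multiplying
#' it by i.i.d. normal deviates yields a smooth random field with unit
#' marginal variance sampled at the centroids.
#'
#' @param xyz Matrix or data.frame of unit-sphere coordinates (columns
#'   x, y, z).
#' @param fwhm Kernel full-width at half-maximum in degrees; 0 gives the
#'   identity (i.i.d. field).
#' @return Numeric matrix \code{P x r}.
#' @export
smooth_map_basis <- function(xyz, fwhm) {
  xyz <- as.matrix(xyz[, c("x", "y", "z")])
  p <- nrow(xyz)
  if (fwhm <= 0) return(diag(p))
  sigma <- fwhm * pi / 180 / (2 * sqrt(2 * log(2)))
  k <- exp(-geodesic_angles(xyz)^2 / (2 * sigma^2))
  e <- eigen(k, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  m <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                sum(keep))
  rn <- sqrt(rowSums(m^2))
  m / rn
}

#' Smooth random map on the sphere
#'
#' Zero-mean Gaussian random field sampled at parcel centroids, with
#' spatial autocorrelation controlled by \code{fwhm}.
#'
#' @param coords Data.frame with columns x, y, z (unit-sphere centroids).
#' @param fwhm Smoothing FWHM in degrees (0 = independent values).
#' @param seed Integer seed.
#' @param basis Optional precomputed \code{\link{smooth_map_basis}}; pass
#'   it when drawing many maps on the same parcellation.
#' @return Numeric vector of length \code{nrow(coords)} with mean zero.
#' @export
generate_smooth_map <- function(coords, fwhm, seed, basis = NULL) {
  stopifnot(fwhm >= 0)
  if (is.null(basis)) basis <- smooth_map_basis(coords, fwhm)
  map <- with_seed(seed, as.numeric(basis %*% stats::rnorm(ncol(basis))))
  map - mean(map)
}

## ---- internal pieces of the generator ------------------------------------

## Confound effects: n x p matrix of additive shifts built from the
## covariate table. 'use' selects which effects apply to the block.
confound_effects <- function(cov, p, strength,
                             use = c("age", "sex", "site", "ethnicity")) {
  n <- nrow(cov)
  eff <- matrix(0, n, p)
  if (strength <= 0 || p == 0) return(eff)
  zs <- function(x) as.numeric(scale(x))
  if ("age" %in% use) {
    eff <- eff + outer(zs(cov$age), stats::rnorm(p, 0, 0.5)) +
      outer(zs(cov$age^2), stats::rnorm(p, 0, 0.3))
  }
  if ("sex" %in% use)
    eff <- eff + outer(as.numeric(cov$sex == "M") - 0.5,
                       stats::rnorm(p, 0, 0.5))
  if ("site" %in% use) {
    shifts <- matrix(stats::rnorm(nlevels(cov$site) * p, 0, 0.5),
                     nlevels(cov$site), p)
    eff <- eff + shifts[as.integer(cov$site), , drop = FALSE]
  }
  if ("ethnicity" %in% use) {
    shifts <- matrix(stats::rnorm(nlevels(cov$ethnicity) * p, 0, 0.3),
                     nlevels(cov$ethnicity), p)
    eff <- eff + shifts[as.integer(cov$ethnicity), , drop = FALSE]
  }
  if ("motion" %in% use)
    eff <- eff + outer(zs(cov$mean_fd), stats::rnorm(p, 0, 0.4))
  if ("icv" %in% use)
    eff <- eff + outer(zs(cov$icv), stats::rnorm(p, 0, 0.4))
  if ("total_area" %in% use)
    eff <- eff + outer(zs(cov$total_area), stats::rnorm(p, 0, 0.4))
  strength * eff
}

## Simulated covariate table for a multi-site pediatric cohort.
simulate_covariates <- function(n, n_sites) {
  w <- stats::runif(n_sites, 0.7, 1.3)
  site <- sample.int(n_sites, n, replace = TRUE, prob = w / sum(w))
  ## guarantee every site has at least two members
  for (s in seq_len(n_sites)) {
    while (sum(site == s) < min(2L, n %/% n_sites + 1L)) {
      big <- which.max(tabulate(site, n_sites))
      site[which(site == big)[1L]] <- s
    }
  }
  icv <- stats::rnorm(n, 1.45e6, 1.3e5)
  data.frame(
    age = stats::runif(n, 9, 11),
    sex = factor(sample(c("F", "M"), n, TRUE, prob = c(0.49, 0.51))),
    site = factor(sprintf("site%02d", site)),
    ethnicity = factor(sample(sprintf("eth%d", 1:5), n, TRUE,
                              prob = c(0.5, 0.2, 0.15, 0.1, 0.05))),
    mean_fd = exp(stats::rnorm(n, -1.6, 0.5)),
    mean_dvars = stats::rnorm(n, 50, 5),
    icv = icv,
    total_area = 1.7e5 + 0.08 * (icv - 1.45e6) + stats::rnorm(n, 0, 6e3))
}

#' Generate a synthetic multimodal dataset with known ground truth
#'
#' Draws a multi-site cohort in which imaging-behavior covariance is
#' carried entirely by \code{n_latent} planted components. Structural
#' blocks (area, thickness, volume) receive spatially smooth salience
#' maps; connectivity is built per subject as a factor model
#' \code{C = B diag(lambda) B' + D} with network-block and
#' gradient-structured columns of \code{B} (positive semi-definite by
#' construction), and latent signal enters through subject-specific factor
#' strengths \code{lambda}. Ordinal items arise by thresholding a Gaussian
#' propensity that loads on the same subject factors.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @param n_networks Networks used for the connectivity block structure
#'   (default 18; reduced automatically if the parcel count is small).
#' @return List with elements \code{dataset} (class
#'   \code{multimodal_dataset}: modality_blocks, behavior, covariates,
#'   subject_ids, rsfc_diagonal, assets) and \code{truth} (class
#'   \code{synthetic_truth}: behavior_saliences, imaging_saliences,
#'   subject_scores, planted_gradient, site_assignment).
#' @export
generate_dataset <- function(cfg, n_networks = 18) {
  stopifnot(inherits(cfg, "synth_config"))
  n_networks <- min(n_networks, max(2L, cfg$n_parcels_cortical %/% 4L))
  assets <- generate_parcellation_assets(cfg, n_networks)
  with_seed(cfg$seed, {
    n <- cfg$n_subjects; L <- cfg$n_latent
    nc <- cfg$n_parcels_cortical; ns <- cfg$n_parcels_subcortical
    P <- nc + ns
    s <- cfg$latent_strength
    coords <- assets$coords
    ctx <- coords$hemisphere != "SC"
    cov <- simulate_covariates(n, cfg$n_sites)

    ## subject factor scores
    F <- matrix(stats::rnorm(n * L), n, L)

    ## behavior saliences: dominant all-positive general factor, then
    ## orthogonal sub-factors (Gram-Schmidt)
    U0 <- cbind(abs(stats::rnorm(cfg$n_items, 1, 0.3)),
                matrix(stats::rnorm(cfg$n_items * max(0L, L - 1L)),
                       cfg$n_items))[, seq_len(L), drop = FALSE]
    U0 <- gram_schmidt(U0)

    ## planted cortical gradient (smooth, zero-mean)
    sm_basis <- smooth_map_basis(coords[ctx, ], 45)
    g_ctx <- as.numeric(sm_basis %*% stats::rnorm(ncol(sm_basis)))
    gradient <- numeric(P)
    gradient[ctx] <- g_ctx
    gradient <- gradient - mean(gradient)

    ## structural salience maps: smooth, orthonormal within each block
    sal_basis <- smooth_map_basis(coords[ctx, ],
                                  max(cfg$spatial_smoothing_fwhm, 15))
    struct_sal <- lapply(1:3, function(b) {
      raw <- sal_basis %*% matrix(stats::rnorm(ncol(sal_basis) * L),
                                  ncol(sal_basis))
      gram_schmidt(raw)
    })

    ## connectivity factor columns: a smooth 1-D manifold along the
    ## planted gradient (leading eigenvectors of a Laplacian kernel on
    ## the rank-uniformized cortical gradient), network indicators, then
    ## dense noise columns; orthonormalized by QR
    ngr <- min(8L, max(1L, nc %/% 4L))
    u <- (rank(gradient[ctx]) - 0.5) / nc - 0.5
    kg <- exp(-abs(outer(u, u, "-")) / 0.25)
    eg <- eigen(kg, symmetric = TRUE)
    grad_cols <- matrix(0, P, ngr)
    grad_cols[ctx, ] <- eg$vectors[, seq_len(ngr), drop = FALSE]
    part_int <- as.integer(assets$partition)
    net_cols <- sapply(seq_len(max(part_int)), function(k)
      as.numeric(part_int == k))
    q_extra <- max(0L, min(30L, P - ncol(net_cols) - ngr))
    extra <- if (q_extra > 0) matrix(stats::rnorm(P * q_extra), P) else NULL
    B_raw <- cbind(grad_cols,
                   net_cols + matrix(stats::rnorm(P * ncol(net_cols), 0,
                                                  0.05), P),
                   extra)
    B <- qr.Q(qr(B_raw))
    q <- ncol(B)
    if (q < L) stop("configuration error: too few connectivity factors ",
                    "for n_latent planted components")

    ## edge-space basis: row j = lower-triangle of b_j b_j'
    ep <- edge_pairs(P)
    E <- t(B[ep[, 1L], , drop = FALSE] * B[ep[, 2L], , drop = FALSE])

    ## planted edge saliences: disjoint factor supports, orthonormalized
    ## in edge space via the Gram metric G = E E'
    G <- tcrossprod(E)
    ## latent components perturb disjoint network-factor strengths
    ## (columns after the gradient block), coupling the planted signal to
    ## network structure
    avail <- q - ngr
    off <- if (avail >= L) ngr else 0L
    if (off == 0L) avail <- q
    m_width <- max(1L, min(3L, avail %/% L))
    M_raw <- matrix(0, q, L)
    for (k in seq_len(L)) {
      idx <- off + ((k - 1L) * m_width + 1L):(k * m_width)
      M_raw[idx, k] <- stats::rnorm(m_width, 0, 1)
    }
    M <- gram_schmidt(M_raw, G = G)   # columns: unit edge-space norm
    edge_sal <- crossprod(E, M)       # n_edges x L, exactly orthonormal

    ## base factor strengths: network structure, gradient structure, noise
    lam0 <- c(rep(4 * cfg$gradient_strength, ngr),
              rep(2, ncol(net_cols)),
              rep(0.8, q_extra))
    c_part <- 0.5  # salience norm split equally over the 4 feature blocks
    Lmat <- matrix(rep(lam0, each = n), n, q) +
      matrix(stats::rnorm(n * q, 0, 0.5), n, q) +
      F %*% t(M * rep(s * c_part, each = q)) +
      confound_effects(cov, q, cfg$confound_strength,
                       use = c("age", "sex", "site", "motion"))
    Lmat <- pmax(Lmat, 0)
    rsfc <- Lmat %*% E
    D_diag <- stats::runif(P, 0.3, 0.7)
    rsfc_diag <- Lmat %*% t(B^2) +
      matrix(rep(D_diag, each = n), n, P)

    ## structural blocks
    blk_names <- c("area", "thickness", "volume")
    extra_cov <- list(area = "total_area", thickness = "icv",
                      volume = "icv")
    struct_blocks <- list()
    for (b in 1:3) {
      mean_prof <- 2 * as.numeric(sal_basis %*%
                                    stats::rnorm(ncol(sal_basis)))
      noise <- 0.6 * (matrix(stats::rnorm(n * ncol(sal_basis)), n) %*%
                        t(sal_basis)) +
        0.8 * matrix(stats::rnorm(n * nc), n, nc)
      X <- matrix(rep(mean_prof, each = n), n, nc) +
        F %*% t(struct_sal[[b]] * rep(s * c_part, each = nc)) + noise +
        confound_effects(cov, nc, cfg$confound_strength,
                         use = c("age", "sex", "site", "ethnicity",
                                 extra_cov[[b]]))
      colnames(X) <- paste0(blk_names[b], ":",
                            coords$parcel_id[ctx])
      struct_blocks[[blk_names[b]]] <- X
    }
    colnames(rsfc) <- paste0("rsfc:", coords$parcel_id[ep[, 1L]], "-",
                             coords$parcel_id[ep[, 2L]])

    ## ordinal behavior: latent propensity -> standardize -> threshold
    prop <- F %*% diag(s, L) %*% t(U0) +
      matrix(stats::rnorm(n * cfg$n_items), n) +
      confound_effects(cov, cfg$n_items, cfg$confound_strength)
    prop <- scale(prop)
    behavior <- matrix(0L, n, cfg$n_items)
    behavior[prop > cfg$item_thresholds[col(prop), 1L]] <- 1L
    behavior[prop > cfg$item_thresholds[col(prop), 2L]] <- 2L
    colnames(behavior) <- sprintf("item:%03d", seq_len(cfg$n_items))

    subject_ids <- sprintf("sub%05d", seq_len(n))
    cov <- cbind(subject_id = subject_ids, cov, stringsAsFactors = FALSE)
    blocks <- c(struct_blocks, list(rsfc = rsfc))
    for (b in seq_along(blocks)) rownames(blocks[[b]]) <- subject_ids
    rownames(behavior) <- subject_ids

    ## Planted imaging saliences are recorded in the standardized feature
    ## space the analysis operates in (PLS z-scores features): the raw
    ## signal directions are rescaled by the realized feature SDs, then
    ## re-orthonormalized. This makes the truth directly comparable to
    ## recovered saliences and loading maps.
    feat_sd <- c(apply(struct_blocks[[1L]], 2L, stats::sd),
                 apply(struct_blocks[[2L]], 2L, stats::sd),
                 apply(struct_blocks[[3L]], 2L, stats::sd),
                 apply(rsfc, 2L, stats::sd))
    feat_sd[feat_sd == 0] <- Inf
    imaging_sal <- rbind(c_part * struct_sal[[1L]],
                         c_part * struct_sal[[2L]],
                         c_part * struct_sal[[3L]],
                         c_part * edge_sal) / feat_sd
    imaging_sal <- gram_schmidt(imaging_sal)
    rownames(imaging_sal) <- c(colnames(struct_blocks[[1L]]),
                               colnames(struct_blocks[[2L]]),
                               colnames(struct_blocks[[3L]]),
                               colnames(rsfc))

    dataset <- structure(list(
      modality_blocks = blocks, behavior = behavior, covariates = cov,
      subject_ids = subject_ids, rsfc_diagonal = rsfc_diag,
      assets = assets, config = cfg), class = "multimodal_dataset")
    truth <- structure(list(
      behavior_saliences = U0, imaging_saliences = imaging_sal,
      subject_scores = F, planted_gradient = gradient,
      site_assignment = cov$site), class = "synthetic_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Group-average connectivity matrix of a synthetic dataset
#'
#' Rebuilds the full-sample mean region-by-region connectivity matrix from
#' the vectorized edges (and the stored diagonal), the input to gradient
#' estimation.
#'
#' @param dataset A \code{multimodal_dataset} from
#'   \code{\link{generate_dataset}}.
#' @return Symmetric \code{P x P} matrix.
#' @export
group_connectivity <- function(dataset) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  p <- nrow(dataset$assets$coords)
  m <- edge_matrix(colMeans(dataset$modality_blocks$rsfc), p)
  diag(m) <- colMeans(dataset$rsfc_diagonal)
  rownames(m) <- colnames(m) <- dataset$assets$coords$parcel_id
  m
}
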