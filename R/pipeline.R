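#' Read a subjects-by-features table
#'
#' Tab-separated (comma accepted) with a header row; first column must be
#' \code{subject_id}.
#'
#' @param path File path.
#' @return Numeric matrix with subject IDs as row names.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "subject_id")
    stop("first column must be subject_id: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate subject IDs in ", path, ": ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a subjects-by-features table
#'
#' @param x Matrix with subject IDs as row names (or supply \code{ids}).
#' @param path Output path (TSV, full precision).
#' @param ids Optional subject IDs.
#' @export
write_feature_table <- function(x, path, ids = rownames(x)) {
  x <- as.matrix(x)
  if (is.null(ids)) ids <- sprintf("sub%05d", seq_len(nrow(x)))
  df <- data.frame(subject_id = ids, x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory of plain-text tables
#'
#' One TSV per modality block plus behavior, covariates, the network
#' partition, parcel centroids, the stored connectivity diagonal, and a
#' JSON sidecar recording the generating configuration and file list.
#' Edges are vectorized lower-triangle, row-major, diagonal excluded.
#'
#' @param dataset A \code{multimodal_dataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the sidecar path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(dataset$modality_blocks)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write_feature_table(dataset$modality_blocks[[nm]], f)
    files[[nm]] <- basename(f)
  }
  write_feature_table(dataset$behavior, file.path(dir, "behavior.tsv"))
  files$behavior <- "behavior.tsv"
  utils::write.table(dataset$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files$covariates <- "covariates.tsv"
  part <- data.frame(parcel_id = names(dataset$assets$partition),
                     network_label = as.character(dataset$assets$partition))
  utils::write.table(part, file.path(dir, "partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$partition <- "partition.tsv"
  utils::write.table(dataset$assets$coords, file.path(dir, "centroids.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files$centroids <- "centroids.tsv"
  write_feature_table(dataset$rsfc_diagonal,
                      file.path(dir, "rsfc_diagonal.tsv"),
                      ids = dataset$subject_ids)
  files$rsfc_diagonal <- "rsfc_diagonal.tsv"
  sidecar <- file.path(dir, "dataset.json")
  cfg <- dataset$config
  cfg$item_thresholds <- NULL
  jsonlite::write_json(list(config = unclass(cfg), files = files,
                            edge_order = "lower-triangle, row-major, no diagonal"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Pipeline configuration
#'
#' @param synth A \code{\link{synth_config}} describing the cohort to
#'   simulate (ignored when \code{run_pipeline} is given a dataset).
#' @param variance_threshold PCA retention threshold (default 0.5).
#' @param n_perm Permutations for component significance (default 10000).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param n_spin Spin permutations (default 1000).
#' @param k_test Leading components tested (default 5).
#' @param q FDR level (default 0.05).
#' @param split_fraction Discovery fraction (default 2/3).
#' @param seed Integer seed governing split, resampling and spins.
#' @param include_volume Keep the cortical volume block (default TRUE).
#' @param include_ethnicity_covariate Keep ethnicity among the
#'   residualization terms (default TRUE).
#' @param procrustes_null Procrustes-aligned permutation nulls.
#' @param standardize_pca Standardize features before PCA.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synth = synth_config(),
                            variance_threshold = 0.5, n_perm = 10000,
                            n_boot = 1000, n_spin = 1000, k_test = 5,
                            q = 0.05, split_fraction = 2 / 3, seed = 1L,
                            include_volume = TRUE,
                            include_ethnicity_covariate = TRUE,
                            procrustes_null = FALSE,
                            standardize_pca = FALSE) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1,
            split_fraction > 0, split_fraction < 1,
            n_perm >= 1, n_boot >= 2, n_spin >= 1, k_test >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full latent-component analysis workflow
#'
#' Executes the whole pipeline on a synthetic or supplied dataset:
#' matched discovery/replication split, per-modality confound
#' residualization, PCA reduction, PLS correlation, site-restricted
#' permutation and bootstrap inference, discovery-to-replication weight
#' transfer, diffusion-map gradients of group connectivity, and
#' spin-permutation contextualization of loading maps against the
#' principal gradient. Artifacts are written under \code{out_dir} and
#' listed in \code{manifest.json}.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory.
#' @param dataset Optional \code{multimodal_dataset}; when NULL one is
#'   generated from \code{config$synth}.
#' @return Invisibly, a list with the main in-memory results
#'   (\code{split}, \code{pls}, \code{permutation}, \code{bootstrap},
#'   \code{transfer}, \code{gradients}, \code{spatial},
#'   \code{manifest}).
#' @export
run_pipeline <- function(config, out_dir, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(dataset))
    dataset <- stage("synth", generate_dataset(config$synth)$dataset)
  blocks <- dataset$modality_blocks
  if (!config$include_volume) blocks$volume <- NULL
  cov <- dataset$covariates
  coords <- dataset$assets$coords
  partition <- dataset$assets$partition

  ## ---- preprocess -------------------------------------------------------
  res <- stage("preprocess", {
    psy <- overall_psychopathology(dataset$behavior)
    split <- matched_split(cov, psy, config$split_fraction, config$seed)
    beh <- drop_invariant_items(dataset$behavior, split$discovery_idx)
    strip <- function(terms) if (config$include_ethnicity_covariate)
      terms else setdiff(terms, "ethnicity")
    resid_blocks <- lapply(names(blocks), function(nm)
      residualize(blocks[[nm]], cov, strip(modality_covariates(nm))))
    names(resid_blocks) <- names(blocks)
    yb <- residualize(beh$behavior, cov,
                      strip(modality_covariates("behavior")))
    list(split = split, blocks = resid_blocks, behavior = yb,
         dropped_items = beh$dropped)
  })
  disc <- res$split$discovery_idx
  repl <- res$split$replication_idx
  take <- function(m, idx) as.matrix(m)[idx, , drop = FALSE]
  disc_blocks <- lapply(res$blocks, take, idx = disc)
  repl_blocks <- lapply(res$blocks, take, idx = repl)

  ## ---- reduce + pls -----------------------------------------------------
  red <- stage("reduce", reduce_fit(disc_blocks, config$variance_threshold,
                                    config$standardize_pca))
  xp <- concatenate_scores(red, disc_blocks)
  pls <- stage("pls", pls_decompose(xp, take(res$behavior, disc)))
  k_test <- min(config$k_test, length(pls$singular_values))

  ## ---- inference --------------------------------------------------------
  site_disc <- cov$site[disc]
  perm <- stage("inference", permutation_test(
    xp, take(res$behavior, disc), site_disc, config$n_perm, k_test,
    seed = config$seed + 1L, procrustes = config$procrustes_null,
    covariates = cov[disc, , drop = FALSE],
    terms = if (config$include_ethnicity_covariate)
      modality_covariates("behavior")
    else setdiff(modality_covariates("behavior"), "ethnicity")))
  boot <- stage("inference", bootstrap_within_site(
    xp, take(res$behavior, disc), site_disc, config$n_boot,
    targets = list(
      behavior = list(data = take(res$behavior, disc), arm = "behavior"),
      rsfc = list(data = disc_blocks$rsfc, arm = "imaging",
                  partition = partition)),
    seed = config$seed + 2L, k = k_test, q = config$q))

  ## ---- generalize -------------------------------------------------------
  transfer <- stage("generalize", {
    tm <- fit_transfer_model(disc_blocks, take(res$behavior, disc),
                             config$variance_threshold,
                             config$standardize_pca)
    ts <- transfer_scores(tm, repl_blocks, take(res$behavior, repl))
    sig <- transfer_significance(tm, repl_blocks,
                                 take(res$behavior, repl),
                                 cov$site[repl],
                                 max(config$n_perm %/% 10L, 99L),
                                 seed = config$seed + 3L, k_test = k_test)
    list(model = tm, scores = ts, significance = sig)
  })

  ## ---- gradients --------------------------------------------------------
  grad <- stage("gradients", {
    gc <- group_connectivity(dataset)
    diffusion_embed(build_affinity(gc, 0.1), alpha = 0.5, t = 0)
  })

  ## ---- spatial ----------------------------------------------------------
  spat <- stage("spatial", {
    ctx <- coords$hemisphere != "SC"
    spins <- spin_permutation(coords[ctx, ], config$n_spin,
                              seed = config$seed + 4L)
    struct_load <- project_loadings_back(
      pls, disc_blocks[setdiff(names(disc_blocks), "rsfc")])
    rsfc_load <- project_loadings_back(pls, disc_blocks["rsfc"])$rsfc
    maps <- list()
    for (lc in seq_len(min(3L, k_test))) {
      for (nm in names(struct_load))
        maps[[paste0(nm, "_LC", lc)]] <- struct_load[[nm]][, lc]
      em <- edge_matrix(rsfc_load[, lc], nrow(coords))
      nl <- network_loading_maps(em, partition)
      maps[[paste0("rsfc_within_LC", lc)]] <- nl$within[ctx]
      maps[[paste0("rsfc_between_LC", lc)]] <- nl$between[ctx]
    }
    g1 <- grad$embedding[ctx, 1L]
    list(spins = spins,
         table = gradient_contextualize(maps, g1, spins, config$q))
  })

  ## ---- artifacts --------------------------------------------------------
  tsv <- function(obj, path) utils::write.table(
    obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(data.frame(subject_id = dataset$subject_ids[disc],
                  pls$LX[, seq_len(k_test)],
                  pls$LY[, seq_len(k_test)], check.names = FALSE),
       "composite_scores.tsv", tsv)
  emit(data.frame(item = rownames(pls$U),
                  pls$behavior_loadings[, seq_len(k_test), drop = FALSE],
                  check.names = FALSE), "behavior_loadings.tsv", tsv)
  emit(as.data.frame(perm$null_distribution), "permutation_null.tsv", tsv)
  emit(res$split$balance_report, "split_balance.tsv", tsv)
  emit(data.frame(parcel_id = rownames(grad$embedding),
                  grad$embedding, check.names = FALSE),
       "gradients.tsv", tsv)
  emit(spat$table, "spin_context.tsv", tsv)
  for (tg in names(boot$targets)) {
    b <- boot$targets[[tg]]
    emit(data.frame(target = rownames(b$loading) %||%
                      seq_len(nrow(b$loading)),
                    loading = b$loading[, 1L], sd = b$sd[, 1L],
                    z = b$z[, 1L], p = b$p[, 1L], q = b$q_adj[, 1L],
                    ci_lo = b$ci_lo[, 1L], ci_hi = b$ci_hi[, 1L]),
         paste0("bootstrap_summary_", tg, ".tsv"), tsv)
  }
  emit(list(singular_values = pls$singular_values,
            covariance_explained = pls$covariance_explained,
            lc_correlations = pls$lc_correlations[seq_len(k_test)],
            permutation_p = perm$p_values, permutation_q = perm$fdr_q,
            retained_components = vapply(red, function(m) m$k, 1L),
            dropped_items = res$dropped_items,
            gradient_variance_explained =
              grad$variance_explained[seq_len(min(10L,
                length(grad$variance_explained)))]),
       "summary.json",
       function(obj, path) jsonlite::write_json(obj, path,
                                                auto_unbox = TRUE,
                                                digits = NA))
  emit(list(within_sample_r = pls$lc_correlations[seq_len(k_test)],
            out_of_sample_r = transfer$scores$r[seq_len(k_test)],
            p = transfer$significance$p_values,
            q = transfer$significance$fdr_q),
       "transfer_report.json",
       function(obj, path) jsonlite::write_json(obj, path,
                                                auto_unbox = TRUE,
                                                digits = NA))
  manifest <- list(
    package_version = as.character(utils::packageVersion("plsmosaic")),
    seed = config$seed,
    n_subjects = length(dataset$subject_ids),
    n_discovery = length(disc), n_replication = length(repl),
    config = lapply(unclass(config), function(x)
      if (inherits(x, "synth_config")) unclass(x)[
        setdiff(names(unclass(x)), "item_thresholds")] else x),
    outputs = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(split = res$split, reduction = red, pls = pls,
                 permutation = perm, bootstrap = boot,
                 transfer = transfer, gradients = grad, spatial = spat,
                 manifest = manifest))
}
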