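#' Default pipeline configuration
#'
#' Materializes every pipeline parameter so the run manifest never contains an
#' implicit default. See [run_pipeline()] for the meaning of each field.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    genotypes = NULL, phenotypes = NULL, annotations = NULL, ppi = NULL,
    trait_column = "trait", covariate_columns = character(0),
    control_cutoff = 0.5, case_cutoff = 0.5,
    orientation = "low_is_control", residualize = TRUE,
    categorize_residual = TRUE,
    seed_genes = NULL,              # default: known-association genes
    subset_to_seeds = TRUE,
    max_missing = 0.05,
    clump = FALSE, r2_threshold = 0.5,
    cross_gene = "ppi", cross_weight = "normalized",
    normalized_laplacian = FALSE,
    n_pcs = 5L, kernel = "linear",
    k1 = 8L, k2 = 2L, gammas = c(1000, 1000, 100),
    k1_grid = 2:8, gamma1_grid = c(0, 10, 100, 1000),
    gamma2_grid = c(0, 10, 100, 1000),
    gamma3_grid = c(0, 10, 100, 1000),
    n_restarts = 50L, tol = 1e-5, max_iter = 500L,
    alpha = 0.01, n_perm = 1000L, perm_restarts = 5L,
    perm_tol = 1e-4, perm_max_iter = 200L,
    select_n_perm = 30L, select_restarts = 5L,
    seed = 1L, output_dir = NULL)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' @param path Config file; keys mirror [run_config()] fields.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(run_config, vals)
}

check_ids <- function(what, have, need) {
  orphans <- setdiff(need, have)
  if (length(orphans))
    stop("identifier mismatch in ", what, "; orphans: ",
         paste(head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) sprintf(" (+%d more)",
                                           length(orphans) - 10) else "")
}

#' Run the full prioritization pipeline
#'
#' Orchestrates preprocessing (phenotype categorization, confounder
#' residualization, seed-gene subsetting, optional LD clumping), SNV-network
#' construction, ancestry-kernel computation, optional grid-search parameter
#' selection, the consensus factorization, the permutation null, and scoring.
#' All randomness flows from `config$seed`; two runs with the same config and
#' inputs produce identical tables.
#'
#' Inputs may be given as file paths in the config (see [run_config()]) or as
#' an in-memory [simulate_bundle()] object via `bundle`.
#'
#' @param config A `run_config` (or path to a YAML/JSON config file).
#' @param bundle Optional `sim_bundle` supplying the inputs directly.
#' @param auto `NULL` (use configured k1/gammas) or a character subset of
#'   `c("k1", "gamma1", "gamma23")` to select by grid search.
#' @return List with `scores` (per-SNV table), `genes` (gene ranking),
#'   `consensus`, `null`, `kernel`, `network`, `selection` (grid results, if
#'   any), `labels`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), bundle = NULL, auto = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()

  ## ---- inputs ----
  if (!is.null(bundle)) {
    R_full <- bundle$R
    ann <- bundle$annotations
    ppi <- bundle$ppi_edges
    pheno <- data.frame(subject_id = colnames(R_full),
                        trait = as.integer(bundle$labels == "case"))
  } else {
    R_full <- read_genotypes(config$genotypes)
    ann <- read_annotations(config$annotations)
    ppi <- if (!is.null(config$ppi)) read_ppi(config$ppi) else NULL
    pheno <- read_phenotypes(config$phenotypes)
  }
  check_ids("phenotype table (subjects absent from genotypes)",
            pheno$subject_id, colnames(R_full))
  check_ids("genotype matrix (subjects absent from phenotypes)",
            colnames(R_full), pheno$subject_id)
  check_ids("genotype matrix (SNVs absent from annotations)",
            ann$snv_id, rownames(R_full))
  pheno <- pheno[match(colnames(R_full), pheno$subject_id), , drop = FALSE]
  ann <- ann[match(rownames(R_full), ann$snv_id), , drop = FALSE]

  ## ---- phenotype: residualize then categorize ----
  trait <- pheno[[config$trait_column]]
  covs <- pheno[, intersect(config$covariate_columns, names(pheno)),
                drop = FALSE]
  corrected <- trait
  if (config$residualize && ncol(covs) > 0) {
    res <- suppressMessages(residualize_trait(trait, covs))
    if (config$categorize_residual)
      corrected <- res + mean(trait, na.rm = TRUE)
  }
  cat_res <- categorize_phenotype(corrected, config$control_cutoff,
                                  config$case_cutoff, config$orientation)
  keep_subj <- cat_res$labels != "excluded"
  labels <- droplevels(cat_res$labels[keep_subj])
  names(labels) <- pheno$subject_id[keep_subj]
  R_subj <- R_full[, keep_subj, drop = FALSE]

  ## ---- SNV subset from seed genes ----
  if (config$subset_to_seeds) {
    seeds <- config$seed_genes %||%
      unique(ann$gene[as.logical(ann$known_association)])
    sub <- select_snv_subset(seeds, ppi, ann)
    ann_sub <- ann[ann$snv_id %in% sub$snv_ids, , drop = FALSE]
  } else {
    ann_sub <- ann
  }
  R <- R_subj[ann_sub$snv_id, , drop = FALSE]

  ## ---- missing data, clumping ----
  imp <- impute_genotypes(R, config$max_missing)
  R <- imp$R
  ann_sub <- ann_sub[ann_sub$snv_id %in% rownames(R), , drop = FALSE]
  proxy_map <- NULL
  if (config$clump) {
    cl <- suppressWarnings(clump_ld(R, labels, ann_sub, config$r2_threshold))
    R <- cl$R
    ann_sub <- cl$annotations
    proxy_map <- cl$proxy_map
  }
  # drop monomorphic rows: they carry no association information and break
  # the standardization inside the ancestry kernel
  poly <- apply(R, 1L, var) > 0
  R <- R[poly, , drop = FALSE]
  ann_sub <- ann_sub[poly, , drop = FALSE]

  ## ---- network, Laplacian, ancestry kernel ----
  net <- build_snv_network(ann_sub, ppi, cross_gene = config$cross_gene,
                           cross_weight = config$cross_weight)
  lp <- laplacian_parts(net, normalized = config$normalized_laplacian)
  kern <- ancestry_kernel(R_subj, n_pcs = config$n_pcs,
                          kernel = config$kernel)
  Vo <- build_phenotype_matrix(labels)

  ## ---- parameter selection ----
  selection <- list()
  k1 <- config$k1
  gammas <- config$gammas
  if (!is.null(auto)) {
    if ("k1" %in% auto) {
      selection$k1 <- select_k1(R, Vo, lp, kern$HAH, gammas,
                                k1_grid = config$k1_grid,
                                n_restarts = config$select_restarts,
                                tol = config$perm_tol,
                                max_iter = config$perm_max_iter,
                                seed = derive_seed(config$seed, 11L))
      k1 <- selection$k1$chosen
    }
    if ("gamma1" %in% auto) {
      selection$gamma1 <- select_gamma1(
        R, labels, lp, kern$HAH, ann_sub,
        known_genes = unique(ann_sub$gene[ann_sub$known_association]),
        gamma1_grid = config$gamma1_grid, gammas23 = gammas[2:3], k1 = k1,
        k2 = config$k2, n_perm = config$select_n_perm, alpha = config$alpha,
        n_restarts = config$select_restarts, perm_restarts = 2L,
        tol = config$perm_tol, max_iter = config$perm_max_iter,
        seed = derive_seed(config$seed, 12L))
      gammas[1] <- selection$gamma1$chosen
    }
    if ("gamma23" %in% auto) {
      selection$gamma23 <- select_gamma23(
        R, labels, lp, kern$HAH, gamma1 = gammas[1],
        gamma2_grid = config$gamma2_grid, gamma3_grid = config$gamma3_grid,
        k1 = k1, k2 = config$k2, n_restarts = config$select_restarts,
        tol = config$perm_tol, max_iter = config$perm_max_iter,
        seed = derive_seed(config$seed, 13L))
      gammas[2:3] <- selection$gamma23$chosen
    }
  }

  ## ---- consensus fit, null, scoring ----
  cons <- suppressMessages(fit_consensus(
    R, Vo, lp, kern$HAH, gammas, k1 = k1, k2 = config$k2,
    n_restarts = config$n_restarts, tol = config$tol,
    max_iter = config$max_iter, seed = derive_seed(config$seed, 21L)))
  null <- suppressMessages(permutation_null(
    R, labels, lp, kern$HAH, gammas, k1 = k1, k2 = config$k2,
    n_perm = config$n_perm, alpha = config$alpha,
    n_restarts = config$perm_restarts, tol = config$perm_tol,
    max_iter = config$perm_max_iter, seed = derive_seed(config$seed, 22L)))
  scores <- score_table(ann_sub, cons$mean_delta, null)
  genes <- rank_genes(scores)

  manifest <- list(
    package_version = as.character(utils::packageVersion("varitri")),
    r_version = R.version.string,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    parameters = unclass(config)[!vapply(unclass(config), is.null,
                                         logical(1))],
    k1 = k1, gammas = gammas,
    n_snvs = nrow(R), n_subjects = ncol(R),
    n_controls = sum(labels == "control"), n_cases = sum(labels == "case"),
    null_cutoffs = c(low = null$cutoff_low, high = null$cutoff_high),
    dispersion = cons$dispersion,
    selection = lapply(selection, function(s)
      list(grid = s$grid, metric = s$metric %||% NULL,
           chosen = s$chosen, criterion = s$criterion)),
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- list(scores = scores, genes = genes, consensus = cons, null = null,
              kernel = kern, network = net, selection = selection,
              labels = labels, proxy_map = proxy_map, R = R,
              annotations = ann_sub, manifest = manifest)
  if (!is.null(config$output_dir)) write_pipeline_outputs(out,
                                                          config$output_dir)
  out
}

#' Write pipeline output tables
#'
#' Emits the prioritization TSV (one row per retained SNV), the gene ranking
#' TSV, the pooled null samples, and a JSON manifest with every materialized
#' parameter, seed and cutoff.
#'
#' @param result Return value of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scores = file.path(dir, "prioritization.tsv"),
             genes = file.path(dir, "genes.tsv"),
             null = file.path(dir, "null_samples.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write.table(result$scores, paths["scores"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$genes, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(delta = result$null$samples), paths["null"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}
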