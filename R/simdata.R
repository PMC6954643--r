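#' Synthetic cohort configuration
#'
#' Collects and validates the generating parameters for a synthetic stratified
#' case-control cohort. Population structure follows the Balding-Nichols
#' model: each SNV draws an ancestral allele frequency from
#' `ancestral_maf_range`, and each population draws its own frequency from a
#' Beta distribution around it with drift parameter `differentiation` (F);
#' F = 0 means identical populations. Phenotypes follow an additive logistic
#' model on the planted causal SNVs with an ancestry term of strength
#' `confound_strength` that confounds phenotype with population membership.
#'
#' @param m_subjects,n_snvs,n_genes,n_populations Cohort dimensions.
#' @param ancestral_maf_range Range of ancestral minor-allele frequencies.
#' @param differentiation Balding-Nichols F in `[0, 1)`.
#' @param n_causal Number of planted causal SNVs.
#' @param effect_size Per-allele log-odds of the causal SNVs.
#' @param causal_clustering `"network_neighbours"` (causal SNVs in genes
#'   forming a connected PPI neighbourhood adjacent to known genes),
#'   `"same_gene"`, or `"random"`.
#' @param confound_strength Ancestry-phenotype confounding in `[0, 1]`; scaled
#'   internally to a log-odds difference of `2 * confound_strength` between
#'   populations.
#' @param damaging_fraction Fraction of SNVs flagged predicted-deleterious.
#' @param prevalence Target case fraction (default 0.5, a balanced
#'   case-control sampling design).
#' @param ld_duplicates Number of SNVs to duplicate as near-perfect-LD
#'   partners within their gene (0 disables; used to exercise clumping).
#' @param seed Master seed; every random draw derives from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(m_subjects = 600L, n_snvs = 800L, n_genes = 40L,
                       n_populations = 2L,
                       ancestral_maf_range = c(0.05, 0.5),
                       differentiation = 0.1, n_causal = 20L,
                       effect_size = 0.5,
                       causal_clustering = c("network_neighbours",
                                             "same_gene", "random"),
                       confound_strength = 0.5, damaging_fraction = 0.05,
                       prevalence = 0.5, ld_duplicates = 0L, seed = 1L) {
  causal_clustering <- match.arg(causal_clustering)
  stopifnot(m_subjects > 0, n_snvs > 0, n_genes >= 2, n_populations >= 1,
            n_causal <= n_snvs, n_causal >= 0,
            differentiation >= 0, differentiation < 1,
            confound_strength >= 0, confound_strength <= 1,
            damaging_fraction >= 0, damaging_fraction <= 1,
            prevalence > 0, prevalence < 1,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] < 1)
  structure(list(m_subjects = as.integer(m_subjects),
                 n_snvs = as.integer(n_snvs), n_genes = as.integer(n_genes),
                 n_populations = as.integer(n_populations),
                 ancestral_maf_range = ancestral_maf_range,
                 differentiation = differentiation,
                 n_causal = as.integer(n_causal), effect_size = effect_size,
                 causal_clustering = causal_clustering,
                 confound_strength = confound_strength,
                 damaging_fraction = damaging_fraction,
                 prevalence = prevalence,
                 ld_duplicates = as.integer(ld_duplicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate stratified genotypes (Balding-Nichols)
#'
#' @param config A [sim_config()] object.
#' @return List with `R` (n x m genotype matrix, entries 0/1/2), `ancestry`
#'   (population label per subject, balanced), and `freqs` (data frame of
#'   ancestral and per-population allele frequencies).
#' @export
simulate_genotypes <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_snvs; m <- config$m_subjects; K <- config$n_populations
  F <- config$differentiation
  p0 <- runif(n, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  pk <- matrix(p0, n, K)
  if (F > 0) {
    for (k in seq_len(K))
      pk[, k] <- rbeta(n, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
  }
  ancestry <- rep(seq_len(K), length.out = m)
  ancestry <- ancestry[order(ancestry)]  # balanced, contiguous
  R <- matrix(0L, n, m)
  for (k in seq_len(K)) {
    cols <- which(ancestry == k)
    R[, cols] <- rbinom(n * length(cols), 2L, pk[, k])
  }
  snv_ids <- sprintf("snv%04d", seq_len(n))
  subject_ids <- sprintf("subj%04d", seq_len(m))
  dimnames(R) <- list(snv_ids, subject_ids)
  list(R = R,
       ancestry = setNames(paste0("pop", ancestry), subject_ids),
       freqs = data.frame(snv_id = snv_ids, ancestral = p0,
                          setNames(as.data.frame(pk),
                                   paste0("pop", seq_len(K)))))
}

#' Simulate annotations and a PPI network, planting the causal set
#'
#' SNVs are partitioned into contiguous gene blocks along a pseudo-chromosome;
#' a scale-free protein-protein interaction network over the genes is drawn by
#' preferential attachment. A subset of genes is flagged as known-association
#' (seed) genes. Causal SNVs are placed according to
#' `config$causal_clustering`: in a single gene, at random, or (default) in
#' genes that are PPI neighbours of the known genes and form a connected
#' induced subgraph — the architecture under which network smoothing can
#' leverage weak signals. Each causal gene gets one predicted-deleterious
#' member so that cross-gene damaging edges link it into the network.
#'
#' Causal SNVs are drawn from variants with ancestral frequency >= 0.15
#' (common causal variants, so the planted effect is realizable).
#'
#' @param config A [sim_config()] object.
#' @param freqs Allele-frequency table from [simulate_genotypes()].
#' @return List with `annotations` (snv_id, gene, position, impact_class,
#'   predicted_deleterious, known_association, causal), `ppi_edges`,
#'   `causal_set`, `known_genes`.
#' @export
simulate_annotations_and_ppi <- function(config, freqs) {
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_snvs; G <- config$n_genes
  sizes <- rep(n %/% G, G)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  gene_ids <- sprintf("gene%03d", seq_len(G))
  gene <- rep(gene_ids, times = sizes)
  position <- seq_len(n) * 100L
  impact <- sample(c("modifier", "low"), n, replace = TRUE,
                   prob = c(0.7, 0.3))
  deleterious <- runif(n) < config$damaging_fraction
  known <- rep(FALSE, n)

  g <- igraph::sample_pa(G, power = 1, m = 2, directed = FALSE)
  igraph::V(g)$name <- gene_ids
  el <- igraph::as_edgelist(g)
  ppi_edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2])

  deg <- igraph::degree(g)
  anchor <- gene_ids[which.max(deg)]
  eligible <- freqs$ancestral >= 0.15
  causal_set <- character(0)
  if (config$n_causal > 0) {
    if (config$causal_clustering == "same_gene") {
      host <- gene_ids[which.max(sizes)]
      pool <- which(gene == host & eligible)
      if (length(pool) < config$n_causal) pool <- which(gene == host)
      if (length(pool) < config$n_causal)
        stop("largest gene too small for same_gene causal clustering")
      causal_set <- freqs$snv_id[pool[seq_len(config$n_causal)]]
    } else if (config$causal_clustering == "random") {
      pool <- which(eligible)
      if (length(pool) < config$n_causal) pool <- seq_len(n)
      causal_set <- freqs$snv_id[sample(pool, config$n_causal)]
    } else {
      # the anchor (a known trait locus, which is by definition associated)
      # and its PPI neighbours in BFS order, so the induced subgraph of
      # causal genes is connected and network-adjacent to the known signal
      bfs <- igraph::bfs(g, root = which.max(deg), unreachable = FALSE)
      ordered <- gene_ids[as.integer(bfs$order)]
      ordered <- ordered[!is.na(ordered)]
      chosen <- character(0)
      for (cg in ordered) {
        pool <- which(gene == cg & eligible)
        take <- head(pool, max(0L, min(length(pool),
                                       config$n_causal - length(chosen))))
        chosen <- c(chosen, freqs$snv_id[take])
        if (length(chosen) >= config$n_causal) break
      }
      causal_set <- head(chosen, config$n_causal)
      if (length(causal_set) < config$n_causal)
        stop("not enough eligible SNVs near the anchor gene")
    }
  }
  causal <- freqs$snv_id %in% causal_set
  # known-association (seed) genes: the anchor — which heads the causal
  # neighbourhood, as known loci carry true associations — plus other
  # high-degree non-causal genes; the remaining causal genes are the "novel"
  # loci the network is meant to reach
  causal_genes <- unique(gene[causal])
  n_known <- max(2L, ceiling(0.1 * G))
  cand <- setdiff(gene_ids[order(-deg)], causal_genes)
  known_genes <- head(unique(c(anchor, head(cand, n_known))), n_known)
  for (kg in known_genes) {
    idx <- head(which(gene == kg), 2L)
    known[idx] <- TRUE
  }
  # one deleterious member per causal gene keeps it reachable by cross-gene
  # damaging edges
  for (cg in causal_genes) {
    first_causal <- which(gene == cg & causal)[1]
    deleterious[first_causal] <- TRUE
  }
  annotations <- data.frame(snv_id = freqs$snv_id, gene = gene,
                            position = position, impact_class = impact,
                            predicted_deleterious = deleterious,
                            known_association = known, causal = causal)
  list(annotations = annotations, ppi_edges = ppi_edges,
       causal_set = causal_set, known_genes = known_genes)
}

#' Plant case-control phenotypes on simulated genotypes
#'
#' Per subject, `logit P(case) = b0 + effect_size * causal allele burden +
#' 2 * confound_strength * (population indicator, centered)`; the intercept
#' `b0` is tuned by bisection so the expected prevalence matches the target
#' within 0.02, then labels are drawn Bernoulli.
#'
#' @param R Genotype matrix.
#' @param ancestry Population labels per subject.
#' @param causal_set SNV identifiers of the causal variants.
#' @param effect_size Per-allele log-odds.
#' @param confound_strength Ancestry confounding in `[0, 1]`.
#' @param prevalence Target case fraction.
#' @param seed Integer seed.
#' @return Factor of `"control"`/`"case"` labels named by subject.
#' @export
plant_phenotypes <- function(R, ancestry, causal_set, effect_size,
                             confound_strength, prevalence = 0.5, seed = 1L) {
  stopifnot(all(causal_set %in% rownames(R)))
  set.seed(derive_seed(seed, 3L))
  burden <- if (length(causal_set))
    colSums(R[causal_set, , drop = FALSE]) else numeric(ncol(R))
  z <- as.integer(factor(ancestry))
  z <- z - mean(z)
  eta0 <- effect_size * burden + 2 * confound_strength * z
  target <- function(b0) mean(plogis(b0 + eta0)) - prevalence
  lo <- -30; hi <- 30
  if (target(lo) > 0 || target(hi) < 0)
    stop("target prevalence unattainable under the planted model")
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (target(mid) > 0) hi <- mid else lo <- mid
  }
  b0 <- (lo + hi) / 2
  if (abs(target(b0)) > 0.02)
    stop("prevalence calibration failed")
  y <- rbinom(ncol(R), 1L, plogis(b0 + eta0))
  if (all(y == 0L) || all(y == 1L))
    stop("degenerate phenotype draw (single class); increase m or adjust ",
         "prevalence")
  factor(setNames(ifelse(y == 1L, "case", "control"), colnames(R)),
         levels = c("control", "case"))
}

# duplicate a subset of SNVs as near-perfect LD partners inside their gene
add_ld_duplicates <- function(R, annotations, n_dup, seed) {
  if (n_dup <= 0L) return(list(R = R, annotations = annotations))
  set.seed(derive_seed(seed, 4L))
  pick <- sample(nrow(R), min(n_dup, nrow(R)))
  Rd <- R[pick, , drop = FALSE]
  # flip a couple of genotypes so r2 is high but < 1 occasionally
  for (i in seq_len(nrow(Rd))) {
    j <- sample(ncol(Rd), 1L)
    Rd[i, j] <- sample(0:2, 1L)
  }
  dup_ann <- annotations[pick, , drop = FALSE]
  dup_ann$snv_id <- paste0(annotations$snv_id[pick], "_dup")
  dup_ann$position <- dup_ann$position + 1L
  dup_ann$causal <- FALSE
  rownames(Rd) <- dup_ann$snv_id
  R2 <- rbind(R, Rd)
  ann2 <- rbind(annotations, dup_ann)
  ord <- order(ann2$position)
  list(R = R2[ord, , drop = FALSE], annotations = ann2[ord, , drop = FALSE])
}

#' Generate a complete synthetic cohort bundle
#'
#' Runs [simulate_genotypes()], [simulate_annotations_and_ppi()] and
#' [plant_phenotypes()] under one master seed and returns everything a
#' pipeline run needs, with full ground truth attached.
#'
#' @param config A [sim_config()] object (or arguments forwarded to it).
#' @param ... Arguments forwarded to [sim_config()] when `config` is missing.
#' @return Object of class `sim_bundle`: `R`, `ancestry`, `labels`,
#'   `annotations`, `ppi_edges`, `causal_set`, `known_genes`, `freqs`,
#'   `config`.
#' @export
simulate_bundle <- function(config = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  ann <- simulate_annotations_and_ppi(config, geno$freqs)
  labels <- plant_phenotypes(geno$R, geno$ancestry, ann$causal_set,
                             config$effect_size, config$confound_strength,
                             config$prevalence, config$seed)
  dup <- add_ld_duplicates(geno$R, ann$annotations, config$ld_duplicates,
                           config$seed)
  structure(list(R = dup$R, ancestry = geno$ancestry, labels = labels,
                 annotations = dup$annotations, ppi_edges = ann$ppi_edges,
                 causal_set = ann$causal_set, known_genes = ann$known_genes,
                 freqs = geno$freqs, config = config),
            class = "sim_bundle")
}

#' Write a simulated bundle in the pipeline's input formats
#'
#' Emits the exact TSV files [run_pipeline()] reads — genotypes, phenotypes
#' (binary trait coded 0/1 with an independent `age` covariate), annotations
#' and PPI edges — plus the generating configuration as JSON, so simulation
#' exercises the real I/O path.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             config = file.path(dir, "sim_config.json"))
  g <- data.frame(snv_id = rownames(bundle$R), bundle$R, check.names = FALSE)
  write.table(g, paths["genotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  set.seed(derive_seed(bundle$config$seed, 5L))
  ph <- data.frame(subject_id = colnames(bundle$R),
                   trait = as.integer(bundle$labels == "case"),
                   age = round(rnorm(ncol(bundle$R), 50, 10), 1),
                   population = unname(bundle$ancestry))
  write.table(ph, paths["phenotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$annotations, paths["annotations"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$ppi_edges, paths["ppi"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- unclass(bundle$config)
  cfg$causal_set <- bundle$causal_set
  cfg$known_genes <- bundle$known_genes
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
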