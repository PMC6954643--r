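#' Categorize a continuous trait into controls, cases and excluded subjects
#'
#' Splits a continuous trait at two cutoffs, keeping only the extreme
#' categories for the case-control factorization. With
#' `orientation = "low_is_control"` (e.g. LDL cholesterol: controls
#' < 100 mg/dl, cases >= 160 mg/dl), a subject is a control when
#' `value < control_cutoff`, a case when `value >= case_cutoff`, and excluded
#' in between. With `orientation = "high_is_control"` (e.g. HDL cholesterol:
#' controls > 60 mg/dl, cases < 40 mg/dl) the rule is mirrored by negating
#' values and cutoffs, so both orientations share one code path exactly.
#'
#' @param values Numeric trait vector.
#' @param control_cutoff,case_cutoff Cutoffs in trait units. A non-empty
#'   excluded band between them is permitted.
#' @param orientation `"low_is_control"` (default) or `"high_is_control"`.
#' @return List with `labels` (factor control/case/excluded) and `counts`.
#' @export
categorize_phenotype <- function(values, control_cutoff, case_cutoff,
                                 orientation = c("low_is_control",
                                                 "high_is_control")) {
  orientation <- match.arg(orientation)
  if (orientation == "high_is_control") {
    return(categorize_phenotype(-values, -control_cutoff, -case_cutoff,
                                "low_is_control"))
  }
  if (control_cutoff > case_cutoff)
    stop("control_cutoff must not exceed case_cutoff for this orientation")
  lab <- ifelse(values < control_cutoff, "control",
                ifelse(values >= case_cutoff, "case", "excluded"))
  lab[is.na(values)] <- "excluded"
  labels <- factor(lab, levels = c("control", "case", "excluded"))
  counts <- table(labels)
  if (counts[["control"]] == 0L || counts[["case"]] == 0L)
    stop("phenotype categorization produced zero ",
         if (counts[["control"]] == 0L) "controls" else "cases",
         "; the factorization needs both classes")
  list(labels = labels, counts = counts)
}

#' Residualize a trait on confounder covariates
#'
#' Fits an ordinary least-squares model of the trait on the covariates plus an
#' intercept and returns the residuals as the confounder-corrected phenotype.
#' Constant covariate columns are dropped; rows with missing covariates or
#' trait are dropped (their residual is `NA`) and counted in the `n_dropped`
#' attribute. Residuals are orthogonal to every retained covariate column.
#'
#' @param values Numeric trait vector.
#' @param covariates Numeric matrix or data frame of covariates (may be
#'   `NULL` or zero-column: intercept-only model, residuals = values - mean).
#' @return Numeric vector of residuals, same length as `values`, with
#'   attribute `n_dropped`.
#' @export
residualize_trait <- function(values, covariates = NULL) {
  n <- length(values)
  X <- if (is.null(covariates)) matrix(numeric(0), n, 0)
       else as.matrix(as.data.frame(covariates))
  if (ncol(X) > 0) {
    const <- apply(X, 2L, function(x) var(x[!is.na(x)]) %in% c(0, NA))
    X <- X[, !const, drop = FALSE]
  }
  keep <- !is.na(values) & (ncol(X) == 0L | stats::complete.cases(X))
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " row(s) dropped from residualization (missing data)")
  M <- cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- rep(NA_real_, n)
  res[keep] <- qr.resid(qrM, values[keep])
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Select the SNV subset from seed genes and their PPI neighbourhood
#'
#' Expands a set of seed genes (genes harbouring known trait associations) to
#' their first neighbourhood in the protein-protein interaction network and
#' returns all annotated SNVs located in the expanded gene set. Seed genes
#' absent from the PPI are retained as isolated nodes.
#'
#' @param seed_genes Character vector of seed gene identifiers (non-empty).
#' @param ppi_edges Two-column data frame of interacting gene pairs (may have
#'   zero rows).
#' @param annotations Annotation data frame with columns `snv_id`, `gene`.
#' @return List with `genes` (seeds plus first neighbours) and `snv_ids`.
#' @export
select_snv_subset <- function(seed_genes, ppi_edges, annotations) {
  seed_genes <- unique(as.character(seed_genes))
  if (length(seed_genes) == 0L) stop("seed gene set is empty")
  genes <- seed_genes
  if (!is.null(ppi_edges) && nrow(ppi_edges) > 0L) {
    a <- as.character(ppi_edges[[1]]); b <- as.character(ppi_edges[[2]])
    nb <- c(b[a %in% seed_genes], a[b %in% seed_genes])
    genes <- unique(c(seed_genes, nb))
  }
  snv_ids <- as.character(annotations$snv_id[annotations$gene %in% genes])
  if (length(snv_ids) == 0L)
    stop("no annotated SNVs fall in the seed genes or their PPI neighbours")
  list(genes = genes, snv_ids = snv_ids)
}

# union-find over 1..n
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (length(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

# single-SNV logistic regression p-value (Wald, slope term)
logistic_p <- function(g, y01) {
  if (var(g) == 0) return(1)
  fit <- tryCatch(suppressWarnings(glm(y01 ~ g, family = binomial())),
                  error = function(e) NULL)
  if (is.null(fit)) return(1)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2L || !is.finite(cf[2, 4])) 1 else cf[2, 4]
}

#' Clump SNVs in high linkage disequilibrium
#'
#' Within each gene, groups SNVs whose pairwise squared Pearson correlation of
#' genotype vectors (composite LD r-squared) exceeds the threshold, taking the
#' transitive closure, and retains one proxy per group: the SNV most
#' associated with the trait by single-SNV logistic regression (smallest Wald
#' p; ties broken by smaller genomic position, then identifier). Non-proxy
#' SNVs are removed, but the proxy inherits a damaging classification if any
#' group member was damaging, so no functional information is lost. LD is
#' never clumped across genes.
#'
#' @param R Genotype matrix (n x m) with SNV identifiers as row names.
#' @param labels Factor/character vector of subject labels (control/case).
#' @param annotations Annotation data frame (one row per SNV of `R`).
#' @param r2_threshold LD threshold in (0, 1]; default 0.5.
#' @return List with `R` (reduced matrix), `annotations` (reduced, flags
#'   updated on proxies), `proxy_map` (data frame snv_id -> proxy), and
#'   `n_constant` (rows excluded from the r-squared computation).
#' @export
clump_ld <- function(R, labels, annotations, r2_threshold = 0.5) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  y <- as.character(labels)
  if (length(unique(y[y %in% c("control", "case")])) < 2L)
    stop("clump_ld() requires both controls and cases")
  y01 <- as.integer(y == "case")
  ids <- rownames(R) %||% as.character(annotations$snv_id)
  ann <- annotations[match(ids, annotations$snv_id), , drop = FALSE]
  classes <- classify_variants(ann)
  n <- nrow(R)
  grp <- integer(n)  # global group id
  gmax <- 0L
  n_constant <- 0L
  for (ii in split(seq_len(n), ann$gene)) {
    v <- apply(R[ii, , drop = FALSE], 1L, var)
    nz <- ii[v > 0]
    n_constant <- n_constant + sum(v == 0)
    edges <- NULL
    if (length(nz) >= 2L) {
      r2 <- suppressWarnings(cor(t(R[nz, , drop = FALSE])))^2
      hit <- which(upper.tri(r2) & r2 > r2_threshold, arr.ind = TRUE)
      if (nrow(hit)) edges <- hit
    }
    comp <- uf_components(length(ii), if (is.null(edges)) NULL else
      cbind(match(nz[edges[, 1]], ii), match(nz[edges[, 2]], ii)))
    grp[ii] <- gmax + comp
    gmax <- gmax + length(ii)
  }
  if (n_constant > 0L)
    warning(n_constant, " constant genotype row(s) excluded from the ",
            "r-squared computation")
  keep <- logical(n)
  proxy_of <- character(n)
  for (members in split(seq_len(n), grp)) {
    if (length(members) == 1L) {
      keep[members] <- TRUE
      proxy_of[members] <- ids[members]
      next
    }
    p <- vapply(members, function(i) logistic_p(R[i, ], y01), numeric(1))
    ord <- order(p, ann$position[members], ids[members])
    px <- members[ord[1]]
    keep[px] <- TRUE
    proxy_of[members] <- ids[px]
    if (any(classes[members] == "damaging"))
      ann$predicted_deleterious[px] <- TRUE
    if (any(as.logical(ann$known_association[members])))
      ann$known_association[px] <- TRUE
  }
  list(R = R[keep, , drop = FALSE],
       annotations = ann[keep, , drop = FALSE],
       proxy_map = data.frame(snv_id = ids, proxy = proxy_of),
       n_constant = n_constant)
}

#' Impute missing genotypes and drop high-missingness SNVs
#'
#' Missing entries are replaced per SNV by the mode of the observed genotypes;
#' SNVs with missingness above `max_missing` are dropped.
#'
#' @param R Genotype matrix possibly containing `NA`.
#' @param max_missing Maximum tolerated per-SNV missing fraction (default
#'   0.05).
#' @return List with `R` (complete matrix) and `dropped` (SNV identifiers).
#' @export
impute_genotypes <- function(R, max_missing = 0.05) {
  fr <- rowMeans(is.na(R))
  drop <- fr > max_missing
  R2 <- R[!drop, , drop = FALSE]
  for (i in which(rowSums(is.na(R2)) > 0)) {
    x <- R2[i, ]
    tab <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)
    R2[i, is.na(x)] <- which.max(tab) - 1L
  }
  list(R = R2, dropped = rownames(R)[drop] %||% which(drop))
}
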