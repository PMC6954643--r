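#' SNV score matrix Omega
#'
#' `Omega = U S` (n SNVs x k2 subject clusters): summarizes how important each
#' variant is for each cluster of subjects, combining the variant's genotype
#' loading and the network-smoothed cluster structure.
#'
#' @param U SNV factor (n x k1), non-negative.
#' @param S Association factor (k1 x k2), non-negative.
#' @return Non-negative n x k2 matrix.
#' @export
snv_scores <- function(U, S) U %*% S

#' Delta scores
#'
#' `delta_s = Omega[s, controls] - Omega[s, cases]`. A positive delta means
#' the recessive allele is carried preferentially by controls (*protective*
#' effect); a negative delta means it is preferentially observed in cases
#' (*detrimental*).
#'
#' @param omega SNV score matrix from [snv_scores()].
#' @param control_cluster,case_cluster Column indices of the control- and
#'   case-enriched subject clusters (from [map_clusters()]); must differ.
#' @return Numeric vector of length n.
#' @export
delta_scores <- function(omega, control_cluster, case_cluster) {
  if (control_cluster == case_cluster)
    stop("control and case cluster indices must differ")
  omega[, control_cluster] - omega[, case_cluster]
}

#' Orient fitted subject clusters against the case-control design
#'
#' Assigns each subject to a cluster by row-argmax of V, then identifies the
#' control cluster as the V column whose assigned subjects overlap most with
#' the controls of Vo. An exact tie in overlap indicates a degenerate fit and
#' raises an error.
#'
#' @param V Fitted subject factor (m x 2).
#' @param Vo Phenotype matrix (m x 2, controls in column 1).
#' @return List with `control` and `case` column indices.
#' @export
map_clusters <- function(V, Vo) {
  if (ncol(V) != 2L || ncol(Vo) != 2L)
    stop("map_clusters() supports the case-control design (k2 = 2) only")
  assign <- max.col(V, ties.method = "first")
  ov <- c(sum(assign == 1L & Vo[, 1] == 1),
          sum(assign == 2L & Vo[, 1] == 1))
  if (ov[1] == ov[2])
    stop("control-enrichment tie between clusters; degenerate fit, re-run ",
         "with a different seed")
  ctrl <- which.max(ov)
  list(control = ctrl, case = 3L - ctrl)
}

#' Permutation null distribution of delta scores
#'
#' Builds the empirical null by rerunning the consensus factorization under
#' `n_perm` random permutations of the case-control labels (case count
#' preserved), pooling the delta scores of all SNVs and permutations into one
#' distribution. Prioritization cutoffs are the empirical quantiles at
#' `alpha/2` and `1 - alpha/2`. Permutation fits may use fewer restarts than
#' the main fit: the null needs the spread of delta scores, not a maximally
#' stable clustering.
#'
#' @inheritParams fit_consensus
#' @param labels Observed `"control"`/`"case"` label vector.
#' @param n_perm Number of permutations (>= 100 recommended; the reference
#'   setting is 1000).
#' @param alpha Significance level, default 0.01.
#' @param n_restarts Restarts per permutation fit (default 5).
#' @return Object of class `null_distribution`: `samples` (pooled delta
#'   scores), `n_permutations`, `alpha`, `cutoff_low`, `cutoff_high`,
#'   `n_failed`.
#' @export
permutation_null <- function(R, labels, lp = NULL, HAH = NULL,
                             gammas = c(0, 0, 0), k1, k2 = 2L,
                             n_perm = 1000L, alpha = 0.01, n_restarts = 5L,
                             tol = 1e-4, max_iter = 200L, seed = 1L) {
  if (n_perm < 100L)
    warning("n_perm < 100: null quantiles will be unstable")
  else if (n_perm < 1000L)
    message("n_perm = ", n_perm, " (reference setting is 1000)")
  labels <- as.character(labels)
  samples <- vector("list", n_perm)
  n_failed <- 0L
  for (p in seq_len(n_perm)) {
    pseed <- derive_seed(seed, 100000L + p)
    set.seed(pseed)
    perm <- sample(labels)
    Vo_p <- build_phenotype_matrix(perm)
    res <- tryCatch(
      suppressWarnings(fit_consensus(R, Vo_p, lp, HAH, gammas, k1, k2,
                                     n_restarts = max(2L, n_restarts),
                                     tol = tol, max_iter = max_iter,
                                     seed = pseed)),
      error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L
    else samples[[p]] <- res$mean_delta
  }
  if (n_failed > 0.1 * n_perm)
    stop("more than 10% of permutations failed (", n_failed, "/", n_perm, ")")
  pooled <- unlist(samples, use.names = FALSE)
  cuts <- quantile(pooled, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(samples = pooled, n_permutations = n_perm - n_failed,
                 alpha = alpha, cutoff_low = cuts[1], cutoff_high = cuts[2],
                 n_failed = n_failed),
            class = "null_distribution")
}

#' Empirical significance of delta scores
#'
#' Two-sided empirical p-value per SNV with add-one smoothing,
#' `p_s = (1 + #\{|null| >= |delta_s|\}) / (1 + #null)`, plus the cutoff-based
#' prioritization flag: an SNV is prioritized when its delta score falls
#' outside the (alpha/2, 1 - alpha/2) empirical quantiles of the null.
#'
#' @param delta Delta-score vector.
#' @param null A `null_distribution` object.
#' @return Data frame with columns `delta`, `p_value`, `prioritized`, `trend`
#'   (protective when delta > 0, detrimental otherwise).
#' @export
assign_significance <- function(delta, null) {
  ns <- abs(null$samples)
  N <- length(ns)
  if (N == 0L) stop("empty null distribution")
  # vectorized tail counting via the sorted null
  srt <- sort(ns)
  ge <- N - findInterval(abs(delta), srt, left.open = TRUE)
  p <- (1 + ge) / (1 + N)
  data.frame(delta = delta,
             p_value = p,
             prioritized = delta < null$cutoff_low | delta > null$cutoff_high,
             trend = ifelse(delta > 0, "protective", "detrimental"),
             row.names = names(delta))
}

#' Assemble the per-SNV score table
#'
#' @param annotations Annotation data frame aligned with the delta vector.
#' @param delta Delta-score vector (named by SNV).
#' @param null A `null_distribution` object.
#' @return Data frame with columns `snv_id`, `gene`, `position`, `class`,
#'   `delta`, `p_value`, `prioritized`, `trend`.
#' @export
score_table <- function(annotations, delta, null) {
  sig <- assign_significance(delta, null)
  data.frame(snv_id = annotations$snv_id,
             gene = annotations$gene,
             position = annotations$position,
             class = unname(classify_variants(annotations)),
             sig,
             row.names = NULL)
}

#' Rank genes by their best variant
#'
#' Each gene is represented by its variant with the lowest empirical p-value
#' (ties broken by larger `|delta|`, then lexicographic SNV identifier); the
#' gene inherits that variant's p-value and trend. Genes are returned sorted
#' by ascending p-value.
#'
#' @param scores Score table from [score_table()].
#' @return Data frame with columns `gene`, `best_snv`, `p_value`, `delta`,
#'   `trend`, `n_snvs`, `prioritized`.
#' @export
rank_genes <- function(scores) {
  parts <- split(scores, scores$gene)
  rows <- lapply(parts, function(d) {
    ord <- order(d$p_value, -abs(d$delta), d$snv_id)
    b <- d[ord[1], ]
    data.frame(gene = b$gene, best_snv = b$snv_id, p_value = b$p_value,
               delta = b$delta, trend = b$trend, n_snvs = nrow(d),
               prioritized = any(d$prioritized))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
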