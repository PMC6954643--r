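#' Choose the number of SNV clusters k1 by consensus stability
#'
#' Grid search over candidate k1 values, fitting a consensus factorization at
#' each and recording the dispersion coefficient of the consensus matrix. The
#' chosen k1 maximizes dispersion (ties go to the smaller k1). Because k1
#' governs the SNV clustering while k2 is pinned at 2 by the case-control
#' design, stability is assessed by default on the SNV-side consensus
#' (`side = "snv"`); `side = "subject"` is available.
#'
#' Note on identifiability: with k2 subject clusters the reconstruction
#' U S V' has rank at most k2, so at most k2 distinct SNV archetypes are
#' distinguishable; a k1 above that bound can only be selected when the
#' subject-side structure supports it.
#'
#' @inheritParams fit_consensus
#' @param k1_grid Integer vector of candidate k1 values (each >= 2).
#' @param k2 Number of subject clusters; defaults to `ncol(Vo)` (or 2 when
#'   `Vo` is `NULL`).
#' @param side `"snv"` (default) or `"subject"` consensus dispersion.
#' @return Object of class `grid_result`: `parameter`, `grid`, `metric`,
#'   `chosen`, `criterion`.
#' @export
select_k1 <- function(R, Vo = NULL, lp = NULL, HAH = NULL,
                      gammas = c(0, 0, 0), k1_grid = 2:8, n_restarts = 10L,
                      k2 = NULL, tol = 1e-4, max_iter = 200L, seed = 1L,
                      side = c("snv", "subject")) {
  side <- match.arg(side)
  if (is.null(k2)) k2 <- if (!is.null(Vo)) ncol(Vo) else 2L
  if (any(k1_grid < 2)) stop("k1 grid values must be >= 2")
  k1_grid <- sort(unique(as.integer(k1_grid)))
  if (length(k1_grid) == 1L)
    warning("degenerate grid of one value; choosing it")
  metric <- rep(NA_real_, length(k1_grid))
  for (i in seq_along(k1_grid)) {
    res <- tryCatch(
      suppressWarnings(
        suppressMessages(fit_consensus(R, Vo, lp, HAH, gammas, k1_grid[i],
                                       k2 = k2, n_restarts = n_restarts,
                                       tol = tol, max_iter = max_iter,
                                       seed = derive_seed(seed, i)))),
      error = function(e) NULL)
    if (!is.null(res))
      metric[i] <- if (side == "snv") res$snv_dispersion else res$dispersion
  }
  if (all(is.na(metric))) stop("all consensus fits degenerate on the k1 grid")
  chosen <- k1_grid[which.max(metric)]  # first max: smaller k1 wins ties
  structure(list(parameter = "k1", grid = k1_grid, metric = metric,
                 chosen = chosen,
                 criterion = paste0("maximal ", side,
                                    "-consensus dispersion")),
            class = "grid_result")
}

#' Choose the network penalty gamma1 by known-loci recall
#'
#' For each candidate gamma1, runs the factorization plus a reduced
#' permutation null, prioritizes SNVs at level `alpha`, and counts the
#' prioritized SNVs located in known-association genes (`metric = "snv"`,
#' default) or the known genes containing at least one prioritized SNV
#' (`metric = "gene"`). The chosen gamma1 maximizes this recall; ties go to
#' the smaller value, so the unpenalized baseline wins unless the network
#' demonstrably helps.
#'
#' @inheritParams permutation_null
#' @param annotations Annotation table aligned with the rows of `R`.
#' @param known_genes Character vector of known-association gene identifiers.
#' @param gamma1_grid Candidate gamma1 values (include 0 as baseline).
#' @param gammas23 `c(gamma2, gamma3)` held fixed during the search.
#' @param n_restarts Restarts for the main fit at each grid point.
#' @param perm_restarts Restarts per permutation fit.
#' @return A `grid_result` (metric = known genes recalled per grid value).
#' @export
select_gamma1 <- function(R, labels, lp, HAH = NULL, annotations,
                          known_genes, gamma1_grid = c(0, 0.01, 0.1, 1, 10),
                          gammas23 = c(0.5, 0), k1, k2 = 2L,
                          n_perm = 30L, alpha = 0.01, n_restarts = 5L,
                          perm_restarts = 2L, tol = 1e-4, max_iter = 200L,
                          seed = 1L, metric = c("snv", "gene")) {
  metric_mode <- match.arg(metric)
  if (length(known_genes) == 0L) stop("known gene set is empty")
  gamma1_grid <- sort(unique(gamma1_grid))
  Vo <- build_phenotype_matrix(labels)
  metric <- rep(NA_real_, length(gamma1_grid))
  for (i in seq_along(gamma1_grid)) {
    g <- c(gamma1_grid[i], gammas23)
    res <- suppressWarnings(suppressMessages(
      fit_consensus(R, Vo, lp, HAH, g, k1, k2, n_restarts = n_restarts,
                    tol = tol, max_iter = max_iter,
                    seed = derive_seed(seed, 1000L + i))))
    null <- suppressWarnings(suppressMessages(
      permutation_null(R, labels, lp, HAH, g, k1, k2, n_perm = n_perm,
                       alpha = alpha, n_restarts = perm_restarts, tol = tol,
                       max_iter = max_iter,
                       seed = derive_seed(seed, 2000L + i))))
    st <- score_table(annotations, res$mean_delta, null)
    metric[i] <- if (metric_mode == "gene") {
      length(intersect(unique(st$gene[st$prioritized]), known_genes))
    } else {
      sum(st$prioritized & st$gene %in% known_genes)
    }
  }
  chosen <- gamma1_grid[which.max(metric)]
  structure(list(parameter = "gamma1", grid = gamma1_grid, metric = metric,
                 chosen = chosen,
                 criterion = paste0("maximal known-association recall (",
                                    metric_mode, " level)")),
            class = "grid_result")
}

#' Choose gamma2 and gamma3 by case-control separation
#'
#' Grid search over the Cartesian product of candidate gamma2 (phenotype) and
#' gamma3 (ancestry) values. The separation metric is the fraction of
#' subjects whose consensus cluster matches their case-control label after
#' majority alignment (so it lies in `[0.5, 1]`). Ties go to the smaller
#' gamma3, then the smaller gamma2.
#'
#' @inheritParams fit_consensus
#' @param labels Observed `"control"`/`"case"` labels.
#' @param gamma1 Network penalty held fixed.
#' @param gamma2_grid,gamma3_grid Candidate values (include 0 baselines).
#' @return List of class `grid_result_pair`: `grid` (data frame gamma2,
#'   gamma3, separation), `chosen` (named vector), `criterion`.
#' @export
select_gamma23 <- function(R, labels, lp = NULL, HAH = NULL, gamma1 = 0,
                           gamma2_grid = c(0, 0.01, 0.1, 1, 10),
                           gamma3_grid = c(0, 0.01, 0.1, 1, 10),
                           k1, k2 = 2L, n_restarts = 5L, tol = 1e-4,
                           max_iter = 200L, seed = 1L) {
  if (!length(gamma2_grid) || !length(gamma3_grid)) stop("empty gamma grid")
  Vo <- build_phenotype_matrix(labels)
  y <- as.integer(as.character(labels) == "case") + 1L
  grid <- expand.grid(gamma2 = sort(unique(gamma2_grid)),
                      gamma3 = sort(unique(gamma3_grid)))
  sep <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- c(gamma1, grid$gamma2[i], grid$gamma3[i])
    res <- tryCatch(suppressWarnings(suppressMessages(
      fit_consensus(R, Vo, lp, HAH, g, k1, k2, n_restarts = n_restarts,
                    tol = tol, max_iter = max_iter,
                    seed = derive_seed(seed, 3000L + i)))),
      error = function(e) NULL)
    if (is.null(res)) next
    cl <- res$subject_clusters
    sep[i] <- max(mean(cl == y), mean(cl == 3L - y))
  }
  if (all(is.na(sep))) stop("all consensus fits degenerate on the gamma grid")
  ord <- order(-sep, grid$gamma3, grid$gamma2)
  best <- ord[1]
  structure(list(grid = cbind(grid, separation = sep),
                 chosen = c(gamma2 = grid$gamma2[best],
                            gamma3 = grid$gamma3[best]),
                 criterion = "maximal majority-aligned case-control separation"),
            class = "grid_result_pair")
}
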