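#' Build the phenotype matrix Vo
#'
#' One-hot encodes case-control labels into the m x 2 phenotype matrix:
#' column 1 flags controls, column 2 flags cases. Vo guides the subject
#' factor V through the penalty `gamma2 * ||V - Vo||_F^2`.
#'
#' @param labels Vector of `"control"`/`"case"` labels (excluded subjects must
#'   already be dropped).
#' @return An m x 2 0/1 matrix with columns `control`, `case`.
#' @export
build_phenotype_matrix <- function(labels) {
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), c("control", "case"))
  if (length(bad))
    stop("unknown labels in phenotype vector: ", paste(bad, collapse = ", "))
  Vo <- cbind(control = as.numeric(lab == "control"),
              case = as.numeric(lab == "case"))
  rownames(Vo) <- names(labels)
  Vo
}

#' Penalized tri-factorization objective
#'
#' Evaluates
#' `||R - U S V'||_F^2 + gamma1 tr(U' L U) + gamma2 ||V - Vo||_F^2 +
#'  gamma3 tr(V V' HAH)`,
#' the quantity minimized by the multiplicative updates. Terms with a zero
#' penalty weight (or a `NULL` operand) are skipped.
#'
#' @param R Genotype matrix (n x m).
#' @param U,S,V Factor matrices (n x k1, k1 x k2, m x k2), non-negative.
#' @param L SNV-network graph Laplacian (n x n) or `NULL`.
#' @param Vo Phenotype matrix (m x k2) or `NULL`.
#' @param HAH Doubly centered ancestry kernel (m x m) or `NULL`.
#' @param gammas Numeric vector `c(gamma1, gamma2, gamma3)` of non-negative
#'   penalty weights.
#' @return Scalar objective value.
#' @export
objective <- function(R, U, S, V, L = NULL, Vo = NULL, HAH = NULL,
                      gammas = c(0, 0, 0)) {
  E <- R - U %*% S %*% t(V)
  val <- sum(E * E)
  if (gammas[1] > 0 && !is.null(L))
    val <- val + gammas[1] * sum(U * (L %*% U))      # tr(U' L U)
  if (gammas[2] > 0 && !is.null(Vo))
    val <- val + gammas[2] * sum((V - Vo)^2)
  if (gammas[3] > 0 && !is.null(HAH))
    val <- val + gammas[3] * sum(V * (HAH %*% V))    # tr(V V' HAH)
  val
}

cnmtf_objective <- objective

#' One multiplicative update pass
#'
#' Applies one Lee-Seung/Ding-family multiplicative update to U, then S, then
#' V, derived from the split of each partial gradient of the objective into
#' positive and negative parts. All factors remain non-negative by
#' construction; a small `eps` in each denominator guards against division
#' blow-up.
#'
#' @param R Genotype matrix.
#' @param U,S,V Current factors (strictly positive).
#' @param lp Laplacian split from `laplacian_parts()` (`NULL` when
#'   `gammas[1] == 0`): list with `d_part` (vector) and `w_part` (matrix),
#'   both entrywise non-negative, such that `L = diag(d_part) - w_part`.
#' @param Vo Phenotype matrix (`NULL` when `gammas[2] == 0`).
#' @param HAH_pos,HAH_neg Element-wise positive and negative parts of the
#'   centered ancestry kernel (`NULL` when `gammas[3] == 0`).
#' @param gammas Penalty weights `c(gamma1, gamma2, gamma3)`.
#' @param eps Denominator guard, default 1e-10.
#' @return List with updated `U`, `S`, `V`.
#' @export
update_step <- function(R, U, S, V, lp = NULL, Vo = NULL,
                        HAH_pos = NULL, HAH_neg = NULL,
                        gammas = c(0, 0, 0), eps = 1e-10) {
  # U update
  VS <- V %*% t(S)                      # m x k1
  num <- R %*% VS
  den <- U %*% crossprod(VS)
  if (gammas[1] > 0 && !is.null(lp)) {
    num <- num + gammas[1] * (lp$w_part %*% U)
    den <- den + gammas[1] * (lp$d_part * U)
  }
  U <- U * num / (den + eps)
  # S update
  num <- crossprod(U, R) %*% V
  den <- crossprod(U) %*% S %*% crossprod(V)
  S <- S * num / (den + eps)
  # V update
  US <- U %*% S                         # n x k2
  num <- crossprod(R, US)
  den <- V %*% crossprod(US)
  if (gammas[2] > 0 && !is.null(Vo)) {
    num <- num + gammas[2] * Vo
    den <- den + gammas[2] * V
  }
  if (gammas[3] > 0 && !is.null(HAH_pos)) {
    num <- num + gammas[3] * (HAH_neg %*% V)
    den <- den + gammas[3] * (HAH_pos %*% V)
  }
  V <- V * num / (den + eps)
  if (!all(is.finite(U)) || !all(is.finite(S)) || !all(is.finite(V)))
    stop("non-finite factor entries after multiplicative update")
  list(U = U, S = S, V = V)
}

#' Fit the penalized tri-factorization once
#'
#' Runs multiplicative updates from a strictly positive random initialization
#' (entries uniform on (0.1, 1.1)) until the relative objective change falls
#' below `tol` or `max_iter` is reached. A factor column collapsing to zero is
#' re-jittered once; a second collapse marks the fit degenerate.
#'
#' @param R Genotype matrix (n x m).
#' @param Vo Phenotype matrix (m x k2) or `NULL`.
#' @param lp Laplacian split from `laplacian_parts()` or `NULL`.
#' @param HAH Centered ancestry kernel or `NULL`.
#' @param gammas Penalty weights `c(gamma1, gamma2, gamma3)`.
#' @param k1 Number of SNV clusters.
#' @param k2 Number of subject clusters (2 for case-control).
#' @param tol Relative objective-change stopping tolerance (default 1e-5).
#' @param max_iter Maximum update passes (default 500).
#' @param seed Integer seed for the initialization.
#' @param eps Denominator guard.
#' @return List of class `cnmtf_fit`: `U`, `S`, `V`, `objective_trace`,
#'   `converged`, `iterations`, `degenerate`.
#' @export
fit_once <- function(R, Vo = NULL, lp = NULL, HAH = NULL,
                     gammas = c(0, 0, 0), k1, k2 = 2L,
                     tol = 1e-5, max_iter = 500L, seed = 1L, eps = 1e-10) {
  R <- as.matrix(R)
  n <- nrow(R); m <- ncol(R)
  stopifnot(k1 >= 1, k2 >= 1)
  set.seed(as.integer(seed))
  U <- matrix(runif(n * k1, 0.1, 1.1), n, k1)
  S <- matrix(runif(k1 * k2, 0.1, 1.1), k1, k2)
  V <- matrix(runif(m * k2, 0.1, 1.1), m, k2)
  use_net <- !is.null(lp) && gammas[1] > 0
  use_vo <- !is.null(Vo) && gammas[2] > 0
  use_hsic <- !is.null(HAH) && gammas[3] > 0
  W_part <- d_part <- NULL
  if (use_net) {
    d_part <- lp$d_part
    W_part <- if (mean(lp$w_part != 0) < 0.25)
      Matrix::Matrix(lp$w_part, sparse = TRUE) else lp$w_part
  }
  HAH_pos <- HAH_neg <- NULL
  if (use_hsic) {
    HAH_pos <- pmax(HAH, 0)
    HAH_neg <- pmax(-HAH, 0)
  }
  RF2 <- sum(R * R)
  # objective via the norm decomposition, reusing per-iteration products:
  # ||R - USV'||^2 = ||R||^2 - 2<R'U S, V> + tr(S'U'US V'V)
  eval_obj <- function(U, S, V) {
    RtUS <- crossprod(R, U %*% S)               # m x k2
    rec <- RF2 - 2 * sum(RtUS * V) +
      sum((crossprod(S, crossprod(U)) %*% S) * crossprod(V))
    if (use_net)
      rec <- rec + gammas[1] *
        (sum(d_part * U * U) - sum(U * as.matrix(W_part %*% U)))
    if (use_vo) rec <- rec + gammas[2] * sum((V - Vo)^2)
    if (use_hsic) rec <- rec + gammas[3] * sum(V * (HAH %*% V))
    rec
  }
  obj <- eval_obj(U, S, V)
  trace <- numeric(max_iter + 1L)
  trace[1] <- obj
  converged <- FALSE
  degenerate <- FALSE
  rejittered <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # U update
    VS <- V %*% t(S)
    num <- R %*% VS
    den <- U %*% crossprod(VS)
    if (use_net) {
      num <- num + gammas[1] * as.matrix(W_part %*% U)
      den <- den + gammas[1] * (d_part * U)
    }
    U <- U * num / (den + eps)
    # S update: U'RV computed as U'(RV), k2-sized intermediate
    num <- crossprod(U, R %*% V)
    den <- crossprod(U) %*% S %*% crossprod(V)
    S <- S * num / (den + eps)
    # V update
    US <- U %*% S
    num <- crossprod(R, US)
    den <- V %*% crossprod(US)
    if (use_vo) {
      num <- num + gammas[2] * Vo
      den <- den + gammas[2] * V
    }
    if (use_hsic) {
      num <- num + gammas[3] * (HAH_neg %*% V)
      den <- den + gammas[3] * (HAH_pos %*% V)
    }
    V <- V * num / (den + eps)
    if (!all(is.finite(U)) || !all(is.finite(S)) || !all(is.finite(V)))
      stop("non-finite factor entries at iteration ", it)
    collapsed <- any(colSums(U) < 1e-12 * n) || any(colSums(V) < 1e-12 * m)
    if (collapsed) {
      if (!rejittered) {
        rejittered <- TRUE
        warning("factor column collapsed; re-jittering once")
        U <- U + matrix(runif(n * k1, 0, 0.01), n, k1)
        V <- V + matrix(runif(m * k2, 0, 0.01), m, k2)
      } else {
        degenerate <- TRUE
        break
      }
    }
    new_obj <- eval_obj(U, S, V)
    trace[it + 1L] <- new_obj
    if (abs(obj - new_obj) / max(abs(obj), eps) < tol) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged && !degenerate)
    attr(converged, "max_iter_reached") <- TRUE
  structure(list(U = U, S = S, V = V,
                 objective_trace = trace[seq_len(it + 1L)],
                 converged = converged, iterations = it,
                 degenerate = degenerate),
            class = "cnmtf_fit")
}

#' Consensus factorization over random restarts
#'
#' Runs [fit_once()] `n_restarts` times from independent initializations
#' (restart seeds derived deterministically from the master seed), extracts
#' hard clusters by row-argmax of V (subjects) and U (SNVs), and aggregates
#' them into consensus co-clustering matrices. Final subject clusters come
#' from average-linkage hierarchical clustering of `1 - consensus` cut at k2
#' groups. Delta scores are computed per restart (oriented by
#' [map_clusters()]) and averaged (or median-combined).
#'
#' Restarts whose fit is degenerate, or whose subject clusters cannot be
#' unambiguously oriented against Vo, are excluded with a warning.
#'
#' @inheritParams fit_once
#' @param n_restarts Number of random restarts (>= 2; default 50).
#' @param combine `"mean"` (default) or `"median"` combination of per-restart
#'   delta scores.
#' @return Object of class `cnmtf_consensus`: `consensus_matrix` (m x m),
#'   `snv_consensus` (n x n), `dispersion`, `snv_dispersion`, `mean_delta`,
#'   `per_restart_objectives`, `subject_clusters`, `best` (factors of the
#'   lowest-objective restart), `n_excluded`.
#' @export
fit_consensus <- function(R, Vo, lp = NULL, HAH = NULL, gammas = c(0, 0, 0),
                          k1, k2 = 2L, n_restarts = 50L, tol = 1e-5,
                          max_iter = 500L, seed = 1L, combine = c("mean",
                                                                  "median")) {
  combine <- match.arg(combine)
  if (n_restarts < 2L)
    stop("fit_consensus() requires n_restarts >= 2 (consensus undefined)")
  R <- as.matrix(R)
  n <- nrow(R); m <- ncol(R)
  Csub <- matrix(0, m, m)
  Csnv <- matrix(0, n, n)
  deltas <- matrix(NA_real_, n, n_restarts)
  objs <- rep(NA_real_, n_restarts)
  best <- NULL; best_obj <- Inf
  kept <- 0L
  cluster_seen <- rep(FALSE, k2)
  # delta scores require the case-control design; for other k2 the consensus
  # is still defined but no orientation against Vo exists
  score_deltas <- !is.null(Vo) && k2 == 2L && ncol(Vo) == 2L
  for (r in seq_len(n_restarts)) {
    fit <- fit_once(R, Vo, lp, HAH, gammas, k1, k2, tol, max_iter,
                    seed = derive_seed(seed, r))
    if (fit$degenerate) next
    mp <- NULL
    if (score_deltas) {
      mp <- tryCatch(map_clusters(fit$V, Vo), error = function(e) NULL)
      if (is.null(mp)) next
    }
    kept <- kept + 1L
    objs[r] <- fit$objective_trace[length(fit$objective_trace)]
    cs <- max.col(fit$V, ties.method = "first")
    cu <- max.col(fit$U, ties.method = "first")
    cluster_seen[unique(cs)] <- TRUE
    Csub <- Csub + outer(cs, cs, "==")
    Csnv <- Csnv + outer(cu, cu, "==")
    if (score_deltas)
      deltas[, kept] <- delta_scores(snv_scores(fit$U, fit$S),
                                     mp$control, mp$case)
    if (objs[r] < best_obj) { best_obj <- objs[r]; best <- fit }
  }
  n_excluded <- n_restarts - kept
  if (kept < 2L)
    stop("fewer than two usable restarts (", n_excluded, " excluded)")
  if (n_excluded > 0L)
    warning(n_excluded, " restart(s) excluded from the consensus")
  if (!all(cluster_seen))
    warning("subject cluster(s) empty in every restart: ",
            paste(which(!cluster_seen), collapse = ", "))
  Csub <- Csub / kept
  Csnv <- Csnv / kept
  deltas <- deltas[, seq_len(kept), drop = FALSE]
  subject_clusters <- cutree(hclust(as.dist(1 - Csub), method = "average"),
                             k = k2)
  md <- if (!score_deltas) rep(NA_real_, n)
        else if (combine == "mean") rowMeans(deltas)
        else apply(deltas, 1L, stats::median)
  names(md) <- rownames(R)
  structure(list(consensus_matrix = Csub, snv_consensus = Csnv,
                 dispersion = dispersion(Csub),
                 snv_dispersion = dispersion(Csnv),
                 mean_delta = md, per_restart_objectives = objs,
                 subject_clusters = subject_clusters,
                 best = best, n_excluded = n_excluded,
                 n_restarts = n_restarts, k1 = k1, k2 = k2),
            class = "cnmtf_consensus")
}

#' Dispersion coefficient of a consensus matrix
#'
#' `rho = mean(4 (C_ij - 0.5)^2)`: 1 when every pair of items is either
#' always or never co-clustered across restarts (perfectly stable), 0 when
#' every entry is 0.5 (maximally ambiguous).
#'
#' @param consensus_matrix Symmetric matrix with entries in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
dispersion <- function(consensus_matrix) {
  mean(4 * (consensus_matrix - 0.5)^2)
}
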