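#' Centering matrix H
#'
#' Returns the m x m centering matrix H = I - (1/m) J, where J is the all-ones
#' matrix. H is idempotent, symmetric, annihilates constant vectors, and has
#' trace m - 1. Double-multiplying a kernel by H (H A H) removes row and
#' column means, which is what makes the empirical HSIC estimator insensitive
#' to constant offsets in either kernel.
#'
#' @param m Number of subjects (>= 2).
#' @return An m x m numeric matrix.
#' @export
centering_matrix <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || m < 2)
    stop("centering_matrix() requires m >= 2")
  m <- as.integer(m)
  diag(m) - 1 / m
}

# H A H without forming H: subtract row means, column means, add grand mean.
center_kernel <- function(A) {
  rm <- rowMeans(A)
  cm <- colMeans(A)
  gm <- mean(A)
  sweep(sweep(A, 1L, rm), 2L, cm) + gm
}

#' Ancestry kernel from genotype principal components
#'
#' Infers population structure by principal components analysis of the
#' standardized genotype matrix and builds a subject-by-subject similarity
#' kernel A on the leading principal component scores. The kernel enters the
#' factorization through the HSIC penalty tr(V V' H A H), which discourages
#' subject clusters that merely track ancestry.
#'
#' SNV rows are standardized to mean 0 / unit variance (monomorphic rows are
#' dropped), subjects are projected onto the first `n_pcs` principal
#' components, each component is scaled to unit variance, and A is either the
#' linear kernel P P' (default) or an RBF kernel with median-heuristic
#' bandwidth on the scaled scores.
#'
#' @param R Genotype matrix, n SNVs x m subjects, entries 0/1/2.
#' @param n_pcs Number of principal components (1 <= n_pcs < m). Default 5.
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param scores Optional externally computed m x p score matrix (e.g. from a
#'   dedicated PCA tool); when supplied, the internal PCA is bypassed.
#' @return An object of class `ancestry_kernel`: list with elements `A`
#'   (m x m PSD kernel), `HAH` (the doubly centered kernel, precomputed once),
#'   `scores` (m x n_pcs), `n_pcs`, `kernel`.
#' @export
ancestry_kernel <- function(R, n_pcs = 5L, kernel = c("linear", "rbf"),
                            scores = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(scores)) {
    R <- as.matrix(R)
    m <- ncol(R)
    if (n_pcs < 1L || n_pcs >= m)
      stop("ancestry_kernel() requires 1 <= n_pcs < m (m = ", m, ")")
    mu <- rowMeans(R)
    s <- apply(R, 1L, sd)
    keep <- s > 0
    if (!any(keep)) {
      # No subject variation at all: constant kernel, HSIC penalty vanishes.
      A <- matrix(0, m, m)
      return(structure(list(A = A, HAH = center_kernel(A),
                            scores = matrix(0, m, n_pcs),
                            n_pcs = as.integer(n_pcs), kernel = kernel),
                       class = "ancestry_kernel"))
    }
    Z <- (R[keep, , drop = FALSE] - mu[keep]) / s[keep]
    # subjects in rows; SNV columns already centered by the standardization
    sv <- svd(t(Z), nu = n_pcs, nv = 0)
    P <- sv$u[, seq_len(n_pcs), drop = FALSE] * rep(sv$d[seq_len(n_pcs)],
                                                    each = m)
  } else {
    P <- as.matrix(scores)
    m <- nrow(P)
    n_pcs <- ncol(P)
  }
  # unit-variance components so no single axis dominates the kernel
  psd <- apply(P, 2L, sd)
  psd[psd == 0] <- 1
  P <- sweep(P, 2L, psd, "/")
  A <- if (kernel == "linear") {
    tcrossprod(P)
  } else {
    d2 <- as.matrix(dist(P))^2
    bw <- stats::median(d2[upper.tri(d2)])
    if (!is.finite(bw) || bw <= 0) bw <- 1
    exp(-d2 / bw)
  }
  structure(list(A = A, HAH = center_kernel(A), scores = P,
                 n_pcs = as.integer(n_pcs), kernel = kernel),
            class = "ancestry_kernel")
}

#' Empirical Hilbert-Schmidt independence criterion
#'
#' Computes the empirical HSIC estimator between two kernel matrices,
#' `trace(K H A H) / (m - 1)^2`, where H is the centering matrix. Small values
#' indicate that the variables underlying K and A are independent; the
#' factorization minimizes this quantity between the subject clustering kernel
#' V V' and the ancestry kernel.
#'
#' @param K,A Square symmetric kernel matrices of identical dimension.
#' @return A scalar; non-negative (up to numerical noise) for PSD inputs.
#' @export
hsic <- function(K, A) {
  K <- as.matrix(K); A <- as.matrix(A)
  if (!all(dim(K) == dim(A)) || nrow(K) != ncol(K))
    stop("hsic() requires square kernel matrices of identical size")
  m <- nrow(K)
  sum(K * center_kernel(A)) / (m - 1)^2
}
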