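# Small fixtures built in code, shared across test files.

# annotation table with explicit classes
tiny_annotations <- function() {
  data.frame(
    snv_id = sprintf("s%02d", 1:8),
    gene = c("g1", "g1", "g1", "g2", "g2", "g3", "g3", "g4"),
    position = c(100, 200, 300, 1100, 1200, 2100, 2200, 3100),
    impact_class = c("modifier", "low", "modifier", "high", "modifier",
                     "modifier", "low", "moderate"),
    predicted_deleterious = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                              FALSE, FALSE, FALSE),
    known_association = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                          TRUE, FALSE, FALSE))
}

# random genotype matrix with SNV/subject names
random_genotypes <- function(n, m, seed = 1, maf = NULL) {
  set.seed(seed)
  p <- if (is.null(maf)) runif(n, 0.1, 0.5) else rep(maf, n)
  R <- matrix(rbinom(n * m, 2, rep(p, m)), n, m)
  dimnames(R) <- list(sprintf("s%04d", seq_len(n)),
                      sprintf("j%04d", seq_len(m)))
  R
}

# two-block genotype structure: subjects in two groups with opposite
# high/low SNV blocks; trivially separable for the factorization
block_genotypes <- function(n = 40, m = 30, p_hi = 0.9, p_lo = 0.05,
                            seed = 1) {
  set.seed(seed)
  half_n <- n %/% 2
  half_m <- m %/% 2
  P <- matrix(p_lo, n, m)
  P[seq_len(half_n), seq_len(half_m)] <- p_hi
  P[(half_n + 1):n, (half_m + 1):m] <- p_hi
  R <- matrix(rbinom(n * m, 2, P), n, m)
  dimnames(R) <- list(sprintf("s%04d", seq_len(n)),
                      sprintf("j%04d", seq_len(m)))
  labels <- factor(rep(c("control", "case"), c(half_m, m - half_m)),
                   levels = c("control", "case"))
  names(labels) <- colnames(R)
  list(R = R, labels = labels)
}

# three SNV blocks, each the extreme archetype of one of three subject
# groups; the natural SNV clustering has exactly 3 identifiable groups
# (identifiability needs subject-side rank 3, hence three subject groups)
three_block_genotypes <- function(n = 90, m = 60, seed = 1) {
  set.seed(seed)
  stopifnot(n %% 3 == 0, m %% 3 == 0)
  third_n <- n / 3; third_m <- m / 3
  P <- matrix(0.05, n, m)
  for (bl in 1:3) {
    rows <- ((bl - 1) * third_n + 1):(bl * third_n)
    cols <- ((bl - 1) * third_m + 1):(bl * third_m)
    P[rows, cols] <- 0.85
  }
  R <- matrix(rbinom(n * m, 2, P), n, m)
  dimnames(R) <- list(sprintf("s%04d", seq_len(n)),
                      sprintf("j%04d", seq_len(m)))
  list(R = R, block = rep(1:3, each = third_n),
       group = rep(1:3, each = third_m))
}

# brute-force HSIC via an explicit centering matrix and matrix products
hsic_oracle <- function(K, A) {
  m <- nrow(K)
  H <- diag(m) - matrix(1 / m, m, m)
  sum(diag(K %*% H %*% A %*% H)) / (m - 1)^2
}

# element-wise brute-force objective (no matrix identities)
objective_oracle <- function(R, U, S, V, L = NULL, Vo = NULL, HAH = NULL,
                             gammas = c(0, 0, 0)) {
  n <- nrow(R); m <- ncol(R); k1 <- ncol(U); k2 <- ncol(V)
  val <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    rec <- 0
    for (a in seq_len(k1)) for (b in seq_len(k2))
      rec <- rec + U[i, a] * S[a, b] * V[j, b]
    val <- val + (R[i, j] - rec)^2
  }
  if (gammas[1] > 0 && !is.null(L)) {
    tr <- 0
    for (a in seq_len(k1)) for (i in seq_len(n)) for (j in seq_len(n))
      tr <- tr + U[i, a] * L[i, j] * U[j, a]
    val <- val + gammas[1] * tr
  }
  if (gammas[2] > 0 && !is.null(Vo))
    val <- val + gammas[2] * sum((V - Vo)^2)
  if (gammas[3] > 0 && !is.null(HAH)) {
    tr <- 0
    for (b in seq_len(k2)) for (i in seq_len(m)) for (j in seq_len(m))
      tr <- tr + V[i, b] * HAH[i, j] * V[j, b]
    val <- val + gammas[3] * tr
  }
  val
}

# monotone-descent checker on an objective trace
is_monotone_trace <- function(tr, rel_tol = 1e-9) {
  all(diff(tr) <= rel_tol * pmax(abs(tr[-length(tr)]), 1e-12))
}
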