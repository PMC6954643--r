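#' Classify variants as damaging or candidate
#'
#' A variant is *damaging* when its transcript impact is high or moderate,
#' when it is predicted deleterious by a protein-impact predictor, or when it
#' is a known trait association; every other variant is a *candidate*.
#' Damaging variants receive preferential cross-gene connectivity in the
#' SNV-SNV network because they are the variants most likely to disrupt a
#' protein-protein interaction.
#'
#' @param annotations Data frame with columns `snv_id`, `impact_class`
#'   (one of high/moderate/low/modifier), `predicted_deleterious` (logical),
#'   `known_association` (logical).
#' @return Character vector (`"damaging"`/`"candidate"`), named by `snv_id`.
#' @export
classify_variants <- function(annotations) {
  req <- c("snv_id", "impact_class", "predicted_deleterious",
           "known_association")
  miss <- setdiff(req, names(annotations))
  if (length(miss))
    stop("annotations missing columns: ", paste(miss, collapse = ", "))
  ok <- annotations$impact_class %in% c("high", "moderate", "low", "modifier")
  if (!all(ok))
    stop("unknown impact_class values in rows: ",
         paste(which(!ok), collapse = ", "), " (",
         paste(unique(annotations$impact_class[!ok]), collapse = ", "), ")")
  dmg <- annotations$impact_class %in% c("high", "moderate") |
    as.logical(annotations$predicted_deleterious) |
    as.logical(annotations$known_association)
  setNames(ifelse(dmg, "damaging", "candidate"), annotations$snv_id)
}

#' Build the weighted SNV-SNV network
#'
#' Two construction rules: (a) every pair of SNVs harboured by the same gene
#' is connected, with edge weight 1/(N-1) where N is the number of variants in
#' that gene — so the within-gene weighted degree of every variant is 1
#' regardless of gene size, removing the node-degree bias of variant-dense
#' genes; (b) damaging variants in distinct genes are connected with weight 1
#' when the two genes interact in the supplied PPI edge list (default), or
#' unconditionally with `cross_gene = "all"`.
#'
#' @param annotations Annotation data frame (columns `snv_id`, `gene`, plus
#'   the classification columns used by [classify_variants()]). Row order
#'   defines node order and must match the genotype matrix.
#' @param ppi_edges Two-column data frame of interacting gene pairs.
#' @param cross_gene `"ppi"` (default) restricts cross-gene damaging-damaging
#'   edges to PPI-linked gene pairs; `"all"` connects all damaging pairs.
#' @param cross_weight `"one"` (default) gives cross-gene edges weight 1;
#'   `"normalized"` uses 1/sqrt((N_a - 1)(N_b - 1)) (floored at 1 variant).
#' @param classes Optional precomputed class vector; defaults to
#'   [classify_variants()] on `annotations`.
#' @return An object of class `snv_network`: list with `W` (symmetric
#'   adjacency, zero diagonal), `snv_ids`, `genes`, `classes`.
#' @export
build_snv_network <- function(annotations, ppi_edges = NULL,
                              cross_gene = c("ppi", "all"),
                              cross_weight = c("one", "normalized"),
                              classes = NULL) {
  cross_gene <- match.arg(cross_gene)
  cross_weight <- match.arg(cross_weight)
  if (is.null(classes)) classes <- classify_variants(annotations)
  ids <- as.character(annotations$snv_id)
  genes <- as.character(annotations$gene)
  if (anyNA(genes) || any(genes == ""))
    stop("every SNV must map to a gene")
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  idx_by_gene <- split(seq_len(n), genes)
  for (ii in idx_by_gene) {
    N <- length(ii)
    if (N >= 2L) W[ii, ii] <- 1 / (N - 1)
  }
  diag(W) <- 0
  dmg <- which(unname(classes) == "damaging")
  if (length(dmg) >= 2L) {
    pair_ok <- function(ga, gb) TRUE
    if (cross_gene == "ppi") {
      if (is.null(ppi_edges) || nrow(ppi_edges) == 0L) {
        keys <- character(0)
      } else {
        a <- as.character(ppi_edges[[1]]); b <- as.character(ppi_edges[[2]])
        keys <- unique(c(paste(a, b, sep = "\r"), paste(b, a, sep = "\r")))
      }
      pair_ok <- function(ga, gb) paste(ga, gb, sep = "\r") %in% keys
    }
    gsize <- lengths(idx_by_gene)
    for (i in seq_along(dmg)) {
      for (j in seq_along(dmg)) {
        if (j <= i) next
        a <- dmg[i]; b <- dmg[j]
        if (genes[a] == genes[b]) next
        if (!pair_ok(genes[a], genes[b])) next
        w <- if (cross_weight == "one") 1 else
          1 / sqrt(max(gsize[[genes[a]]] - 1, 1) *
                   max(gsize[[genes[b]]] - 1, 1))
        W[a, b] <- W[b, a] <- w
      }
    }
  }
  structure(list(W = W, snv_ids = ids, genes = genes,
                 classes = unname(classes)),
            class = "snv_network")
}

#' Graph Laplacian of an SNV network
#'
#' Basic form `L = D - W`; normalized form `L = I - D^(-1/2) W D^(-1/2)`,
#' where zero-degree nodes contribute identity rows (their `D^(-1/2)` entry is
#' taken as 0), keeping L symmetric positive semidefinite in both modes.
#'
#' @param network An `snv_network` object (or a bare symmetric adjacency
#'   matrix).
#' @param normalized Use the normalized Laplacian. Default `FALSE`.
#' @return An n x n Laplacian matrix.
#' @export
laplacian <- function(network, normalized = FALSE) {
  p <- laplacian_parts(network, normalized)
  diag(p$d_part) - p$w_part
}

#' Laplacian split for the multiplicative updates
#'
#' Returns `L = diag(d_part) - w_part` with `w_part` entrywise non-negative:
#' basic mode gives `d_part` = degree, `w_part` = W; normalized mode gives
#' `d_part` = 1 and `w_part = D^(-1/2) W D^(-1/2)`. This split is what
#' [update_step()] consumes.
#'
#' @inheritParams laplacian
#' @return List with `d_part` (vector), `w_part` (matrix), `normalized`.
#' @export
laplacian_parts <- function(network, normalized = FALSE) {
  W <- if (inherits(network, "snv_network")) network$W else as.matrix(network)
  deg <- rowSums(W)
  if (!normalized) {
    list(d_part = deg, w_part = W, normalized = FALSE)
  } else {
    inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    Q <- W * tcrossprod(inv)
    list(d_part = rep(1, nrow(W)), w_part = Q, normalized = TRUE)
  }
}

#' Export an SNV network as edge and node tables
#'
#' @param network An `snv_network` object.
#' @param edges_path,nodes_path Output TSV paths (edge list `snv_a`, `snv_b`,
#'   `weight`; node table `snv_id`, `gene`, `class`).
#' @return Invisibly, the edge data frame.
#' @export
write_snv_network <- function(network, edges_path, nodes_path) {
  W <- network$W
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(snv_a = network$snv_ids[ut[, 1]],
                      snv_b = network$snv_ids[ut[, 2]],
                      weight = W[ut])
  write.table(edges, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- data.frame(snv_id = network$snv_ids, gene = network$genes,
                      class = network$classes)
  write.table(nodes, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}
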