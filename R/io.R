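#' Read a genotype matrix
#'
#' Accepts either a TSV with an `snv_id` column followed by one column per
#' subject (entries 0/1/2, `NA` for missing), or a VCF of biallelic sites
#' (requires the vcfR package; additive dosage is derived from the GT field).
#'
#' @param path Input file; format chosen by extension (`.vcf`/`.vcf.gz` vs
#'   anything else).
#' @return Integer matrix, SNVs in rows (row names = identifiers), subjects
#'   in columns.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      ifelse(is.na(x), NA_integer_,
             vapply(strsplit(gsub("\\|", "/", x), "/"),
                    function(a) sum(a == "1"), integer(1)))
    }
    R <- apply(gt, 2L, count_alt)
    ids <- v@fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(v@fix[, "CHROM"], ":",
                                           v@fix[, "POS"])[is.na(ids) |
                                                            ids == "."]
    rownames(R) <- ids
    return(R)
  }
  d <- read.delim(path, check.names = FALSE)
  R <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(R) <- "integer"
  rownames(R) <- as.character(d[[1]])
  R
}

#' Read a phenotype/covariate table
#'
#' TSV keyed by `subject_id`, with a trait column and any number of covariate
#' columns.
#'
#' @param path Input TSV.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) read.delim(path, check.names = FALSE)

#' Read an SNV annotation table
#'
#' TSV with columns `snv_id`, `gene`, `position`, `impact_class`,
#' `predicted_deleterious`, `known_association` (extra columns are kept).
#'
#' @param path Input TSV.
#' @return Data frame.
#' @export
read_annotations <- function(path) {
  a <- read.delim(path, check.names = FALSE)
  req <- c("snv_id", "gene", "position", "impact_class",
           "predicted_deleterious", "known_association")
  miss <- setdiff(req, names(a))
  if (length(miss))
    stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  a$predicted_deleterious <- as.logical(a$predicted_deleterious)
  a$known_association <- as.logical(a$known_association)
  a
}

#' Read a PPI edge list
#'
#' Two-column TSV of interacting gene identifiers.
#'
#' @param path Input TSV.
#' @return Data frame with two columns.
#' @export
read_ppi <- function(path) {
  e <- read.delim(path, check.names = FALSE)
  if (ncol(e) < 2L) stop("PPI edge list needs two columns")
  e[, 1:2]
}
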