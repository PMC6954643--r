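Package: varitri
Title: Variant Prioritization by Corrected Non-Negative Matrix Tri-Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates case-control genotypes, a functional SNV-SNV network
    derived from protein-protein interactions, and subject ancestry into a
    penalized non-negative matrix tri-factorization that clusters subjects and
    scores single nucleotide variants for trait association. The factorization
    is guided by a graph-Laplacian penalty on the SNV network, a phenotype
    matrix pulling subject clusters towards the case-control design, and a
    Hilbert-Schmidt independence criterion penalty that decouples the subject
    clustering from population structure inferred via principal components.
    Includes preprocessing (phenotype categorization, confounder
    residualization, seed-gene network subsetting, LD clumping), consensus
    clustering over random restarts, permutation-based empirical significance
    of variant delta scores, grid-search parameter selection, and a synthetic
    data generator for stratified genotypes with planted causal architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
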