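test_that("phenotype categorization applies lipid-style cutoffs", {
  # LDL-like: controls < 100, cases >= 160
  r <- categorize_phenotype(c(95, 130, 170), 100, 160, "low_is_control")
  expect_equal(as.character(r$labels), c("control", "excluded", "case"))
  # HDL-like: controls > 60, cases < 40
  r <- categorize_phenotype(c(65, 50, 30), 60, 40, "high_is_control")
  expect_equal(as.character(r$labels), c("control", "excluded", "case"))
  expect_error(categorize_phenotype(c(95, 96), 100, 160),
               "zero cases")
  expect_error(categorize_phenotype(c(170, 180), 100, 160),
               "zero controls")
})

test_that("orientation reversal maps onto the mirrored code path exactly", {
  set.seed(2)
  v <- rnorm(500, 50, 20)
  hi <- categorize_phenotype(v, 60, 40, "high_is_control")$labels
  lo <- categorize_phenotype(-v, -60, -40, "low_is_control")$labels
  expect_identical(hi, lo)
})

test_that("residualization returns OLS residuals orthogonal to covariates", {
  set.seed(9)
  n <- 500
  age <- rnorm(n, 50, 10)
  # trait identical to a covariate: perfect fit
  r <- residualize_trait(age, data.frame(age = age))
  expect_lt(max(abs(r)), 1e-10)
  # intercept-only model
  v <- rnorm(20)
  expect_equal(as.numeric(residualize_trait(v)), v - mean(v))
  # simulated confounded trait
  trait <- 2 * age + rnorm(n)
  res <- residualize_trait(trait, data.frame(age = age))
  expect_lt(abs(cor(res, age)), 0.05)
  # collinear design names the offending column
  expect_error(
    residualize_trait(trait, data.frame(age = age, age2 = 2 * age)),
    "collinear columns.*age2")
})

test_that("residualization drops and counts incomplete rows", {
  v <- c(1, 2, NA, 4, 5)
  cov <- data.frame(x = c(1, NA, 3, 4, 5))
  expect_message(r <- residualize_trait(v, cov), "2 row")
  expect_equal(attr(r, "n_dropped"), 2L)
  expect_true(all(is.na(r[2:3])))
})

test_that("seed-gene subset expands one PPI hop and keeps isolated seeds", {
  ann <- data.frame(snv_id = paste0("v", 1:6),
                    gene = c("g1", "g1", "g2", "g3", "g4", "g4"),
                    position = 1:6, impact_class = "modifier",
                    predicted_deleterious = FALSE, known_association = FALSE)
  s <- select_snv_subset("g1", data.frame(a = "g1", b = "g2"), ann)
  expect_setequal(s$genes, c("g1", "g2"))
  expect_setequal(s$snv_ids, c("v1", "v2", "v3"))
  # isolated seed retained
  s <- select_snv_subset("g1", data.frame(a = character(0),
                                          b = character(0)), ann)
  expect_equal(s$genes, "g1")
  # second neighbours excluded
  s <- select_snv_subset(c("g1", "g2"),
                         data.frame(a = c("g1", "g3"), b = c("g3", "g4")),
                         ann)
  expect_setequal(s$genes, c("g1", "g2", "g3"))
  expect_false("v5" %in% s$snv_ids)
  expect_error(select_snv_subset("nope", NULL, ann), "no annotated SNVs")
})

test_that("one-hop expansion matches a BFS oracle on random graphs", {
  set.seed(14)
  for (rep in 1:10) {
    genes <- paste0("g", 1:12)
    ed <- data.frame(a = sample(genes, 15, TRUE), b = sample(genes, 15, TRUE))
    ed <- ed[ed$a != ed$b, ]
    ann <- data.frame(snv_id = paste0("v", 1:24),
                      gene = rep(genes, each = 2), position = 1:24,
                      impact_class = "modifier",
                      predicted_deleterious = FALSE,
                      known_association = FALSE)
    seeds <- sample(genes, 2)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                       vertices = genes)
    nb <- unique(unlist(lapply(seeds, function(s)
      names(igraph::neighbors(g, s)))))
    expected <- union(seeds, nb)
    got <- select_snv_subset(seeds, ed, ann)
    expect_setequal(got$genes, expected)
  }
})

test_that("perfect-LD duplicates clump to one proxy that inherits flags", {
  set.seed(4)
  g <- rbinom(60, 2, 0.4)
  R <- rbind(a1 = g, a2 = g, b1 = rbinom(60, 2, 0.4))
  ann <- data.frame(snv_id = c("a1", "a2", "b1"), gene = "g1",
                    position = c(10, 20, 30),
                    impact_class = c("modifier", "high", "modifier"),
                    predicted_deleterious = FALSE,
                    known_association = FALSE)
  labels <- factor(rep(c("control", "case"), 30),
                   levels = c("control", "case"))
  out <- clump_ld(R, labels, ann, 0.5)
  expect_equal(nrow(out$R), 2L)
  kept <- out$annotations$snv_id
  expect_true("b1" %in% kept)
  proxy <- setdiff(kept, "b1")
  expect_length(proxy, 1L)
  # the damaging high-impact member's status is inherited by the proxy
  expect_true(out$annotations$predicted_deleterious[
    out$annotations$snv_id == proxy])
  expect_equal(sort(unique(out$proxy_map$proxy)), sort(kept))
})

test_that("uncorrelated SNVs are never clumped", {
  set.seed(5)
  R <- rbind(x = rbinom(200, 2, 0.5), y = rbinom(200, 2, 0.5))
  ann <- data.frame(snv_id = c("x", "y"), gene = "g1", position = 1:2,
                    impact_class = "modifier",
                    predicted_deleterious = FALSE, known_association = FALSE)
  labels <- factor(rep(c("control", "case"), 100),
                   levels = c("control", "case"))
  expect_lt(cor(R[1, ], R[2, ])^2, 0.1)
  out <- clump_ld(R, labels, ann, 0.5)
  expect_equal(nrow(out$R), 2L)
})

test_that("clumping is idempotent and monotone in the threshold", {
  set.seed(6)
  b <- simulate_bundle(sim_config(m_subjects = 80, n_snvs = 60, n_genes = 6,
                                  n_causal = 4, ld_duplicates = 15,
                                  seed = 21))
  out1 <- suppressWarnings(clump_ld(b$R, b$labels, b$annotations, 0.5))
  out2 <- suppressWarnings(clump_ld(out1$R, b$labels, out1$annotations, 0.5))
  expect_identical(out1$R, out2$R)
  # lower threshold groups more aggressively: same or fewer proxies
  prev <- Inf
  for (th in c(0.9, 0.5, 0.2)) {
    o <- suppressWarnings(clump_ld(b$R, b$labels, b$annotations, th))
    expect_lte(nrow(o$R), prev)
    prev <- nrow(o$R)
  }
})

test_that("constant genotype rows are excluded from r2 with a warning", {
  R <- rbind(c1 = rep(1, 40), x = rbinom(40, 2, 0.5))
  ann <- data.frame(snv_id = c("c1", "x"), gene = "g1", position = 1:2,
                    impact_class = "modifier",
                    predicted_deleterious = FALSE, known_association = FALSE)
  labels <- factor(rep(c("control", "case"), 20),
                   levels = c("control", "case"))
  expect_warning(out <- clump_ld(R, labels, ann, 0.5), "constant genotype")
  expect_equal(nrow(out$R), 2L)  # constant row kept as its own group
})

test_that("biallelic VCF genotypes load as additive dosages", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "sA", "sB", "sC", sep = "\t"),
           paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
                 "0/0", "0/1", "1/1", sep = "\t"),
           paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
                 "0|1", "1|1", "./.", sep = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  R <- read_genotypes(path)
  expect_equal(dim(R), c(2L, 3L))
  expect_equal(unname(R["rs1", ]), c(0L, 1L, 2L))
  expect_equal(unname(R["rs2", ]), c(1L, 2L, NA_integer_))
})

test_that("genotype imputation fills the per-SNV mode and drops bad SNVs", {
  R <- rbind(a = c(0, 0, 1, NA, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                   0, 0),
             b = c(NA, NA, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2,
                   2, 2))
  out <- impute_genotypes(R, max_missing = 0.05)
  expect_equal(rownames(out$R), "a")
  expect_equal(unname(out$R["a", 4]), 0)
  expect_equal(out$dropped, "b")
})
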