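# varitri

Prioritization of SNV-trait associations in case-control cohorts by
**corrected non-negative matrix tri-factorization**: the additive genotype
matrix *R* (*n* SNVs × *m* subjects, entries 0/1/2) is decomposed as
*R* ≈ *USV*ᵀ with non-negative factors, minimizing

```
J = ||R − USVᵀ||²_F + γ₁·tr(UᵀLU) + γ₂·||V − Vo||²_F + γ₃·tr(VVᵀHAH)
```

* **tr(UᵀLU)** — graph-Laplacian penalty of a weighted SNV–SNV network
  (same-gene edges weighted 1/(N−1); damaging variants of PPI-interacting
  genes connected across genes) that shares association signal between
  functionally related variants, rescuing individually weak causal loci;
* **||V − Vo||²** — pulls the subject clusters towards the case-control
  design (Vo one-hot, controls first);
* **tr(VVᵀHAH)** — empirical Hilbert–Schmidt independence criterion between
  the subject clustering and an ancestry kernel *A* built from genotype
  principal components, correcting the clustering for population
  stratification.

Variants are scored by Ω = *US*; the **delta score**
ΔΩₛ = Ω(s, controls) − Ω(s, cases) is positive for protective and negative
for detrimental recessive alleles, with empirical significance from a
permutation null of the phenotype labels (pooled across SNVs, cutoffs at the
α/2 and 1−α/2 quantiles, α = 0.01). Solutions are consensus-aggregated over
random restarts; k₁ and the γ weights are chosen by grid search (cluster
stability, known-loci recall, case-control separation).

Intended for method developers and analysts working with case-control
genotype panels restricted to a seed-gene PPI neighbourhood (hundreds to
thousands of SNVs), not genome-wide scans.

## Worked example

Everything runs on synthetic cohorts with known ground truth; the generator
writes the exact input formats the pipeline reads.

```r
library(varitri)

# two populations (Fst 0.1), 20 causal SNVs (log-odds 0.5/allele) in
# PPI-adjacent genes, ancestry-phenotype confounding 0.5
bundle <- simulate_bundle(sim_config(m_subjects = 600, n_snvs = 800,
                                     n_genes = 40, n_causal = 20, seed = 11))

# k1 = 16 SNV clusters (the value a select_k1() grid search settles on at
# this scale); 3 consensus restarts and a 100-permutation null
cfg <- run_config(k1 = 16, n_restarts = 3, n_perm = 100, perm_restarts = 3,
                  max_iter = 150, perm_max_iter = 150, tol = 1e-4, seed = 11)
out <- run_pipeline(cfg, bundle = bundle)

head(out$scores[order(out$scores$p_value),
                c("snv_id", "gene", "class", "delta", "p_value",
                  "prioritized", "trend")])
#>     snv_id    gene     class      delta      p_value prioritized       trend
#> 26 snv0026 gene002 candidate -0.1895773 1.724108e-05        TRUE detrimental
#> 27 snv0027 gene002 candidate -0.1784728 1.724108e-05        TRUE detrimental
#> 30 snv0030 gene002 candidate -0.2259362 1.724108e-05        TRUE detrimental
#> 31 snv0031 gene002  damaging -0.1787351 1.724108e-05        TRUE detrimental
#> 32 snv0032 gene002 candidate -0.1823665 1.724108e-05        TRUE detrimental
#> 34 snv0034 gene002 candidate -0.1844753 1.724108e-05        TRUE detrimental

sum(out$scores$prioritized)
#> [1] 24
table(out$scores$prioritized[out$scores$snv_id %in% bundle$causal_set])
#> FALSE  TRUE
#>     6    14
out$genes[1:3, ]
#>      gene best_snv      p_value      delta       trend n_snvs prioritized
#> 1 gene002  snv0039 1.724108e-05 -0.2633835 detrimental     20        TRUE
#> 2 gene001  snv0003 1.206876e-04 -0.1511512 detrimental     20        TRUE
#> 3 gene034  snv0665 5.861968e-04 -0.1348081 detrimental     20        TRUE
```

Negative deltas mark recessive alleles carried preferentially by cases
(detrimental trend). The two top-ranked genes are exactly the genes
harbouring the 20 planted causal variants (14 of which are individually
prioritized), and the whole of `gene002` rises together — the network
penalty shares signal among variants of the same gene, which is the point
of the method. The p-value floor of 1.7e-05 is the add-one-smoothed minimum
for this null size.

Parameter selection and the stratification correction are available through
the same entry point:

```r
out <- run_pipeline(cfg, bundle = bundle, auto = c("k1", "gamma1", "gamma23"))
out$manifest$selection   # grids, metrics, chosen values
```

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/varitri", package="varitri"))') \
  simulate --out sim/ --seed 11
```

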