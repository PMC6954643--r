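---
title: "Corrected non-negative matrix tri-factorization for variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected non-negative matrix tri-factorization for variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-SNV regression in case-control GWAS only detects variants of large
effect: when different subjects carry different causal variants within a gene
region — or within genes participating in the same cellular function — each
individual variant is underpowered. varitri addresses this by clustering the
raw genotype matrix jointly over SNVs and subjects, sharing association
signal along a functional SNV-SNV network, while explicitly correcting the
subject clustering for population stratification.

## The model

Let $R$ be the $n \times m$ genotype matrix under the additive coding
($R_{ij} \in \{0,1,2\}$ copies of the recessive allele). We seek non-negative
factors $U$ ($n \times k_1$), $S$ ($k_1 \times k_2$) and $V$
($m \times k_2$) minimizing

$$
J = \lVert R - USV^{\top}\rVert_F^2
  + \gamma_1\,\mathrm{tr}(U^{\top} L U)
  + \gamma_2\,\lVert V - V_o\rVert_F^2
  + \gamma_3\,\mathrm{tr}(V V^{\top} H A H),
$$

where

* $L = D - W$ is the graph Laplacian of a weighted SNV-SNV network (a
  normalized Laplacian $I - D^{-1/2} W D^{-1/2}$ is available); the penalty
  $\mathrm{tr}(U^\top L U) = \sum_{ij} W_{ij}\lVert u_i - u_j\rVert^2 / 2$
  smooths SNV factor rows over network edges;
* $V_o$ is the $m \times 2$ one-hot phenotype matrix (controls in column 1),
  pulling the subject clusters towards the case-control design;
* $A$ is an ancestry kernel on the subjects and $H = I - \tfrac1m J$ the
  centering matrix; $\mathrm{tr}(V V^{\top} H A H)$ is (up to the constant
  $1/(m-1)^2$, which we fold into the reported HSIC but not the objective)
  the empirical Hilbert–Schmidt independence criterion between the clustering
  kernel $V V^{\top}$ and $A$ — small when the subject clustering is
  independent of ancestry.

Subjects are assigned to clusters by row-argmax of $V$. SNVs are scored by
$\Omega = US$, and each variant's delta score
$\Delta\Omega_s = \Omega_{s,\text{controls}} - \Omega_{s,\text{cases}}$
measures how much of its allele load the reconstruction attributes to the
control-enriched versus the case-enriched cluster: positive values are
protective, negative detrimental.

### The SNV-SNV network

Two rules build the network from annotations and a protein-protein
interaction (PPI) edge list. All variants harboured by the same gene are
pairwise connected with weight $1/(N-1)$, $N$ the number of variants in the
gene, so every variant's within-gene weighted degree is exactly 1 regardless
of gene size — variant-dense genes get no degree advantage. *Damaging*
variants (high/moderate transcript impact, predicted deleterious, or known
trait association) in different genes are additionally connected when their
genes interact in the PPI.

The weight of these cross-gene edges is configurable. `cross_weight = "one"`
uses unit weights; the pipeline default is `"normalized"`,
$1/\sqrt{(N_a-1)(N_b-1)}$, which puts cross-gene edges on the same scale as
within-gene edges. The distinction matters: with unit cross-gene weights a
damaging variant's cross-gene degree can exceed its within-gene degree, so
increasing $\gamma_1$ homogenizes $U$ *across* genes before it has finished
smoothing *within* genes, diluting gene-local signal into the PPI
neighbourhood. With normalized weights the within-gene term dominates
per-node and $\gamma_1$ primarily aggregates the per-variant signals of a
gene — which is what rescues individually weak causal variants that cluster
in genes.

### Scale of the penalty weights

The objective is used exactly as written, without internal rescaling of the
four terms. The gradient of the reconstruction term with respect to $V$ grows
with $n$ (and with $m$ for $U$), so the $\gamma$ values at which the
penalties compete with reconstruction scale with the data: for inputs of
hundreds of SNVs and subjects, $\gamma_2$ must reach the hundreds before $V$
tracks $V_o$, and useful $\gamma_1, \gamma_3$ values are of similar
magnitude. The default grids (`0, 10, 100, 1000`) are log-spaced around that
regime; all three weights are chosen by data-driven grid search
(see *Parameter selection*), so the defaults only need to bracket the useful
range. Fixing the HSIC constant $1/(m-1)^2$ outside the objective keeps a
given $\gamma_3$ roughly transferable across cohort sizes.

## Optimization

Multiplicative Lee–Seung/Ding-type updates are derived by splitting each
partial gradient into positive and negative parts; with
$\epsilon = 10^{-10}$ guarding denominators:

$$
U \leftarrow U \circ \frac{RVS^{\top} + \gamma_1 W_\ast U}
 {U S V^{\top} V S^{\top} + \gamma_1 D_\ast U + \epsilon},
\qquad
S \leftarrow S \circ \frac{U^{\top} R V}{U^{\top} U S V^{\top} V + \epsilon},
$$
$$
V \leftarrow V \circ \frac{R^{\top} US + \gamma_2 V_o + \gamma_3 (HAH)^- V}
 {V S^{\top} U^{\top} U S + \gamma_2 V + \gamma_3 (HAH)^+ V + \epsilon},
$$

where $L = \mathrm{diag}(D_\ast) - W_\ast$ with $W_\ast \ge 0$ entry-wise
(basic: degree and adjacency; normalized: $I$ and $D^{-1/2}WD^{-1/2}$), and
$(HAH)^{\pm}$ are the element-wise positive/negative parts of the centered
kernel, precomputed once. Factors are initialized uniform on $(0.1, 1.1)$ —
strictly positive, since multiplicative updates cannot leave zeros. Updates
stop when the relative objective change falls below `tol` (default `1e-5`)
or after `max_iter` passes (default 500). Monotone descent of the objective
is verified empirically by the test suite over random instances and penalty
combinations rather than proven in-package.

Numerical notes. A factor column that collapses towards zero mid-run is
re-jittered once; a second collapse marks the restart degenerate and it is
excluded from the consensus. Near rank-deficient optima the updates descend
through long, slow plateaus; the planted-factor recovery tests therefore
disable the stopping rule and run a fixed large budget. Per-iteration cost is
dominated by the $n \times m$ reconstruction products and the $n \times n$
network multiply, hence quadratic in the number of SNVs at fixed $m$.

## Consensus, stability and delta scores

The algorithm restarts `n_restarts` times (default 50) from independent
initializations derived deterministically from one master seed. Each restart
yields hard subject clusters (argmax of $V$), hard SNV clusters (argmax of
$U$) and, after orienting clusters against $V_o$ by control-overlap, a delta
score vector. Restart results are combined into consensus co-clustering
matrices (fraction of restarts in which two items share a cluster); final
subject clusters are obtained by average-linkage hierarchical clustering of
one minus the consensus, and delta scores are averaged (`combine = "median"`
is available). The dispersion coefficient
$\rho = \tfrac{1}{m^2}\sum_{ij} 4 (C_{ij} - \tfrac12)^2 \in [0, 1]$
summarizes stability: 1 when every pair always or never co-clusters, 0 when
the consensus is uniformly ambiguous.

## Empirical significance

The null distribution of delta scores is built by refitting the model under
random permutations of the case-control labels (case count preserved),
pooling all SNVs' delta scores across permutations into a single empirical
distribution (the reference setting is 1000 permutations; per-SNV nulls at
that depth would be prohibitively wide). Prioritization cutoffs are the
pooled quantiles at $\alpha/2$ and $1-\alpha/2$ with $\alpha = 0.01$;
additionally a two-sided empirical p-value with add-one smoothing,
$p_s = (1 + \#\{|\text{null}| \ge |\Delta\Omega_s|\}) / (1 + \#\text{null})$,
is reported per SNV. Permutation fits use fewer restarts (default 5) than
the main fit: the null needs the spread of delta scores, not a maximally
stable clustering. Genes are ranked by their variant of smallest p-value
(ties: larger $|\Delta\Omega|$, then identifier).

## Parameter selection

Two stages, mirroring the sequential design of the method.

* **$k_1$ by cluster stability.** Grid search, choosing the $k_1$ that
  maximizes the dispersion coefficient. Because $k_2$ is pinned at 2 by the
  case-control design, the subject-side consensus is nearly insensitive to
  $k_1$; stability is therefore assessed on the SNV-side consensus by
  default. A caveat the user should know: the reconstruction $USV^\top$ has
  rank at most $k_2$, so at most $k_2$ extreme SNV archetypes are
  identifiable — a planted SNV-cluster structure beyond that bound can only
  be recovered where the subject-side structure supports it (the package
  allows $k_2 > 2$ in the library functions for exactly this kind of
  exploration, while the pipeline restricts itself to case-control).
* **$\gamma_1$ by known-loci recall**: the number of prioritized SNVs
  falling in known-association genes (a gene-level count is available),
  maximized over the $\gamma_1$ grid at reduced permutation depth. The
  baseline $\gamma_1 = 0$ is always evaluated and wins ties, so a positive
  $\gamma_1$ is chosen only when the network demonstrably helps.
* **$(\gamma_2, \gamma_3)$ by case-control separation**: the fraction of
  subjects whose consensus cluster matches their label after majority
  alignment, maximized over the product grid; ties prefer smaller
  $\gamma_3$, then smaller $\gamma_2$.

## The synthetic cohort generator

`simulate_bundle()` produces fully synthetic inputs with known ground truth,
in the exact file formats the pipeline reads.

* **Population structure** follows the Balding–Nichols model: ancestral
  frequency $p_0 \sim U(\text{maf range})$ per SNV; population $k$ draws
  $p_k \sim \mathrm{Beta}\big(p_0 \tfrac{1-F}{F}, (1-p_0)\tfrac{1-F}{F}\big)$
  with drift $F$; genotypes are $\mathrm{Binomial}(2, p_k)$. $F$ is directly
  interpretable as the expected $F_{ST}$ between populations.
* **Phenotypes** follow a logistic model,
  $\mathrm{logit}\,P(\text{case}) = \beta_0 + \beta \sum_{s \in \text{causal}}
  g_s + 2c \cdot z$, with per-allele log-odds $\beta$, centered population
  indicator $z$, confounding strength $c \in [0,1]$ (scaled so $c = 1$ is a
  two-unit log-odds gap between populations), and $\beta_0$ tuned by
  bisection to the target prevalence (default 0.5, a balanced case-control
  sampling design).
* **Annotations and PPI**: SNVs are partitioned into contiguous gene blocks;
  the gene-level PPI is scale-free (preferential attachment). Known
  (seed) genes are the network anchor plus other hub genes; under
  `causal_clustering = "network_neighbours"` the causal SNVs are placed in
  the anchor and its BFS neighbourhood, so the causal genes form a connected
  induced subgraph headed by a known locus — known loci carry true
  associations by definition, and the adjacent causal genes are the novel
  loci the network is meant to reach. Causal variants are drawn from
  common variants (ancestral frequency at least 0.15) so the planted
  per-allele effect is realizable; each causal gene contains one
  predicted-deleterious member, keeping it attached to the damaging
  cross-gene backbone.

What the generator does *not* emulate: linkage disequilibrium beyond
optional near-duplicate variants inside a gene (used to exercise clumping),
admixed individuals, genotyping error and missingness patterns of real
arrays, and any realistic gene-length or MAF spectrum. Tests passing on
these bundles therefore demonstrate the algorithm's mechanics — descent,
calibration, stratification correction, network leverage — not performance
on real cohort data.

## Preprocessing choices

* Phenotypes are residualized on confounder covariates by OLS first; the
  residuals, re-centered at the original trait mean so published cutoff
  levels remain meaningful, are then categorized (raw-trait categorization
  is available). The mirrored orientation (`high_is_control`) negates values
  and cutoffs and reuses the low-is-control path exactly.
* Missing genotypes are imputed per SNV with the mode of observed values;
  SNVs above 5% missingness are dropped.
* LD clumping groups SNVs within a gene whose squared Pearson correlation of
  genotype vectors (composite LD, no phasing) exceeds `r2 = 0.5`, taking the
  transitive closure; the proxy is the member with the smallest single-SNV
  logistic regression p-value (ties: smaller position, then identifier), and
  it inherits the damaging and known-association flags of its group.
  Cross-gene LD is never clumped.

## Problem sizes used in the test suite

The acceptance-style checks run on deliberately desk-scale instances chosen
as the package's own test design: the standard stratified fixture is
$m = 600$ subjects, $n = 800$ SNVs, 40 genes, two populations at $F = 0.1$,
20 causal SNVs of per-allele log-odds 0.5 in network-adjacent genes, and
confounding strength 0.5, analyzed through the seed-gene PPI-neighbourhood
subset exactly as the pipeline does; permutation nulls in tests use 200
permutations for calibration checks and 12–25 elsewhere, with 2–3 restarts
per fit, against the pipeline defaults of 1000 and 50. Null-calibration
checks deliberately give the observed fit and every permutation fit the same
restart count and iteration budget: the permutation null is a null for the
statistic *as computed*, and an asymmetric budget shifts its scale. One
consequence of reduced budgets is a run-level delta-scale factor (the
multiplicative updates converge scale slowly), which leaves the prioritized
fraction calibrated but correlates p-values within a run; the p-value
uniformity check therefore runs a smaller fixture to full convergence, where
that factor provably stabilizes. The monotonicity, oracle and recovery
checks use matrices of tens of rows and columns.

## Known limitations

* The pooled null mixes SNVs of different minor-allele frequency, so
  low-frequency variants are conservatively thresholded relative to a
  per-SNV null (available behind a flag, at much higher permutation cost).
* The delta score lives on the raw allele-count scale; two variants of equal
  effect but different frequency get different scores.
* Only biallelic, unphased genotypes are supported; no multi-allelic
  decomposition or reference-panel imputation.
* With $k_2 = 2$ the factorization cannot represent more than two subject
  archetypes; heavily substructured cohorts should be inspected through the
  ancestry kernel and, if needed, analyzed per subpopulation.
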