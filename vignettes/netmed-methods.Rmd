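---
title: "netmed: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netmed: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package does

`netmed` implements an integrated causal-analysis pipeline for paired
systemic (e.g. PBMC) and local (e.g. nasal airway) RNA-seq cohorts with
genotypes. Per tissue it runs:

1. CPM normalization and low-abundance filtering (genes with CPM <= 5 in
   more than 10% of samples are removed);
2. a reproducible 2:1 discovery/test split (discovery size
   `ceiling(2n/3)`, which reproduces 228/113 for n = 341);
3. per-gene negative-binomial differential expression with covariates
   (age, sex, race), Wald tests, BH adjustment, and cross-set directional
   validation ("asthma genes");
4. weighted co-expression modules (unsigned TOM, average-linkage, static
   cut), hypergeometric module enrichment for the validated genes
   ("asthma modules": fold > 1 and FDR <= 0.05), and logistic
   eigengene-phenotype association;
5. cis-eQTL mapping (1 Mb closed window around TSS/TES, MAF >= 0.01,
   ancestry PCs + age + sex as covariates);
6. discrete Bayesian network reconstruction on the module genes
   (3-state K-means discretization, BIC-scored structure search by
   annealed Metropolis-Hastings chains, eQTL-anchored), with a 30%
   edge-frequency consensus;
7. key driver analysis: enrichment of module members in directed k-step
   downstream neighborhoods (k = 1..7) against the K-step subnetwork
   background, Bonferroni over k, BH across nodes, discovery/test
   validation.

Across tissues, validated key drivers enter a causal mediation screen in
both directions (systemic exposure/airway mediator and the converse),
with Sobel inference, optional bootstrap and mediator-permutation tests,
and BH adjustment per direction.

# The scoring model for causal networks

Expression is discretized per gene into three ordered states by 1-D
K-means (K = 3, 10 seeded restarts, states relabelled by ascending
mean). A network is scored by the decomposable BIC

  score = sum_i [ logL_i - (d_i / 2) log n ] + log prior,

where `logL_i` is the multinomial ML log-likelihood of gene i given its
parents' state configurations and `d_i = 2 * 3^{|parents|}`. The prior
subtracts `kappa` (default 1 nat) per edge and adds `lambda` (default
ln 2) for each edge from an eQTL-anchored gene into a non-anchored one.

**Genetic instruments.** A lambda bonus alone orients only edges touching
anchored genes. The package therefore lets each anchored gene carry its
best cis-eQTL genotype as a *fixed instrument parent* in its family. With
the genotype in the likelihood, the factorizations `G -> X -> Y` and
`G -> X <- Y` are no longer equivalent (the latter asserts marginal
independence of G and Y, which the data contradict), so orientation
propagates down unanchored chains. This is, we believe, the substance of
the statement that genetic anchors break Markov equivalence; a pure prior
bonus does not achieve it.

**Sampling.** Each of `n_networks` chains starts from a jittered
Chow-Liu tree (maximum spanning tree on pairwise mutual information, 5%
multiplicative weight noise per chain, oriented away from the anchors)
and runs single-edge add/delete/reverse Metropolis-Hastings with a
geometric temperature schedule (2 down to 0.2 over the first 60% of
sweeps). Each chain's final graph is one "reconstructed network"; the
consensus retains directed edges present in at least 30% of them (closed
inequality: 300 of 1000 is retained). Annealing is deliberate: the
reference implementation of this methodology also reconstructs each
network by simulated annealing and takes cross-run consensus, and plain
T = 1 chains demonstrably fail to mix across the near-tied spanning
structures of hub-shaped modules. Default sweeps in the pipeline are 10
proposals per ordered node pair.

# The synthetic world

`sim_config()` states the generator's world once:

- **Modules.** Five 50-gene modules per tissue. Key drivers form a chain
  KD1 -> KD2 (weight 1.5x below); 90% of the other members are direct
  driver targets, 10% hang off an earlier member (shallow cascades).
  Latent log-expression propagates as `child = w * sum(parents) + noise`
  with `edge_weight` w = 0.8, root noise sd 1, member noise sd 0.8.
  Lead drivers of consecutive modules are bridged (weight 1.3 w) so the
  tissue network is connected. Half a module's worth of *peripheral*
  genes (noise sd 1.5) hang off random module genes: causally attached
  but too weakly correlated to join the co-expression module -- they are
  the non-member background that key driver enrichment needs.
- **Geometry of identifiability.** These constants are not arbitrary:
  parent-child observed correlation (~0.8) must clearly exceed
  sibling-sibling correlation (~0.65) for hub edges to be stable across
  chains; bridges must stay detectable by BIC at the discovery sample
  size while staying below the co-expression merge range. Star-like
  regulons are also what key driver analysis presumes biologically.
- **Genotypes.** Biallelic Hardy-Weinberg dosages with MAF uniform in
  [0.1, 0.5]; every key driver has a cis SNP 100 bp upstream with a
  per-allele effect of 1 on log expression. Genes sit 2 Mb apart so each
  1 Mb cis window contains only the gene's own SNP: with denser spacing,
  co-regulated neighbours of a driver become significant eGenes for the
  driver's SNP and act as false instruments.
- **Phenotype.** A liability `L = b*M + c'*X + noise` thresholded to hit
  the target case fraction, where X is the lead PBMC driver of module M1
  and M (nasal M1 lead driver) is `a*X + eqtl + noise`; defaults
  a = b = 0.5, c' = 0 (complete mediation, so the converse direction is
  exactly false).
- **Differential expression.** The remaining module-M1 members of each
  tissue get a one-directional case shift (default 0.5 natural logs;
  the disease modules in real cohorts also move together). The shift is
  exogenous with respect to the network, so large values would make the
  planted DAG no longer the data's dependency skeleton; 0.5 keeps the
  network dominant while the shift stays detectable. DE-stage recovery
  tests use a shift of 1 as their stated experiment.
- **Counts.** NB with shared dispersion 0.1 (variance mu + 0.1 mu^2),
  log-normal size factors (sd 0.2), and per-gene baselines drawn from
  U(log 50, log 500) minus half the gene's latent variance so that
  heavy-tailed module genes do not dominate library sizes.

**What a green test does not establish.** The generator has no linkage
disequilibrium, no population structure, no batch effects, no gene
length or GC bias, tissue-specific gene sets that do not overlap, and
modules that are cleanly separated in correlation space. Recovery under
this world shows the pipeline's stages are wired correctly and calibrate
where theory says they should; it does not certify performance on a real
cohort.

# Numerical and procedural choices

- **Normalization.** Abundance filtering is done on CPM as stated in the
  underlying methodology; all downstream analyses use
  `log(counts / sf + 1)` with median-of-ratios size factors, and the
  pipeline's NB offsets use the same factors. At desk scale, raw library
  sizes are dominated by the planted modules, and CPM then leaks
  phenotype-correlated compositional noise into every gene (spurious DE
  in null genes, spurious negative correlation). Median-of-ratios is
  also what the referenced DE tool uses internally.
- **Fisher sidedness.** Two-sided p-values use probability ordering (sum
  of all tables with the observed margins at most as probable as
  observed), the dominant convention.
- **Enrichment.** One-sided upper hypergeometric tail; the "enrichment
  score" is fold enrichment (observed / expected overlap).
- **DE validation.** Default follows direction-only replication in the
  test set; `strict = TRUE` additionally requires test-set FDR <= 0.05.
- **Eigengenes.** First right singular vector of the gene-standardized
  module matrix, sign-oriented to correlate non-negatively with average
  module expression. Quasi-separated logistic fits fall back to a Rao
  score test and are flagged.
- **Mediation.** Linear models throughout (binary outcome as a linear
  probability model) with HC0 sandwich standard errors; for nested OLS
  on the same samples `c = c' + a*b` holds exactly, which the tests
  assert to 1e-10. Rank-deficient designs (a noise-free chain makes the
  mediator and exposure collinear) are resolved by pivoting; aliased
  coefficients are 0 with zero SE. The permutation test shuffles the
  mediator, breaking both paths while preserving the X-Y association.
  Note the Sobel product test is conservative when both paths are null;
  it is calibrated when exactly one path is active, and the calibration
  tests use that regime.
- **Key drivers.** Background = K-step *undirected* neighborhood of the
  member list (union the members themselves); downstream neighborhoods
  are directed; per-node Bonferroni over the k values actually tested,
  then BH across nodes; `min_downstream = 5` suppresses one-target
  "drivers".
- **Determinism.** A single master seed deterministically derives
  per-stage seeds (polynomial string hash below 2^31), so every stage is
  independently reproducible and full pipeline re-runs are
  byte-identical.

# Known limitations

- Exact replication of the reference DE tool (dispersion shrinkage,
  outlier handling, independent filtering) is out of scope; the NB Wald
  GLM reproduces a Poisson GLM as dispersion goes to zero, which the
  suite checks against an independent fit.
- Module genes are over-dispersed relative to the NB model because of
  their latent propagation noise; the per-gene ML dispersion absorbs
  this only approximately, so Wald calibration is exact only for
  constant-mean genes (the calibration tests use those).
- Test-set (n ~ 113) networks are reconstructed from too few samples for
  module-bridge edges to clear the BIC threshold, so cross-set key
  driver validation is under-powered at desk scale; discovery-side
  recovery is the tested contract.
- The static 0.99 tree cut is permissive: weakly attached genes can be
  absorbed into a module, and strongly bridged modules can merge. The
  generator's constants keep the planted world inside the regime where
  the cut behaves; real data may need the dynamic cut this package
  deliberately does not implement.
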