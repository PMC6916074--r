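---
title: "Shared genetic architecture networks across quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared genetic architecture networks across quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenonet)
```

## The problem

Clinical biochemistry panels measure dozens of quantitative traits — lipids,
immunoglobulins, hormones, liver and kidney markers — on the same people.
These traits are not independent: variants with pleiotropic effects, shared
pathways and shared environments knit them into a network. phenonet
implements a phenomics workflow that asks, for every pair of traits, whether
they are linked by (a) their phenotypic correlation, (b) the overlap and
interaction of their associated genes on a protein–protein interaction (PPI)
network, or (c) their genome-wide genetic correlation, and then fuses the
three evidence channels into a single trait network whose best-connected
nodes ("hub traits") summarise the phenome's shared biology. Alongside the
network it tallies pleiotropy directly: which SNPs and genes are associated
with many traits at once.

Because real cohort genotypes are access-restricted, the package ships a
synthetic-cohort generator with known ground truth (LD structure, causal
variants, per-trait heritability, trait–trait genetic correlation), so every
stage is testable end to end.

## The pipeline

1. **QC** (`qc_filter`): keep SNPs with MAF > 0.01, exact Hardy–Weinberg
   p > 10⁻³ (computed on complete genotypes) and call rate > 95%. All three
   thresholds are strict inequalities and configurable.
2. **Stratification PCs** (`compute_pcs`): principal components of the
   standardized, mean-imputed dosage matrix; the leading components separate
   subpopulations.
3. **Association scans** (`run_scan`): per trait and SNP, OLS of the
   (log-transformed where flagged) trait on dosage with PC1, PC2 and age as
   covariates. Two-sided p-values use the t distribution with
   `n − p_cov − 2` degrees of freedom. The genomic-control factor
   λ (median χ² / 0.45494) is reported per trait.
4. **Phenotypic correlation** (`correlation_matrix`, `significant_pairs`):
   pairwise-complete Pearson (or Spearman) correlations; a pair is called
   when |r| > 0.3 *and* p < 0.01 (strict). `cluster_traits` cuts a
   complete-linkage dendrogram on 1 − r.
5. **Molecular comorbidity index** (`mci`, `mci_matrix`): traits are mapped
   to genes (any SNP with scan p < 10⁻³ inside the gene body ± 10 kb),
   restricted to the interactome, and compared by a Jaccard-style index
   whose numerator adds direct PPI cross-interactors:
   |(A∩B) ∪ {a∈A adjacent to B} ∪ {b∈B adjacent to A}| / |A∪B|.
   Pairs with MCI > 0.6 (strict) are called. With an edgeless PPI the index
   reduces exactly to Jaccard; adding edges can only increase it.
6. **LD score regression** (`ld_scores`, `h2_regression`, `rg_estimate`,
   `rg_matrix`): LD scores are windowed sums of squared dosage correlations
   (self term included, finite-sample bias corrected). Heritability comes
   from regressing χ² on ℓ (slope × M / N̄), genetic covariance from
   regressing Z₁Z₂ on ℓ; rg = ρ_g/√(h²₁h²₂). Pairs with undefined rg or
   |rg| > 1.25 are flagged as outliers; the rest are called at p < 0.05.
7. **Integration** (`integrate_pairs`, `hub_tiers`): the trait network is
   the union of the three pair sets with per-edge evidence flags; Venn
   counts are exact and satisfy inclusion–exclusion. Hub tiers encode
   degree ≥ 21, 16–20, 11–15.
8. **Pleiotropy** (`snp_pleiotropy`, `gene_pleiotropy`, `catalogue_join`):
   per-SNP and per-gene counts of traits below a threshold, and the
   cross-reference of multi-trait SNPs against an external catalogue at
   p < 10⁻⁸.

## The synthetic cohort

`simulate_genotypes` draws diploid genotypes from a latent-Gaussian copula.
SNPs come in blocks (default 50 SNPs, 1 kb spacing); within a block the
latent haplotype variables follow an AR(1) process and blocks are
independent, giving Markov-style LD that never crosses a block or
chromosome boundary. Each block draws its autoregressive parameter
uniformly from `within_block_r = c(0.7, 0.995)` by default. This range was
chosen so that the LD-score distribution is strongly heterogeneous and
right-skewed (scores from 1 to roughly 25 at the default sizes), the
feature of real genomes that gives LD score regression its leverage; with a
single shared LD strength the LD scores are nearly constant and the
regression slope is unidentifiable in any cohort of realistic size. Because
haplotypes are thresholded independently at each SNP's allele frequency,
marginal genotype frequencies satisfy Hardy–Weinberg proportions exactly;
realized dosage correlations are attenuated relative to the latent
parameter, as usual for discretized copulas.

Population stratification is a two-group allele-frequency shift
(`strat_fraction`, `strat_shift`): the minimal structure that makes PC
adjustment meaningful. Missing calls are masked completely at random.

`simulate_architecture` follows the standard additive model: causal SNPs
are drawn uniformly; per-SNP effect vectors are multivariate normal across
traits with the target genetic correlation matrix, scaled so each causal
SNP explains equal variance on the standardized-genotype scale; effect
columns are then rescaled so the realized genetic variance equals the
heritability target. `simulate_traits` adds a uniform age (20–69 years)
effect and multivariate-normal environmental noise scaled so each trait has
total variance ≈ 1. An optional `lognormal` switch exponentiates selected
traits to emulate the right-skewed biochemical measurements that motivate
log transformation; no attempt is made to match the skewness of any
particular real trait.

What the generator deliberately does **not** emulate: realistic human LD
maps and recombination hotspots, allele-frequency spectra, imputation
uncertainty, relatedness, sex differences (the motivating cohort is
male-only), or genotyping batch artifacts. Passing tests on this cohort
demonstrate the estimators' correctness and calibration under a clean
additive model, not robustness to those real-data complications.

## Numerical and design choices

* **HWE test**: plain exact conditional tail (no mid-p), the QC standard;
  monomorphic SNPs return p = 1; the test uses complete genotypes only.
* **Missing dosages** are mean-imputed inside each SNP's regression rather
  than dropped, keeping the sample size stable; the observed-genotype count
  is reported separately (`n_geno`).
* **Degenerate SNPs** (zero dosage variance) report beta = 0, p = 1, are
  flagged, and are excluded from λ and the sumstats.
* **PC signs** are fixed by making each component's largest-magnitude
  loading positive, so outputs are bitwise reproducible.
* **LDSC weights** are a single pass of 1/max(ℓ, 1) — a deliberate
  simplification of the reference implementation's iterative
  heteroscedasticity weights, adequate at the scales the package targets.
  The intercept is always free: in a single-cohort design the cross-trait
  intercept must absorb complete sample overlap.
* **Jackknife**: 20 contiguous equal-count SNP blocks by default; the rg
  standard error jackknifes the full ratio (all three regressions per
  block).
* **Outlier rule** for rg pairs (undefined, or |rg| > 1.25) is exposed as
  configuration, as is every threshold above.
* **Clustering ties**: traits are sorted alphabetically before clustering
  so the partition is independent of input order.
* **Coordinates**: gene maps are BED-convention (0-based half-open); SNP
  positions are 1-based; the overlap layer converts internally and is
  tested on boundary positions.
* **SNP→gene mapping** is positional (body ± 10 kb window by default).
  A web-tool annotation used in earlier practice is not reproducible
  offline; positional mapping is transparent and configurable.
* **"Cross-interactors" in the MCI** are direct PPI neighbours (path length
  1); longer paths would require a distance parameter with no principled
  default.
* **Linear model**: the scan is fixed-effect OLS with PC and age
  covariates. A mixed model is a documented non-goal; at the simulated
  relatedness (none) the two coincide.

## Problem sizes used in the tests

Unit tests run on small panels (tens to hundreds of samples). The
statistical validation suite uses the cohort scale the package targets:
2,000 samples and 20,000 LD-blocked SNPs with fully polygenic h² = 0.5
traits for LD score regression recovery (true rg ∈ {−0.5, 0, +0.5}, ten
architecture seeds per setting over two genotype panels — the panel plays
the role of the fixed cohort genome, so architecture and noise vary within
it), the same scale for null calibration of λ and scan p-values, and a
planted 3-hub / 5-isolated architecture (800 samples, 6,000 SNPs; the
isolated traits are non-heritable, the strongest form of genetic isolation,
so their undefined genetic correlations also exercise the outlier-removal
path) for end-to-end network recovery. At these sizes the whole suite completes in
well under half an hour on a single CPU. `scripts/acceptance.R` re-runs the
same computations from scratch and writes the headline numbers as JSON.

## Known limitations

* LDSC at 20,000 SNPs and n = 2,000 carries large sampling error
  (jackknife SEs of 0.1–0.4 on h² and rg are typical); estimates are
  approximately unbiased and the jackknife intervals are honest, but
  single-trait point estimates at this scale are indicative only.
* The MCI depends strongly on interactome coverage: genes without curated
  interactions silently shrink both numerator and denominator. The
  `restrict_to_interactome` step reports the per-trait loss.
* The catalogue join is only as current as the supplied catalogue table;
  version-dependent counts are out of scope.
* With a sparse scan (few SNPs below threshold) trait gene sets can be
  empty; their MCI pairs are reported as missing, never as zero.

## A short worked example

```{r example, eval = FALSE}
library(phenonet)
bundle <- run_pipeline(list(seed = 5L))
bundle$qc_report
bundle$lambda_gc
bundle$venn
head(bundle$network$edges)
bundle$hub_tiers
```
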