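---
title: "Methods: allele-specific expression and expression patterns during electric-organ ontogeny"
author: "eodase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression and expression patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The design and the model

The package targets a two-species/F1-hybrid bulk RNA-seq design sampled
at two life stages. Two parental cohorts (called `parentA` and
`parentB` throughout; in the motivating system, a species with a
constant ~0.4 ms electric organ discharge and one whose discharge
elongates from ~5 ms to ~40 ms during ontogeny) are genotyped together
with juvenile and adult F1 hybrids. At any site where the parental
cohorts are fixed for alternate alleles, each hybrid read is assignable
to a parental subgenome, and the parent-A allelic proportion

\[ p = \frac{d_A}{d_A + d_B} \]

of the allelic depths measures relative allelic expression. The
package's inferential targets are (i) the per-gene, per-stage mean of
`p`, (ii) its classification into *balanced* (`p` in `[0.45, 0.55]`) or
parent-dominant, (iii) the ontogenetic shift `|p_adult − p_juv|` with a
flag at `> 0.1`, and (iv) a stage comparison of per-sample gene
proportions after the variance-stabilizing arcsine-square-root
transform, by two-sided Welch t-test.

Key modelling assumptions: reads are assigned without mapping bias
(assumed corrected upstream, e.g. by WASP-style filtering); allelic
counts at a site are beta-binomial around the gene's latent proportion
(overdispersion from library and biological noise); SNPs within a gene
share that latent proportion, so the gene value is their unweighted
mean; and individuals are independent, which forces the unpaired test.

## Filtering rules and their defaults

| parameter | default | meaning |
|---|---|---|
| `qual_min` | 70 | minimum variant QUAL for a usable site |
| `depth_min` | 10 | minimum per-sample two-allele depth at a site |
| `band` | [0.45, 0.55] | inclusive balanced-expression band |
| `shift_threshold` | 0.1 | ontogenetic shift flag, strict `>` |
| `max_missing` | 0 | missing parental genotypes tolerated |

Decisions that were genuinely open, and the package's choices:

* **"Fixed" is strict.** Every parental sample must be called and
  homozygous, cohorts on opposite alleles. Missing genotypes are not
  counted as support; `max_missing` can relax this explicitly.
* **The depth filter applies to the two-allele total** (`d_A + d_B`),
  not per allele: the precision of a proportion is governed by the
  total informative depth, and a per-allele rule would bias against
  strongly imbalanced genes.
* **The band is inclusive at both ends and the shift rule is strict**
  ("over 0.1"); both are configurable, and `detect_shift()` compares
  with a `1e-9` tolerance so decimally-boundary magnitudes (e.g.
  `|0.20 − 0.30|`) behave as their decimal values.
* **Arcsine transform** is `asin(sqrt(p))`, the variance-stabilizing
  form for proportions; plain `asin(p)` is available as an option.
  Welch's unequal-variance test is the default since stage groups are
  small and their variances need not match.
* **Stage-test p-values are reported raw** by default (the emulated
  workflow reports per-gene raw P); a BH option exists.
* **Missing `AD` is a missing observation**, never zero depth — zeros
  would silently pass or fail the depth filter.
* **A SNP mapping to two genes is an error** by default (per-gene
  averaging is ill-defined under double counting); a flag assigns it to
  all its genes with a warning.

## The expression arm

Counts are cleaned by the low-count rule (keep genes with count > 10 in
at least two samples), normalized by median-of-ratios size factors
(median over all-positive genes of `count / geometric row mean`,
rescaled to geometric mean 1). One subtlety is documented rather than
hidden: with the reference recomputed from the data, scaling one
library by `c` multiplies its factor *relative to every other sample*
by exactly `c` (asserted in the tests); the absolute factors move only
up to the overall geometric-mean convention.

PCA is performed on gene-centered `log2(normalized count + 1)` via the
sample-space covariance — no per-gene variance scaling — so
high-variance genes dominate exactly as in the covariance convention.
The `+1` offset keeps zeros finite and is deliberately simple; a
variance-stabilizing transform is out of scope.

**Association with EOD duration.** Durations span two orders of
magnitude (0.4–40 ms), so duration enters the per-gene NB GLM as
`log10(duration)` (a linear-in-ms covariate would let the longest
group dominate); a factor mode exists. Per gene, the full model
(intercept + `log10` duration, size-factor offsets) is compared with
the intercept-only model by twice the log-likelihood difference, with
one dispersion per gene shared by both models, estimated once under the
full model. Two numerical choices matter at `n = 30`:

* the moment dispersion solves the Pearson matching equation
  `sum((y − mu)^2 / (mu + alpha mu^2)) = n − p` (floored at `1e-8`),
  which accounts for the residual degrees of freedom — the naive
  `(y − mu)^2` moment estimator from fitted means is biased low;
* the statistic is referred to `F(df, n − p)` rather than
  `chi-squared(df)` (option `ref = "chisq"`), because the dispersion is
  itself estimated from the same few samples; the plug-in chi-squared
  reference is measurably anticonservative at this size (empirical
  type-I ~0.08 at nominal 0.05), while the F reference is calibrated
  (~0.05, Kolmogorov–Smirnov test of null p-values against uniform not
  rejected; both measured on 2000 simulated flat genes in the test
  suite and acceptance script).

No dispersion shrinkage across genes is attempted — this is a
documented self-contained stand-in, not a re-implementation of a
full DE engine.

**Pattern clustering.** Significant genes (BH-adjusted p below
`lrt_alpha`, default 0.05) are summarized as z-scores of mean
log-expression per cohort-stage condition, clustered hierarchically
(correlation distance, average linkage) and cut into `k` groups
(default 14, mirroring the emulated analysis; group *numbering* is
arbitrary). A group is labelled increasing/decreasing when the Spearman
correlation between its medoid profile and the conditions' EOD
durations reaches ±0.8. Constant profiles get zero z-scores and an
undefined correlation, which maps to `non-monotone`.

**Pairwise DE and triage.** The adult-vs-juvenile contrast per cohort
uses the same NB machinery (Wald p on the stage coefficient); the
reported `log2FC` comes from normalized stage means with a pseudo-mean
`eps = 0.5` substituted for zero means so it is always finite. DEG
flags use raw p by default (`|log2FC| > 1`, `p < 0.05`, both
configurable). Venn sets are `A = (rhy ∩ hybrid) \ com`,
`B = com \ (rhy ∪ hybrid)`, `C = com ∩ rhy ∩ hybrid` — disjoint by
construction. The triage ledger records, for every gene in a monotone
cluster group, membership in the five evidence lists (A, B, C, and two
externally supplied lists), and calls a candidate at `min_evidence >= 3`
lines of evidence. Note one ambiguity inherited from the emulated
workflow: "in set A and B" can only mean the union, since A and B are
disjoint; the union is what the ledger's flags afford. Fisher's exact
enrichment (two-sided, via the exact hypergeometric null) is computed
per annotation term against a user background; terms annotating no
background gene are skipped and counted.

## What the simulator emulates — and what it does not

The generator reproduces the statistical skeleton of the study design:

* 5 individuals per cohort and stage; hybrid EODs 0.4 ms (juvenile) to
  4 ms (adult), parental cohorts at 0.4/0.4 and 5/40 ms;
* parental genotypes with, in expectation, `frac_fixed_sites` fixed
  differences and three planted confounder classes (shared homozygote,
  heterozygous parent, low QUAL < 70), each rejected by a distinct
  filter so the filters are unit-testable;
* hybrid allelic depths: total ~ Poisson(`depth_mean`), zeros resampled
  (a proportion is undefined at zero depth and the real depth filter
  removes such sites; `allow_zero_depth` re-enables them to test the
  filter), parent-A counts beta-binomial with intra-class correlation
  `rho`, parameterized so `rho = 0` is exactly binomial;
* NB expression counts with per-gene mean
  `baseline * 2^(slope * log10(duration / d0))`, so `slope` is the
  log2 fold change per duration decade and flat genes have slope
  exactly 0.

Defaults chosen once where the design left them open, with the
reasoning:

* `snps_per_gene_mean = 25` (of which ~70% fixed, i.e. ~17 informative
  SNPs per gene): congeneric coding sequence of a few kb at ~1% fixed
  divergence carries sites at this order, and a per-gene aggregate over
  many SNPs is what makes stage means precise enough (analytic SD
  ~0.02) for the band/shift geometry used here. The per-site
  overdispersion `rho = 0.1` at depth 50 leaves only ~8 effective reads
  per site, so the SNP count per gene, not the depth, governs
  precision.
* true proportions are drawn clear of the band edges (margin 0.04) with
  ~60% balanced genes and 10% of genes shifted by exactly 0.15 — the
  regime the recovery experiment quantifies (accuracy, recall,
  false-flag rate are measured against this truth in the acceptance
  script).
* the two-gene worked scenario (0.30 → 0.20 and 0.55 → 0.67) uses depth
  100, 10 SNPs/gene and `rho = 0.05`, chosen by an a-priori power
  calculation so the arcsine t-test has power comparable to the
  per-gene aggregation of a typical multi-SNP coding sequence; with a
  truth of 0.55 sitting exactly on the inclusive band edge, the
  faithful juvenile call is "near-equal" (balanced or marginally
  parent-A dominant), and the tests assert exactly that.

Features of real data the simulator does **not** model, and which
passing tests therefore say nothing about: read-level artefacts and
mapping bias (no FASTQ simulation), reference bias toward the genome of
one parent, multi-allelic sites and indels, linkage between SNPs within
a gene (sites are conditionally independent given the gene proportion),
per-individual biological variation of the latent proportion beyond
beta-binomial site noise, and library-composition effects beyond global
size factors.

## Problem sizes and determinism

The shipped tests and the acceptance script use 200-gene recovery
experiments, 2000-gene null calibrations and ≤50-site oracle fixtures —
sizes chosen so each property is measured with useful precision while
the whole suite stays fast. Every generator function seeds the RNG from
`sim_config$seed` (sub-streams offset by small constants), so identical
configurations give byte-identical bundles; `run_all()` reruns are
byte-identical for fixed inputs.

## Known limitations

* The fixed-difference rule is conservative: polymorphic-but-divergent
  sites are discarded, so genes without fixed differences are invisible
  to the ASE arm (in the motivating system only a few hundred genes
  carry fixed SNPs).
* The LRT stand-in estimates one dispersion per gene with no sharing
  across genes; at very low counts its dispersion estimate is noisy and
  power suffers relative to shrinkage-based engines.
* cis/trans decomposition, phasing, and mapping-bias correction are out
  of scope; the package consumes a VCF and count matrix as given.
* The stage test treats per-sample gene proportions as independent
  observations; with very few SNPs per gene the arcsine transform's
  variance stabilization is approximate.
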