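---
title: "Haplotype heritability mapping: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype heritability mapping: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

For a quantitative phenotype $y$ on $N$ individuals and a candidate
genomic window, `haplohm` fits

$$y = X\beta + g_r + g_w + e, \qquad
  g_r \sim N(0, K_r\,\sigma^2_r),\;
  g_w \sim N(0, K_w\,\sigma^2_w),\;
  e \sim N(0, I\,\sigma^2_e),$$

where $K_w$ is the usual genome-wide SNP relationship matrix and $K_r$ a
*regional* relationship matrix computed from the window only. Two regional
estimators are available:

* **SNP-based (RHM).** With dosages $O_{ik} \in \{0,1,2\}$ and counted-allele
  frequencies $P_k$ over the window's $S$ polymorphic SNPs,
  $$\mathrm{IBS}_{ij} = \frac1S \sum_{k=1}^{S}
    \frac{(O_{ik} - 2P_k)(O_{jk} - 2P_k)}{2P_k(1-P_k)}.$$
* **Haplotype-based (HHM).** The window's $H$ distinct haplotype alleles are
  enumerated over the $2N$ phased chromosomes; $Q_{ik}$ counts how many
  copies of allele $k$ individual $i$ carries and $P_k$ is the allele's
  chromosome frequency:
  $$\mathrm{HIBS}_{ij} = \frac1H \sum_{k=1}^{H}
    \frac{(Q_{ik} - 2P_k)(Q_{jk} - 2P_k)}{2P_k(1-P_k)}.$$

For a 1-SNP window the two coincide exactly (a property the test suite
asserts at $10^{-12}$). Two individuals sharing an allele of frequency $p$
contribute $(2-2p)^2 / (2p(1-p)H)$ — strictly decreasing in $p$ — so rare
shared alleles dominate the estimated relationship. Haplotype alleles
routinely reach frequencies far below SNP minor-allele frequencies, which
is the mechanism by which HHM detects rare causal variation that SNP
estimators miss.

The regional component is tested by
$\mathrm{LRT} = \max\{0,\, 2(\ell_{\text{full}} - \ell_{\text{null}})\}$
against the model without $g_r$. Because $\sigma^2_r$ is tested on the
boundary of its space, the asymptotic null is the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; about half of all null LRTs are
exactly zero. The per-window summary is the regional heritability
$\mathrm{RH} = \sigma^2_r/(\sigma^2_r + \sigma^2_w + \sigma^2_e)$.

### Frequencies

Allele and haplotype frequencies are estimated from the analyzed
individuals themselves, not from an external reference. This makes the
GRMs exactly centered (the grand sum of every sample-frequency GRM is 0, a
tested invariant) and keeps the tool self-contained. Using base-population
instead of analyzed-sample frequencies was considered and rejected: the
estimators are defined for whatever sample is in hand, and the choice only
matters at second order.

## Analysis windows

Windows are haplotype blocks delimited by recombination hotspots in a
*reference* genetic map: the interval between two adjacent SNPs is
assigned the maximum map rate over its bp span, and a boundary is placed
wherever that rate is at least the threshold (5 or 10 cM/Mb
conventionally; the comparison is inclusive). Design points:

* the interval rate is a *maximum over the span*, so a hotspot lying
  strictly between two SNPs splits them even though neither SNP sits on
  it — hotspots are features of intervals, not of SNP positions;
* a map breakpoint exactly on a SNP position is assigned to the interval
  preceding that SNP (the map convention "rate applies from this position
  to the next row" makes any other choice ambiguous);
* single-SNP windows are legal and retained;
* windows at a lower threshold nest inside windows at a higher threshold
  (hotspots at $\ge t_2$ are a subset of those at $\ge t_1 < t_2$), a
  tested invariant.

Blocks are deliberately *not* inferred from the sample's own LD: a
reference map yields windows that are identical across cohorts and chips,
enabling meta-analysis.

## REML implementation

* **Two-component fits** use dense average-information (AI) REML:
  Cholesky of $V = K_r\sigma^2_r + K_w\sigma^2_w + I\sigma^2_e$ per
  iteration; scores and the AI matrix from $Py$; an
  expectation-maximization step whenever the AI proposal fails to improve
  the restricted likelihood (after six step-halvings); convergence at
  relative log-likelihood change $<10^{-8}$ or parameter change
  $<10^{-6}\cdot\mathrm{var}(y)$, at most 200 iterations.
* **Boundary handling.** Variances are floored at
  $10^{-8}\cdot\mathrm{var}(y)$ during iteration (keeping $V$ positive
  definite) and reported as 0 when they finish at the floor. Components
  pinned at the floor whose score points further down are frozen out of
  the AI step (active set); without this the iteration crawls near the
  boundary and LRTs acquire $10^{-5}$-scale negative noise. The LRT is
  floored at 0.
* **Single-component fits** (the null model, and regional-only passes in
  the fast modes) are solved exactly in the kernel's eigenbasis by
  profiling $\sigma^2_e$ out and optimizing the variance ratio in one
  dimension (coarse log-grid, then Brent). Regional GRMs carry their
  low-rank loadings $Z$ (with $K = ZZ^\top$), so their eigenbasis costs
  $O(Nm^2)$ instead of $O(N^3)$; the whole-genome GRM is decomposed once
  per data set (`grm_precompute_eigen`) and reused across windows and
  replicates. All three likelihood paths share one constant convention,
  verified against an independent determinant/solve evaluation, so LRTs
  may mix them.
* **Starting values**: $\sigma^2_e = \tfrac12\mathrm{var}(y)$, the genetic
  components splitting the other half equally — neutral and
  scale-equivariant (scaling $y$ by $c$ scales all estimates by $c^2$ and
  leaves RH and LRT unchanged, a tested invariant).
* A component matrix numerically equal to $I$ is rejected: its variance is
  not separable from the residual.
* **Fast approximations**, for genome-scale scans: (i) a regional-only
  first pass (whole-genome component omitted) with full refits of the top
  fraction of windows; (ii) GRAMMAR-style pre-adjustment, regressing out
  the whole-genome BLUP once and scanning the residuals with
  regional-only fits. The GRAMMAR residuals here are plain BLUP residuals
  $y - X\hat\beta - \hat g_w = \hat\sigma^2_e V^{-1}(y - X\hat\beta)$,
  without the deregression factor of GRAMMAR+; with an intercept in $X$
  they have exactly zero mean. Both approximations are flagged
  `approximate` in scan output, and refitted windows reproduce the full
  scan exactly (tested).

## Significance thresholds

`bonferroni_threshold(alpha, n_windows)` returns the LRT value whose null
upper-tail probability is `alpha/n_windows` under the
$\tfrac12\chi^2_0+\tfrac12\chi^2_1$ mixture (a pure $\chi^2_1$ null is
available). Published genome-wide rules — 21.60 for 5 cM/Mb windows,
20.60 for 10 cM/Mb — are *not* reproduced by either null at the published
window counts (the mixture gives 22.62 at $\alpha=0.05$, $n=50{,}604$);
the distributional assumption behind those constants is not stated in the
source. They are therefore supported through the `override` argument and
used verbatim when reproducing published decision rules, rather than
silently re-derived.

## The synthetic cohort

No real cohort ships with the package; the simulator is first-class code
and the stand-in for one. It emulates, feature by feature:

* **Block-structured haplotypes.** Each chromosome is a chain of blocks
  separated by hotspot intervals. Per block, haplotype-allele frequencies
  are drawn from a symmetric Dirichlet with concentration 0.3 — small
  enough that most alleles are rare (the median of the per-block minimum
  haplotype frequency is below 0.02, matching the rare-variant regime the
  method targets; tested). Each allele is a distinct random binary SNP
  string; chromosomes are sampled independently across blocks.
* **Genome geometry.** Defaults: 5 chromosomes × 60 blocks, 1–12 SNPs per
  block (≈ 5–7 SNPs per window on average, matching the per-window
  density of a 300K array partitioned into ~50K hotspot windows), SNPs
  5 kb apart, hotspot intervals of 20 kb at 50 cM/Mb against a 1 cM/Mb
  baseline. The emitted genetic map is consistent with these rates, so
  `define_blocks` at any threshold in (1, 50] recovers the generating
  blocks exactly (tested). The genome-to-sample ratio is S/N ≈ 2 — far
  below a real array's ≈ 120, but large enough that the whole-genome
  GRM's eigenvalues stay $O(1)$; with toy genomes (S ≪ N) the null model
  already predicts inflated variance along any marker direction and
  window LRTs are structurally deflated, an artifact of genome size
  rather than of either estimator. This is the main respect in which a
  green test here understates real-data power.
* **Demography.** Constant population size, discrete generations, sexes
  assigned 1:1 at birth, parent pairs drawn uniformly with replacement,
  one child per mating, 20 generations by default. Gametes recombine via
  a Poisson crossover process on the cM scale with no interference and no
  mutation (the standard neutral choice; the source pipeline does not
  specify a recombination model). One-generation drift variance matches
  $p(1-p)/2N$ and transmission is an exact parental mosaic (both tested).
* **QC.** Drift fixes rare variants, so the emulated panel is passed
  through the same QC as a real one (MAF < 0.01, exact-test HWE
  $P < 10^{-8}$, call rate < 0.95) before windows are defined — the
  analysis always sees a post-QC panel. The HWE test is the exact
  enumeration test, not the $\chi^2$ approximation, because the
  frequencies of interest are exactly where the approximation fails.
* **Phenotypes.** Four regional architectures on a causal window:
  `1SNP` (one SNP's dosage), `AllSNP` (every SNP, effects
  $\propto 1/\sqrt{2P(1-P)}$ with random signs so each SNP contributes
  equal variance before scaling), `1Hap` (one haplotype allele chosen
  uniformly among the window's distinct alleles, *regardless of
  frequency*, so most draws are rare), `AllHap` (one standard-normal
  effect per haplotype allele). The polygenic value sums standard-normal
  effects over all SNPs outside the region. Components are centered,
  successively orthogonalized and rescaled so the realized variances are
  *exactly* 0.05, 0.25 and 0.70 and $\mathrm{var}(y)=1$ exactly — the
  empirical orthogonalization is this package's way of making
  parameter-recovery tests sharp; it perturbs the polygenic and residual
  draws by their sample projection on the preceding components, a
  $O(1/\sqrt N)$ adjustment.
* **Seeding.** One master seed; named sub-seeds are derived for each
  replicate (and internally for mating, effects, residuals) so
  architectures can be compared on identical genotypes and any replicate
  can be replayed in isolation.

### Open choices, resolved

* `1Hap` draws the causal allele uniformly over *distinct* alleles, not
  over chromosomes — "regardless of haplotype frequency" admits only the
  former reading.
* The polygenic background excludes only the causal region's SNPs, not
  the whole chromosome.
* The whole-genome GRM includes the tested window's SNPs by default
  (exclusion is an option); nothing in the method requires leaving them
  out, and with realistic genome sizes the difference is negligible.
* `AllSNP` effect signs are random ±1; only "equal variance per SNP" is
  specified, and signs do not affect the per-SNP variance contribution.
* Variances are constrained non-negative (estimates at the floor report
  as 0) rather than allowed negative.
* In the window-enlargement study, regions whose enclosing
  larger-threshold window is identical contribute ratio 1; the study
  errors only when *no* region has a strictly larger enclosing window
  (an all-identical comparison measures nothing).

## Degenerate inputs and numerical edges

* Monomorphic SNPs are dropped from Eq.-style estimators (undefined
  denominators); windows with no polymorphic SNP, or a single haplotype
  allele ($H=1$), are skipped with an explicit reason carried into scan
  output rather than silently vanishing.
* Missing genotypes are representable only pre-QC; every analysis
  operation demands a complete panel. `qc_filter` iterates to a fixed
  point (SNP removal changes individual call rates and vice versa), which
  is what makes it idempotent.
* Haplotype alleles are ordered by descending frequency with
  lexicographic tie-break, so enumeration — and everything downstream —
  is deterministic. Scans are sequential and deterministic given inputs.

## Known limitations

* Phasing is assumed: unphased or missing GT fields are an error, not an
  imputation trigger. No PLINK binary support; no sex chromosomes.
* The simulator has no mutation, selection, migration or population
  structure, and its S/N ratio is compressed relative to real arrays (see
  above); absolute LRT magnitudes on synthetic data therefore understate
  real-data values, while RH estimation accuracy transfers.
* Only two genetic variance components; no dominance or epistatic
  relationship matrices; no binary-trait liability model.
* Null-distribution thresholds assume the boundary mixture; permutation
  thresholds are out of scope.
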