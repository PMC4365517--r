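---
title: "Pedigree and genomic relationship estimation under MAF-restriction scenarios"
author: "relkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree and genomic relationship estimation under MAF-restriction scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relkit)
```

## The problem

Breeding and conservation decisions in livestock rest on estimates of how
related animals are and how inbred they are. Three data sources give such
estimates: pedigree records, SNP-chip genotypes, and whole-genome sequence
(WGS) genotypes. They do not measure the same thing. Pedigree gives the
*expected* proportion of genome shared, relative to an assumed unrelated
founder population (identity by descent, IBD). Markers measure the *realized*
shared proportion (identity by state, IBS), which differs from the
expectation through Mendelian sampling, and whose reference population is set
by the allele frequencies used. Chips are further ascertained towards common
variants, so rare alleles — most of the variation a conservation programme
wants to keep — are visible only in sequence data.

`relkit` implements the estimators and the complete comparison analysis
needed to study these differences, together with a gene-dropping simulator
that provides ground truth, so every stage is testable without access to any
restricted data set.

## Estimators

**Pedigree additive relationships** are computed by the tabular method over
the whole pedigree in topological order:

\[
A_{xy} = \tfrac12\,(A_{s(x),y} + A_{d(x),y}), \qquad
A_{xx} = 1 + \tfrac12 A_{s(x),d(x)},
\]

with unknown parents contributing 0 (founders unrelated and non-inbred).
Wright's inbreeding coefficient is \(F_x = A_{xx} - 1\), computed
independently by a memoised kinship recursion (`pedigree_inbreeding()`) and
cross-checked against the tabular diagonal in the test suite.

**The frequency-weighted (Yang) genomic estimator** standardises each variant
by its heterozygosity. With genotype \(x_{ij} \in \{0,1,2\}\) counting copies
of the coded allele with frequency \(p_i\):

\[
G_{jk} = \frac1N \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1-p_i)},
\qquad
G_{jj} = 1 + \frac1N \sum_i
  \frac{x_{ij}^2 - (1+2p_i)x_{ij} + 2p_i^2}{2p_i(1-p_i)}.
\]

The diagonal uses its own formula, which corrects for the sampling of an
individual's own alleles. Division by \(2p(1-p)\) gives rare variants more
weight, which is why this estimator is sensitive to the MAF make-up of the
variant panel. Frequencies default to the current-sample estimate
\(\hat p_i = \overline{x_i}/2\) (the common practice the analysis is designed
to study); user-supplied frequencies support founder-frequency experiments.

**The similarity estimator** counts shared alleles without frequency
weighting:

\[
\mathbf G = \frac{(\mathbf M - 1)(\mathbf M - 1)'}{N/2},
\]

equivalent to fixing all frequencies at 0.5. Its entries lie in \([-2, 2]\):
\(-2\) for opposing homozygotes at every variant, \(2\) for identical
homozygotes, and an individual's diagonal equals twice its homozygous
fraction. Genomic inbreeding for either estimator is the self-relationship
minus 1 and may be negative (an excess of heterozygous genotypes relative to
the frequencies used).

Both genomic estimators are invariant to which allele is coded (proven per
variant, tested exhaustively), accumulate per-variant contributions in
blocks so sequence-scale panels never require a standardised copy of the
whole genotype matrix in memory, and are averaging-consistent: the estimate
on a concatenation of panels is the variant-count-weighted average of the
per-panel estimates.

## MAF scenarios and the exact HWE test

Variants are filtered by minor allele frequency into three scenarios:
common (`5+`, MAF ≥ 5%), common-plus-rare (`1+`, MAF ≥ 1%) and rare-only
(`1_5`, 1% ≤ MAF < 5%). Intervals are half-open \([\ell, h)\) with the top
value 0.5 always kept, so `1+` is the exact disjoint union of `5+` and
`1_5` — a property asserted on every data set the tests touch. The 1%
floor corresponds, at 118 diploids, to requiring at least 3 copies of the
minor allele (2 copies give MAF \(2/236 \approx 0.85\% < 1\%\)).

Departure from Hardy–Weinberg proportions is tested with the exact
conditional test: given \(n\) individuals and \(n_m\) minor alleles, the
null probability of \(h\) heterozygotes is proportional to
\(n!/(n_{aa}!\,h!\,n_{AA}!)\cdot 2^h\), and the p-value sums all
configurations no more likely than the observed one (ties included; a mid-p
variant is available but off by default, since the plain exact construction
is the standard one). The test is exact at any MAF, which is the reason to
prefer it over the chi-square approximation for rare variants. Note the
test is *conservative* under the null — discreteness keeps the rejection
rate at or below the nominal level — so calibration checks assert
conservative-to-nominal behaviour rather than a symmetric envelope around
\(\alpha\).

## The synthetic cohort

`sim_config()` defaults describe the kind of cohort the analysis targets: a
dairy-cattle-like panel of 118 genotyped individuals drawn (with recency
weighting) from a 5-generation pedigree of 40 founders and 40–60 offspring
per generation, containing parent–offspring pairs, full-sib pairs, half-sib
families of 2–5, and occasionally inbred matings
(`p_inbred_mating = 0.08`). Founder MAF spectra are `"uniform"` on
\([1\%, 50\%]\) (chip-like) or `"l_shaped"` with density \(\propto 1/p\)
(sequence-like); `chip_thinning()` emulates chip ascertainment from
sequence-like data by stratified sampling to a flat MAF histogram.

`gene_drop()` transmits founder alleles down the pedigree, one uniformly
chosen allele per parent per variant, at unlinked loci. With
`track_founder_alleles = TRUE` every founder allele carries a unique label
and the exact IBD relationship matrix is returned on the additive scale; its
expectation over replicate drops equals the pedigree \(\mathbf A\), which is
how the suite verifies, at a scale where it is literally testable, that the
frequency-weighted estimator computed with *true founder* frequencies is an
unbiased estimator of pedigree relationships.

Pedigree-depth variation is created by an *observed* copy of the pedigree in
which non-genotyped ancestors lose their parent records with probability
`record_loss = 0.15`; genotyped individuals always keep both parents, so
complete-generation depth is at least 1 and varies above that. With
independent masking the depth-group sizes are qualitative (nested,
decreasing, all non-empty at thresholds 1/2/4) rather than an exact match to
any particular cohort; real herdbook record quality is correlated along
lineages, which independent masking cannot reproduce and the package does
not attempt to.

What the simulator deliberately omits: linkage and LD (none of the
estimators uses it and all formulas are per-locus sums), mutation,
selection, genotyping error and imputation error. Passing tests therefore
demonstrate correctness of the estimators and comparisons under Mendelian
transmission at unlinked loci — not robustness to LD structure or data
quality problems in real sequence data.

## Comparison machinery

Pairs are grouped by the pedigree value: first degree \([0.5, 1)\), second
degree \([0.25, 0.5)\), less related \([0, 0.25)\); the diagonal feeds the
inbreeding analysis. Descriptive statistics use the \(n-1\) variance.
Correlations are Pearson's, with the t-test against 0 from `cor.test`;
because a Fisher-z test against exactly 1 is degenerate, "different from 1"
is declared when the Fisher-z 95% interval's upper bound falls below
\(1 - \varepsilon\) with \(\varepsilon = 5\times10^{-4}\) by default, and
the method is recorded in every result. Scenario differences are tested
with the paired Wilcoxon signed-rank test on the pooled off-diagonal
estimates; the exact null distribution is computed by dynamic programming
over doubled midranks for \(n \le 25\) (exact even under ties), with a
continuity- and tie-corrected normal approximation above. Correlations from
different depth groups are compared with the independent-samples Fisher-z
test, annotated as approximate because nested groups are not independent.

## Numerical and design choices

* Tie handling in the exact tests uses a relative tolerance of \(10^{-10}\)
  when comparing configuration probabilities computed in log space.
* Monomorphic variants are removed (with a logged count) before either
  estimator; user-supplied frequencies must lie strictly in (0, 1).
* Missing genotypes default to an error (`missing_policy = "fail"`), since
  the intended input is fully imputed; mean imputation (rounded) and
  variant dropping are conveniences.
* Multi-allelic VCF records are skipped, not split: the estimators are
  biallelic.
* All simulation entry points require an explicit integer seed and restore
  the caller's RNG state; outputs are bit-reproducible per seed.
* Monte-Carlo recovery checks compare per-entry deviations to their own
  Monte-Carlo standard errors. With a few hundred entries, one or two
  |z|-scores above 3 are the expected behaviour of an unbiased estimator,
  so the suite bounds the exceedance *fraction* (≤ 2%, max |z| < 5, mean
  z ≈ 0) instead of asserting a literal elementwise 3-SE band that an
  exactly unbiased estimator would fail on a large share of seeds.
* Problem sizes in the validation suite — a 20-member pedigree with
  \(10^5\) variants and 200 replicate gene drops for recovery; 118
  individuals with \(10^5\) L-shaped variants and 20 resampling replicates
  for the frequency-sensitivity analysis; a 118-individual cohort with
  30,000 sequence-like variants thinned to a 4,000-variant chip for the
  scenario comparison — were chosen as the smallest scales at which the
  Monte-Carlo standard errors are decisively below the effects being
  demonstrated.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(n_variants = 30000L, seed = 2026),
  n_chip = 4000L)
res <- run_pipeline(cfg)
res$hwe
res$report
```

The report contains the scenario variant counts (with the `1+` row equal to
the sum of `5+` and `1_5` for each source), per-group descriptive
statistics for every matrix, the correlation table with significance flags,
the paired Wilcoxon results, and the depth-stratified inbreeding
correlations.

## Known limitations

* Unlinked loci only; no LD-aware variance corrections.
* The "different from 1" flag is a confidence-interval convention, not a
  formal test against a composite boundary; its \(\varepsilon\) is
  configurable and always recorded.
* The depth-group comparison assumes independent samples although the
  groups are nested; the result carries that annotation.
* Pedigree storage is dense: the tabular \(\mathbf A\) is quadratic in
  pedigree size, fine for cohorts of thousands but not for national
  herdbooks (the inbreeding recursion itself never materialises
  \(\mathbf A\)).
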