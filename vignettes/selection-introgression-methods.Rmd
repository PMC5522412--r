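---
title: "Methods: selection tests, constraint matching, introgression and sweep scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection tests, constraint matching, introgression and sweep scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selintro)
```

# Scope and model

`selintro` implements the statistical core of a multi-stage evolutionary
analysis of candidate gene modules — the kind of analysis applied to gene
sets implicated in neurodevelopmental disorders, where one asks whether a
module's genes were shaped by episodic positive selection deep in the
vertebrate phylogeny, by unusually strong purifying selection in modern
humans, by admixture with archaic hominins, or by selection in early modern
humans after the archaic split.

The package deliberately does **not** fit codon models, site-level selection
methods, population-genetic mixed models, or introgression maps: those are
produced upstream by specialised tools, and `selintro` consumes their
outputs (paired log-likelihoods, per-codon posteriors and p-values,
constraint parameters, per-SNP ancestry probabilities and sweep-scan
scores). What the package owns is everything downstream of those fits:
the declaration rules, the multiple-testing handling, the consensus logic,
the matched-background construction, the outlier and region calling, the
haplotype-network reconstruction, and a synthetic-data generator that makes
the whole chain testable against known truth.

## Likelihood-ratio tests and declaration rules

For a pair of nested codon models the test statistic is
$2\Delta \ln L = 2(\ln L_\text{alt} - \ln L_\text{null})$, clamped at zero
(a better-fitting null is reported as statistic 0 with p = 1), and compared
to a central chi-square upper tail with 1 or 2 degrees of freedom.

Two conventions deserve note:

* **The neutral-boundary comparison uses a plain chi-square(1) tail**, not
  the 50:50 point-mass mixture sometimes recommended for
  boundary-constrained alternatives. The published worked examples the
  package reproduces are exactly the plain chi-square(1) tails of the
  printed statistics, so the plain tail is the convention implemented; it
  is conservative relative to the mixture.
* **FDR families are configuration, not code.** `bh_adjust()` implements
  Benjamini–Hochberg step-up adjustment (via `stats::p.adjust`) within an
  explicit, user-supplied family key. Published adjusted p-values in this
  line of work are not always recoverable from a single family grouping, so
  the package refuses to guess: the default is one family per vector
  passed, and any other grouping is declared by the caller.

Positive selection on a branch is declared only when the adjusted p-value
clears the significance level under **both** codon-frequency
parameterizations (F3X4 and F61); site-model selection requires rejection
of both neutral models (the beta model M7 and the neutral-boundary model
M8a) against the selection model M8, again under both codon-frequency
models — four significant arms in total. These conjunction rules trade
power for a low false-positive rate, which is the stated rationale for
their use on small candidate gene sets.

## Consensus site calling

Per-codon evidence is combined across methods with mixed directionality
encoded per method, never globally: BEB and FUBAR posteriors pass at
$\ge 0.90$, MEME passes at p $\le 0.1$, REL passes at Bayes factor
$\ge 50$. Branch-level sites require BEB **and** MEME agreement at the same
codon; phylogeny-level sites require at least two of {BEB, FUBAR, REL}.
Codon indices are 1-based positions in the human protein sequence
throughout. Lineage-specific selected sites are kept when the posterior
probability of a population-scaled selection coefficient $\gamma \ge 1$ is
*strictly* greater than 0.75 — a site at exactly the cutoff is dropped.

## Constraint comparison against matched backgrounds

The constraint parameter $f$ (the proportion of non-synonymous mutations
that are not deleterious; lower $f$ = stronger purifying selection) is
compared between module genes and background gene sets matched on
confounding features. A candidate matches a focal gene when **every**
feature of the chosen mode deviates by at most 10% relative to the focal
value; the two modes are joint GC-content + CDS-length matching and GERP
score matching. Two design points were genuinely open:

* The matching phrase "differed less or more than 10%" is read as
  *less than* 10% (consistent with a ±10% threshold and with the
  matching procedure it derives from); implemented as relative deviation
  $\le 0.10$.
* GC and length are matched **jointly** (both within tolerance), since
  they are listed as one matching mode; marginal matching is available by
  calling `match_genes()` with each feature mode separately.

A focal feature of exactly zero makes the relative tolerance undefined and
is a signalled error, never a silent skip. Group comparisons use Student's
t, Wilcoxon rank-sum, one-way ANOVA + Tukey, or Kruskal–Wallis + Nemenyi,
matching the conventions used for each published figure panel. The Nemenyi
post-hoc test is computed from mean ranks with the studentized-range
approximation at infinite degrees of freedom; it omits a tie correction,
which is appropriate for the continuous scores it is applied to here.

## Introgression scoring and archaic regions

A gene's introgression score in a population is the arithmetic mean of the
marginal probabilities of Neanderthal ancestry over its SNPs (half-open
interval membership); a gene with no scoreable SNP gets a *missing* score,
excluded downstream rather than imputed as zero. European and East Asian
scores are kept separate, never pooled. Outliers are genes whose score is
*strictly* above the 95th percentile of the background gene distribution,
with percentiles computed by linear interpolation between order statistics
(R quantile type 7) — the source analyses name no convention, and this is
R's default.

A SNP is archaic-specific when the Altai Neanderthal genotype is homozygous
for an allele absent in Africans (frequency exactly 0) and present in at
least one non-African population. Missing archaic genotypes make the SNP
*not callable*, distinct from a negative call. Introgressed regions are
maximal runs of qualifying archaic SNPs above the score threshold; runs are
bounded at gene boundaries (and optionally by a maximum inter-SNP gap), so
the default reproduces one contiguous haplotype block per gene. Whether the
score threshold for region SNPs should come from the SNP-level or the
gene-level distribution is ambiguous in the source description; both are
accepted, and the pipeline default uses the gene-level 95th percentile.

## Median-joining haplotype networks

Phased haplotypes over the region's SNPs are collapsed to distinct
sequences (rows with missing sites are excluded and reported, never
imputed), then connected in the median-joining spirit: median (per-site
majority) vectors of triplets linked in the minimum spanning network are
added greedily while they reduce the total connection cost, and obsolete
medians are pruned. Sites are binary with uniform weights, matching the
biallelic SNPs the method is applied to.

With the sparsest setting ($\varepsilon = 0$) the emitted edge set is the
canonical minimum spanning tree over observed + median nodes, with
deterministic lexicographic tie-breaking on sequence strings, so the output
is invariant to input order. This is a deliberate narrowing of the full
median-joining construction, which can retain reticulations (alternative
equal-cost links): a tree is what the downstream genealogy interpretation
uses, and it makes the cost guarantee (`total weight <=` observed-only MST
weight) exact. On small instances (up to 4 haplotypes of length up to 8)
the construction provably matched an exhaustive Steiner-point search in the
package's test suite.

## Modern-allele filtering and sweep scanning

A modern-human-specific candidate passes three conjunctive criteria: both
archaic genomes homozygous ancestral; derived-allele frequency of at least
0.90 in **every** modern population; and at least one brain-regulatory
annotation (brain eQTL, open chromatin, enhancer histone marks, or DNase
hypersensitivity). The 0.90 floor is a configurable default: the pattern it
encodes — fixation in Asia with very high frequency elsewhere — motivates
the value, but the original catalogue's exact threshold is external to this
package.

Sweep candidate regions are maximal runs of consecutive SNPs whose S scores
all fall strictly below the genome-wide 5th percentile, emitted when the
run spans at least 25 kb (`last_pos - first_pos`). Region boundaries are
defined by member SNPs, not by arbitrary genomic windows, because the rule
quantifies over "all SNPs" in a window; coordinates are half-open
`[first, last + 1)` on output, BED convention.

# The synthetic-data generator

`simulate_cohort()` generates a cohort with the statistical structure every
stage assumes, with planted signals recorded as machine-readable truth. Its
defaults are fixed study conditions, not tuning dials:

| parameter | default | rationale |
|---|---|---|
| module sizes | 47 + 21 | the two module sizes of the motivating study |
| background genes | 2000 | desk-scale stand-in for the genome-wide coding background; large enough for stable 95th/5th percentiles |
| SNPs per gene | ~30 (Poisson, min 2) | typical gene-body SNP counts at 1000-Genomes density |
| ancestry probabilities | Beta mixture, background mean 0.02; planted 0.9 | introgression maps are near 0 almost everywhere with rare high-probability haplotypes; the Beta shape is a modeling choice, not an inference about any real map |
| planted haplotype | 20 SNPs, full LD, carrier fraction 0.05 | mirrors the motivating ~108 kb, 20-SNP archaic haplotype carried by a small fraction of non-African chromosomes |
| sweep span | 30 kb (floor 25 kb) | comfortably above the 25 kb scan rule so recovery is a real test, not a boundary case |
| f shift | 0.2 on a background mean of 0.6 | produces module-vs-background differences detectable at n = 200/group without being trivial |

One root seed drives everything; each stage derives a child seed
deterministically from the root plus a stage label (`derive_seed()`), so
adding a stage never perturbs earlier draws and a fixed seed reproduces the
cohort byte for byte.

Two constructions are intentionally idealized. First, the planted
haplotype matrix contains exactly two modern states (carriers and
non-carriers): full pairwise $r^2 = 1$ among the planted SNPs is a defining
property of the planted signal, and any extra variation at those columns
would break it, so background haplotype diversity is not simulated at the
planted sites. Second, archaic "genotypes" are unordered allele pairs with
explicit missingness, drawn near the ancestral state rather than from a
coalescent model.

What passing tests therefore show is that each stage implements its rule
exactly and recovers signals of the planted form; they do not show
robustness to features the generator omits — realistic site-frequency
spectra, linkage beyond the planted haplotype, recombination maps, or the
error modes of the upstream tools whose outputs are consumed.

# Numerical choices and degenerate inputs

* Percentiles: linear interpolation (quantile type 7) everywhere; all
  threshold comparisons are strict (`>` above, `<` below), following the
  "higher/lower than the percentile" phrasing of the rules.
* LRT statistics are clamped at 0; `p(0) = 1` exactly.
* Probabilities are validated into `[0, 1]` at entry; violations are
  errors, not warnings.
* Empty inputs (no SNPs in a gene, empty candidate pool, empty score list)
  are signalled explicitly; missing data (archaic genotype, ancestry
  probability, S score) is propagated as `NA` and excluded from the
  specific rule it blocks, never imputed.
* Unsorted SNP input to run-based builders (regions, sweep scan) is an
  error rather than silently re-sorted, so positional semantics stay the
  caller's responsibility.

# Problem sizes used by the test and acceptance suites

The bundled suites run cohorts of 8–12 module genes with 80–150 background
genes (a few thousand SNPs), 2000-gene null calibrations for the FDR and
outlier rates, 500 randomized instances for the sweep-scan oracle, 1000
randomized vectors for the BH oracle, and exhaustive Steiner searches up to
4 haplotypes × 8 sites. These sizes were chosen so the full default suite
completes in well under a minute while keeping every estimate's Monte Carlo
error far below the tolerances asserted; the generator scales to the full
study conditions (68 + 2000 genes, ~60 000 SNPs) in seconds via
`run_pipeline()`.

# Known limitations

* The package consumes upstream fits and inherits their biases; nothing
  here validates codeml, MEME/FUBAR/REL, SnIPRE or the introgression map
  themselves.
* The haplotype network is a tree by construction (see above); analyses
  that need reticulations should use a full median-joining implementation.
* The Nemenyi post-hoc omits tie corrections; with heavily tied data
  (e.g. many identical scores) its p-values are approximate.
* Real-data counts that depend on external annotation resources (e.g. the
  number of variants passing the modern-allele filter genome-wide) are not
  reproducible from this package and are not claimed.
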