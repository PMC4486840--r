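---
title: "Cross-species candidate gene prioritization: models and methods"
author: "crossqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species candidate gene prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossqtl)
```

# The problem

Human GWAS of psychiatric traits localize association signals to single
SNPs but are underpowered after genome-wide multiple-testing correction;
mouse linkage studies in recombinant inbred (RI) panels have high power
but coarse resolution, yielding QTL intervals containing tens to hundreds
of genes. `crossqtl` implements the combined strategy: map QTL for a
behavioural trait on RI strain means, take the human homologs of the genes
under the significant mouse intervals, and test only those homologs for
association in human GWAS summary statistics with gene-based tests and a
region-specific Bonferroni correction. Surviving genes are candidates
jointly supported by both species, and a coexpression
(guilt-by-association) stage characterizes their functional context.

Every input has a synthetic stand-in generator, so the full pipeline is
exercised end to end without any external download.

# Mouse stage: QTL on strain means

## Single-marker likelihood-ratio scan

For a trait measured as one mean value per inbred line, `lrsScan()`
regresses the trait on the allele code $x \in \{-1 (\mathrm{B}),
+1 (\mathrm{D})\}$ at every marker:

$$\mathrm{LRS} = n \,\ln\!\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1},
\qquad a = \tfrac{1}{2}(\bar{y}_\mathrm{D} - \bar{y}_\mathrm{B}),$$

where $\mathrm{RSS}_0$ and $\mathrm{RSS}_1$ are the residual sums of
squares of the intercept-only and the genotype model over the $n$ lines
genotyped at the marker. A negative additive coefficient $a$ means the B
allele increases the trait. LOD $= \mathrm{LRS}/4.61$. Single-marker
regression stands in for interval mapping: on a dense marker map the
peak-marker statistic defines the same regions, and regions (not
positions between markers) are what the cross-species stage consumes.

Numerical edge cases: a marker with only one allele class observed has no
defined LRS and is reported `NA`; a perfect fit is floored at
$\mathrm{RSS}_1 = 10^{-12}\,\mathrm{RSS}_0$, capping the LRS while
preserving ordering; a zero-variance trait returns an all-zero scan with
a warning.

## Permutation threshold

`permutationThreshold()` shuffles the trait values across strains (one
shared shuffled order per genome scan, equivalent to jointly permuting
genotype rows), rescans, and keeps the genome-wide maximum LRS of each of
`nPerm` permutations. The threshold at level $\alpha$ is the $k$-th
smallest maximum with $k = \lceil (1-\alpha)\,n_\mathrm{perm} \rceil$,
and a marker is significant iff its LRS is **strictly** greater (an LRS
"greater than 95% of the permuted datasets"); ties at the threshold are
not significant. The reference practice is 5000 permutations; the
package's tests use 500--1000, which changes only the Monte-Carlo noise
of the threshold, not its definition.

## Intervals, sub-regions, consensus

`significantIntervals()` turns maximal runs of significant markers into
regions. Two runs separated by at most `maxGapMarkers` sub-threshold
markers merge into a parent region that keeps the runs as nested
sub-regions -- the characteristic structure of a wide QTL that separates
into two peaks with a non-significant stretch between them. Candidate
thresholds are later computed per region *and* per sub-region, each with
its own homolog count. `consensusRegions()` union-merges overlapping
regions found for different traits on a chromosome and records the number
of supporting traits. Region bounds are reported twice: the marker span
(in the `QtlRegion`) and, after gene overlap, the span of the genes under
the region (`RegionGeneSet@geneSpanMb`), which is the convention used in
printed region tables.

# Human stage: gene-based tests on GWAS summary statistics

## GATES

With the $M$ SNP p-values of a gene sorted ascending (ties broken by
position order) and $\rho_{ij}$ the correlation between p-values induced
by LD, the effective number of tests among the top $j$ SNPs is

$$m_e(j) = j - \sum_{\lambda_i > 1} (\lambda_i - 1)$$

over the eigenvalues of the leading $j \times j$ correlation submatrix,
and the gene p-value is

$$P_\mathrm{GATES} = \min_j \frac{M_e \, p_{(j)}}{m_e(j)},
\qquad M_e = m_e(M).$$

This reduces to the Simes test for independent SNPs and to the minimum
p-value when all SNPs are perfectly correlated; the SNP achieving the
minimum is the *key SNP*.

## The p-value correlation mapping

The LD store supplies $r^2$; GATES needs the correlation of the two
*p-values*. Because a two-sided p-value depends on its Z-score only
through $|Z|$, that correlation is an even function of the Z correlation
$r$ -- hence a function of $r^2$ alone, with no sign ambiguity.
`pvalueCorrelation()` therefore offers:

* `"exact"` (default): the Pearson correlation of
  $p_i = 2\Phi(-|Z_i|)$ under the bivariate normal, evaluated by
  Gauss--Legendre quadrature on the positive quadrant (where the folded
  density of $(|Z_1|, |Z_2|)$ is smooth) and cached as a monotone spline
  over an $r^2$ grid. It is exactly 0 at $r^2 = 0$ and 1 at $r^2 = 1$.
* `"r2"`: the r-squared itself. This simple shortcut overstates the
  p-value correlation at intermediate LD (e.g. 0.64 vs the exact 0.50 at
  $r = 0.8$), which shrinks $M_e$ and makes the test marginally liberal:
  measured type-I error 0.0515 vs 0.0458 for `"exact"` at nominal 0.05 on
  10,000 null 8-SNP genes with first-order autoregressive LD 0.8.

The default is `"exact"` because it is the principled quantity and keeps
the null calibration on the conservative side; the mapping is a single
pluggable site, so any published polynomial approximation can be swapped
in without touching callers.

## HYST

`ldBlocks()` partitions a gene's position-sorted SNPs greedily: a SNP
joins the current block iff its $r^2$ with the block's last member is at
least `r2Join` (default 0.8). Each block gets its own GATES p-value and
key SNP, and `hystTest()` combines the $K$ block p-values through the
scaled chi-square (correlated Fisher) machinery:

$$T = -2 \sum_k \ln p_k, \quad E = 2K, \quad
\mathrm{Var} = 4K + 2\!\!\sum_{i<j}\! c_{ij}, \quad
P = \Pr\!\left[\chi^2_f > T/c\right]$$

with $c = \mathrm{Var}/2E$ and $f = 2E^2/\mathrm{Var}$. For the
inter-block covariance $c_{ij}$ of $-2\ln p$ two models are available:

* `"exact"` (default): the covariance of $-2 \ln p$ for two-sided normal
  p-values at the key-SNP $r^2$, computed by the same folded quadrature
  (0 at $r^2=0$; exactly 4, the $\chi^2_2$ variance, at $r^2=1$).
* `"brown"`: Brown's classical fit $c_{ij} = \rho(3.25 + 0.75\rho)$ on
  the p-value correlation, negatives truncated to zero.

Brown's fit targets one-sided statistics and understates the covariance
for two-sided tests (1.83 vs the true 2.53 at $r = 0.8$). The deficit
barely moves the 0.05-level behaviour but inflates the far tail -- about
7-fold at the $10^{-4}$--$10^{-3}$ thresholds the region-Bonferroni stage
uses -- which is why `"exact"` is the default. Even so, two residual
far-tail inflations are intrinsic to the methods themselves: extreme
minima of correlated Gaussians decorrelate ("tail independence"), so
GATES approaches factor $M/M_e$ in the extreme tail ($\approx$1.4--1.7
here), and a Satterthwaite chi-square matches the mean and variance but
underweights the tail of a sum of dependent $\chi^2_2$ terms ($\approx$2.4
here). Users calling candidates at very small thresholds should treat the
resulting family-wise error as approximately, not exactly, $\alpha$.

Both tests collapse correctly at the boundaries: one block returns the
block p-value exactly; perfectly redundant blocks return the common block
p-value; independent blocks give Fisher's method.

## Cross-species candidate calling

`homologsInRegion()` collects the mouse genes overlapping a QTL region
(any 1-bp overlap counts) and maps them through the one-to-one homology
table; `regionThreshold()` computes $\alpha / (n \times 2)$ with $n$ the
homolog count and 2 the number of gene-based tests; `callCandidates()`
declares a gene a candidate iff $\min(P_\mathrm{GATES}, P_\mathrm{HYST})
\le$ threshold. Three conventions are deliberate:

* $n$ counts homologous genes whether or not they carry SNPs: printed
  thresholds derive from homolog counts, not tested-gene counts, and an
  untested gene still spends its share of $\alpha$.
* The pass rule is inclusive ($\le$). Printed comparisons read "lower
  than", but no realistic case sits exactly on a threshold; documented
  divergence.
* A gene inside both a parent region and a sub-region is judged against
  each region's own threshold; the final candidate list is the set of
  distinct passing genes.

# Coexpression stage

`correlationMatrix()` computes pairwise Pearson correlations
(pairwise-complete; two-sided p from the $t$ transform with the
pair-specific $n$). `coexpressionCalls()` declares a pair coexpressed iff
$|r| \ge 0.5$ *and* $p \le \alpha/n_\mathrm{probes}$. The published rule
reads "dividing the p-value by the number of probes"; dividing the
p-value itself would make results *more* significant, contradicting the
worked value $0.05/63 = 7.94\times10^{-4}$ used as a threshold, so the
package divides the family alpha (Bonferroni), matching that number.
The probe count is the number of probes targeting the genes of interest.

`consistentProbes()` keeps the probes of a gene correlating ($r \ge 0.5$,
$p \le 0.05$) with at least one sibling probe (single-probe genes are
kept with a logged caveat); `phenotypeScreen()` keeps phenotypes
correlating with *every* retained probe of a gene, requiring a consistent
sign across probes -- mixed signs would make "correlates with all probes"
ambiguous.

`conditionalCoexpression()` implements condition-profile coexpression: a
gene's value for a target is the fraction of conditions with a two-fold
up-call among the conditions where the target is two-fold up. The
database behind this definition publishes no significance recipe, so the
package uses a one-sided binomial upper tail of the joint-up count given
the gene's marginal up-frequency, documented and pluggable; the commonly
coexpressed set is value $\ge 0.5$ with $p \le 0.05$.

`oraEnrichment()` is hypergeometric over-representation
($\Pr[X \ge \mathrm{overlap}]$) against a user-supplied universe with
Benjamini--Hochberg adjustment across the supplied terms -- generic ORA on
user term sets rather than any hosted annotation content.
`pc1Trait()` builds a synthetic trait from the first principal component;
columns are standardized by default because the traits mixed here (beam
breaks, log2 intensities) live on heterogeneous scales, and the
orientation is fixed by a non-negative loading sum so a global sign flip
changes nothing. For two traits the variance fraction is exactly
$(1+|r|)/2$.

# The synthetic-data generators

`simulateRiPanel()` draws each line's chromosome as a two-state mosaic:
marker spacing (Mb) is converted to genetic distance at a constant rate
(default 0.5 cM/Mb, mouse-typical), Haldane's map function gives the
recombination fraction $r$, and the RI (sib-mating) map expansion
$R = 4r/(1+6r)$ gives the per-interval switch probability, capped by
construction at 0.5. Genotypes are homozygous only; an optional
missingness rate masks calls, mimicking residual heterozygous/unknown
calls that the readers also map to missing.

`simulateStrainTrait()` plants one additive QTL:
$y = \mu + a x + e$ with $\sigma$ set from the target heritability via
$h^2 = a^2/(a^2 + \sigma^2)$ (using $\mathrm{Var}(x)=1$, i.e. balanced
alleles). $h^2 = 1$ gives a noise-free trait; $a = 0$ leaves $\sigma$
undetermined by the formula, so an explicit `residualSd` (default 1)
covers null traits.

`simulateGwasRegion()` works at the summary-statistic level, as the
pipeline does: per gene a Z-vector is drawn from a multivariate normal
with first-order autoregressive correlation between adjacent SNPs, every
SNP of a causal gene carries the per-SNP non-centrality, and
$p = 2\Phi(-|Z|)$. The LD store records the exact $r^2$ implied by the
correlation used, so the human stage sees perfectly consistent LD.

`simulateAnnotation()` tiles non-overlapping genes across regions and
pairs each mouse gene with a human partner with probability
`homologRate` (one-to-one). `simulateExpression()` generates probe-level
values $\mathrm{loading} \times \mathrm{factor} + e_\mathrm{gene} +
e_\mathrm{probe}$; genes sharing a factor with equal loadings have
expected cross-gene probe correlation $\mathrm{loading}^2 /
(\mathrm{loading}^2 + \sigma^2_\mathrm{gene} + \sigma^2_\mathrm{probe})$.
Condition up-call matrices threshold simulated per-condition log2 fold
changes (same module structure) at two-fold.

What the generators do *not* emulate: real BXD marker maps and their LD
idiosyncrasies, selection and family structure, case-control sampling
noise in GWAS effect sizes, batch structure or mean-variance trends in
microarray intensities, and many-to-many homology. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative assumptions, not robustness to every artefact of real
data.

# Verification choices and problem sizes

The test-suite experiments run at sizes chosen to make Monte-Carlo error
small while keeping the default suite quick: null-calibration of GATES on
2000 simulated genes (8 SNPs, AR-LD 0.8); genome-wide FWER of the
permutation threshold on 500 null traits over a 20-marker, 40-line panel
with 1000 permutations each; planted-QTL recovery ($h^2 = 0.5$, 75
lines) over 100 replicates; full-pipeline recovery of one causal gene
(per-SNP non-centrality 5.5 among 30 homologs) over 200 replicates with
500 permutations per mouse scan; and planted-coexpression-module recovery
(three genes at expected cross-gene probe r 0.7, two probes per gene, 30
strains) over 100 replicates. For the coexpression experiment the
probe-level design -- two probes per gene, with two genes linked when any
probe pair between them is called -- mirrors how exon-array coexpression
is judged in practice (gene-level conclusions are drawn from probe-level
calls, including intron-only probe sets when no exon probes exist). The
recovery probability of that experiment sits near its 90% target by
construction of the planted correlation (0.7) and sample size (30): a
100-replicate run can land on either side of it.

Other numerical conventions collected in one place: quadrature uses
96-node Gauss--Legendre on $[0, 8.5]$ (normal mass beyond $|z| = 8.5$ is
below $10^{-15}$) with 201-point monotone (Hyman) splines over the $r^2$
grid; GATES ties in p are broken by input (position) order; block key
SNPs are the blocks' GATES key SNPs; zero block p-values are clamped to
the smallest representable double with a warning; correlation values are
clipped to $[-1, 1]$ before the $t$ transform; and all simulators are
deterministic given their seed arguments.

# Known limitations

* Single-marker scans cannot separate linked QTL closer than the marker
  spacing; no kinship correction is applied (RI strain means, not
  individuals, are modelled).
* GATES/HYST far-tail calibration is approximate, as quantified above;
  region-level candidate calling at very small $\alpha/(2n)$ inherits
  that approximation.
* The homology model is strictly one-to-one; paralog expansions are
  skipped at read time (with a logged count) rather than resolved.
* The conditional-coexpression significance model is a package choice
  (binomial against the marginal up-frequency), not a published recipe.
* LD pairs absent from a store are treated as $r^2 = 0$, which is
  conservative for GATES but optimistic for HYST block separation if the
  store is very sparse.
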