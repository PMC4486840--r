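# crossqtl

Cross-species candidate gene prioritization: combine QTL mapping on
recombinant inbred (RI) mouse strain means with gene-based association
tests on human GWAS summary statistics, restricted to the human homologs
of the genes under significant mouse QTL, and follow up with a
coexpression (guilt-by-association) stage.

## Who this is for

Researchers with (a) strain-mean phenotypes and genotypes for an RI panel
(GeneNetwork-style files), (b) human GWAS SNP summary p-values plus
pairwise LD (HapMap-dialect text), and (c) gene annotations and a
mouse–human homology table, who want to turn broad mouse linkage
intervals into a short list of genes supported in both species. A
synthetic-data module generates statistically faithful stand-ins for all
of these, so the pipeline can be explored and validated without any
download.

## The statistics at the core

- **Mouse stage.** Per-marker likelihood-ratio scan on strain means,
  LRS = n·ln(RSS₀/RSS₁), additive coefficient a = (ȳ_D − ȳ_B)/2 (a < 0
  means the B allele raises the trait), with a permutation genome-wide
  threshold: the k-th smallest of the permuted genome-wide maxima,
  k = ⌈(1−α)·n_perm⌉, used with strict inequality. Significant runs of
  markers become QTL regions; nearby runs merge into parent regions with
  two-peak sub-structure; overlapping regions across traits merge into
  consensus regions.
- **Human stage.** GATES: P = min_j Me·p₍j₎/me(j), where me(j) is the
  effective number of tests (eigenvalue-excess rule) among the j smallest
  SNP p-values and the p-value correlation comes from LD r² through an
  exact quadrature mapping (or the plain r² shortcut). HYST: greedy LD
  blocks, per-block GATES p-values combined by a scaled chi-square with
  inter-block covariances of −2·ln p taken from the key-SNP r².
- **Cross-species calling.** Per region, threshold = α/(n·2) with n the
  homolog count (two tests per gene: GATES and HYST); a gene is a
  candidate iff min(P_GATES, P_HYST) ≤ threshold.
- **Coexpression stage.** Pearson matrices with probe-count-adjusted
  alpha (e.g. 0.05/63 = 7.94e-4) and |r| ≥ 0.5; probe-consistency and
  phenotype screens; conditional coexpression values (fraction of the
  target's two-fold up-conditions shared); hypergeometric ORA with BH
  adjustment; PC1 synthetic traits.

See `vignettes/crossqtl-methods.Rmd` for models, assumptions, numerical
choices and limitations.

## Worked example

Simulate a 75-line panel, plant a QTL (h² = 0.5) at marker `1_m0020`,
map it, and test the 30 human homologs under the detected region against
simulated GWAS summary statistics in which gene `HGENE0007` is causal:

```r
library(crossqtl)

geno  <- simulateRiPanel(75, data.frame(name = c("1", "2"),
                                        lengthMb = c(100, 90),
                                        nMarkers = c(40, 35)), seed = 11)
trait <- simulateStrainTrait(geno, "1_m0020", additive = 1, h2 = 0.5,
                             mu = 120, seed = 12, traitId = "open_arm_time")
scan  <- lrsScan(geno, trait)
scan
#> QtlScan of open_arm_time - 75 markers; peak LRS 57.99 at 1_m0020

thr <- permutationThreshold(geno, trait, nPerm = 1000, seed = 13)
thr
#> Genome-wide LRS threshold 10.84 (alpha = 0.05, 1000 permutations)

cons   <- consensusRegions(list(significantIntervals(scan, thr,
                                                     maxGapMarkers = 2)))
peakMb <- scanTable(scan)$mb[which.max(scanTable(scan)$lrs)]
region <- Filter(function(r) r@startMb <= peakMb && r@endMb >= peakMb,
                 cons)[[1]]
region
#> QtlRegion 1:33.750-71.250 Mb, peak 1_m0020 (LRS 58)

ann   <- simulateAnnotation(data.frame(chr = "1", startMb = region@startMb,
                                       endMb = region@endMb),
                            genesPerRegion = 30, homologRate = 1, seed = 14)
sim   <- simulateGwasRegion(ann$human, snpsPerGene = 8, arCorr = 0.8,
                            causal = "HGENE0007", ncp = 5.5, seed = 15)
assoc <- geneAssociation(sim$gwas, sim$ld, ann$human)
head(assoc[order(assoc$p_gates),
           c("gene", "n_snps", "n_blocks", "p_gates", "p_hyst")], 3)
#>         gene n_snps n_blocks      p_gates       p_hyst
#> 7  HGENE0007      8        8 4.959154e-13 4.315592e-25
#> 29 HGENE0029      8        8 1.626881e-02 4.299172e-02
#> 23 HGENE0023      8        8 2.487740e-02 1.663396e-03

rs <- homologsInRegion(region, ann$mouse, ann$homology)
rs
#> RegionGeneSet 1:33.750-71.250 - 30 human homologs (gene span 33.750-70.625 Mb)

calls <- callCandidates(list(rs), assoc)
unique(calls$threshold)
#> [1] 0.0008333333
candidateGenes(calls)
#> [1] "HGENE0007"
```

The scan peaks at the planted marker (LRS 58, far above the permutation
threshold 10.84); the detected region's 30 homologs set the
region-specific threshold 0.05/(30·2) = 8.33e-4; the planted causal gene
is the only one whose GATES/HYST p-value clears it. The same arithmetic
reproduces thresholds for printed homolog counts, e.g.
`regionThreshold(0.05, 185, 2)` = 1.35e-4.

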