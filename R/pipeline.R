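#' Cross-species candidate prioritization pipeline
#'
#' Runs the full chain on prepared inputs: per-trait genome scans and
#' permutation thresholds, trait filtering, significant-interval
#' extraction, consensus regions across traits, homolog lookup per region,
#' gene-based GWAS association (GATES + HYST) and region-thresholded
#' candidate calling.
#'
#' @param geno a \code{GenotypeMatrix}.
#' @param traits list of \code{TraitTable}.
#' @param mouseGenes \code{GRanges} of mouse genes with \code{gene_id}.
#' @param homology a \code{HomologyMap}.
#' @param gwas a \code{GwasSnpTable} of human SNP summary p-values.
#' @param ld an \code{LdStore}.
#' @param humanGenes \code{GRanges} of human genes with \code{gene_id}.
#' @param nPerm permutations per trait (default 1000).
#' @param alpha family-wise level used both genome-wide (mouse) and per
#'   region (human; default 0.05).
#' @param maxGapMarkers run-merging gap for interval extraction
#'   (default 0).
#' @param flankKb,blockR2 gene-based test settings (defaults 0 and 0.8).
#' @param seed integer RNG seed for the permutations.
#' @return list with components \code{scans}, \code{thresholds},
#'   \code{significantTraits}, \code{regions} (consensus),
#'   \code{regionSets}, \code{assoc}, \code{calls} and \code{candidates}.
#' @export
runCrossSpeciesPipeline <- function(geno, traits, mouseGenes, homology,
                                    gwas, ld, humanGenes, nPerm = 1000,
                                    alpha = 0.05, maxGapMarkers = 0,
                                    flankKb = 0, blockR2 = 0.8, seed) {
  seed <- as.integer(seed)
  scans <- lapply(traits, lrsScan, geno = geno)
  thresholds <- lapply(seq_along(traits), function(i)
    permutationThreshold(geno, traits[[i]], nPerm = nPerm, alpha = alpha,
                         seed = seed + i))
  kept <- filterTraits(traits, scans, thresholds)
  keptIdx <- which(vapply(traits, function(t)
    any(vapply(kept, identical, logical(1), t)), logical(1)))
  perTrait <- lapply(keptIdx, function(i)
    significantIntervals(scans[[i]], thresholds[[i]], maxGapMarkers))
  regions <- consensusRegions(perTrait)
  regionSets <- lapply(regions, homologsInRegion, mouseGenes = mouseGenes,
                       homology = homology)
  assoc <- geneAssociation(gwas, ld, humanGenes, flankKb = flankKb,
                           blockR2 = blockR2)
  calls <- callCandidates(regionSets, assoc, alpha = alpha)
  list(scans = scans, thresholds = thresholds,
       significantTraits = kept, regions = regions,
       regionSets = regionSets, assoc = assoc, calls = calls,
       candidates = candidateGenes(calls))
}
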