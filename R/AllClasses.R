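#' @import methods
#' @importFrom stats cor pchisq pnorm pt rnorm pbinom phyper p.adjust
#'   prcomp rbinom runif setNames var
#' @importFrom utils read.table write.table packageVersion
NULL

#' GenotypeMatrix: recombinant inbred genotypes
#'
#' Holds allele calls for a panel of inbred lines at an ordered set of
#' markers. Calls are stored as an integer matrix (strains x markers) coded
#' -1 for the B parental allele, +1 for the D parental allele and \code{NA}
#' for missing (heterozygous or unknown calls collapse to missing: the lines
#' are expected homozygous). The marker map carries chromosome, genetic (cM)
#' and physical (Mb) positions, strictly increasing within chromosome.
#'
#' @slot calls integer matrix, rows = strains, columns = markers, values in
#'   \{-1, +1, NA\}.
#' @slot markers data.frame with columns \code{id}, \code{chr}, \code{cm},
#'   \code{mb}, one row per marker, in map order.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", markers = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@markers
  msg <- character(0)
  if (!all(c("id", "chr", "cm", "mb") %in% names(m)))
    msg <- c(msg, "markers must have columns id, chr, cm, mb")
  else {
    if (ncol(object@calls) != nrow(m))
      msg <- c(msg, "number of call columns must equal number of markers")
    bad <- !tapply(m$mb, factor(m$chr, levels = unique(m$chr)),
                   function(p) all(diff(p) > 0))
    if (any(bad))
      msg <- c(msg, paste("marker Mb positions not strictly increasing on",
                          paste(names(bad)[bad], collapse = ", ")))
  }
  vals <- object@calls[!is.na(object@calls)]
  if (length(vals) && !all(vals %in% c(-1L, 1L)))
    msg <- c(msg, "allele calls must be -1, +1 or NA")
  if (length(msg)) msg else TRUE
})

#' TraitTable: one strain-mean phenotype
#'
#' A single quantitative trait measured as one mean value per strain (for
#' example beam-break counts in an open field test), with a free-text
#' metadata string.
#'
#' @slot traitId character(1) trait identifier.
#' @slot values named numeric vector, one value per strain.
#' @slot metadata character(1) description.
#' @exportClass TraitTable
setClass("TraitTable",
  representation(traitId = "character", values = "numeric",
                 metadata = "character"))

setValidity("TraitTable", function(object) {
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    return("trait values must be named by strain, uniquely")
  if (any(is.na(object@values)))
    return("trait values must be non-missing (omit strains instead)")
  TRUE
})

#' GwasSnpTable: GWAS SNP summary statistics
#'
#' Per-SNP association p-values from a human GWAS, as distributed in summary
#' form: SNP id, chromosome, physical position (1-based bp) and p-value.
#'
#' @slot snps data.frame with columns \code{snp}, \code{chr}, \code{bp},
#'   \code{p}.
#' @slot nDropped integer(1), rows removed at read time because the p-value
#'   was outside (0, 1].
#' @exportClass GwasSnpTable
setClass("GwasSnpTable",
  representation(snps = "data.frame", nDropped = "integer"))

setValidity("GwasSnpTable", function(object) {
  s <- object@snps
  if (!all(c("snp", "chr", "bp", "p") %in% names(s)))
    return("snps must have columns snp, chr, bp, p")
  if (anyDuplicated(s$snp)) return("duplicated SNP ids")
  if (nrow(s) && (any(s$p <= 0) || any(s$p > 1)))
    return("p-values must lie in (0, 1]")
  if (nrow(s) && any(s$bp <= 0)) return("positions must be positive")
  TRUE
})

#' LdStore: pairwise linkage disequilibrium
#'
#' Symmetric lookup of pairwise r-squared between SNPs. Pairs never seen
#' (e.g. distant pairs omitted from an LD dump) have r-squared 0 by
#' contract, which treats them as independent -- conservative for the
#' gene-based tests.
#'
#' @slot env environment mapping a canonical "rs1|rs2" key (ids sorted) to
#'   a numeric r-squared in [0, 1].
#' @exportClass LdStore
setClass("LdStore", representation(env = "environment"))

#' QtlScan: genome scan of one trait
#'
#' Per-marker likelihood-ratio statistics (LRS, natural-log scale) and
#' additive coefficients from regressing a strain-mean trait on the allele
#' code x in \{-1 (B), +1 (D)\}. The additive coefficient is
#' (mean_D - mean_B) / 2, so a negative value means the B (C57BL/6J-like)
#' allele increases the trait.
#'
#' @slot traitId character(1).
#' @slot table data.frame with columns \code{marker}, \code{chr}, \code{mb},
#'   \code{lrs}, \code{additive}, \code{n} (lines used); \code{lrs} is
#'   \code{NA} where only one allele class is observed.
#' @exportClass QtlScan
setClass("QtlScan",
  representation(traitId = "character", table = "data.frame"))

setValidity("QtlScan", function(object) {
  t <- object@table
  if (!all(c("marker", "chr", "mb", "lrs", "additive", "n") %in% names(t)))
    return("scan table missing required columns")
  if (any(t$lrs < -1e-8, na.rm = TRUE)) return("LRS must be non-negative")
  TRUE
})

#' GenomeWideThreshold: permutation significance threshold
#'
#' The genome-wide LRS threshold at a given alpha, defined from the
#' empirical distribution of the maximum LRS over permuted traits. A marker
#' is genome-wide significant iff its observed LRS is strictly greater than
#' the threshold.
#'
#' @slot alpha numeric(1) family-wise error rate.
#' @slot nPerm integer(1) number of permutations.
#' @slot threshold numeric(1) the k-th smallest permutation maximum with
#'   k = ceiling((1 - alpha) * nPerm).
#' @slot maxima numeric permutation max-LRS sample, retained for audit.
#' @slot seed integer(1) RNG seed used.
#' @exportClass GenomeWideThreshold
setClass("GenomeWideThreshold",
  representation(alpha = "numeric", nPerm = "integer", threshold = "numeric",
                 maxima = "numeric", seed = "integer"))

setValidity("GenomeWideThreshold", function(object) {
  k <- ceiling((1 - object@alpha) * object@nPerm)
  if (length(object@maxima) != object@nPerm)
    return("maxima sample length must equal nPerm")
  if (abs(sort(object@maxima)[k] - object@threshold) > 1e-12)
    return("threshold must equal the stated order statistic of maxima")
  TRUE
})

#' QtlRegion: a significant QTL interval
#'
#' A maximal run of genome-wide significant markers, possibly carrying
#' sub-regions: two significant runs separated by a short sub-threshold gap
#' are merged into one parent region whose two peaks are kept as nested
#' sub-regions (the "two smaller QTL" structure seen in wide intervals).
#'
#' @slot chr character(1) chromosome.
#' @slot startMb,endMb numeric(1) span of above-threshold markers, Mb.
#' @slot peakMarker character(1) marker with the highest LRS in the region.
#' @slot peakMb,peakLrs numeric(1) its position and LRS.
#' @slot subRegions list of QtlRegion (empty when the region is a single
#'   run), nested and disjoint.
#' @slot support integer(1) number of traits supporting the region (1 for a
#'   single-trait region; set by \code{consensusRegions}).
#' @slot traitIds character ids of the supporting traits.
#' @exportClass QtlRegion
setClass("QtlRegion",
  representation(chr = "character", startMb = "numeric", endMb = "numeric",
                 peakMarker = "character", peakMb = "numeric",
                 peakLrs = "numeric", subRegions = "list",
                 support = "integer", traitIds = "character"),
  prototype(subRegions = list(), support = 1L, traitIds = character(0)))

setValidity("QtlRegion", function(object) {
  if (object@startMb > object@endMb) return("startMb must be <= endMb")
  if (length(object@peakMb) &&
      (object@peakMb < object@startMb || object@peakMb > object@endMb))
    return("peak must lie within [startMb, endMb]")
  TRUE
})

#' HomologyMap: one-to-one mouse/human gene homology
#'
#' An injective (both ways) map between mouse and human gene ids, as built
#' from homology groups containing exactly one gene of each species.
#'
#' @slot mouse,human parallel character vectors of gene ids.
#' @exportClass HomologyMap
setClass("HomologyMap",
  representation(mouse = "character", human = "character"))

setValidity("HomologyMap", function(object) {
  if (length(object@mouse) != length(object@human))
    return("mouse and human id vectors must be parallel")
  if (anyDuplicated(object@mouse) || anyDuplicated(object@human))
    return("homology map must be one-to-one (duplicate ids found)")
  TRUE
})

#' RegionGeneSet: the genes under a QTL region
#'
#' The mouse genes overlapping one QTL region together with their human
#' homologs. \code{n} counts the homologous genes and feeds the
#' region-specific Bonferroni threshold; \code{geneSpanMb} is the span of
#' the overlapping mouse genes (the "position of genes" convention used for
#' reporting region bounds).
#'
#' @slot regionId character(1) label of the source region.
#' @slot region the source \code{QtlRegion}, or \code{NULL} for worked
#'   examples constructed directly from printed counts.
#' @slot mouseGenes GRanges (possibly empty) of overlapping mouse genes.
#' @slot humanGenes character human homolog gene ids.
#' @slot n integer(1) homolog count.
#' @slot geneSpanMb numeric(2) min start / max end of the mouse genes, Mb.
#' @exportClass RegionGeneSet
setClass("RegionGeneSet",
  representation(regionId = "character", region = "ANY", mouseGenes = "ANY",
                 humanGenes = "character", n = "integer",
                 geneSpanMb = "numeric"))

setValidity("RegionGeneSet", function(object) {
  if (object@n != length(object@humanGenes))
    return("n must equal the number of human homologs")
  TRUE
})

#' CorrelationResult: pairwise Pearson correlations
#'
#' Pairwise Pearson correlation of items (probes or traits) across samples,
#' pairwise-complete over missing values, with two-sided p-values from the
#' t transform using the pair-specific sample size.
#'
#' @slot r,p,n square matrices: correlation, two-sided p, samples per pair.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(r = "matrix", p = "matrix", n = "matrix"))

setValidity("CorrelationResult", function(object) {
  if (!isTRUE(all.equal(object@r, t(object@r), tolerance = 1e-8,
                        check.attributes = FALSE)))
    return("correlation matrix must be symmetric")
  if (any(abs(object@r) > 1 + 1e-8, na.rm = TRUE))
    return("|r| must be <= 1")
  TRUE
})

#' CoexpressionCalls: thresholded coexpression links
#'
#' Boolean pairwise coexpression calls: a pair is called iff |r| >= rMin and
#' the correlation p-value is at most the probe-count-adjusted alpha
#' (alpha / nProbes, a Bonferroni correction on the family alpha).
#'
#' @slot calls logical matrix (diagonal FALSE).
#' @slot adjustedAlpha numeric(1) alpha / nProbes.
#' @slot rMin numeric(1) magnitude threshold on r.
#' @slot rImplied numeric(1) the |r| that reaches adjustedAlpha at the
#'   (median) pair sample size; NA when undefined.
#' @exportClass CoexpressionCalls
setClass("CoexpressionCalls",
  representation(calls = "matrix", adjustedAlpha = "numeric",
                 rMin = "numeric", rImplied = "numeric"))
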