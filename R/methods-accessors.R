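#' @rdname GenotypeMatrix-class
setMethod("strainNames", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname TraitTable-class
setMethod("strainNames", "TraitTable", function(x) names(x@values))

#' @rdname GenotypeMatrix-class
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markers)

#' @rdname GenotypeMatrix-class
setMethod("genoCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname TraitTable-class
setMethod("traitValues", "TraitTable", function(x) x@values)

#' @rdname TraitTable-class
setMethod("traitId", "TraitTable", function(x) x@traitId)

#' @rdname GwasSnpTable-class
setMethod("snpTable", "GwasSnpTable", function(x) x@snps)

.ldKey <- function(a, b) {
  swap <- a > b
  k1 <- ifelse(swap, b, a)
  k2 <- ifelse(swap, a, b)
  paste(k1, k2, sep = "|")
}

#' @rdname ldR2
setMethod("ldR2", "LdStore", function(x, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  keys <- .ldKey(a, b)
  out <- numeric(n)
  same <- a == b
  out[same] <- 1
  for (i in which(!same)) {
    v <- x@env[[keys[i]]]
    if (!is.null(v)) out[i] <- v
  }
  out
})

#' @rdname QtlScan-class
setMethod("scanTable", "QtlScan", function(x) x@table)

#' @rdname QtlScan-class
setMethod("traitId", "QtlScan", function(x) x@traitId)

#' @rdname QtlScan-class
setMethod("lodScores", "QtlScan", function(x) x@table$lrs / 4.61)

#' @rdname GenomeWideThreshold-class
setMethod("thresholdLrs", "GenomeWideThreshold", function(x) x@threshold)

#' @rdname QtlRegion-class
setMethod("subRegions", "QtlRegion", function(x) x@subRegions)

#' @rdname RegionGeneSet-class
setMethod("humanHomologs", "RegionGeneSet", function(x) x@humanGenes)

#' @rdname CorrelationResult-class
setMethod("corValues", "CorrelationResult", function(x) x@r)

#' @rdname CorrelationResult-class
setMethod("corPvalues", "CorrelationResult", function(x) x@p)

#' @rdname CoexpressionCalls-class
setMethod("callMatrix", "CoexpressionCalls", function(x) x@calls)

#' Convert a HomologyMap to a two-column data.frame
#'
#' @param x a \code{HomologyMap}.
#' @param ... ignored.
#' @return data.frame with columns \code{mouse}, \code{human}.
#' @export
as.data.frame.HomologyMap <- function(x, ...) {
  data.frame(mouse = x@mouse, human = x@human, stringsAsFactors = FALSE)
}

#' Map mouse gene ids to human homologs
#'
#' @param map a \code{HomologyMap}.
#' @param mouseIds character mouse gene ids.
#' @return character vector of the same length; \code{NA} where a gene has
#'   no homolog.
#' @export
humanPartner <- function(map, mouseIds) {
  stopifnot(is(map, "HomologyMap"))
  map@human[match(mouseIds, map@mouse)]
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "strains x",
      ncol(object@calls), "markers on",
      length(unique(object@markers$chr)), "chromosome(s)\n")
  nmiss <- sum(is.na(object@calls))
  if (nmiss) cat("  missing calls:", nmiss, "\n")
})

setMethod("show", "TraitTable", function(object) {
  cat("TraitTable", object@traitId, "-", length(object@values), "strains\n")
  if (nzchar(object@metadata)) cat(" ", object@metadata, "\n")
})

setMethod("show", "GwasSnpTable", function(object) {
  cat("GwasSnpTable:", nrow(object@snps), "SNPs")
  if (object@nDropped > 0)
    cat(" (", object@nDropped, " rows dropped at read)", sep = "")
  cat("\n")
})

setMethod("show", "LdStore", function(object) {
  cat("LdStore:", length(ls(object@env)), "SNP pairs\n")
})

setMethod("show", "QtlScan", function(object) {
  t <- object@table
  i <- which.max(t$lrs)
  cat("QtlScan of", object@traitId, "-", nrow(t), "markers; peak LRS",
      format(t$lrs[i], digits = 4), "at", t$marker[i], "\n")
})

setMethod("show", "GenomeWideThreshold", function(object) {
  cat(sprintf("Genome-wide LRS threshold %.4g (alpha = %g, %d permutations)\n",
              object@threshold, object@alpha, object@nPerm))
})

setMethod("show", "QtlRegion", function(object) {
  cat(sprintf("QtlRegion %s:%.3f-%.3f Mb, peak %s (LRS %.3g)",
              object@chr, object@startMb, object@endMb,
              object@peakMarker, object@peakLrs))
  if (length(object@subRegions))
    cat(",", length(object@subRegions), "sub-regions")
  if (object@support > 1L) cat(", support", object@support)
  cat("\n")
})

setMethod("show", "HomologyMap", function(object) {
  cat("HomologyMap:", length(object@mouse), "one-to-one gene pairs\n")
})

setMethod("show", "RegionGeneSet", function(object) {
  cat("RegionGeneSet", object@regionId, "-", object@n, "human homologs")
  if (length(object@geneSpanMb) == 2)
    cat(sprintf(" (gene span %.3f-%.3f Mb)", object@geneSpanMb[1],
                object@geneSpanMb[2]))
  cat("\n")
})

setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult:", nrow(object@r), "items\n")
})

setMethod("show", "CoexpressionCalls", function(object) {
  cat(sprintf(
    "CoexpressionCalls: %d/%d pairs called (|r| >= %.3g, p <= %.3g)\n",
    sum(object@calls[upper.tri(object@calls)]),
    sum(upper.tri(object@calls)), object@rMin, object@adjustedAlpha))
})
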