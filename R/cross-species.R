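#' Human homologs of the genes under a mouse QTL region
#'
#' Mouse genes with any 1-based inclusive overlap with the region span are
#' collected; those with a homology entry contribute their human partner.
#' The gene span (min start to max end of the overlapping mouse genes, in
#' Mb) is recorded: region bounds reported from gene positions rather than
#' marker positions, the convention used for printed region tables.
#'
#' @param region a \code{QtlRegion}.
#' @param mouseGenes \code{GRanges} of mouse genes with \code{gene_id}.
#' @param homology a \code{HomologyMap}.
#' @param regionId label for the region (default built from its span).
#' @return a \code{\linkS4class{RegionGeneSet}}.
#' @export
homologsInRegion <- function(region, mouseGenes, homology,
                             regionId = NULL) {
  stopifnot(is(region, "QtlRegion"), is(mouseGenes, "GRanges"),
            is(homology, "HomologyMap"))
  if (is.null(regionId))
    regionId <- sprintf("%s:%.3f-%.3f", region@chr, region@startMb,
                        region@endMb)
  span <- GenomicRanges::GRanges(
    region@chr,
    IRanges::IRanges(max(1, round(region@startMb * 1e6)),
                     round(region@endMb * 1e6)))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(mouseGenes, span))
  inRegion <- mouseGenes[S4Vectors::queryHits(hits)]
  partners <- humanPartner(homology,
                           GenomicRanges::mcols(inRegion)$gene_id)
  human <- partners[!is.na(partners)]
  span <- if (length(inRegion))
    c(min(GenomicRanges::start(inRegion)),
      max(GenomicRanges::end(inRegion))) / 1e6
  else numeric(0)
  new("RegionGeneSet", regionId = regionId, region = region,
      mouseGenes = inRegion, humanGenes = unname(human),
      n = length(human), geneSpanMb = span)
}

#' Construct a RegionGeneSet directly from a homolog list
#'
#' For worked examples and tests where only the homolog ids (or count) of
#' a region are known, without the underlying mouse scan.
#'
#' @param regionId character(1) label.
#' @param humanGenes character human homolog ids.
#' @return a \code{\linkS4class{RegionGeneSet}}.
#' @export
regionGeneSet <- function(regionId, humanGenes) {
  new("RegionGeneSet", regionId = regionId, region = NULL,
      mouseGenes = NULL, humanGenes = humanGenes,
      n = length(humanGenes), geneSpanMb = numeric(0))
}

#' Region-specific Bonferroni threshold
#'
#' threshold = alpha / (nGenes * nTests): the family is the homologous
#' genes compared in the region times the number of gene-based tests run
#' on each (two: GATES and HYST).
#'
#' @param alpha family-wise level (default 0.05).
#' @param nGenes number of homologous genes in the region (>= 1; genes
#'   without SNP coverage still count).
#' @param nTests number of gene-based tests per gene (default 2).
#' @return numeric(1) p-value threshold.
#' @examples
#' regionThreshold(0.05, 185, 2)   # 1.4e-4 at two significant figures
#' @export
regionThreshold <- function(alpha = 0.05, nGenes, nTests = 2) {
  if (nGenes < 1) stop("no testable genes in region")
  stopifnot(nTests >= 1, alpha > 0, alpha < 1)
  alpha / (nGenes * nTests)
}

#' Call candidate genes in QTL regions
#'
#' Per region, the threshold is \code{regionThreshold(alpha, n, 2)} with n
#' the region's homolog count; a gene passes iff
#' min(p_GATES, p_HYST) <= threshold (the winning test is recorded). A
#' gene falling in both a parent region and a sub-region is evaluated in
#' each against that region's own threshold. Homologs without an
#' association record (no SNP coverage) still count toward n but cannot
#' pass; they are reported with \code{NA} p-values.
#'
#' @param regionSets list of \code{RegionGeneSet}.
#' @param assoc data.frame from \code{\link{geneAssociation}} (columns
#'   \code{gene}, \code{p_gates}, \code{p_hyst}).
#' @param alpha family-wise level per region (default 0.05).
#' @param nTests tests per gene (default 2).
#' @return data.frame with one row per (region, gene): \code{region},
#'   \code{gene}, \code{n_genes}, \code{threshold}, \code{test} (GATES or
#'   HYST), \code{p}, \code{pass}. The distinct passing genes are the
#'   candidate list, \code{\link{candidateGenes}}.
#' @export
callCandidates <- function(regionSets, assoc, alpha = 0.05, nTests = 2) {
  rows <- list()
  for (rs in regionSets) {
    stopifnot(is(rs, "RegionGeneSet"))
    if (rs@n < 1) next
    thr <- regionThreshold(alpha, rs@n, nTests)
    for (g in rs@humanGenes) {
      i <- match(g, assoc$gene)
      if (is.na(i)) {
        rows[[length(rows) + 1]] <- data.frame(
          region = rs@regionId, gene = g, n_genes = rs@n, threshold = thr,
          test = NA_character_, p = NA_real_, pass = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      ps <- c(GATES = assoc$p_gates[i], HYST = assoc$p_hyst[i])
      w <- which.min(ps)
      rows[[length(rows) + 1]] <- data.frame(
        region = rs@regionId, gene = g, n_genes = rs@n, threshold = thr,
        test = names(ps)[w], p = unname(ps[w]), pass = unname(ps[w]) <= thr,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(region = character(0), gene = character(0),
                         n_genes = integer(0), threshold = numeric(0),
                         test = character(0), p = numeric(0),
                         pass = logical(0))
  nUntested <- sum(is.na(out$p))
  if (nUntested)
    message(nUntested,
            " homolog(s) had no association record; counted toward n")
  out
}

#' @rdname callCandidates
#' @param calls the data.frame returned by \code{callCandidates}.
#' @return \code{candidateGenes}: character vector of distinct passing
#'   genes.
#' @export
candidateGenes <- function(calls) {
  unique(calls$gene[calls$pass])
}
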