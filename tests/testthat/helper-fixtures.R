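# Shared fixture builders: everything is generated in code at test time.

# A tiny genotype object built directly (bypasses the simulator so the
# simulator itself can be tested against it).
makeGeno <- function(calls, chr = "1", mb = NULL) {
  nm <- ncol(calls)
  if (is.null(mb)) mb <- seq_len(nm) * 10
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("m%02d", seq_len(nm))
  new("GenotypeMatrix", calls = calls,
      markers = data.frame(id = colnames(calls), chr = rep(chr, nm),
                           cm = mb * 0.5, mb = mb,
                           stringsAsFactors = FALSE))
}

makeTrait <- function(values, strains = NULL, id = "t") {
  if (!is.null(strains)) names(values) <- strains
  new("TraitTable", traitId = id, values = values, metadata = "")
}

# A QtlScan built from an explicit LRS pattern (for interval extraction).
makeScan <- function(lrs, chr = "1", id = "t") {
  nm <- length(lrs)
  new("QtlScan", traitId = id,
      table = data.frame(marker = sprintf("m%02d", seq_len(nm)),
                         chr = rep(chr, nm), mb = seq_len(nm) * 10,
                         lrs = lrs, additive = 0, n = 20,
                         stringsAsFactors = FALSE))
}

makeRegion <- function(chr, startMb, endMb, peakMb = NULL, peakLrs = 10,
                       id = "t") {
  if (is.null(peakMb)) peakMb <- (startMb + endMb) / 2
  new("QtlRegion", chr = chr, startMb = startMb, endMb = endMb,
      peakMarker = "m", peakMb = peakMb, peakLrs = peakLrs,
      traitIds = id)
}

makeGenes <- function(chr, starts, ends, ids) {
  GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends),
                         gene_id = ids, symbol = ids)
}
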