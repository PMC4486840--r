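#' @rdname GenotypeMatrix-class
#' @param object,x an object.
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))

#' @rdname TraitTable-class
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' @rdname TraitTable-class
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname GwasSnpTable-class
#' @export
setGeneric("snpTable", function(x) standardGeneric("snpTable"))

#' Look up pairwise LD r-squared
#'
#' Symmetric lookup; a pair absent from the store has r-squared 0 by
#' contract.
#'
#' @param x an \code{LdStore}.
#' @param a,b SNP ids (vectorized, recycled to common length).
#' @return numeric vector of r-squared values in [0, 1].
#' @export
setGeneric("ldR2", function(x, a, b) standardGeneric("ldR2"))

#' @rdname QtlScan-class
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname QtlScan-class
#' @export
setGeneric("lodScores", function(x) standardGeneric("lodScores"))

#' @rdname GenomeWideThreshold-class
#' @export
setGeneric("thresholdLrs", function(x) standardGeneric("thresholdLrs"))

#' @rdname QtlRegion-class
#' @export
setGeneric("subRegions", function(x) standardGeneric("subRegions"))

#' @rdname RegionGeneSet-class
#' @export
setGeneric("humanHomologs", function(x) standardGeneric("humanHomologs"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("corPvalues", function(x) standardGeneric("corPvalues"))

#' @rdname CoexpressionCalls-class
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))
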