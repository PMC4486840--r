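#' Pairwise Pearson correlation with t-based p-values
#'
#' Standard Pearson product-moment correlation across samples,
#' pairwise-complete over missing values; the two-sided p-value comes from
#' t = r sqrt((n - 2) / (1 - r^2)) with the pair-specific n. Items with
#' zero variance get \code{NA} correlations and a warning. Pairs sharing
#' fewer than 3 samples are an error (the p-value is undefined).
#'
#' @param values numeric matrix, items (probes or traits) x samples.
#' @return a \code{\linkS4class{CorrelationResult}}.
#' @export
correlationMatrix <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 1, ncol(values) >= 3)
  obs <- !is.na(values)
  n <- tcrossprod(obs + 0)
  if (any(n < 3))
    stop("every item pair must share at least 3 samples")
  sds <- apply(values, 1, function(v) var(v[!is.na(v)]))
  if (any(sds == 0))
    warning("zero-variance item(s): ",
            paste(rownames(values)[sds == 0], collapse = ", "),
            "; correlations set to NA")
  r <- suppressWarnings(cor(t(values), use = "pairwise.complete.obs"))
  r <- pmin(pmax(r, -1), 1)             # guard rounding just past +/-1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  diag(p) <- 0
  new("CorrelationResult", r = r, p = p, n = n)
}

#' Probe-count-adjusted coexpression calls
#'
#' A pair coexpresses iff |r| >= rMin and its correlation p-value is at
#' most alpha / nProbes -- a Bonferroni correction of the family alpha by
#' the number of probes targeting the genes of interest (e.g. 0.05 / 63 =
#' 7.94e-4). The |r| that exactly reaches the adjusted alpha at the median
#' pair sample size is reported for reference.
#'
#' @param corr a \code{CorrelationResult}.
#' @param alpha family alpha (default 0.05).
#' @param nProbes number of probes in the correction family (>= 1).
#' @param rMin correlation magnitude threshold (default 0.5).
#' @return a \code{\linkS4class{CoexpressionCalls}}.
#' @export
coexpressionCalls <- function(corr, alpha = 0.05, nProbes, rMin = 0.5) {
  stopifnot(is(corr, "CorrelationResult"), nProbes >= 1)
  adj <- alpha / nProbes
  calls <- !is.na(corr@r) & abs(corr@r) >= rMin & corr@p <= adj
  diag(calls) <- FALSE
  nmed <- stats::median(corr@n[upper.tri(corr@n)])
  rImp <- if (is.finite(nmed) && nmed > 2) {
    tcrit <- stats::qt(adj / 2, df = nmed - 2, lower.tail = FALSE)
    tcrit / sqrt(nmed - 2 + tcrit^2)
  } else NA_real_
  new("CoexpressionCalls", calls = calls, adjustedAlpha = adj,
      rMin = rMin, rImplied = rImp)
}

#' Probes of a gene that correlate with their siblings
#'
#' Keeps the probes of a gene that show r >= 0.5 with p <= 0.05 against at
#' least one other probe of the same gene (a consistency screen against
#' misbehaving probes); a single-probe gene keeps its probe with a
#' \code{message()} caveat.
#'
#' @param expr \code{SummarizedExperiment} with assay \code{exprs} and
#'   rowData \code{gene_id}.
#' @param gene gene id.
#' @param rMin,alpha screen thresholds (defaults 0.5 and 0.05).
#' @return character vector of retained probe ids.
#' @export
consistentProbes <- function(expr, gene, rMin = 0.5, alpha = 0.05) {
  rd <- SummarizedExperiment::rowData(expr)
  probes <- rownames(expr)[rd$gene_id == gene]
  if (!length(probes)) stop("gene '", gene, "' has no probes")
  if (length(probes) == 1) {
    message("gene '", gene, "' has a single probe; kept without ",
            "consistency check")
    return(probes)
  }
  m <- SummarizedExperiment::assay(expr, "exprs")[probes, , drop = FALSE]
  cr <- correlationMatrix(m)
  ok <- cr@r >= rMin & cr@p <= alpha
  diag(ok) <- FALSE
  probes[apply(ok, 1, any, na.rm = TRUE)]
}

#' Phenotypes correlating with every probe of a gene
#'
#' Retains the phenotypes whose correlation with EVERY supplied probe
#' satisfies |r| >= rMin and p <= alpha, with a consistent sign of r
#' across probes (a phenotype positive with one probe and negative with
#' another is ambiguous and dropped).
#'
#' @param probeValues numeric matrix, probes x strains.
#' @param phenoValues numeric matrix, phenotypes x strains (same strain
#'   columns; names are matched when present).
#' @param rMin,alpha thresholds (defaults 0.5 and 0.05).
#' @return character vector of retained phenotype ids (rownames of
#'   \code{phenoValues}).
#' @export
phenotypeScreen <- function(probeValues, phenoValues, rMin = 0.5,
                            alpha = 0.05) {
  probeValues <- as.matrix(probeValues)
  phenoValues <- as.matrix(phenoValues)
  stopifnot(nrow(probeValues) >= 1)
  if (!is.null(colnames(probeValues)) && !is.null(colnames(phenoValues))) {
    shared <- intersect(colnames(probeValues), colnames(phenoValues))
    probeValues <- probeValues[, shared, drop = FALSE]
    phenoValues <- phenoValues[, shared, drop = FALSE]
  }
  cr <- correlationMatrix(rbind(probeValues, phenoValues))
  np <- nrow(probeValues)
  keep <- vapply(seq_len(nrow(phenoValues)), function(i) {
    r <- cr@r[np + i, seq_len(np)]
    p <- cr@p[np + i, seq_len(np)]
    all(!is.na(r)) && all(abs(r) >= rMin) && all(p <= alpha) &&
      (all(r > 0) || all(r < 0))
  }, logical(1))
  rownames(phenoValues)[keep]
}

#' Conditional (condition-profile) coexpression values
#'
#' For a target gene, each gene's coexpression value is the fraction of
#' conditions in which it is two-fold up-regulated among the conditions in
#' which the target is two-fold up-regulated: a value of 0.50 means the
#' gene is up in half the cases the target is up. The p-value is a
#' one-sided binomial upper tail of the joint-up count given the gene's
#' marginal up-frequency across all conditions (the null of no
#' association between the two up-profiles). Genes with value >= 0.50 and
#' p <= 0.05 form the commonly-coexpressed set.
#'
#' @param conditions logical (or 0/1) matrix, genes x conditions: the
#'   two-fold up-regulation calls.
#' @param target target gene id (rowname); must be up in at least one
#'   condition.
#' @return data.frame (one row per gene, target excluded): \code{gene},
#'   \code{value}, \code{p}, \code{joint_up}, \code{target_up},
#'   \code{common} (the set membership flag).
#' @export
conditionalCoexpression <- function(conditions, target) {
  conditions <- conditions > 0
  stopifnot(!is.null(rownames(conditions)), target %in% rownames(conditions))
  tUp <- conditions[target, ]
  if (!any(tUp))
    stop("target gene is never up-regulated; coexpression values undefined")
  others <- setdiff(rownames(conditions), target)
  nT <- sum(tUp)
  joint <- rowSums(conditions[others, tUp, drop = FALSE])
  marg <- rowMeans(conditions[others, , drop = FALSE])
  value <- joint / nT
  p <- pbinom(joint - 1, size = nT, prob = marg, lower.tail = FALSE)
  data.frame(gene = others, value = unname(value), p = unname(p),
             joint_up = unname(joint), target_up = nT,
             common = unname(value >= 0.5 & p <= 0.05),
             stringsAsFactors = FALSE)
}

#' Over-representation analysis against user-supplied term sets
#'
#' Hypergeometric upper-tail enrichment P[X >= overlap] of a gene list in
#' each term set, against a stated universe (e.g. the whole genome), with
#' Benjamini-Hochberg adjustment across the supplied terms. Results are
#' sorted by q.
#'
#' @param geneList character gene ids (non-empty, subset of
#'   \code{universe}).
#' @param termSets named list of character vectors (terms are intersected
#'   with the universe).
#' @param universe character background gene ids.
#' @return data.frame: \code{term}, \code{universe_size}, \code{term_size},
#'   \code{list_size}, \code{overlap}, \code{p}, \code{q}.
#' @export
oraEnrichment <- function(geneList, termSets, universe) {
  geneList <- unique(geneList)
  if (!length(geneList)) stop("empty gene list")
  if (!all(geneList %in% universe))
    stop("gene list must be a subset of the universe")
  N <- length(unique(universe))
  nl <- length(geneList)
  rows <- lapply(names(termSets), function(tm) {
    term <- intersect(unique(termSets[[tm]]), universe)
    k <- length(intersect(term, geneList))
    p <- phyper(k - 1, length(term), N - length(term), nl,
                lower.tail = FALSE)
    data.frame(term = tm, universe_size = N, term_size = length(term),
               list_size = nl, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$q, out$p), , drop = FALSE]
}

#' First principal component as a synthetic trait
#'
#' Centers (and by default unit-scales -- the traits are on heterogeneous
#' scales) the trait columns and projects the samples on the leading
#' eigenvector. When PC1 explains a high fraction of the variance its
#' scores serve as a single synthetic trait capturing the traits' shared
#' variation. Orientation is fixed by requiring the loading sum to be
#' non-negative, so flipping the sign of all inputs does not change the
#' variance fraction.
#'
#' @param values numeric matrix, samples x traits (>= 3 samples, >= 2
#'   traits).
#' @param standardize scale columns to unit variance (default TRUE; a
#'   constant column is then an error).
#' @return list with \code{scores} (named by sample),
#'   \code{varianceFraction} (lambda_1 / sum lambda) and \code{loadings}
#'   (unit-norm).
#' @export
pc1Trait <- function(values, standardize = TRUE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 3, ncol(values) >= 2)
  if (standardize && any(apply(values, 2, var) == 0))
    stop("constant trait column cannot be standardized")
  pc <- prcomp(values, center = TRUE, scale. = standardize)
  load <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (sum(load) < 0) {
    load <- -load
    scores <- -scores
  }
  list(scores = scores,
       varianceFraction = pc$sdev[1]^2 / sum(pc$sdev^2),
       loadings = load)
}
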