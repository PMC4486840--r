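#' Map LD r-squared to p-value correlation
#'
#' The single pluggable site converting pairwise LD into the correlation
#' of the two association p-values. Two mappings are provided, both exact
#' at r2 = 0 (independence) and r2 = 1 (duplicate SNP) and monotone in
#' between:
#' \describe{
#'   \item{\code{"exact"} (default)}{the Pearson correlation of the
#'     two-sided p-values of bivariate-normal Z-scores with correlation
#'     r. Since p depends on Z only through |Z| this is an even function
#'     of r, hence determined by r-squared; it is evaluated by quadrature
#'     and cached as a monotone spline. Slightly conservative for the
#'     gene-based tests.}
#'   \item{\code{"r2"}}{the r-squared itself, a simple upper
#'     approximation (it overstates the p-value correlation at
#'     intermediate LD, making the tests marginally liberal).}
#' }
#'
#' @param r2 numeric vector of r-squared values in [0, 1].
#' @param method \code{"exact"} or \code{"r2"}.
#' @return p-value correlations, same length.
#' @examples
#' pvalueCorrelation(c(0, 0.64, 1))
#' pvalueCorrelation(0.25, method = "r2")   # identity mapping
#' @export
pvalueCorrelation <- function(r2, method = c("exact", "r2")) {
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1))
    stop("r2 must lie in [0, 1]")
  method <- match.arg(method)
  if (method == "r2") return(r2)
  out <- pmin(pmax(.rhoSpline()(as.vector(r2)), 0), 1)
  out[as.vector(r2) == 0] <- 0
  out[as.vector(r2) == 1] <- 1
  attributes(out) <- attributes(r2)     # keep matrix shape if given one
  out
}

#' Effective number of independent tests
#'
#' Me = M - sum over eigenvalues lambda > 1 of (lambda - 1), computed on a
#' correlation matrix: equals M for the identity and 1 when all entries
#' are 1.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @return numeric(1) in [1, M].
#' @export
effectiveTests <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) ||
      !isTRUE(all.equal(corr, t(corr), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("correlation matrix must be symmetric")
  if (nrow(corr) == 1) return(1)
  lam <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  me <- nrow(corr) - sum(pmax(lam - 1, 0))
  min(max(me, 1), nrow(corr))
}

#' GATES: gene-based association from correlated SNP p-values
#'
#' Extended Simes test: with SNP p-values sorted ascending (ties broken by
#' input order) and me(j) the effective number of tests among the top j
#' SNPs (Me = me(M) for all of them),
#' P = min_j Me * p_(j) / me(j), clamped at 1. The key SNP is the one at
#' which the minimum is achieved (smallest j on ties). Reduces to the
#' Simes test for independent SNPs and to the minimum p-value when all
#' SNPs are perfectly correlated.
#'
#' @param p numeric vector of SNP p-values in (0, 1], optionally named by
#'   SNP id.
#' @param rho p-value correlation matrix aligned with \code{p} (default
#'   identity).
#' @return list with \code{p} (gene p-value), \code{keySnp} (name or index
#'   of the key SNP), \code{me} (effective tests over all SNPs),
#'   \code{meJ} (the per-rank me(j) vector, audit metadata).
#' @export
gatesTest <- function(p, rho = NULL) {
  stopifnot(length(p) >= 1, all(p > 0), all(p <= 1))
  M <- length(p)
  if (is.null(rho)) rho <- diag(M)
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == M, ncol(rho) == M)
  ord <- order(p)                       # stable: ties keep input order
  ps <- p[ord]
  rs <- rho[ord, ord, drop = FALSE]
  meJ <- vapply(seq_len(M), function(j)
    effectiveTests(rs[seq_len(j), seq_len(j), drop = FALSE]), numeric(1))
  Me <- meJ[M]
  terms <- Me * ps / meJ
  j <- which.min(terms)                 # smallest j on ties
  key <- if (!is.null(names(p))) names(p)[ord[j]] else ord[j]
  list(p = min(terms[j], 1), keySnp = key, me = Me, meJ = meJ)
}

#' Greedy LD-block partition of a gene's SNPs
#'
#' Left-to-right over position-sorted SNPs: a SNP joins the current block
#' iff its r-squared with the block's last member is at least
#' \code{r2Join}; otherwise it starts a new block. The partition covers
#' all SNPs and preserves order.
#'
#' @param snpIds character SNP ids.
#' @param positions numeric positions (bp), same length.
#' @param ld an \code{LdStore}.
#' @param r2Join joining threshold (default 0.8).
#' @return list of character vectors of SNP ids, one per block.
#' @export
ldBlocks <- function(snpIds, positions, ld, r2Join = 0.8) {
  stopifnot(length(snpIds) == length(positions), length(snpIds) >= 1)
  ord <- order(positions)
  ids <- snpIds[ord]
  blocks <- list(ids[1])
  if (length(ids) > 1) {
    for (i in 2:length(ids)) {
      cur <- blocks[[length(blocks)]]
      if (ldR2(ld, cur[length(cur)], ids[i]) >= r2Join)
        blocks[[length(blocks)]] <- c(cur, ids[i])
      else blocks[[length(blocks) + 1]] <- ids[i]
    }
  }
  blocks
}

#' HYST: scaled chi-square combination of block p-values
#'
#' Combines per-LD-block GATES p-values with a correlated-Fisher scaled
#' chi-square: T = -2 sum ln p_k has mean E = 2K and variance
#' Var = 4K + 2 sum_\{i<j\} c_ij, where c_ij models the covariance of
#' -2 ln p between blocks i and j from their key-SNP LD. The combined
#' p-value is the upper tail of a chi-square with f = 2 E^2 / Var degrees
#' of freedom at T / c, c = Var / (2 E). With one block, or perfectly
#' redundant blocks, the block p-value is returned exactly; with
#' independent blocks this is Fisher's method.
#'
#' Two covariance models are available:
#' \describe{
#'   \item{\code{"exact"} (default)}{c_ij is the covariance of
#'     -2 ln p for two-sided p-values of bivariate-normal Z-scores at the
#'     key-SNP r-squared, evaluated by quadrature (0 at r2 = 0, exactly 4
#'     at r2 = 1). Brown's linear-quadratic fit understates this
#'     covariance for two-sided tests, which inflates the far tail of the
#'     combined statistic.}
#'   \item{\code{"brown"}}{Brown's approximation
#'     c_ij = rho (3.25 + 0.75 rho) on the p-value correlation rho,
#'     negatives truncated to 0.}
#' }
#'
#' @param blockP numeric vector of per-block p-values.
#' @param rho K x K p-value correlation matrix between block key SNPs
#'   (default identity = independent blocks).
#' @param r2 optional K x K key-SNP r-squared matrix; when supplied it
#'   overrides \code{rho} for the \code{"exact"} model (otherwise r2 is
#'   recovered from \code{rho} by inverting the exact mapping).
#' @param covModel \code{"exact"} or \code{"brown"}.
#' @return numeric(1) combined p-value.
#' @export
hystTest <- function(blockP, rho = NULL, r2 = NULL,
                     covModel = c("exact", "brown")) {
  covModel <- match.arg(covModel)
  K <- length(blockP)
  stopifnot(K >= 1, all(blockP <= 1))
  if (any(blockP <= 0)) {
    warning("block p-value of 0 clamped to the smallest representable value")
    blockP[blockP <= 0] <- .Machine$double.xmin
  }
  if (is.null(rho) && is.null(r2)) rho <- diag(K)
  if (covModel == "exact") {
    if (is.null(r2)) r2 <- .r2FromRho(pmax(as.matrix(rho), 0))
    r2 <- as.matrix(r2)
    stopifnot(nrow(r2) == K, ncol(r2) == K)
    cij <- matrix(pmin(pmax(.covLogPSpline()(as.vector(r2)), 0), 4), K, K)
    cij[r2 == 1] <- 4
    cij[r2 == 0] <- 0
  } else {
    if (is.null(rho)) stop("covModel 'brown' needs a rho matrix")
    rho <- as.matrix(rho)
    stopifnot(nrow(rho) == K, ncol(rho) == K)
    rr <- pmax(rho, 0)
    cij <- rr * (3.25 + 0.75 * rr)
  }
  T <- -2 * sum(log(blockP))
  E <- 2 * K
  Var <- 4 * K + 2 * sum(cij[upper.tri(cij)])
  cc <- Var / (2 * E)
  f <- 2 * E^2 / Var
  pchisq(T / cc, df = f, lower.tail = FALSE)
}

#' Assign GWAS SNPs to genes
#'
#' A SNP is assigned to every gene whose 1-based inclusive span, extended
#' by \code{flankKb} kilobases on both sides, contains its position (a SNP
#' inside two overlapping genes is assigned to both). Genes receiving no
#' SNP are flagged untested.
#'
#' @param gwas a \code{GwasSnpTable}.
#' @param genes \code{GRanges} with a \code{gene_id} metadata column.
#' @param flankKb flanking distance in kb (default 0: gene body only).
#' @return list with \code{sets}: named list (per tested gene) of
#'   data.frames (snp, bp, p) sorted by position; \code{untested}:
#'   character ids of genes without SNPs.
#' @export
assignSnpsToGenes <- function(gwas, genes, flankKb = 0) {
  stopifnot(is(gwas, "GwasSnpTable"), is(genes, "GRanges"))
  s <- snpTable(gwas)
  ids <- GenomicRanges::mcols(genes)$gene_id
  snpGr <- GenomicRanges::GRanges(s$chr, IRanges::IRanges(s$bp, s$bp))
  ext <- suppressWarnings(GenomicRanges::resize(
    genes, GenomicRanges::width(genes) + 2 * flankKb * 1000, fix = "center"))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snpGr, ext))
  sets <- list()
  for (g in unique(S4Vectors::subjectHits(hits))) {
    idx <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == g]
    sub <- s[idx, c("snp", "bp", "p")]
    sets[[ids[g]]] <- sub[order(sub$bp), , drop = FALSE]
  }
  list(sets = sets, untested = setdiff(ids, names(sets)))
}

.rhoMatrix <- function(snpIds, ld, rhoMethod = "exact") {
  M <- length(snpIds)
  rho <- diag(M)
  if (M > 1) {
    for (i in 1:(M - 1)) for (j in (i + 1):M) {
      rho[i, j] <- rho[j, i] <-
        pvalueCorrelation(ldR2(ld, snpIds[i], snpIds[j]), method = rhoMethod)
    }
  }
  rho
}

#' Per-gene GATES and HYST association from GWAS summary statistics
#'
#' Orchestrates the gene-based stage: SNPs are assigned to genes, the
#' pairwise p-value correlation matrix is derived from LD r-squared, GATES
#' gives one gene p-value, and HYST combines per-LD-block GATES p-values
#' (greedy blocks, block key SNP = the SNP achieving the block's GATES
#' minimum, inter-block correlation taken between key SNPs).
#'
#' @param gwas a \code{GwasSnpTable}.
#' @param ld an \code{LdStore}.
#' @param genes \code{GRanges} with \code{gene_id}.
#' @param flankKb flank for SNP assignment (default 0).
#' @param blockR2 r-squared threshold for the greedy block partition
#'   (default 0.8).
#' @param rhoMethod p-value correlation mapping, see
#'   \code{\link{pvalueCorrelation}}.
#' @param covModel HYST inter-block covariance model, see
#'   \code{\link{hystTest}}.
#' @return data.frame with one row per tested gene: \code{gene},
#'   \code{n_snps}, \code{n_blocks}, \code{p_gates}, \code{key_snp},
#'   \code{p_hyst}, \code{me}; the ids of untested genes are kept in
#'   attribute \code{"untested"}.
#' @examples
#' ann <- simulateAnnotation(
#'   data.frame(chr = "1", startMb = 10, endMb = 12), 5, 1, seed = 1)
#' sim <- simulateGwasRegion(ann$human, causal = "HGENE0001", ncp = 5,
#'   seed = 2)
#' geneAssociation(sim$gwas, sim$ld, ann$human)
#' @export
geneAssociation <- function(gwas, ld, genes, flankKb = 0, blockR2 = 0.8,
                            rhoMethod = c("exact", "r2"),
                            covModel = c("exact", "brown")) {
  rhoMethod <- match.arg(rhoMethod)
  covModel <- match.arg(covModel)
  asg <- assignSnpsToGenes(gwas, genes, flankKb)
  rows <- lapply(names(asg$sets), function(gid) {
    sub <- asg$sets[[gid]]
    p <- setNames(sub$p, sub$snp)
    rho <- .rhoMatrix(sub$snp, ld, rhoMethod)
    ga <- gatesTest(p, rho)
    blocks <- ldBlocks(sub$snp, sub$bp, ld, r2Join = blockR2)
    blockP <- numeric(length(blocks))
    keys <- character(length(blocks))
    for (b in seq_along(blocks)) {
      i <- match(blocks[[b]], sub$snp)
      gb <- gatesTest(p[i], rho[i, i, drop = FALSE])
      blockP[b] <- gb$p
      keys[b] <- gb$keySnp
    }
    kr2 <- diag(length(keys))
    if (length(keys) > 1) {
      for (bi in 1:(length(keys) - 1)) for (bj in (bi + 1):length(keys)) {
        kr2[bi, bj] <- kr2[bj, bi] <- ldR2(ld, keys[bi], keys[bj])
      }
    }
    ph <- hystTest(blockP, r2 = kr2, covModel = covModel)
    data.frame(gene = gid, n_snps = nrow(sub), n_blocks = length(blocks),
               p_gates = ga$p, key_snp = ga$keySnp, p_hyst = ph,
               me = ga$me, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(0), n_snps = integer(0),
                         n_blocks = integer(0), p_gates = numeric(0),
                         key_snp = character(0), p_hyst = numeric(0),
                         me = numeric(0))
  attr(out, "untested") <- asg$untested
  out
}
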