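#' Simulate a recombinant inbred genotype panel
#'
#' Generates an inbred-line genotype mosaic of the two parental allele
#' states (B = -1, D = +1) along each chromosome with a first-order switch
#' process. Physical marker spacing is converted to genetic distance at a
#' constant cM/Mb rate, the Haldane map function gives the per-interval
#' recombination fraction r, and the recombinant-inbred (sib-mating) map
#' expansion R = 4r / (1 + 6r) gives the strand-switch probability, which
#' therefore lies in [0, 0.5].
#'
#' @param nLines number of inbred lines (>= 2).
#' @param chromosomes data.frame with columns \code{name},
#'   \code{lengthMb}, \code{nMarkers} (each >= 1); markers are placed at
#'   the midpoints of equal bins, so positions are strictly increasing.
#' @param cmPerMb genetic map rate, cM per Mb (default 0.5, mouse-typical).
#'   0 gives switch probability 0 (no recombination).
#' @param missingRate probability that a call is masked to missing.
#' @param seed integer RNG seed; the output is deterministic given the
#'   full argument set.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @examples
#' geno <- simulateRiPanel(20,
#'   data.frame(name = "1", lengthMb = 100, nMarkers = 30), seed = 1)
#' geno
#' @export
simulateRiPanel <- function(nLines, chromosomes, cmPerMb = 0.5,
                            missingRate = 0, seed) {
  stopifnot(nLines >= 2, is.data.frame(chromosomes),
            all(c("name", "lengthMb", "nMarkers") %in% names(chromosomes)),
            cmPerMb >= 0, missingRate >= 0, missingRate < 1)
  if (any(chromosomes$nMarkers < 1))
    stop("every chromosome must carry at least one marker")
  set.seed(as.integer(seed))
  strains <- sprintf("BXS%03d", seq_len(nLines))
  markerList <- list()
  callList <- list()
  for (k in seq_len(nrow(chromosomes))) {
    chr <- as.character(chromosomes$name[k])
    nm <- chromosomes$nMarkers[k]
    pos <- chromosomes$lengthMb[k] * (seq_len(nm) - 0.5) / nm
    d <- diff(pos) * cmPerMb                 # cM between adjacent markers
    r <- 0.5 * (1 - exp(-2 * d / 100))      # Haldane
    R <- 4 * r / (1 + 6 * r)                # RI map expansion
    g <- matrix(0L, nLines, nm)
    g[, 1] <- ifelse(runif(nLines) < 0.5, -1L, 1L)
    if (nm > 1) {
      for (j in 2:nm) {
        sw <- runif(nLines) < R[j - 1]
        g[, j] <- ifelse(sw, -g[, j - 1], g[, j - 1])
      }
    }
    markerList[[k]] <- data.frame(
      id = sprintf("%s_m%04d", chr, seq_len(nm)), chr = chr,
      cm = pos * cmPerMb, mb = pos, stringsAsFactors = FALSE)
    callList[[k]] <- g
  }
  markers <- do.call(rbind, markerList)
  calls <- do.call(cbind, callList)
  if (missingRate > 0)
    calls[runif(length(calls)) < missingRate] <- NA
  dimnames(calls) <- list(strains, markers$id)
  new("GenotypeMatrix", calls = calls, markers = markers)
}

#' Simulate a strain-mean trait with one planted additive QTL
#'
#' trait = mu + a * x + e with allele code x in \{-1 (B), +1 (D)\}. The
#' residual standard deviation is derived from the planted effect and the
#' target heritability via h2 = Var(a x) / (Var(a x) + sigma^2) with
#' Var(x) = 1 (balanced alleles), i.e. sigma = |a| sqrt((1 - h2) / h2).
#' With h2 = 1 the trait is noise-free; with a = 0 the heritability formula
#' is uninformative and \code{residualSd} is used directly (a pure null
#' trait). Lines missing a genotype at the planted marker are omitted.
#'
#' @param geno a \code{GenotypeMatrix}.
#' @param marker id of the planted marker (must exist in \code{geno}).
#' @param additive planted additive effect a, in trait units per allele
#'   substitution; positive means the D allele increases the trait.
#' @param h2 heritability in [0, 1].
#' @param mu baseline trait mean.
#' @param residualSd residual sd used only when \code{additive == 0}
#'   (default 1).
#' @param seed integer RNG seed.
#' @param traitId,metadata identifiers stored on the result.
#' @return a \code{\linkS4class{TraitTable}}.
#' @export
simulateStrainTrait <- function(geno, marker, additive, h2, mu = 0,
                                residualSd = 1, seed, traitId = "sim_trait",
                                metadata = "") {
  stopifnot(is(geno, "GenotypeMatrix"), h2 >= 0, h2 <= 1)
  calls <- genoCalls(geno)
  if (!marker %in% colnames(calls))
    stop("planted marker '", marker, "' not present in the panel")
  if (additive != 0 && h2 == 0)
    stop("h2 = 0 is inconsistent with a non-zero planted effect")
  set.seed(as.integer(seed))
  x <- calls[, marker]
  keep <- !is.na(x)
  x <- x[keep]
  sigma <- if (additive == 0) residualSd
           else if (h2 == 1) 0
           else abs(additive) * sqrt((1 - h2) / h2)
  y <- mu + additive * x + rnorm(length(x), 0, sigma)
  names(y) <- rownames(calls)[keep]
  new("TraitTable", traitId = traitId, values = y, metadata = metadata)
}

#' Simulate GWAS summary statistics with LD structure
#'
#' For each gene, a Z-score vector is drawn from a multivariate normal with
#' first-order autoregressive correlation \code{arCorr} between adjacent
#' SNPs and mean equal to the non-centrality vector (0 for null genes; for
#' a causal gene every SNP carries \code{ncp}). Two-sided p-values are
#' p = 2 * Phi(-|Z|). The returned \code{LdStore} holds the exact pairwise
#' r-squared implied by the correlation used, (arCorr^{|i-j|})^2.
#'
#' @param genes a \code{GRanges} of human genes with a \code{gene_id}
#'   metadata column (as from \code{\link{simulateAnnotation}}).
#' @param snpsPerGene SNPs placed per gene, evenly within the gene span.
#' @param arCorr adjacent-SNP correlation in [0, 1).
#' @param causal character vector of causal gene ids (subset of
#'   \code{gene_id}).
#' @param ncp per-SNP non-centrality (>= 0) applied to every SNP of a
#'   causal gene.
#' @param seed integer RNG seed.
#' @return list with elements \code{gwas} (a
#'   \code{\linkS4class{GwasSnpTable}}) and \code{ld} (an
#'   \code{\linkS4class{LdStore}}).
#' @export
simulateGwasRegion <- function(genes, snpsPerGene = 8, arCorr = 0.8,
                               causal = character(0), ncp = 0, seed) {
  stopifnot(is(genes, "GRanges"), snpsPerGene >= 1,
            arCorr >= 0, arCorr < 1, ncp >= 0)
  ids <- GenomicRanges::mcols(genes)$gene_id
  if (is.null(ids)) stop("genes must carry a gene_id metadata column")
  if (!all(causal %in% ids)) stop("causal gene ids not found in annotation")
  set.seed(as.integer(seed))
  Sigma <- arCorr ^ abs(outer(seq_len(snpsPerGene), seq_len(snpsPerGene), "-"))
  L <- chol(Sigma)
  env <- new.env(parent = emptyenv())
  rows <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    id <- ids[g]
    st <- GenomicRanges::start(genes)[g]
    en <- GenomicRanges::end(genes)[g]
    pos <- round(st + (en - st) * (seq_len(snpsPerGene) - 0.5) / snpsPerGene)
    snp <- sprintf("rs_%s_%02d", id, seq_len(snpsPerGene))
    mu <- if (id %in% causal) rep(ncp, snpsPerGene) else rep(0, snpsPerGene)
    z <- mu + drop(crossprod(L, rnorm(snpsPerGene)))
    p <- 2 * pnorm(-abs(z))
    p[p < .Machine$double.xmin] <- .Machine$double.xmin
    rows[[g]] <- data.frame(
      snp = snp, chr = as.character(GenomicRanges::seqnames(genes)[g]),
      bp = pos, p = p, stringsAsFactors = FALSE)
    if (snpsPerGene > 1) {
      for (i in 1:(snpsPerGene - 1)) for (j in (i + 1):snpsPerGene) {
        env[[.ldKey(snp[i], snp[j])]] <- (arCorr ^ (j - i))^2
      }
    }
  }
  tab <- do.call(rbind, rows)
  list(gwas = new("GwasSnpTable", snps = tab, nDropped = 0L),
       ld = new("LdStore", env = env))
}

#' Simulate gene annotations and a homology map
#'
#' Tiles non-overlapping genes across each supplied region on both the
#' mouse and the human assembly (same synthetic coordinates), and pairs
#' each mouse gene with a human partner with probability
#' \code{homologRate}; the resulting map is one-to-one.
#'
#' @param regions data.frame with columns \code{chr}, \code{startMb},
#'   \code{endMb}, or a list of \code{QtlRegion} objects.
#' @param genesPerRegion genes tiled per region; genes occupy half of each
#'   tile, so the region must be wide enough for every gene to span at
#'   least 1 bp.
#' @param homologRate probability in [0, 1] that a mouse gene has a human
#'   homolog.
#' @param seed integer RNG seed.
#' @return list with elements \code{mouse}, \code{human} (both
#'   \code{GRanges} with \code{gene_id} and \code{symbol}) and
#'   \code{homology} (a \code{\linkS4class{HomologyMap}}).
#' @export
simulateAnnotation <- function(regions, genesPerRegion, homologRate, seed) {
  stopifnot(homologRate >= 0, homologRate <= 1, genesPerRegion >= 1)
  if (is.list(regions) && !is.data.frame(regions) &&
      all(vapply(regions, is, logical(1), "QtlRegion"))) {
    regions <- data.frame(
      chr = vapply(regions, function(r) r@chr, character(1)),
      startMb = vapply(regions, function(r) r@startMb, numeric(1)),
      endMb = vapply(regions, function(r) r@endMb, numeric(1)))
  }
  set.seed(as.integer(seed))
  mouse <- list(); human <- list(); hm <- character(0); hh <- character(0)
  idx <- 0
  for (k in seq_len(nrow(regions))) {
    startBp <- round(regions$startMb[k] * 1e6)
    endBp <- round(regions$endMb[k] * 1e6)
    tile <- floor((endBp - startBp + 1) / genesPerRegion)
    glen <- floor(tile / 2)
    if (glen < 1)
      stop("region too small to tile ", genesPerRegion,
           " non-overlapping genes")
    st <- startBp + (seq_len(genesPerRegion) - 1) * tile
    en <- st + glen - 1
    mid <- sprintf("mgene%04d", idx + seq_len(genesPerRegion))
    hid <- toupper(sub("^m", "h", mid))
    chr <- as.character(regions$chr[k])
    mouse[[k]] <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en),
      gene_id = mid, symbol = mid)
    human[[k]] <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en),
      gene_id = hid, symbol = hid)
    has <- runif(genesPerRegion) < homologRate
    hm <- c(hm, mid[has]); hh <- c(hh, hid[has])
    idx <- idx + genesPerRegion
  }
  mouse <- do.call(c, mouse)
  humanAll <- do.call(c, human)
  human <- humanAll[GenomicRanges::mcols(humanAll)$gene_id %in% hh]
  list(mouse = mouse, human = human,
       homology = new("HomologyMap", mouse = hm, human = hh))
}

#' Simulate a modular probe-level expression matrix
#'
#' Each gene is assigned to a latent factor (module); a probe's value is
#' loading * factor(strain) + gene-level noise + probe-level noise, on a
#' log2-intensity-like scale. Two genes sharing a factor with equal
#' loadings have expected pairwise probe correlation
#' loading^2 * Var(factor) / total variance (factor variance is 1).
#' Optionally, a binary condition-by-gene up-regulation matrix is derived
#' by thresholding simulated per-condition log2 fold changes (same factor
#' structure across conditions) at two-fold.
#'
#' @param moduleAssign named integer/character vector: gene id -> factor
#'   label; genes with distinct labels load on independent factors.
#' @param loading per-gene factor loading, recycled (default 1).
#' @param geneNoiseSd,probeNoiseSd residual sds (> 0 jointly; either may
#'   be 0).
#' @param nStrains number of strains (>= 3, else correlation p-values are
#'   undefined downstream).
#' @param probesPerGene probes per gene (all probes of a gene share its
#'   gene-level signal and differ by probe noise).
#' @param nConditions conditions for the up-call matrix (0 = skip).
#' @param regionType probe annotation region type, recycled over probes
#'   ("exon" by default).
#' @param seed integer RNG seed.
#' @return list with \code{expr} (a \code{SummarizedExperiment}, assay
#'   \code{exprs}, rowData \code{gene_id} and \code{region_type}) and
#'   \code{conditions} (logical genes x conditions matrix, or NULL).
#' @export
simulateExpression <- function(moduleAssign, loading = 1,
                               geneNoiseSd = 0.5, probeNoiseSd = 0.3,
                               nStrains = 30, probesPerGene = 2,
                               nConditions = 0, regionType = "exon", seed) {
  stopifnot(length(moduleAssign) >= 1, !is.null(names(moduleAssign)),
            geneNoiseSd >= 0, probeNoiseSd >= 0)
  if (nStrains < 3)
    stop("nStrains must be >= 3 (correlation p-values undefined below)")
  set.seed(as.integer(seed))
  genes <- names(moduleAssign)
  loading <- rep_len(loading, length(genes))
  mods <- unique(moduleAssign)
  strains <- sprintf("BXS%03d", seq_len(nStrains))
  fac <- matrix(rnorm(length(mods) * nStrains), length(mods), nStrains,
                dimnames = list(as.character(mods), strains))
  probes <- character(0); probeGene <- character(0)
  vals <- list()
  for (i in seq_along(genes)) {
    gsig <- loading[i] * fac[as.character(moduleAssign[i]), ] +
      rnorm(nStrains, 0, geneNoiseSd)
    for (k in seq_len(probesPerGene)) {
      probes <- c(probes, sprintf("%s_p%02d", genes[i], k))
      probeGene <- c(probeGene, genes[i])
      vals[[length(vals) + 1L]] <- gsig + rnorm(nStrains, 0, probeNoiseSd)
    }
  }
  m <- do.call(rbind, vals)
  dimnames(m) <- list(probes, strains)
  rd <- S4Vectors::DataFrame(
    gene_id = probeGene,
    region_type = rep_len(regionType, length(probes)),
    row.names = probes)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), rowData = rd)
  conds <- NULL
  if (nConditions > 0) {
    cf <- matrix(rnorm(length(mods) * nConditions), length(mods), nConditions)
    fc <- matrix(NA_real_, length(genes), nConditions,
                 dimnames = list(genes, sprintf("cond%04d",
                                                seq_len(nConditions))))
    for (i in seq_along(genes)) {
      fc[i, ] <- loading[i] * cf[match(moduleAssign[i], mods), ] +
        rnorm(nConditions, 0, geneNoiseSd)
    }
    conds <- fc >= 1          # log2 fold change >= 1, i.e. two-fold up
  }
  list(expr = se, conditions = conds)
}
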