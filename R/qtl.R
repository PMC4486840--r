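# Internal vectorized two-group RSS engine.
#
# calls: n x M matrix in {-1, +1, NA}; Y: n x P matrix of trait columns
# (observed trait and/or permutations). For each marker and each column,
# LRS = n_m * ln(RSS0 / RSS1), with RSS0 the intercept-only residual sum of
# squares over the lines genotyped at that marker and RSS1 the two-group
# fit. Returns list(lrs = M x P matrix, additive = M x P, n = M vector).
# RSS1 below eps * RSS0 is floored at eps * RSS0 (documented LRS ceiling).
.lrsEngine <- function(calls, Y, eps = 1e-12) {
  B <- (!is.na(calls) & calls == -1L) + 0
  D <- (!is.na(calls) & calls == 1L) + 0
  nB <- colSums(B)
  nD <- colSums(D)
  n <- nB + nD
  sB <- crossprod(B, Y)                 # M x P group sums
  sD <- crossprod(D, Y)
  s2 <- crossprod(B + D, Y^2)
  sT <- sB + sD
  rss0 <- s2 - sT^2 / n                 # matrix / per-marker vector: rowwise
  termB <- sB^2 / nB
  termB[nB == 0, ] <- 0
  termD <- sD^2 / nD
  termD[nD == 0, ] <- 0
  rss1 <- pmax(s2 - termB - termD, eps * rss0)
  lrs <- n * log(rss0 / rss1)
  lrs[rss0 <= 0] <- 0                   # zero trait variance at the marker
  add <- (sD / nD - sB / nB) / 2
  onecls <- nB == 0 | nD == 0
  lrs[onecls, ] <- NA                   # LRS undefined: one allele class
  add[onecls, ] <- NA
  list(lrs = lrs, additive = add, n = n)
}

.alignTrait <- function(geno, trait) {
  shared <- intersect(strainNames(geno), strainNames(trait))
  if (length(shared) < 8)
    stop("need >= 8 strains shared between genotypes and trait (found ",
         length(shared), ")")
  list(calls = genoCalls(geno)[shared, , drop = FALSE],
       y = traitValues(trait)[shared])
}

#' Single-marker likelihood-ratio genome scan
#'
#' Regresses a strain-mean trait on the allele code x in \{-1 (B), +1 (D)\}
#' at every marker: LRS = n * ln(RSS0 / RSS1) with RSS0 from the
#' intercept-only fit and RSS1 from the genotype fit, both over the lines
#' genotyped at the marker; the additive coefficient is
#' a = (mean_D - mean_B) / 2, so a < 0 means the B allele increases the
#' trait. LOD = LRS / 4.61 is available via \code{\link{lodScores}}.
#' Markers at which only one allele class is observed get \code{NA}. A
#' perfect fit (RSS1 = 0) is floored at RSS1 = 1e-12 * RSS0, capping the
#' LRS while preserving ordering. A zero-variance trait yields an all-zero
#' scan with a warning.
#'
#' @param geno a \code{GenotypeMatrix}.
#' @param trait a \code{TraitTable}; at least 8 strains must be shared
#'   with the panel.
#' @return a \code{\linkS4class{QtlScan}}.
#' @examples
#' geno <- simulateRiPanel(40,
#'   data.frame(name = "1", lengthMb = 100, nMarkers = 25), seed = 1)
#' trait <- simulateStrainTrait(geno, "1_m0013", additive = 1, h2 = 0.5,
#'   seed = 2)
#' lrsScan(geno, trait)
#' @export
lrsScan <- function(geno, trait) {
  al <- .alignTrait(geno, trait)
  if (var(al$y) == 0) {
    warning("trait has zero variance; returning all-zero scan")
    m <- markerInfo(geno)
    return(new("QtlScan", traitId = traitId(trait),
               table = data.frame(marker = m$id, chr = m$chr, mb = m$mb,
                                  lrs = 0, additive = 0,
                                  n = length(al$y))))
  }
  e <- .lrsEngine(al$calls, matrix(al$y, ncol = 1))
  m <- markerInfo(geno)
  new("QtlScan", traitId = traitId(trait),
      table = data.frame(marker = m$id, chr = m$chr, mb = m$mb,
                         lrs = as.vector(e$lrs),
                         additive = as.vector(e$additive),
                         n = e$n, stringsAsFactors = FALSE))
}

#' Genome-wide threshold from a list of permutation maxima
#'
#' The threshold at family-wise level alpha is the k-th smallest of the
#' permutation genome-wide maxima with k = ceiling((1 - alpha) * nPerm); an
#' observed LRS is significant iff strictly greater than it ("greater than
#' 95 percent of the permuted datasets").
#'
#' @param maxima numeric vector of per-permutation genome-wide max LRS.
#' @param alpha family-wise error rate in (0, 1).
#' @return numeric(1) threshold.
#' @export
thresholdFromMaxima <- function(maxima, alpha) {
  stopifnot(length(maxima) >= 1, alpha > 0, alpha < 1)
  k <- ceiling((1 - alpha) * length(maxima))
  sort(maxima)[k]
}

#' Permutation-based genome-wide significance threshold
#'
#' Shuffles the trait values across strains (one shared shuffled order per
#' genome scan, equivalent to jointly permuting genotype rows), rescans,
#' and records the genome-wide maximum LRS of each permutation. The
#' threshold is the order statistic defined by
#' \code{\link{thresholdFromMaxima}}.
#'
#' @param geno a \code{GenotypeMatrix}.
#' @param trait a \code{TraitTable} with at least two distinct values.
#' @param nPerm number of permutations (>= 100; the reference practice is
#'   5000).
#' @param alpha family-wise error rate (default 0.05).
#' @param seed integer RNG seed; identical seeds give identical thresholds.
#' @return a \code{\linkS4class{GenomeWideThreshold}}.
#' @export
permutationThreshold <- function(geno, trait, nPerm = 1000, alpha = 0.05,
                                 seed) {
  stopifnot(nPerm >= 100, alpha > 0, alpha < 1)
  al <- .alignTrait(geno, trait)
  if (length(unique(al$y)) < 2)
    stop("trait must have at least two distinct values")
  set.seed(as.integer(seed))
  n <- length(al$y)
  Y <- vapply(seq_len(nPerm), function(i) al$y[sample.int(n)],
              numeric(n))
  maxima <- apply(.lrsEngine(al$calls, Y)$lrs, 2, max, na.rm = TRUE)
  new("GenomeWideThreshold", alpha = alpha, nPerm = as.integer(nPerm),
      threshold = thresholdFromMaxima(maxima, alpha), maxima = maxima,
      seed = as.integer(seed))
}

.makeRegion <- function(tab, idx, traitId) {
  peak <- idx[which.max(tab$lrs[idx])]
  new("QtlRegion", chr = tab$chr[idx[1]], startMb = tab$mb[idx[1]],
      endMb = tab$mb[idx[length(idx)]], peakMarker = tab$marker[peak],
      peakMb = tab$mb[peak], peakLrs = tab$lrs[peak],
      traitIds = traitId)
}

#' Extract significant QTL intervals from a scan
#'
#' Maximal runs of markers with LRS strictly above the threshold become
#' regions (markers with undefined LRS count as below). Two runs separated
#' by at most \code{maxGapMarkers} sub-threshold markers are merged into a
#' single parent region that keeps both runs as sub-regions -- the
#' structure of a wide QTL that separates into two smaller peaks with a
#' non-significant stretch in between. Each region and sub-region records
#' its own peak marker.
#'
#' @param scan a \code{QtlScan}.
#' @param threshold numeric LRS threshold or a
#'   \code{GenomeWideThreshold}.
#' @param maxGapMarkers maximum number of intervening sub-threshold
#'   markers for two runs to merge (default 0: no merging).
#' @return list of \code{\linkS4class{QtlRegion}} (empty when nothing is
#'   significant).
#' @export
significantIntervals <- function(scan, threshold, maxGapMarkers = 0) {
  stopifnot(is(scan, "QtlScan"))
  if (is(threshold, "GenomeWideThreshold")) threshold <- thresholdLrs(threshold)
  tab <- scanTable(scan)
  out <- list()
  for (chr in unique(tab$chr)) {
    ct <- tab[tab$chr == chr, , drop = FALSE]
    sig <- !is.na(ct$lrs) & ct$lrs > threshold
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- lapply(which(r$values), function(i) starts[i]:ends[i])
    # merge runs separated by <= maxGapMarkers sub-threshold markers
    groups <- list(runs[[1]])
    if (length(runs) > 1) {
      for (i in 2:length(runs)) {
        last <- groups[[length(groups)]]
        gap <- runs[[i]][1] - last[length(last)] - 1
        if (gap <= maxGapMarkers)
          groups[[length(groups)]] <- c(last, runs[[i]])
        else groups[[length(groups) + 1]] <- runs[[i]]
      }
    }
    for (g in groups) {
      sub <- Filter(function(run) all(run %in% g), runs)
      parent <- .makeRegion(ct, g[sig[g]], traitId(scan))
      if (length(sub) > 1)
        parent@subRegions <- lapply(sub, .makeRegion, tab = ct,
                                    traitId = traitId(scan))
      out[[length(out) + 1]] <- parent
    }
  }
  out
}

#' Consensus regions across traits
#'
#' Union-merges overlapping regions found for different traits on the same
#' chromosome: the consensus span runs from the minimum start to the
#' maximum end of the merged members, and the number of distinct
#' supporting traits is recorded (e.g. seven zero-maze traits supporting
#' one distal-chromosome interval).
#'
#' @param perTraitRegions list of region lists (one list per trait, as
#'   returned by \code{\link{significantIntervals}}).
#' @return list of consensus \code{\linkS4class{QtlRegion}}, with
#'   \code{support} set.
#' @export
consensusRegions <- function(perTraitRegions) {
  regs <- unlist(perTraitRegions, recursive = FALSE)
  if (!length(regs)) return(list())
  out <- list()
  for (chr in unique(vapply(regs, function(r) r@chr, character(1)))) {
    cr <- Filter(function(r) r@chr == chr, regs)
    ord <- order(vapply(cr, function(r) r@startMb, numeric(1)))
    cr <- cr[ord]
    cur <- cr[[1]]
    members <- list(cr[[1]])
    flush <- function(cur, members) {
      peaks <- vapply(members, function(r) r@peakLrs, numeric(1))
      best <- members[[which.max(peaks)]]
      cur@peakMarker <- best@peakMarker
      cur@peakMb <- best@peakMb
      cur@peakLrs <- best@peakLrs
      tids <- unique(unlist(lapply(members, function(r) r@traitIds)))
      cur@traitIds <- tids
      cur@support <- length(tids)
      cur@subRegions <- list()
      cur
    }
    if (length(cr) > 1) {
      for (i in 2:length(cr)) {
        if (cr[[i]]@startMb <= cur@endMb) {      # overlap -> extend
          cur@endMb <- max(cur@endMb, cr[[i]]@endMb)
          members[[length(members) + 1]] <- cr[[i]]
        } else {
          out[[length(out) + 1]] <- flush(cur, members)
          cur <- cr[[i]]
          members <- list(cr[[i]])
        }
      }
    }
    out[[length(out) + 1]] <- flush(cur, members)
  }
  out
}

#' Keep traits with at least one genome-wide significant marker
#'
#' @param traits list of \code{TraitTable}.
#' @param scans list of \code{QtlScan}, aligned with \code{traits}.
#' @param thresholds list of \code{GenomeWideThreshold} (or numeric),
#'   aligned.
#' @return the subset of \code{traits} whose scan exceeds its own
#'   genome-wide threshold at one or more markers (strict inequality).
#' @export
filterTraits <- function(traits, scans, thresholds) {
  stopifnot(length(traits) == length(scans),
            length(scans) == length(thresholds))
  keep <- vapply(seq_along(traits), function(i) {
    thr <- thresholds[[i]]
    if (is(thr, "GenomeWideThreshold")) thr <- thresholdLrs(thr)
    any(scanTable(scans[[i]])$lrs > thr, na.rm = TRUE)
  }, logical(1))
  traits[keep]
}
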