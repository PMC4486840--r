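.headerLines <- function(seed = NULL) {
  c(sprintf("# crossqtl %s", as.character(packageVersion("crossqtl"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
}

.readLinesNoComment <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^[#@]", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a GeneNetwork-style genotype file
#'
#' Tab-separated dialect: comment/header lines starting with '#' or '@' are
#' skipped; the column header is \code{Chr Locus cM Mb} followed by one
#' column per strain; cells are \code{B}, \code{D}, \code{H} or \code{U}.
#' \code{H} (residual heterozygous) and \code{U} (unknown) are both stored
#' as missing: the lines are expected homozygous. Any other cell value is
#' an error naming the offending line and column. Marker positions must be
#' strictly increasing within each chromosome.
#'
#' @param path file path.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @seealso \code{\link{writeGenotypes}} (lossless round trip).
#' @export
readGenotypes <- function(path) {
  got <- .readLinesNoComment(path)
  if (length(got$lines) < 2) stop("no genotype rows in ", path)
  fields <- strsplit(got$lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  if (!identical(hdr[1:4], c("Chr", "Locus", "cM", "Mb")))
    stop("expected header columns Chr, Locus, cM, Mb; found: ",
         paste(hdr[1:4], collapse = ", "))
  strains <- hdr[-(1:4)]
  body <- fields[-1]
  nm <- length(body)
  markers <- data.frame(
    id = vapply(body, `[`, character(1), 2),
    chr = vapply(body, `[`, character(1), 1),
    cm = as.numeric(vapply(body, `[`, character(1), 3)),
    mb = as.numeric(vapply(body, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
  if (any(is.na(markers$cm)) || any(is.na(markers$mb)))
    stop("malformed numeric position field in ", path)
  calls <- matrix(NA_integer_, length(strains), nm,
                  dimnames = list(strains, markers$id))
  code <- c(B = -1L, D = 1L, H = NA_integer_, U = NA_integer_)
  for (j in seq_len(nm)) {
    cells <- body[[j]][-(1:4)]
    if (length(cells) != length(strains))
      stop("line ", got$lineno[j + 1], ": expected ", length(strains),
           " genotype cells, found ", length(cells))
    bad <- !cells %in% names(code)
    if (any(bad))
      stop("line ", got$lineno[j + 1], ", column ",
           which(bad)[1] + 4, ": unknown allele code '",
           cells[bad][1], "'")
    calls[, j] <- code[cells]
  }
  new("GenotypeMatrix", calls = calls, markers = markers)
}

#' Write a GeneNetwork-style genotype file
#'
#' @param geno a \code{GenotypeMatrix}.
#' @param path output path.
#' @param seed optional seed recorded in the '#' header.
#' @export
writeGenotypes <- function(geno, path, seed = NULL) {
  stopifnot(is(geno, "GenotypeMatrix"))
  m <- markerInfo(geno)
  calls <- genoCalls(geno)
  sym <- matrix("U", nrow(calls), ncol(calls))
  sym[!is.na(calls) & calls == -1L] <- "B"
  sym[!is.na(calls) & calls == 1L] <- "D"
  rows <- vapply(seq_len(nrow(m)), function(j) {
    paste(c(m$chr[j], m$id[j], format(m$cm[j], digits = 15),
            format(m$mb[j], digits = 15), sym[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(.headerLines(seed),
               paste(c("Chr", "Locus", "cM", "Mb", rownames(calls)),
                     collapse = "\t"), rows), path)
  invisible(path)
}

#' Read / write a two-column strain trait table
#'
#' TSV with columns \code{strain}, \code{value}; '#' lines are skipped and
#' may carry a \code{trait:} and \code{info:} annotation emitted by the
#' writer.
#'
#' @param path file path.
#' @param traitId,metadata used when absent from the file header.
#' @return \code{readTraitTable}: a \code{\linkS4class{TraitTable}}.
#' @export
readTraitTable <- function(path, traitId = NULL, metadata = "") {
  all <- readLines(path)
  tid <- sub("^# trait: ", "", grep("^# trait: ", all, value = TRUE))
  meta <- sub("^# info: ", "", grep("^# info: ", all, value = TRUE))
  got <- .readLinesNoComment(path)
  fields <- strsplit(got$lines, "\t", fixed = TRUE)
  if (identical(fields[[1]][1:2], c("strain", "value")))
    fields <- fields[-1]
  vals <- as.numeric(vapply(fields, `[`, character(1), 2))
  if (any(is.na(vals))) stop("malformed numeric trait value in ", path)
  names(vals) <- vapply(fields, `[`, character(1), 1)
  new("TraitTable",
      traitId = if (length(tid)) tid else if (!is.null(traitId)) traitId
                else basename(path),
      values = vals,
      metadata = if (length(meta)) meta else metadata)
}

#' @rdname readTraitTable
#' @param trait a \code{TraitTable}.
#' @param seed optional seed recorded in the header.
#' @export
writeTraitTable <- function(trait, path, seed = NULL) {
  stopifnot(is(trait, "TraitTable"))
  writeLines(c(.headerLines(seed),
               paste0("# trait: ", traitId(trait)),
               paste0("# info: ", trait@metadata),
               "strain\tvalue",
               paste(names(traitValues(trait)),
                     format(traitValues(trait), digits = 15), sep = "\t")),
             path)
  invisible(path)
}

.gwasSynonyms <- list(
  snp = c("snpid", "snp", "rsid"),
  chr = c("chr", "hg18chr"),
  bp = c("bp", "pos"),
  p = c("pval", "p", "pvalue"))

#' Read a GWAS summary-statistics table
#'
#' Whitespace/tab-separated table with a header row. Required columns are
#' located case-insensitively among synonyms (snpid|snp|rsid, chr|hg18chr,
#' bp|pos, pval|p|pvalue); extra columns are ignored. Rows with a p-value
#' outside (0, 1] are dropped and the count reported via \code{message()}
#' and kept on the object. Duplicate SNP ids are an error.
#'
#' @param path file path.
#' @return a \code{\linkS4class{GwasSnpTable}}.
#' @export
readGwasSummary <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE)
  hdr <- tolower(names(tab))
  pick <- function(key) {
    i <- which(hdr %in% .gwasSynonyms[[key]])
    if (!length(i))
      stop("required column '", key, "' not found; file headers: ",
           paste(names(tab), collapse = ", "))
    i[1]
  }
  out <- data.frame(snp = as.character(tab[[pick("snp")]]),
                    chr = as.character(tab[[pick("chr")]]),
                    bp = as.numeric(tab[[pick("bp")]]),
                    p = as.numeric(tab[[pick("p")]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$bp)) || any(is.na(out$p)))
    stop("malformed numeric field in ", path)
  bad <- out$p <= 0 | out$p > 1
  if (any(bad)) {
    message(sum(bad), " row(s) dropped: p-value outside (0, 1]")
    out <- out[!bad, , drop = FALSE]
  }
  if (anyDuplicated(out$snp))
    stop("duplicated SNP id: ", out$snp[anyDuplicated(out$snp)])
  new("GwasSnpTable", snps = out, nDropped = sum(bad))
}

#' @rdname readGwasSummary
#' @param gwas a \code{GwasSnpTable}.
#' @param seed optional seed recorded in the header.
#' @export
writeGwasSummary <- function(gwas, path, seed = NULL) {
  stopifnot(is(gwas, "GwasSnpTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLines(seed), con)
  s <- snpTable(gwas)
  writeLines("snpid\thg18chr\tbp\tpval", con)
  writeLines(paste(s$snp, s$chr, s$bp, format(s$p, digits = 15),
                   sep = "\t"), con)
  invisible(path)
}

#' Build an LdStore from vectors of SNP pairs
#'
#' @param rs1,rs2 character SNP ids (parallel vectors).
#' @param r2 numeric r-squared values in [0, 1].
#' @return an \code{\linkS4class{LdStore}}.
#' @export
ldStore <- function(rs1 = character(0), rs2 = character(0),
                    r2 = numeric(0)) {
  stopifnot(length(rs1) == length(rs2), length(rs2) == length(r2),
            all(r2 >= 0), all(r2 <= 1))
  env <- new.env(parent = emptyenv())
  for (i in seq_along(rs1)) env[[.ldKey(rs1[i], rs2[i])]] <- r2[i]
  new("LdStore", env = env)
}

#' Read a HapMap-style pairwise LD file
#'
#' Whitespace-separated rows with columns (pos1, pos2, population, rs1,
#' rs2, D', r2, LOD, fbin); only rs1, rs2 and r2 are retained, stored
#' symmetrically. An r2 outside [0, 1] is an error reporting the line
#' number.
#'
#' @param path file path.
#' @return an \code{\linkS4class{LdStore}}.
#' @export
readHapmapLd <- function(path) {
  got <- .readLinesNoComment(path)
  env <- new.env(parent = emptyenv())
  for (i in seq_along(got$lines)) {
    f <- strsplit(trimws(got$lines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 7)
      stop("line ", got$lineno[i], ": expected >= 7 whitespace fields")
    r2 <- suppressWarnings(as.numeric(f[7]))
    if (is.na(r2) || r2 < 0 || r2 > 1)
      stop("line ", got$lineno[i], ": r2 '", f[7], "' outside [0, 1]")
    env[[.ldKey(f[4], f[5])]] <- r2
  }
  new("LdStore", env = env)
}

#' @rdname readHapmapLd
#' @param ld an \code{LdStore}.
#' @param seed optional seed recorded in the header.
#' @export
writeHapmapLd <- function(ld, path, seed = NULL) {
  stopifnot(is(ld, "LdStore"))
  keys <- sort(ls(ld@env))
  parts <- strsplit(keys, "|", fixed = TRUE)
  rows <- vapply(seq_along(keys), function(i) {
    r2 <- ld@env[[keys[i]]]
    paste(0, 0, "CEU", parts[[i]][1], parts[[i]][2],
          format(sqrt(r2), digits = 10), format(r2, digits = 10), 0, 0)
  }, character(1))
  writeLines(c(.headerLines(seed), rows), path)
  invisible(path)
}

#' Read gene annotations from BED
#'
#' BED4+ via \code{rtracklayer}: the 0-based half-open BED coordinates
#' become 1-based inclusive on the returned \code{GRanges} (this reader and
#' its writer are the only coordinate-conversion sites in the package);
#' the BED name column becomes the \code{gene_id}.
#'
#' @param path file path.
#' @param species optional label stored in the \code{species} metadata
#'   column.
#' @return \code{GRanges} with metadata columns \code{gene_id},
#'   \code{symbol} (and \code{species} when given).
#' @export
readGeneBed <- function(path, species = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (!any(nzchar(trimws(lines))))
    return(GenomicRanges::GRanges(gene_id = character(0),
                                  symbol = character(0)))
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) stop("BED file must have >= 4 columns (name)")
  if (anyDuplicated(gr$name)) stop("duplicate gene ids in ", path)
  out <- GenomicRanges::granges(gr)
  GenomicRanges::mcols(out)$gene_id <- gr$name
  GenomicRanges::mcols(out)$symbol <- gr$name
  if (!is.null(species)) GenomicRanges::mcols(out)$species <- species
  out
}

#' @rdname readGeneBed
#' @param genes \code{GRanges} with a \code{gene_id} column.
#' @export
writeGeneBed <- function(genes, path) {
  stopifnot(is(genes, "GRanges"))
  gr <- GenomicRanges::granges(genes)
  GenomicRanges::mcols(gr)$name <- GenomicRanges::mcols(genes)$gene_id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a homology-group table
#'
#' Three-column TSV: group id, taxon tag (\code{mouse} or \code{human}),
#' gene id. Groups containing exactly one mouse and one human gene become
#' map entries; all other groups (paralog expansions, single-species
#' groups) are skipped with a \code{message()}.
#'
#' @param path file path.
#' @return a \code{\linkS4class{HomologyMap}}.
#' @export
readHomology <- function(path) {
  got <- .readLinesNoComment(path)
  f <- strsplit(got$lines, "\t", fixed = TRUE)
  if (length(f) && identical(f[[1]][1], "group")) f <- f[-1]
  if (!length(f))
    return(new("HomologyMap", mouse = character(0), human = character(0)))
  tab <- data.frame(group = vapply(f, `[`, character(1), 1),
                    taxon = vapply(f, `[`, character(1), 2),
                    gene = vapply(f, `[`, character(1), 3),
                    stringsAsFactors = FALSE)
  if (!all(tab$taxon %in% c("mouse", "human")))
    stop("taxon tags must be 'mouse' or 'human'")
  mouse <- character(0); human <- character(0); skipped <- 0L
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    m <- sub$gene[sub$taxon == "mouse"]
    h <- sub$gene[sub$taxon == "human"]
    if (length(m) == 1 && length(h) == 1) {
      mouse <- c(mouse, m); human <- c(human, h)
    } else skipped <- skipped + 1L
  }
  if (skipped)
    message(skipped, " homology group(s) skipped (not one mouse + one human)")
  new("HomologyMap", mouse = mouse, human = human)
}

#' @rdname readHomology
#' @param map a \code{HomologyMap}.
#' @param seed optional seed recorded in the header.
#' @export
writeHomology <- function(map, path, seed = NULL) {
  stopifnot(is(map, "HomologyMap"))
  n <- length(map@mouse)
  grp <- sprintf("hg%05d", seq_len(n))
  writeLines(c(.headerLines(seed), "group\ttaxon\tgene",
               paste(rep(grp, each = 2),
                     rep(c("mouse", "human"), n),
                     as.vector(rbind(map@mouse, map@human)), sep = "\t")),
             path)
  invisible(path)
}

#' Read a probe expression matrix with its annotation
#'
#' The matrix file is a TSV of probes x strains (first column \code{probe},
#' then one column per strain); the annotation file is a TSV with columns
#' \code{probe}, \code{gene_id}, \code{region_type} (exon/intron). Every
#' probe in the matrix must be annotated; a missing probe is an error
#' naming it.
#'
#' @param matrixPath,annotationPath file paths.
#' @return a \code{SummarizedExperiment} with assay \code{exprs} and
#'   rowData \code{gene_id}, \code{region_type}.
#' @export
readExpression <- function(matrixPath, annotationPath) {
  m <- read.table(matrixPath, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE)
  ann <- read.table(annotationPath, header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "gene_id", "region_type") %in% names(ann)))
  probes <- as.character(m[[1]])
  missing <- setdiff(probes, ann$probe)
  if (length(missing))
    stop("probe '", missing[1], "' has no annotation")
  vals <- as.matrix(m[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("malformed numeric expression value")
  rownames(vals) <- probes
  ai <- match(probes, ann$probe)
  rd <- S4Vectors::DataFrame(gene_id = ann$gene_id[ai],
                             region_type = ann$region_type[ai],
                             row.names = probes)
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = vals),
                                             rowData = rd)
}

#' @rdname readExpression
#' @param expr a \code{SummarizedExperiment} as returned by
#'   \code{readExpression} or \code{simulateExpression}.
#' @param seed optional seed recorded in the headers.
#' @export
writeExpression <- function(expr, matrixPath, annotationPath, seed = NULL) {
  m <- SummarizedExperiment::assay(expr, "exprs")
  rd <- SummarizedExperiment::rowData(expr)
  con <- file(matrixPath, "w"); on.exit(close(con))
  writeLines(.headerLines(seed), con)
  writeLines(paste(c("probe", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m),
                   apply(format(m, digits = 15), 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  writeLines(c(.headerLines(seed), "probe\tgene_id\tregion_type",
               paste(rownames(m), rd$gene_id, rd$region_type, sep = "\t")),
             annotationPath)
  invisible(matrixPath)
}
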