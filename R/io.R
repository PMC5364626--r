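#' Read peak intervals from a BED file
#'
#' Accepts BED3 or BED6, optionally extended with a 7th column giving the
#' summit as a 0-based offset from the interval start. BED coordinates
#' (0-based half-open) are converted to the package's 1-based closed
#' `GRanges` representation on read. When no summit column is present the
#' summit defaults to the interval midpoint. Peaks are returned sorted.
#'
#' @param path BED file path.
#' @param layout `Seqinfo` from [genomeLayout()]; intervals outside its
#'   chromosomes or bounds are an error.
#' @param provenance Label stored on the returned set (defaults to the file
#'   name).
#' @return A [PeakSet-class].
#' @seealso [writePeaks()]
#' @export
readPeaks <- function(path, layout, provenance = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GRanges(seqinfo = layout)
    mcols(gr)$summit <- integer()
    mcols(gr)$score <- numeric()
    return(PeakSet(gr, provenance))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": invalid start/end")
  score <- rep(0, length(lines))
  has5 <- nf >= 5L
  if (any(has5)) {
    sc <- suppressWarnings(as.numeric(
      vapply(fields[has5], `[[`, character(1), 5L)))
    if (anyNA(sc))
      stop("malformed BED line ", which(has5)[which(is.na(sc))[1L]],
           ": non-numeric score")
    score[has5] <- sc
  }
  start1 <- as.integer(start0 + 1)
  end1 <- as.integer(end0)
  summit <- .midpointSummit(start1, end1)
  has7 <- nf >= 7L
  if (any(has7)) {
    off <- suppressWarnings(as.numeric(
      vapply(fields[has7], `[[`, character(1), 7L)))
    if (anyNA(off))
      stop("malformed BED line ", which(has7)[which(is.na(off))[1L]],
           ": non-numeric summit offset")
    summit[has7] <- start1[has7] + as.integer(off)
    bad <- which(summit < start1 | summit > end1)
    if (length(bad))
      stop("malformed BED line ", bad[1L], ": summit offset outside interval")
  }
  sl <- seqlengths(layout)
  unknown <- !(chrom %in% names(sl))
  if (any(unknown))
    stop("BED line ", which(unknown)[1L], ": chromosome '",
         chrom[which(unknown)[1L]], "' not in layout")
  over <- end1 > sl[chrom]
  if (any(over))
    stop("BED line ", which(over)[1L], ": interval exceeds chromosome length")
  gr <- GRanges(chrom, IRanges(start1, end1), seqinfo = layout,
                summit = summit, score = score)
  PeakSet(gr, provenance)
}

#' Write a PeakSet as BED6 + summit-offset column
#'
#' Emits 0-based half-open BED with name, score, strand (`.`) and a 7th
#' column holding the summit offset from the interval start. Reading the
#' file back with [readPeaks()] reproduces the set exactly.
#'
#' @param x A `PeakSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(x, path) {
  gr <- peakRanges(x)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = sprintf("peak_%d", seq_along(gr)),
                   score = peakScores(x), strand = ".",
                   summit = summits(x) - start(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF-style annotation
#'
#' Expects `gene` and `exon` features with `gene_id` and `gene_class`
#' attributes (1-based inclusive coordinates, the GTF convention). Genes
#' without a definite strand, or with a class outside the supported set
#' (protein_coding, snRNA, snoRNA, lincRNA, miRNA), are rejected; rejection
#' reasons are recorded in `metadata(geneRanges(result))$rejections`.
#'
#' @param path GTF file path.
#' @param layout `Seqinfo` from [genomeLayout()].
#' @return A [GeneCatalog-class].
#' @seealso [writeGenes()]
#' @export
readGenes <- function(path, layout) {
  nonempty <- length(grep("^[^#]", readLines(path))) > 0
  if (!nonempty) {
    g <- GRanges(seqinfo = layout)
    mcols(g)$gene_id <- character()
    mcols(g)$gene_class <- character()
    return(GeneCatalog(g))
  }
  gtf <- rtracklayer::import(path, format = "gtf")
  genes <- gtf[gtf$type == "gene"]
  exons <- gtf[gtf$type == "exon"]
  rejections <- data.frame(gene_id = character(), reason = character())
  noStrand <- as.character(strand(genes)) == "*"
  if (any(noStrand)) {
    rejections <- rbind(rejections, data.frame(
      gene_id = genes$gene_id[noStrand], reason = "missing strand"))
    genes <- genes[!noStrand]
  }
  badClass <- is.na(genes$gene_class) | !(genes$gene_class %in% .GENE_CLASSES)
  if (any(badClass)) {
    rejections <- rbind(rejections, data.frame(
      gene_id = genes$gene_id[badClass], reason = "unknown gene class"))
    genes <- genes[!badClass]
  }
  g <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
               strand = strand(genes), seqinfo = layout,
               gene_id = genes$gene_id, gene_class = genes$gene_class)
  .checkLayout(g, layout, "genes")
  exons <- exons[exons$gene_id %in% g$gene_id]
  exl <- methods::as(
    S4Vectors::split(
      GRanges(seqnames(exons), IRanges(start(exons), end(exons)),
              strand = strand(exons), seqinfo = layout),
      factor(exons$gene_id, levels = g$gene_id)),
    "GRangesList")
  exl <- methods::as(lapply(exl, GenomicRanges::sort), "GRangesList")
  empty <- lengths(exl) == 0L
  if (any(empty))  # genes without exon records span a single exon
    exl[empty] <- methods::as(granges(g[empty]), "GRangesList")
  metadata(g)$rejections <- rejections
  GeneCatalog(g, exl)
}

#' Write a GeneCatalog as GTF-style annotation
#'
#' @param x A `GeneCatalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGenes <- function(x, path) {
  g <- geneRanges(x)
  ex <- exonsByGene(x)
  attr1 <- sprintf('gene_id "%s"; gene_class "%s";', g$gene_id, g$gene_class)
  geneLines <- sprintf("%s\tchipRegulome\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       as.character(seqnames(g)), start(g), end(g),
                       as.character(strand(g)), attr1)
  exFlat <- unlist(ex, use.names = FALSE)
  exGene <- rep(seq_along(g), lengths(ex))
  exonLines <- sprintf("%s\tchipRegulome\texon\t%d\t%d\t.\t%s\t.\t%s",
                       as.character(seqnames(g))[exGene],
                       start(exFlat), end(exFlat),
                       as.character(strand(g))[exGene], attr1[exGene])
  ## interleave so each gene is followed by its exons
  ord <- order(c(seq_along(g), exGene + 0.5))
  writeLines(c(geneLines, exonLines)[ord], path)
  invisible(path)
}

#' Read / write a binned SignalTrack as fixed-step bedGraph
#'
#' The dialect is a strict bin grid: every line covers exactly one bin of
#' the declared width (the final bin of a chromosome may be truncated by the
#' chromosome end), 0-based half-open, in genomic order with no gaps.
#'
#' @param path bedGraph file path.
#' @param layout `Seqinfo` from [genomeLayout()].
#' @param binWidth Bin width in bp.
#' @return `readSignalTrack()`: a [SignalTrack-class]; `writeSignalTrack()`:
#'   `path`, invisibly.
#' @export
readSignalTrack <- function(path, layout, binWidth) {
  df <- utils::read.table(path, sep = "\t", col.names =
    c("chrom", "start", "end", "value"),
    colClasses = c("character", "numeric", "numeric", "numeric"))
  sl <- seqlengths(layout)
  values <- lapply(names(sl), function(ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    n <- ceiling(sl[[ch]] / binWidth)
    if (nrow(d) != n)
      stop("chromosome ", ch, ": expected ", n, " bins, found ", nrow(d))
    idx <- d$start / binWidth + 1
    if (any(idx != seq_len(n)))
      stop("chromosome ", ch, ": bins are off the fixed-step grid")
    d$value
  })
  names(values) <- names(sl)
  SignalTrack(values, binWidth, layout)
}

#' @rdname readSignalTrack
#' @param x A `SignalTrack`.
#' @export
writeSignalTrack <- function(x, path) {
  sl <- seqlengths(seqinfo(x))
  w <- binWidth(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(trackValues(x))) {
    v <- trackValues(x)[[ch]]
    s <- (seq_along(v) - 1L) * w
    e <- pmin(s + w, sl[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, s, e, v), con)
  }
  invisible(path)
}

#' Read / write chromosome sizes as two-column TSV
#'
#' @param path TSV path with columns (chromosome, length).
#' @return `readChromSizes()`: a `Seqinfo`; `writeChromSizes()`: `path`,
#'   invisibly.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genomeLayout(df$chrom, df$length)
}

#' @rdname readChromSizes
#' @param layout A `Seqinfo`.
#' @export
writeChromSizes <- function(layout, path) {
  sl <- seqlengths(layout)
  utils::write.table(data.frame(names(sl), unname(sl)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
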