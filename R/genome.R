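#' Describe a genome as named chromosome lengths
#'
#' Builds the `Seqinfo` object used throughout the package to pin every
#' interval, gene and track to a common coordinate system. Chromosome names
#' must be unique and lengths strictly positive.
#'
#' @param chromosomes Character vector of chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' layout <- genomeLayout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genomeLayout <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (length(lengths) != length(chromosomes))
    stop("'chromosomes' and 'lengths' must have equal length")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("chromosome lengths must be strictly positive")
  Seqinfo(seqnames = chromosomes, seqlengths = as.integer(lengths))
}

.sameLayout <- function(a, b) {
  identical(seqlengths(a), seqlengths(b))
}

## expand both sides by w and clip to chromosome bounds, quietly
.expandTrim <- function(gr, w) {
  suppressWarnings(trim(gr + w))
}

.checkLayout <- function(gr, layout, what = "intervals") {
  sl <- seqlengths(layout)
  sn <- as.character(seqnames(gr))
  bad <- !(sn %in% names(sl))
  if (any(bad))
    stop(what, " on chromosomes absent from the layout: ",
         paste(unique(sn[bad]), collapse = ", "))
  over <- end(gr) > sl[sn] | start(gr) < 1L
  if (any(over))
    stop(what, " exceeding chromosome bounds (first offender: entry ",
         which(over)[1L], ")")
  invisible(TRUE)
}

## ---- PeakSet ---------------------------------------------------------------

#' Construct a PeakSet
#'
#' Sorts the supplied ranges by (chromosome, start, end) -- ties ordered by
#' score descending then input order, for reproducibility -- and validates
#' the result. Missing summits default to the interval midpoint
#' (`floor((start - 1 + end) / 2) + 1`, the centre base); missing scores
#' default to 0.
#'
#' @param ranges A `GRanges`, optionally with `summit` (absolute position)
#'   and `score` metadata columns, carrying complete sequence lengths.
#' @param provenance Single character label (e.g. a donor id).
#' @return A [PeakSet-class].
#' @examples
#' layout <- genomeLayout("chr1", 1000L)
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 51), c(20, 60)),
#'                              seqinfo = layout)
#' ps <- PeakSet(gr, provenance = "demo")
#' summits(ps)  # midpoints 16 and 56
#' @export
PeakSet <- function(ranges, provenance = "unspecified") {
  if (is.null(mcols(ranges)$summit))
    mcols(ranges)$summit <- .midpointSummit(start(ranges), end(ranges))
  if (is.null(mcols(ranges)$score))
    mcols(ranges)$score <- 0
  mcols(ranges)$summit <- as.integer(mcols(ranges)$summit)
  mcols(ranges)$score <- as.numeric(mcols(ranges)$score)
  o <- order(as.integer(seqnames(ranges)), start(ranges), end(ranges),
             -mcols(ranges)$score, seq_along(ranges))
  new("PeakSet", ranges = ranges[o], provenance = as.character(provenance))
}

## centre base of a 1-based closed interval; equals the floor midpoint of the
## equivalent 0-based half-open interval, shifted back to 1-based
.midpointSummit <- function(start, end) {
  as.integer(floor((start - 1 + end) / 2) + 1)
}

#' @rdname PeakSet-class
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@ranges)

#' @rdname PeakSet-class
#' @export
setMethod("summits", "PeakSet", function(x) mcols(x@ranges)$summit)

#' @rdname PeakSet-class
#' @export
setMethod("peakScores", "PeakSet", function(x) mcols(x@ranges)$score)

#' @rdname PeakSet-class
#' @export
setMethod("provenance", "PeakSet", function(x) x@provenance)

#' @rdname PeakSet-class
#' @export
setMethod("length", "PeakSet", function(x) length(x@ranges))

#' @rdname PeakSet-class
#' @param i Index.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "PeakSet", function(x, i, j, ..., drop = TRUE) {
  PeakSet(x@ranges[i], x@provenance)  # constructor restores sort order
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet with", length(object), "peaks (provenance:",
      object@provenance, ")\n")
  if (length(object)) {
    tab <- table(seqnames(object@ranges))
    cat("  per chromosome:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

#' Summit positions as width-1 GRanges
#'
#' @param x A `PeakSet`.
#' @return A `GRanges` of width-1 summit positions, parallel to the peaks.
#' @export
summitRanges <- function(x) {
  gr <- peakRanges(x)
  GRanges(seqnames(gr), IRanges(summits(x), width = 1L),
          seqinfo = seqinfo(gr))
}

## ---- GeneCatalog -----------------------------------------------------------

#' Construct a GeneCatalog
#'
#' @param genes Stranded `GRanges` with `gene_id` and `gene_class` metadata
#'   columns and complete sequence lengths.
#' @param exons Optional `GRangesList` parallel to `genes` (named by gene
#'   id). Defaults to one exon spanning each gene body.
#' @return A [GeneCatalog-class].
#' @export
GeneCatalog <- function(genes, exons = NULL) {
  if (is.null(exons)) {
    exons <- methods::as(granges(genes), "GRangesList")
    names(exons) <- mcols(genes)$gene_id
  }
  new("GeneCatalog", genes = genes, exons = exons)
}

#' @rdname GeneCatalog-class
#' @export
setMethod("geneRanges", "GeneCatalog", function(x) x@genes)

#' @rdname GeneCatalog-class
#' @export
setMethod("geneIds", "GeneCatalog", function(x) mcols(x@genes)$gene_id)

#' @rdname GeneCatalog-class
#' @export
setMethod("geneClasses", "GeneCatalog", function(x) mcols(x@genes)$gene_class)

#' @rdname GeneCatalog-class
#' @export
setMethod("exonsByGene", "GeneCatalog", function(x) x@exons)

#' @rdname GeneCatalog-class
#' @export
setMethod("length", "GeneCatalog", function(x) length(x@genes))

#' @rdname GeneCatalog-class
#' @param i Index.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "GeneCatalog", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, geneIds(x))
  new("GeneCatalog", genes = x@genes[i], exons = x@exons[i])
})

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog with", length(object), "genes\n")
  if (length(object)) {
    tab <- table(geneClasses(object))
    cat("  classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

## ---- SignalTrack -----------------------------------------------------------

#' Construct a SignalTrack
#'
#' @param values Named list of per-chromosome numeric bin vectors.
#' @param binWidth Bin width in bp.
#' @param layout A `Seqinfo` from [genomeLayout()].
#' @return A [SignalTrack-class].
#' @export
SignalTrack <- function(values, binWidth, layout) {
  new("SignalTrack", binWidth = as.integer(binWidth),
      values = lapply(values, as.numeric), seqinfo = layout)
}

#' @rdname SignalTrack-class
#' @export
setMethod("binWidth", "SignalTrack", function(x) x@binWidth)

#' @rdname SignalTrack-class
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname SignalTrack-class
#' @export
setMethod("seqinfo", "SignalTrack", function(x) x@seqinfo)

setMethod("show", "SignalTrack", function(object) {
  n <- sum(lengths(object@values))
  cat("SignalTrack:", length(object@values), "chromosomes,", n,
      "bins of", object@binWidth, "bp\n")
})

## ---- TSS / TES anchors -----------------------------------------------------

#' Strand-aware TSS and TES anchors
#'
#' The transcription start site of a plus-strand gene is its leftmost base;
#' for a minus-strand gene it is the rightmost (last covered) base. The
#' transcription end site is the opposite end. A single-base gene has
#' TSS = TES on either strand. Unstranded genes are rejected.
#'
#' @param x A `GeneCatalog`, or a stranded `GRanges`.
#' @return `tssSites()`/`tesSites()`: named integer vector of positions
#'   (names are gene ids when available). `tssRanges()`: width-1 `GRanges`
#'   at the TSS positions.
#' @examples
#' layout <- genomeLayout("chr1", 1000L)
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 500),
#'                             strand = "-", seqinfo = layout)
#' tssSites(g)  # 500: last covered base of a minus-strand gene
#' @export
tssSites <- function(x) {
  gr <- if (methods::is(x, "GeneCatalog")) geneRanges(x) else x
  st <- as.character(strand(gr))
  if (any(st == "*")) stop("unstranded gene: TSS is undefined")
  pos <- ifelse(st == "+", start(gr), end(gr))
  names(pos) <- if (!is.null(mcols(gr)$gene_id)) mcols(gr)$gene_id
  pos
}

#' @rdname tssSites
#' @export
tesSites <- function(x) {
  gr <- if (methods::is(x, "GeneCatalog")) geneRanges(x) else x
  st <- as.character(strand(gr))
  if (any(st == "*")) stop("unstranded gene: TES is undefined")
  pos <- ifelse(st == "+", end(gr), start(gr))
  names(pos) <- if (!is.null(mcols(gr)$gene_id)) mcols(gr)$gene_id
  pos
}

#' @rdname tssSites
#' @export
tssRanges <- function(x) {
  gr <- if (methods::is(x, "GeneCatalog")) geneRanges(x) else x
  GRanges(seqnames(gr), IRanges(unname(tssSites(gr)), width = 1L),
          seqinfo = seqinfo(gr))
}

## ---- gapped overlap --------------------------------------------------------

#' Which query peaks overlap a feature set, allowing a gap
#'
#' Tests, for every query peak, whether it overlaps (by at least one base)
#' any subject feature after expanding each feature by `gap` bp on both
#' sides. Both inputs must live on the same genome layout.
#'
#' @param query A `PeakSet` or `GRanges`.
#' @param subject A `GRanges` (or `PeakSet`) of features.
#' @param gap Nonnegative expansion in bp applied to the subject.
#' @return Logical vector, one entry per query interval.
#' @examples
#' layout <- genomeLayout("chr1", 1000L)
#' q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20), seqinfo = layout)
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(21, 30), seqinfo = layout)
#' overlapsAnyGapped(q, s, gap = 0)  # FALSE: adjacent, not overlapping
#' overlapsAnyGapped(q, s, gap = 5)  # TRUE
#' @export
overlapsAnyGapped <- function(query, subject, gap = 0L) {
  if (gap < 0) stop("'gap' must be nonnegative")
  qgr <- if (methods::is(query, "PeakSet")) peakRanges(query) else query
  sgr <- if (methods::is(subject, "PeakSet")) peakRanges(subject) else subject
  if (!.sameLayout(seqinfo(qgr), seqinfo(sgr)))
    stop("query and subject are on different genome layouts")
  if (gap > 0) sgr <- .expandTrim(sgr, gap)
  IRanges::overlapsAny(qgr, sgr, ignore.strand = TRUE)
}
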