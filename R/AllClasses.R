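#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end width
#'   strand findOverlaps countOverlaps reduce resize trim shift sort
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqinfo<- seqlengths seqlevels
#'   seqnames genome
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom GenomeInfoDb Seqinfo
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' Scored, summit-bearing peak intervals
#'
#' A `PeakSet` holds ChIP-seq (or comparable) peak calls as a sorted
#' [GenomicRanges::GRanges] whose metadata columns carry the absolute summit
#' position (`summit`, 1-based, always inside the peak) and a nonnegative
#' `score`. Peaks are kept sorted by (chromosome, start, end) with no
#' duplicated (chromosome, start, end) triples; a `provenance` label records
#' where the calls came from (for example a donor identifier).
#'
#' @slot ranges A `GRanges` with `summit` (integer) and `score` (numeric)
#'   metadata columns, sorted, duplicate-free, with a complete `Seqinfo`.
#' @slot provenance Single character label.
#'
#' @seealso [PeakSet()], [readPeaks()], [genPeaks()]
#' @export
setClass("PeakSet",
  slots = c(ranges = "GRanges", provenance = "character"))

setValidity("PeakSet", function(object) {
  gr <- object@ranges
  msg <- character()
  if (length(object@provenance) != 1L)
    msg <- c(msg, "'provenance' must be a single string")
  if (!all(c("summit", "score") %in% names(mcols(gr))))
    msg <- c(msg, "ranges must carry 'summit' and 'score' metadata columns")
  if (any(is.na(seqlengths(seqinfo(gr)))))
    msg <- c(msg, "all chromosome lengths must be known")
  if (length(gr)) {
    if (is.unsorted(order(as.integer(seqnames(gr)), start(gr), end(gr))))
      msg <- c(msg, "peaks must be sorted by (chromosome, start, end)")
    key <- paste(seqnames(gr), start(gr), end(gr))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chromosome, start, end) peaks are not allowed")
    s <- mcols(gr)$summit
    if (any(s < start(gr) | s > end(gr)))
      msg <- c(msg, "every summit must lie inside its peak")
    if (any(mcols(gr)$score < 0))
      msg <- c(msg, "scores must be nonnegative")
    if (any(end(gr) > seqlengths(gr)[as.character(seqnames(gr))]) ||
        any(start(gr) < 1L))
      msg <- c(msg, "peaks must lie within chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Strand-aware gene models with exon structure and gene classes
#'
#' A `GeneCatalog` stores gene bodies as a stranded `GRanges` (metadata
#' columns `gene_id`, `gene_class`) together with per-gene exons as a
#' `GRangesList` named by gene id. Gene classes are restricted to the five
#' biotypes profiled in the metagene analyses: protein_coding, snRNA,
#' snoRNA, lincRNA and miRNA. Every gene must have a definite strand, which
#' anchors its transcription start (TSS) and end (TES) sites.
#'
#' @slot genes Stranded `GRanges`; mcols `gene_id` (unique) and `gene_class`.
#' @slot exons `GRangesList` parallel to `genes`, exons ordered and
#'   non-overlapping within each gene's bounds.
#'
#' @seealso [GeneCatalog()], [readGenes()], [genGenome()], [tssSites()]
#' @export
setClass("GeneCatalog",
  slots = c(genes = "GRanges", exons = "GRangesList"))

.GENE_CLASSES <- c("protein_coding", "snRNA", "snoRNA", "lincRNA", "miRNA")

setValidity("GeneCatalog", function(object) {
  g <- object@genes
  msg <- character()
  if (!all(c("gene_id", "gene_class") %in% names(mcols(g))))
    msg <- c(msg, "genes must carry 'gene_id' and 'gene_class'")
  else {
    if (anyDuplicated(mcols(g)$gene_id))
      msg <- c(msg, "gene ids must be unique")
    if (!all(mcols(g)$gene_class %in% .GENE_CLASSES))
      msg <- c(msg, paste("gene_class must be one of:",
                          paste(.GENE_CLASSES, collapse = ", ")))
    if (length(object@exons) != length(g))
      msg <- c(msg, "exons list must be parallel to genes")
  }
  if (length(g) && any(strand(g) == "*"))
    msg <- c(msg, "every gene must be stranded (+ or -)")
  if (length(g) && length(object@exons) == length(g)) {
    ex <- object@exons
    within <- all(unlist(start(ex)) >= rep(start(g), lengths(ex))) &&
      all(unlist(end(ex)) <= rep(end(g), lengths(ex)))
    if (!within)
      msg <- c(msg, "exons must lie within their gene's interval")
  }
  if (length(msg)) msg else TRUE
})

#' Binned numeric signal over a genome
#'
#' A `SignalTrack` is fixed-width binned coverage (ChIP signal, DNase
#' accessibility, conservation scores, ...) stored as one numeric vector per
#' chromosome. Bin `i` of a chromosome covers bases
#' `[(i-1)*binWidth + 1, i*binWidth]`; the last bin may be truncated by the
#' chromosome end but still stores a single value. All values are finite.
#'
#' @slot binWidth Positive integer bin width in bp.
#' @slot values Named list of numeric vectors, one per chromosome, of length
#'   `ceiling(chromosome length / binWidth)`.
#' @slot seqinfo `Seqinfo` describing the genome the track lives on.
#'
#' @seealso [SignalTrack()], [genSignalPair()], [profileAroundSummits()]
#' @export
setClass("SignalTrack",
  slots = c(binWidth = "integer", values = "list", seqinfo = "Seqinfo"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@binWidth) != 1L || object@binWidth < 1L)
    msg <- c(msg, "binWidth must be a single positive integer")
  sl <- seqlengths(object@seqinfo)
  if (!identical(sort(names(object@values)), sort(names(sl))))
    msg <- c(msg, "values must have one vector per chromosome in seqinfo")
  else {
    expected <- ceiling(sl[names(object@values)] / as.numeric(object@binWidth))
    if (!all(lengths(object@values) == expected))
      msg <- c(msg, "each vector must have ceiling(chrom length / binWidth) bins")
    if (!all(vapply(object@values, function(v) all(is.finite(v)), logical(1))))
      msg <- c(msg, "all bin values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Consensus shortlist of knockdown-responsive genes
#'
#' Result of [consensusShortlist()] in gene mode. The `reproducible` set
#' holds genes significant (q < alpha) with a consistent direction in both
#' independent knockdown comparisons and not significant in the
#' transfection-control comparison; the `rescued` set holds genes
#' significant in all three comparisons whose shared knockdown direction is
#' opposite to the control-comparison direction (deregulation masked by a
#' transfection artifact acting the other way). The two sets are disjoint
#' and their union is the shortlisted core regulome.
#'
#' @slot reproducible Character vector of gene ids.
#' @slot rescued Character vector of gene ids.
#' @slot direction Named character ("up"/"down"), the shared knockdown
#'   direction for every shortlisted gene.
#' @slot signDisagreements Number of genes dropped because the two knockdown
#'   comparisons disagreed on direction.
#' @slot alpha FDR threshold used.
#'
#' @seealso [consensusShortlist()], [regulomeTotal()]
#' @export
setClass("CoreRegulomeResult",
  slots = c(reproducible = "character", rescued = "character",
            direction = "character", signDisagreements = "integer",
            alpha = "numeric"))

setValidity("CoreRegulomeResult", function(object) {
  msg <- character()
  if (length(intersect(object@reproducible, object@rescued)))
    msg <- c(msg, "reproducible and rescued sets must be disjoint")
  members <- c(object@reproducible, object@rescued)
  if (!all(members %in% names(object@direction)))
    msg <- c(msg, "every shortlisted gene needs a direction")
  if (!all(object@direction %in% c("up", "down")))
    msg <- c(msg, "directions must be 'up' or 'down'")
  if (length(msg)) msg else TRUE
})

#' Per-chromosome randomization overlap test result
#'
#' Result of [randomizedOverlapTest()]: the observed fraction of query
#' peaks overlapping a feature set, the permutation-null mean and standard
#' deviation obtained by re-placing every query interval uniformly at random
#' within its own chromosome (lengths and per-chromosome counts preserved),
#' the Z-score of the observed fraction against that null, and an
#' add-one-corrected empirical p-value.
#'
#' @slot observed Observed overlap fraction in [0, 1].
#' @slot permMean,permSd Permutation-null mean and sd of the fraction.
#' @slot zScore `(observed - permMean) / permSd`; `NA` when `permSd == 0`.
#' @slot pValue Empirical p, `(1 + #(perm >= observed)) / (1 + n)`.
#' @slot nPermutations Number of permutations.
#' @slot seed Seed used for the permutation stream.
#'
#' @seealso [randomizedOverlapTest()]
#' @export
setClass("OverlapTestResult",
  slots = c(observed = "numeric", permMean = "numeric", permSd = "numeric",
            zScore = "numeric", pValue = "numeric",
            nPermutations = "integer", seed = "integer"))

setValidity("OverlapTestResult", function(object) {
  msg <- character()
  if (object@observed < 0 || object@observed > 1)
    msg <- c(msg, "observed fraction must be in [0, 1]")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "empirical p must be in (0, 1]")
  if (!is.na(object@zScore) && object@permSd > 0) {
    z <- (object@observed - object@permMean) / object@permSd
    if (abs(z - object@zScore) > 1e-8)
      msg <- c(msg, "zScore inconsistent with observed/permMean/permSd")
  }
  if (length(msg)) msg else TRUE
})
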