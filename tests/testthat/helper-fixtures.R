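## Small hand-built fixtures shared across test files. All coordinates are
## 1-based closed (the package's GRanges convention); the BED fixtures below
## are written 0-based half-open as the format requires.

tinyLayout <- function() genomeLayout(c("chrA", "chrB"), c(100000L, 50000L))

## two-gene catalog: plus-strand gene with two exons, minus-strand single-exon
tinyGenes <- function(layout = tinyLayout()) {
  g <- GenomicRanges::GRanges(
    c("chrA", "chrA"),
    IRanges::IRanges(c(10001, 40001), c(20000, 45000)),
    strand = c("+", "-"), seqinfo = layout,
    gene_id = c("gPlus", "gMinus"),
    gene_class = c("protein_coding", "protein_coding"))
  ex <- methods::as(list(
    GenomicRanges::GRanges("chrA", IRanges::IRanges(c(10001, 15001),
                                                    c(12000, 20000)),
                           strand = "+", seqinfo = layout),
    GenomicRanges::GRanges("chrA", IRanges::IRanges(40001, 45000),
                           strand = "-", seqinfo = layout)),
    "GRangesList")
  names(ex) <- c("gPlus", "gMinus")
  GeneCatalog(g, ex)
}

peaksAt <- function(summits, chrom = "chrA", halfWidth = 50L,
                    layout = tinyLayout(), score = NULL) {
  sl <- GenomeInfoDb::seqlengths(layout)
  s <- pmax(1L, as.integer(summits) - halfWidth)
  e <- pmin(sl[chrom], as.integer(summits) + halfWidth)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                               seqinfo = layout,
                               summit = as.integer(summits))
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  PeakSet(gr, provenance = "fixture")
}

flatTrack <- function(value, binWidth = 100L, layout = tinyLayout()) {
  sl <- GenomeInfoDb::seqlengths(layout)
  vals <- lapply(sl, function(L) rep(value, ceiling(L / binWidth)))
  SignalTrack(vals, binWidth, layout)
}

## naive O(n*m) pairwise overlap oracle with gap expansion (closed intervals)
naiveOverlapAny <- function(qs, qe, qc, ss, se, sc, gap = 0) {
  vapply(seq_along(qs), function(i) {
    any(sc == qc[i] & (ss - gap) <= qe[i] & (se + gap) >= qs[i])
  }, logical(1))
}

## naive O(n^2) Benjamini-Hochberg step-up oracle
naiveBH <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    o <- order(p)
    r <- which(o == i)  # rank of p[i]
    min(vapply(r:n, function(j) p[o[j]] * n / j, numeric(1)), 1)
  }, numeric(1))
}
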