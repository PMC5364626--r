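#' Configuration for summit-based feature annotation
#'
#' @param promoterWindow Half-window around the TSS defining the promoter
#'   category, in bp (default 3000).
#' @param proximalWindow Half-window defining TSS-proximal promoter
#'   binding, in bp (default 1000); must not exceed `promoterWindow`.
#' @param downstreamWindow Extent past the TES of the downstream category,
#'   in bp (default 3000).
#' @param precedence Category order used when a summit falls in several
#'   feature types; must be a permutation of
#'   `promoter, exon, intron, downstream, intergenic`.
#' @return A validated list of class `AnnotationConfig`.
#' @export
annotationConfig <- function(promoterWindow = 3000L, proximalWindow = 1000L,
                             downstreamWindow = 3000L,
                             precedence = c("promoter", "exon", "intron",
                                            "downstream", "intergenic")) {
  if (proximalWindow > promoterWindow)
    stop("proximalWindow must not exceed promoterWindow")
  if (!setequal(precedence, c("promoter", "exon", "intron", "downstream",
                              "intergenic")) || length(precedence) != 5L)
    stop("precedence must cover the five categories exactly once")
  structure(list(promoterWindow = as.integer(promoterWindow),
                 proximalWindow = as.integer(proximalWindow),
                 downstreamWindow = as.integer(downstreamWindow),
                 precedence = precedence),
            class = "AnnotationConfig")
}

#' Assign peaks to fixed genomic features by summit position
#'
#' Each peak is assigned, by its summit (a single point, so categories form
#' a partition of the peak set), the highest-precedence category whose
#' footprint contains it: promoter (TSS +/- `promoterWindow`), exon,
#' intron (gene body minus exons), downstream (up to `downstreamWindow` bp
#' past the TES, strand-aware), or intergenic. Also reports the fraction of
#' promoter-category summits lying within `proximalWindow` of the nearest
#' TSS.
#'
#' @param peaks A [PeakSet-class].
#' @param genes A [GeneCatalog-class].
#' @param config An [annotationConfig()].
#' @return List of class `AnnotationSummary`: `category` (factor per peak),
#'   `counts`, `percentages` (of total peaks, summing to 100),
#'   `promoterProximalFraction`.
#' @export
assignFeatures <- function(peaks, genes, config = annotationConfig()) {
  su <- summitRanges(peaks)
  g <- geneRanges(genes)
  tss <- tssRanges(genes)
  layoutOk <- .sameLayout(seqinfo(su), seqinfo(g))
  if (!layoutOk) stop("peaks and genes are on different genome layouts")
  exons <- unlist(exonsByGene(genes), use.names = FALSE)
  tes <- tesSites(genes)
  plus <- as.character(strand(g)) == "+"
  dnStart <- ifelse(plus, tes + 1L, pmax(1L, tes - config$downstreamWindow))
  dnEnd <- ifelse(plus, tes + config$downstreamWindow, tes - 1L)
  valid <- dnEnd >= dnStart
  downstream <- suppressWarnings(trim(GRanges(
    seqnames(g)[valid], IRanges(dnStart[valid], dnEnd[valid]),
    seqinfo = seqinfo(g))))
  footprints <- list(
    promoter = .expandTrim(tss, config$promoterWindow),
    exon = exons,
    intron = granges(g),  # gene body; exons win only via precedence
    downstream = downstream)
  ## intron must mean "in gene body but not exon": enforce regardless of the
  ## configured order by masking exon hits out of the intron footprint test
  inExon <- IRanges::overlapsAny(su, exons, ignore.strand = TRUE)
  cat_ <- rep(NA_character_, length(su))
  for (cg in config$precedence) {
    if (cg == "intergenic") next
    hit <- if (cg == "intron")
      IRanges::overlapsAny(su, footprints$intron, ignore.strand = TRUE) & !inExon
    else IRanges::overlapsAny(su, footprints[[cg]], ignore.strand = TRUE)
    cat_[is.na(cat_) & hit] <- cg
  }
  cat_[is.na(cat_)] <- "intergenic"
  category <- factor(cat_, levels = c("promoter", "exon", "intron",
                                      "downstream", "intergenic"))
  counts <- table(category)
  prox <- NA_real_
  promIdx <- which(cat_ == "promoter")
  if (length(promIdx)) {
    d <- GenomicRanges::distanceToNearest(su[promIdx], tss)
    prox <- mean(S4Vectors::mcols(d)$distance <= config$proximalWindow)
  }
  structure(list(category = category, counts = c(counts),
                 percentages = 100 * c(counts) / length(su),
                 promoterProximalFraction = prox, config = config),
            class = "AnnotationSummary")
}

#' Write an annotation summary as TSV and JSON
#'
#' @param x An `AnnotationSummary` from [assignFeatures()].
#' @param tsvPath,jsonPath Output paths (`NULL` to skip).
#' @return Invisibly, the summary as a list.
#' @export
writeAnnotationSummary <- function(x, tsvPath = NULL, jsonPath = NULL) {
  df <- data.frame(category = names(x$counts), count = unname(x$counts),
                   percentage = unname(x$percentages))
  if (!is.null(tsvPath))
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out <- list(counts = as.list(x$counts),
              percentages = as.list(x$percentages),
              promoter_proximal_fraction = x$promoterProximalFraction)
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Metagene profile over scaled gene bodies with fixed-bp flanks
#'
#' Aggregates peak-summit density (for a `PeakSet`) or mean signal (for a
#' `SignalTrack`) over a metagene coordinate system: `flankBins` bins of
#' fixed `flankBp`/`flankBins` width upstream of the TSS, `bodyBins` bins
#' over the length-scaled gene body, and `flankBins` bins downstream of the
#' TES. Minus-strand genes are reversed so bin 1 is always the 5' flank.
#' Summit densities are per-bp within each gene before averaging, so
#' genome-uniform peaks give a flat profile. Genes shorter than `bodyBins`
#' bp are skipped (their count is reported).
#'
#' @param x A [PeakSet-class] or [SignalTrack-class].
#' @param genes A [GeneCatalog-class] subset to aggregate over.
#' @param bodyBins Number of gene-body bins (default 60).
#' @param flankBp Flank extent in bp (default 2000).
#' @param flankBins Number of bins per flank (default 20).
#' @return List of class `MetageneProfile`: `values` (per-bin mean),
#'   `bin` (index), `region` (factor: upstream/body/downstream),
#'   `nGenes`, `nSkipped`.
#' @export
metageneProfile <- function(x, genes, bodyBins = 60L, flankBp = 2000L,
                            flankBins = 20L) {
  if (!length(genes)) stop("'genes' must be nonempty")
  g <- geneRanges(genes)
  L <- width(g)
  skip <- L < bodyBins
  nSkipped <- sum(skip)
  g <- g[!skip]
  if (!length(g)) stop("all genes shorter than the bin count")
  nbTotal <- bodyBins + 2L * flankBins
  flankBinBp <- flankBp / flankBins
  plus <- as.character(strand(g)) == "+"
  acc <- matrix(0, nrow = length(g), ncol = nbTotal)
  if (methods::is(x, "PeakSet")) {
    su <- summitRanges(x)
    hits <- findOverlaps(.expandTrim(granges(g), flankBp), su, ignore.strand = TRUE)
    gi <- S4Vectors::queryHits(hits)
    pos <- start(su)[S4Vectors::subjectHits(hits)]
    d5 <- ifelse(plus[gi], pos - start(g)[gi], end(g)[gi] - pos)
    Lg <- width(g)[gi]
    bin <- integer(length(gi))
    inUp <- d5 < 0
    inBody <- d5 >= 0 & d5 < Lg
    inDn <- d5 >= Lg
    bin[inUp] <- flankBins + 1L + floor(d5[inUp] / flankBinBp)  # d5 in [-flankBp,0)
    bin[inBody] <- flankBins + 1L + floor(d5[inBody] / Lg[inBody] * bodyBins)
    bin[inDn] <- flankBins + bodyBins + 1L + floor((d5[inDn] - Lg[inDn]) / flankBinBp)
    ok <- bin >= 1L & bin <= nbTotal
    ## per-gene per-bin counts converted to per-bp densities
    binBp <- ifelse(bin <= flankBins | bin > flankBins + bodyBins,
                    flankBinBp, Lg / bodyBins)
    cell <- gi[ok] + (bin[ok] - 1L) * nrow(acc)
    agg <- tapply(1 / binBp[ok], cell, sum)
    acc[as.integer(names(agg))] <- agg
  } else if (methods::is(x, "SignalTrack")) {
    w <- binWidth(x)
    vals <- trackValues(x)
    sl <- seqlengths(seqinfo(x))
    for (i in seq_along(g)) {
      ch <- as.character(seqnames(g))[i]
      Lg <- width(g)[i]
      ## metagene bin midpoints in genomic coordinates, 5'->3'
      upMid <- -flankBp + (seq_len(flankBins) - 0.5) * flankBinBp
      bodyMid <- (seq_len(bodyBins) - 0.5) * (Lg / bodyBins)
      dnMid <- Lg + (seq_len(flankBins) - 0.5) * flankBinBp
      rel <- c(upMid, bodyMid, dnMid)
      posG <- if (plus[i]) start(g)[i] + rel else end(g)[i] - rel
      posG <- pmin(pmax(posG, 1), sl[[ch]])
      acc[i, ] <- vals[[ch]][floor((posG - 1) / w) + 1]
    }
  } else stop("'x' must be a PeakSet or a SignalTrack")
  values <- colMeans(acc)
  structure(list(values = values, bin = seq_len(nbTotal),
                 region = factor(rep(c("upstream", "body", "downstream"),
                                     c(flankBins, bodyBins, flankBins)),
                                 levels = c("upstream", "body", "downstream")),
                 bodyBins = bodyBins, flankBins = flankBins,
                 flankBp = flankBp, nGenes = length(g), nSkipped = nSkipped),
            class = "MetageneProfile")
}

#' Write a metagene or summit profile as TSV
#'
#' @param x A `MetageneProfile` or `SummitProfile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(x, path) {
  df <- if (inherits(x, "MetageneProfile"))
    data.frame(bin = x$bin, region = as.character(x$region), value = x$values)
  else data.frame(offset = x$offsets, value = x$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chromosome-level correlation of binding with gene content and length
#'
#' Pearson correlation of per-chromosome peak counts against (a) the
#' per-chromosome number of genes and (b) chromosome length -- the classic
#' check that binding tracks genes rather than sheer sequence.
#'
#' @param peaks A [PeakSet-class].
#' @param genes A [GeneCatalog-class].
#' @param layout `Seqinfo`; needs at least 3 chromosomes.
#' @return List with `rGenes`, `rLength` and the per-chromosome table
#'   (`chrom`, `peaks`, `genes`, `length`). Zero-variance inputs give `NA`
#'   with a warning.
#' @export
chromCorrelation <- function(peaks, genes, layout) {
  sl <- seqlengths(layout)
  if (length(sl) < 3) stop("need at least 3 chromosomes")
  chr <- names(sl)
  pk <- table(factor(as.character(seqnames(peakRanges(peaks))), levels = chr))
  gn <- table(factor(as.character(seqnames(geneRanges(genes))), levels = chr))
  df <- data.frame(chrom = chr, peaks = as.integer(pk),
                   genes = as.integer(gn), length = as.numeric(sl))
  corSafe <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance: correlation undefined")
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  list(rGenes = corSafe(df$peaks, df$genes),
       rLength = corSafe(df$peaks, df$length), table = df)
}
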