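## Every generator is a pure function of (parameters, seed). A single global
## seed is expanded into per-generator subseeds by a fixed affine splitting
## rule so adding one generator never perturbs the draws of another.

.subseed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 + 9973 * stream) %%
    2147483647L
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.newTruth <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = seed, ...),
            class = "SyntheticTruth")
}

#' Serialize / restore a SyntheticTruth sidecar
#'
#' Every generator returns (or is accompanied by) a `SyntheticTruth` record
#' of the parameters it planted. Downstream recovery tests read planted
#' values only from this sidecar, never from the data.
#'
#' @param truth A `SyntheticTruth` (named list of planted parameters).
#' @param path JSON file path.
#' @return `writeSyntheticTruth()`: `path` invisibly;
#'   `readSyntheticTruth()`: the restored list.
#' @export
writeSyntheticTruth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSyntheticTruth
#' @export
readSyntheticTruth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "SyntheticTruth")
}

## gene-length models by class (bp); chosen to mimic the broad size contrast
## between protein-coding / lincRNA genes and the short structural RNA classes
.geneLengths <- function(class, n) {
  switch(class,
    protein_coding = pmax(2000L, as.integer(round(stats::rlnorm(n, log(15000), 0.6)))),
    lincRNA = pmax(1000L, as.integer(round(stats::rlnorm(n, log(4000), 0.6)))),
    snRNA = as.integer(round(stats::runif(n, 100, 250))),
    snoRNA = as.integer(round(stats::runif(n, 70, 200))),
    miRNA = as.integer(round(stats::runif(n, 60, 120))))
}

#' Generate a synthetic multi-chromosome genome with gene models
#'
#' Places the requested number of genes of each class on the genome,
#' non-overlapping with at least `minGeneGap` bp between neighbours, strands
#' i.i.d. Bernoulli(0.5). Genes are split into 1--5 ordered non-overlapping
#' exons. Deterministic given `seed`.
#'
#' @param lengths Chromosome lengths in bp (chromosomes are named
#'   `chr1 ... chrN`).
#' @param genesPerClass Named integer vector over the supported classes,
#'   e.g. `c(protein_coding = 200, snRNA = 20)`.
#' @param minGeneGap Minimum bp between adjacent genes (default 1000).
#' @param seed Integer seed.
#' @return List with elements `layout` (`Seqinfo`), `genes`
#'   ([GeneCatalog-class]) and `truth` (`SyntheticTruth`).
#' @examples
#' g <- genGenome(c(2e6, 1e6), c(protein_coding = 50, snRNA = 10), seed = 1)
#' table(geneClasses(g$genes))
#' @export
genGenome <- function(lengths, genesPerClass, minGeneGap = 1000L, seed = 1L) {
  stopifnot(all(genesPerClass >= 0), all(names(genesPerClass) %in% .GENE_CLASSES))
  layout <- genomeLayout(paste0("chr", seq_along(lengths)), lengths)
  .withSeed(.subseed(seed, 1L), {
    classes <- rep(names(genesPerClass), genesPerClass)
    n <- length(classes)
    glen <- integer(n)
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      glen[idx] <- .geneLengths(cl, length(idx))
    }
    ## random assignment of genes to chromosomes, weighted by length
    chrom <- sample(seqlevels(layout), n, replace = TRUE,
                    prob = lengths / sum(lengths))
    starts <- integer(n)
    for (ch in seqlevels(layout)) {
      idx <- which(chrom == ch)
      if (!length(idx)) next
      L <- seqlengths(layout)[[ch]]
      slack <- L - sum(glen[idx]) - (length(idx) + 1) * minGeneGap
      if (slack < 0)
        stop("infeasible gene packing on chromosome ", ch)
      idx <- sample(idx)  # random genomic order
      w <- stats::rexp(length(idx) + 1)
      gaps <- minGeneGap + slack * w / sum(w)  # n+1 gaps; last is trailing
      before <- cumsum(gaps)[seq_along(idx)]
      starts[idx] <- as.integer(round(before +
        cumsum(c(0, glen[idx[-length(idx)]])))) + 1L
    }
    gr <- GRanges(chrom, IRanges(starts, width = glen),
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  seqinfo = layout,
                  gene_id = sprintf("g%05d", seq_len(n)),
                  gene_class = classes)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    gr$gene_id <- sprintf("g%05d", seq_len(n))  # ids in genomic order
    exl <- methods::as(lapply(seq_len(n), function(i) {
      .splitExons(start(gr)[i], end(gr)[i], as.character(seqnames(gr))[i],
                  as.character(strand(gr))[i], layout)
    }), "GRangesList")
    names(exl) <- gr$gene_id
    truth <- .newTruth("genGenome", seed, lengths = lengths,
                       genesPerClass = as.list(genesPerClass),
                       minGeneGap = minGeneGap)
    list(layout = layout, genes = GeneCatalog(gr, exl), truth = truth)
  })
}

.splitExons <- function(s, e, chrom, strand, layout) {
  len <- e - s + 1L
  nEx <- if (len < 400L) 1L else sample(1:5, 1L)
  if (nEx == 1L)
    return(GRanges(chrom, IRanges(s, e), strand = strand, seqinfo = layout))
  ## 2*nEx - 2 interior cut points; alternate exon / intron segments
  cuts <- sort(sample(seq.int(s + 1L, e - 1L), 2L * nEx - 2L))
  bounds <- c(s, cuts, e)
  starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  ends[length(ends)] <- e
  GRanges(chrom, IRanges(starts, ends), strand = strand, seqinfo = layout)
}

#' Generate a peak set with a tunable TSS-proximity bias
#'
#' A fraction `tssBias` of peaks place their summit uniformly within
#' `proximityWindow` bp of a randomly chosen TSS; the remainder place it
#' uniformly over the genome. Peak widths are Normal(`widthMean`,
#' `widthSd`), truncated positive; intervals are clipped to chromosome
#' bounds with the summit kept inside.
#'
#' @param genes A [GeneCatalog-class] (TSS anchors).
#' @param layout `Seqinfo`.
#' @param nPeaks Number of peaks.
#' @param tssBias Fraction in [0, 1] of TSS-proximal peaks.
#' @param proximityWindow Half-window around the TSS in bp (default 1000).
#' @param widthMean,widthSd Peak width distribution in bp.
#' @param seed Integer seed.
#' @return List with `peaks` ([PeakSet-class]) and `truth`.
#' @export
genPeaks <- function(genes, layout, nPeaks, tssBias,
                     proximityWindow = 1000L, widthMean = 200, widthSd = 50,
                     seed = 1L) {
  stopifnot(tssBias >= 0, tssBias <= 1, nPeaks >= 0)
  truth <- .newTruth("genPeaks", seed, nPeaks = nPeaks, tssBias = tssBias,
                     proximityWindow = proximityWindow,
                     widthMean = widthMean, widthSd = widthSd)
  if (nPeaks == 0) {
    gr <- GRanges(seqinfo = layout)
    mcols(gr)$summit <- integer(); mcols(gr)$score <- numeric()
    return(list(peaks = PeakSet(gr, "synthetic"), truth = truth))
  }
  .withSeed(.subseed(seed, 2L), {
    sl <- seqlengths(layout)
    tssPos <- tssSites(genes)
    tssChrom <- as.character(seqnames(geneRanges(genes)))
    biased <- stats::runif(nPeaks) < tssBias
    chrom <- character(nPeaks); summit <- numeric(nPeaks)
    nb <- sum(biased)
    if (nb) {
      gi <- sample(length(tssPos), nb, replace = TRUE)
      chrom[biased] <- tssChrom[gi]
      off <- round(stats::runif(nb, -proximityWindow, proximityWindow))
      summit[biased] <- pmin(pmax(tssPos[gi] + off, 1), sl[chrom[biased]])
    }
    nu <- sum(!biased)
    if (nu) {
      chrom[!biased] <- sample(names(sl), nu, replace = TRUE,
                               prob = sl / sum(sl))
      summit[!biased] <- floor(stats::runif(nu, 1, sl[chrom[!biased]] + 1))
    }
    half <- pmax(10L, as.integer(round(
      stats::rnorm(nPeaks, widthMean, widthSd) / 2)))
    s <- pmax(1, summit - half)
    e <- pmin(sl[chrom], summit + half)
    gr <- GRanges(chrom, IRanges(as.integer(s), as.integer(e)),
                  seqinfo = layout, summit = as.integer(summit),
                  score = round(stats::runif(nPeaks, 1, 100), 2))
    key <- paste(chrom, s, e)
    gr <- gr[!duplicated(key)]
    list(peaks = PeakSet(gr, "synthetic"), truth = truth)
  })
}

#' Generate a feature interval set with a planted peak-overlap fraction
#'
#' About `overlapFraction * length(peaks)` features are placed so each
#' overlaps one distinct randomly chosen peak; the remaining features are
#' placed uniformly while avoiding all peaks (rejection sampling).
#'
#' @param peaks A [PeakSet-class].
#' @param layout `Seqinfo`.
#' @param overlapFraction Planted fraction f in [0, 1] of peaks overlapped.
#' @param nFeatures Total features to emit; must be at least
#'   `round(f * length(peaks))`.
#' @param widthMean,widthSd Feature width distribution in bp.
#' @param seed Integer seed.
#' @return List with `features` (`GRanges`) and `truth`.
#' @export
genFeatureSet <- function(peaks, layout, overlapFraction, nFeatures,
                          widthMean = 400, widthSd = 100, seed = 1L) {
  stopifnot(overlapFraction >= 0, overlapFraction <= 1)
  k <- round(overlapFraction * length(peaks))
  if (nFeatures < k)
    stop("nFeatures (", nFeatures, ") is smaller than the required ",
         "overlapping count (", k, ")")
  .withSeed(.subseed(seed, 3L), {
    sl <- seqlengths(layout)
    w <- pmax(50L, as.integer(round(stats::rnorm(nFeatures, widthMean, widthSd))))
    pgr <- peakRanges(peaks)
    chrom <- character(nFeatures); s <- integer(nFeatures)
    if (k) {
      pick <- sample(length(peaks), k)
      pc <- as.character(seqnames(pgr))[pick]
      chrom[seq_len(k)] <- pc
      ## prefer placements that touch only the chosen peak, so the planted
      ## per-peak overlap count stays (near-)exact; redraw spillers a few times
      lo <- pmax(1L, start(pgr)[pick] - w[seq_len(k)] + 1L)
      hi <- pmin(end(pgr)[pick], sl[pc] - w[seq_len(k)] + 1L)
      hi <- pmax(hi, lo)
      st <- as.integer(floor(stats::runif(k, lo, hi + 1)))
      for (round in seq_len(25L)) {
        cand <- GRanges(pc, IRanges(st, width = w[seq_len(k)]),
                        seqinfo = layout)
        spill <- countOverlaps(cand, pgr) > 1L
        if (!any(spill)) break
        st[spill] <- as.integer(floor(stats::runif(sum(spill), lo[spill],
                                                   hi[spill] + 1)))
      }
      s[seq_len(k)] <- st
    }
    if (nFeatures > k) {
      for (i in seq.int(k + 1L, nFeatures)) {
        for (it in seq_len(1000L)) {
          ch <- sample(names(sl), 1L, prob = sl / sum(sl))
          st <- floor(stats::runif(1, 1, sl[[ch]] - w[i] + 2))
          cand <- GRanges(ch, IRanges(st, width = w[i]), seqinfo = layout)
          if (!any(IRanges::overlapsAny(cand, pgr))) break
          if (it == 1000L) stop("could not place a peak-avoiding feature")
        }
        chrom[i] <- ch; s[i] <- as.integer(st)
      }
    }
    feats <- GenomicRanges::sort(
      GRanges(chrom, IRanges(s, width = w), seqinfo = layout),
      ignore.strand = TRUE)
    truth <- .newTruth("genFeatureSet", seed,
                       overlapFraction = overlapFraction,
                       nFeatures = nFeatures, plantedOverlapCount = k)
    list(features = feats, truth = truth)
  })
}

#' Generate a pair of signal tracks with a planted correlation
#'
#' Bin values are a bivariate Gaussian construction with population
#' correlation `rho`, shifted so each track's minimum is exactly zero
#' (a constant shift, which leaves the Pearson correlation unchanged).
#'
#' @param layout `Seqinfo`.
#' @param binWidth Bin width in bp.
#' @param rho Target correlation in [-1, 1].
#' @param seed Integer seed.
#' @return List with `trackA`, `trackB` ([SignalTrack-class]) and `truth`.
#' @export
genSignalPair <- function(layout, binWidth, rho, seed = 1L) {
  stopifnot(abs(rho) <= 1)
  .withSeed(.subseed(seed, 4L), {
    sl <- seqlengths(layout)
    nBins <- ceiling(sl / binWidth)
    z1 <- stats::rnorm(sum(nBins))
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(sum(nBins))
    z1 <- z1 - min(z1); z2 <- z2 - min(z2)
    splitBy <- rep(names(nBins), nBins)
    va <- split(z1, factor(splitBy, levels = names(nBins)))
    vb <- split(z2, factor(splitBy, levels = names(nBins)))
    truth <- .newTruth("genSignalPair", seed, rho = rho, binWidth = binWidth,
                       nBins = sum(nBins))
    list(trackA = SignalTrack(va, binWidth, layout),
         trackB = SignalTrack(vb, binWidth, layout), truth = truth)
  })
}

#' Generate a conservation-style track with bumps planted at summits
#'
#' Baseline plus i.i.d. Gaussian noise, with a Gaussian-shaped bump of the
#' stated height and full width at half maximum centred on every summit.
#'
#' @param layout `Seqinfo`.
#' @param binWidth Bin width in bp.
#' @param baseline Baseline level.
#' @param bumpHeight Bump height above baseline (0 for a flat track).
#' @param bumpWidth Bump full width at half maximum, in bp.
#' @param summits A [PeakSet-class], or a `GRanges` of width-1 positions.
#' @param noiseSd Noise standard deviation (default 0.01).
#' @param seed Integer seed.
#' @return List with `track` ([SignalTrack-class]) and `truth`.
#' @export
genConservationTrack <- function(layout, binWidth, baseline, bumpHeight,
                                 bumpWidth, summits, noiseSd = 0.01,
                                 seed = 1L) {
  stopifnot(bumpWidth > 0)
  sgr <- if (methods::is(summits, "PeakSet")) summitRanges(summits) else summits
  .withSeed(.subseed(seed, 5L), {
    sl <- seqlengths(layout)
    sigma <- bumpWidth / (2 * sqrt(2 * log(2)))
    values <- lapply(names(sl), function(ch) {
      n <- ceiling(sl[[ch]] / binWidth)
      v <- baseline + stats::rnorm(n, 0, noiseSd)
      pos <- start(sgr)[as.character(seqnames(sgr)) == ch]
      centres <- (seq_len(n) - 0.5) * binWidth
      reach <- ceiling(4 * sigma / binWidth)
      for (p in pos) {
        b0 <- floor((p - 1) / binWidth) + 1
        idx <- max(1, b0 - reach):min(n, b0 + reach)
        v[idx] <- v[idx] + bumpHeight * exp(-(centres[idx] - p)^2 / (2 * sigma^2))
      }
      v
    })
    names(values) <- names(sl)
    truth <- .newTruth("genConservationTrack", seed, baseline = baseline,
                       bumpHeight = bumpHeight, bumpWidth = bumpWidth,
                       noiseSd = noiseSd, nSummits = length(sgr))
    list(track = SignalTrack(values, binWidth, layout), truth = truth)
  })
}

.VENN_REGIONS <- c("A", "C", "U", "AC", "AU", "CU", "ACU")

#' Generate three differential-expression tables with planted Venn structure
#'
#' Emits one table per comparison (knockdown A vs scrambled control,
#' knockdown C vs scrambled control, un-transfected vs scrambled control)
#' over a common gene universe, such that the set of genes significant
#' (BH q < `alpha`) in each three-way Venn region matches the requested
#' counts exactly when re-derived from the emitted q-values. Within the
#' triple intersection, exactly `oppositeCount` genes have a knockdown
#' fold-change direction opposite to their control-comparison direction;
#' all other planted genes are direction-consistent. Significant genes draw
#' p-values below the Benjamini-Hochberg feasibility threshold; all other
#' genes draw p uniformly above `alpha`, which guarantees q > `alpha` under
#' the step-up procedure (the exact-replant contract).
#'
#' @param genes Gene universe: a [GeneCatalog-class], a character vector of
#'   ids, or a single integer count.
#' @param vennCounts Named counts for the regions
#'   `A, C, U, AC, AU, CU, ACU` (missing regions default to 0). `A`/`C` are
#'   the two knockdown comparisons, `U` the un-transfected control
#'   comparison.
#' @param oppositeCount Number of triple-intersection genes whose knockdown
#'   direction opposes the control-comparison direction; at most
#'   `vennCounts["ACU"]`.
#' @param log2fcMean,log2fcSd Magnitude distribution of significant log2
#'   fold changes.
#' @param alpha Significance level the structure is planted at.
#' @param seed Integer seed.
#' @return List with `tables` (named list `NC_vs_A`, `NC_vs_C`, `UT_vs_NC`
#'   of data frames `gene_id, log2fc, pvalue, qvalue`) and `truth`.
#' @export
genDeTables <- function(genes, vennCounts, oppositeCount = 0L,
                        log2fcMean = 1.5, log2fcSd = 0.5, alpha = 0.05,
                        seed = 1L) {
  ids <- if (methods::is(genes, "GeneCatalog")) geneIds(genes)
         else if (is.character(genes)) genes
         else sprintf("g%05d", seq_len(genes))
  counts <- stats::setNames(integer(length(.VENN_REGIONS)), .VENN_REGIONS)
  stopifnot(all(names(vennCounts) %in% .VENN_REGIONS))
  counts[names(vennCounts)] <- as.integer(vennCounts)
  if (sum(counts) > length(ids))
    stop("Venn counts exceed the gene universe size")
  if (oppositeCount > counts[["ACU"]])
    stop("oppositeCount exceeds the triple-intersection count")
  .withSeed(.subseed(seed, 6L), {
    n <- length(ids)
    member <- sample(ids, sum(counts))
    region <- rep(.VENN_REGIONS, counts)
    names(region) <- member
    ## direction shared by both knockdowns; control direction flipped for
    ## the planted opposite-direction subset of the triple intersection
    baseSign <- sample(c(-1, 1), sum(counts), replace = TRUE)
    names(baseSign) <- member
    triple <- member[region == "ACU"]
    opp <- if (oppositeCount) sample(triple, oppositeCount) else character()
    mkTable <- function(letter) {
      inTab <- member[grepl(letter, region)]
      m <- length(inTab)
      p <- stats::runif(n, alpha, 1)
      fc <- stats::rnorm(n, 0, 0.15)
      names(p) <- names(fc) <- ids
      if (m) {
        p[inTab] <- stats::runif(m, 0, 0.5 * alpha * m / n)
        mag <- pmax(0.1, abs(stats::rnorm(m, log2fcMean, log2fcSd)))
        sg <- baseSign[inTab]
        if (letter == "U") sg[inTab %in% opp] <- -sg[inTab %in% opp]
        fc[inTab] <- sg * mag
      }
      fc[fc == 0] <- 1e-6
      data.frame(gene_id = ids, log2fc = unname(fc), pvalue = unname(p),
                 qvalue = bhFdr(unname(p)))
    }
    tables <- list(NC_vs_A = mkTable("A"), NC_vs_C = mkTable("C"),
                   UT_vs_NC = mkTable("U"))
    truth <- .newTruth("genDeTables", seed,
                       vennCounts = as.list(counts),
                       oppositeCount = oppositeCount, alpha = alpha,
                       log2fcMean = log2fcMean, log2fcSd = log2fcSd)
    list(tables = tables, truth = truth)
  })
}

#' Generate a DE table whose significance depends on promoter binding
#'
#' Plants the dependency behind regulome inference: genes with at least one
#' peak summit within `window` bp of their TSS are `beta` times more likely
#' (odds multiplier) to be drawn into the down-regulated set. Up-regulated
#' genes are drawn uniformly from the remainder. Significance is planted as
#' in [genDeTables()].
#'
#' @param genes A [GeneCatalog-class].
#' @param peaks A [PeakSet-class].
#' @param nUp,nDown Planted numbers of up/down-regulated genes.
#' @param beta Odds multiplier linking promoter binding to down-regulation
#'   (1 = no dependency).
#' @param window TSS half-window in bp defining "bound" (default 1000).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return List with `table` (data frame `gene_id, log2fc, pvalue, qvalue`)
#'   and `truth`.
#' @export
genBindingLinkedDe <- function(genes, peaks, nUp, nDown, beta = 1,
                               window = 1000L, alpha = 0.05, seed = 1L) {
  ids <- geneIds(genes)
  n <- length(ids)
  stopifnot(nUp + nDown <= n, beta > 0)
  tssW <- .expandTrim(tssRanges(genes), window)
  bound <- IRanges::overlapsAny(tssW, summitRanges(peaks))
  .withSeed(.subseed(seed, 7L), {
    wgt <- ifelse(bound, beta, 1)
    down <- sample(ids, nDown, prob = wgt)
    up <- sample(setdiff(ids, down), nUp)
    m <- nUp + nDown
    p <- stats::runif(n, alpha, 1)
    fc <- stats::rnorm(n, 0, 0.15)
    names(p) <- names(fc) <- ids
    p[c(up, down)] <- stats::runif(m, 0, 0.5 * alpha * m / n)
    fc[up] <- pmax(0.1, abs(stats::rnorm(nUp, 1.5, 0.5)))
    fc[down] <- -pmax(0.1, abs(stats::rnorm(nDown, 1.5, 0.5)))
    fc[fc == 0] <- 1e-6
    truth <- .newTruth("genBindingLinkedDe", seed, nUp = nUp, nDown = nDown,
                       beta = beta, window = window, alpha = alpha,
                       nBound = sum(bound))
    list(table = data.frame(gene_id = ids, log2fc = unname(fc),
                            pvalue = unname(p), qvalue = bhFdr(unname(p))),
         truth = truth)
  })
}

#' Generate replicate FPKM expression values with a planted silenced fraction
#'
#' A `silencedFraction` of genes get FPKM 0 in all three replicates; the
#' rest draw log-normal FPKM with occasional single-replicate dropouts
#' (always keeping at least one replicate positive).
#'
#' @param genes A [GeneCatalog-class] or character vector of gene ids.
#' @param silencedFraction Fraction of fully silent genes.
#' @param seed Integer seed.
#' @return List with `fpkm` (matrix, genes x 3 replicates) and `truth`.
#' @export
genFpkm <- function(genes, silencedFraction = 0.3, seed = 1L) {
  ids <- if (methods::is(genes, "GeneCatalog")) geneIds(genes) else genes
  .withSeed(.subseed(seed, 8L), {
    n <- length(ids)
    m <- matrix(stats::rlnorm(3 * n, log(10), 1), nrow = n,
                dimnames = list(ids, paste0("rep", 1:3)))
    drop <- matrix(stats::runif(3 * n) < 0.05, nrow = n)
    drop[rowSums(drop) == 3L, 1L] <- FALSE  # keep expressed genes expressed
    m[drop] <- 0
    sil <- sample(n, round(silencedFraction * n))
    m[sil, ] <- 0
    truth <- .newTruth("genFpkm", seed, silencedFraction = silencedFraction,
                       nSilenced = length(sil))
    list(fpkm = m, truth = truth)
  })
}
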