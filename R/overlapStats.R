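## Fast "does [a, b] hit any feature" lookups against a per-chromosome index
## of reduced, sorted features: starts ascending + running max of ends.
.featureIndex <- function(features) {
  red <- reduce(GenomicRanges::sort(features, ignore.strand = TRUE),
                ignore.strand = TRUE)
  sp <- split(red, seqnames(red))
  lapply(sp, function(gr) {
    list(starts = start(gr), cummaxEnds = cummax(end(gr)))
  })
}

.hitsIndex <- function(idx, chrom, qStart, qEnd) {
  out <- logical(length(qStart))
  for (ch in unique(chrom)) {
    ix <- idx[[ch]]
    sel <- chrom == ch
    if (is.null(ix) || !length(ix$starts)) next
    ## overlap iff some feature i has start_i <= qEnd and end_i >= qStart
    k <- findInterval(qEnd[sel], ix$starts)
    out[sel] <- k >= 1L & ix$cummaxEnds[pmax(k, 1L)] >= qStart[sel]
  }
  out
}

#' Per-chromosome randomization overlap test
#'
#' Tests whether query peaks overlap a feature set more than expected by
#' chance. The statistic is the fraction of query intervals overlapping at
#' least one feature (features optionally expanded by `gap` bp). The null
#' re-places every query interval uniformly at random within its own
#' chromosome, preserving its length and the per-chromosome interval
#' counts, `nPermutations` times; the Z-score measures the distance of the
#' observed fraction from the permutation mean in permutation standard
#' deviations, and the empirical p-value uses the add-one correction
#' `(1 + #(perm >= obs)) / (1 + n)` so it is never zero.
#'
#' @param query A [PeakSet-class] (or `GRanges`).
#' @param features `GRanges` of features on the same layout.
#' @param layout `Seqinfo`.
#' @param nPermutations At least 100 (default 1000).
#' @param gap Expansion of features in bp before overlap testing
#'   (default 0).
#' @param seed Integer seed for the permutation stream.
#' @param returnPermutations If `TRUE`, attach the permuted fractions (and
#'   the first permutation's intervals) for audit.
#' @return An [OverlapTestResult-class]; when `returnPermutations` is set,
#'   the permuted fractions are in `attr(result, "permuted")` and the first
#'   permutation draw in `attr(result, "firstDraw")`.
#' @export
randomizedOverlapTest <- function(query, features, layout,
                                  nPermutations = 1000L, gap = 0L, seed = 1L,
                                  returnPermutations = FALSE) {
  if (nPermutations < 100) stop("need at least 100 permutations")
  qgr <- if (methods::is(query, "PeakSet")) peakRanges(query) else query
  if (!.sameLayout(seqinfo(qgr), seqinfo(features)) ||
      !.sameLayout(seqinfo(qgr), layout))
    stop("query and features must share the genome layout")
  feats <- if (gap > 0) .expandTrim(features, gap) else features
  idx <- .featureIndex(feats)
  chrom <- as.character(seqnames(qgr))
  w <- width(qgr)
  sl <- seqlengths(layout)
  observed <- mean(.hitsIndex(idx, chrom, start(qgr), end(qgr)))
  maxStart <- sl[chrom] - w + 1
  permuted <- numeric(nPermutations)
  firstDraw <- NULL
  .withSeed(.subseed(seed, 9L), {
    for (i in seq_len(nPermutations)) {
      s <- floor(stats::runif(length(w), 1, maxStart + 1))
      permuted[i] <- mean(.hitsIndex(idx, chrom, s, s + w - 1))
      if (i == 1L && returnPermutations)
        firstDraw <- GRanges(chrom, IRanges(as.integer(s), width = w),
                             seqinfo = layout)
    }
  })
  m <- mean(permuted); sdev <- stats::sd(permuted)
  z <- if (sdev > 0) (observed - m) / sdev else NA_real_
  res <- new("OverlapTestResult", observed = observed, permMean = m,
             permSd = sdev, zScore = z,
             pValue = (1 + sum(permuted >= observed)) / (1 + nPermutations),
             nPermutations = as.integer(nPermutations),
             seed = as.integer(seed))
  if (returnPermutations) {
    attr(res, "permuted") <- permuted
    attr(res, "firstDraw") <- firstDraw
  }
  res
}

setMethod("show", "OverlapTestResult", function(object) {
  cat(sprintf(paste0("OverlapTestResult: observed %.4f, null %.4f +/- %.4f ",
                     "(n = %d)\n  Z = %s, empirical p = %.4g\n"),
              object@observed, object@permMean, object@permSd,
              object@nPermutations,
              ifelse(is.na(object@zScore), "undefined",
                     sprintf("%.2f", object@zScore)), object@pValue))
})

#' Serialize an overlap test result as JSON
#'
#' @param x An [OverlapTestResult-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeOverlapTest <- function(x, path) {
  jsonlite::write_json(list(observed = x@observed, perm_mean = x@permMean,
                            perm_sd = x@permSd, z_score = x@zScore,
                            p_value = x@pValue,
                            n_permutations = x@nPermutations, seed = x@seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pearson correlation of two signal tracks
#'
#' Correlates bin values genome-wide, or restricted to the bins that
#' intersect `regions` (e.g. promoter windows or the union of two donors'
#' peak calls). Tracks must share layout and bin width.
#'
#' @param a,b [SignalTrack-class] objects.
#' @param regions Optional `GRanges` restriction.
#' @return Pearson correlation (`NA` with a warning on zero variance).
#' @export
signalCorrelation <- function(a, b, regions = NULL) {
  if (binWidth(a) != binWidth(b) ||
      !.sameLayout(seqinfo(a), seqinfo(b)))
    stop("tracks must share genome layout and bin width")
  chr <- names(trackValues(a))
  va <- unlist(trackValues(a)[chr], use.names = FALSE)
  vb <- unlist(trackValues(b)[chr], use.names = FALSE)
  if (!is.null(regions)) {
    w <- binWidth(a)
    keep <- logical(length(va))
    offset <- 0L
    for (ch in chr) {
      n <- length(trackValues(a)[[ch]])
      rr <- regions[as.character(seqnames(regions)) == ch]
      if (length(rr)) {
        b0 <- floor((start(rr) - 1) / w) + 1
        b1 <- floor((end(rr) - 1) / w) + 1
        for (j in seq_along(rr))
          keep[offset + seq.int(b0[j], min(b1[j], n))] <- TRUE
      }
      offset <- offset + n
    }
    va <- va[keep]; vb <- vb[keep]
  }
  if (length(va) < 3) stop("fewer than 3 usable bins")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Average signal profile around peak summits
#'
#' Mean track value at each binned offset from the summit, averaged over
#' all summits whose full window lies inside chromosome bounds
#' (out-of-bounds summits are skipped and counted). Offsets are in track
#' bins, spanning `[-window, +window]` bp.
#'
#' @param track A [SignalTrack-class].
#' @param peaks A [PeakSet-class].
#' @param window Half-window in bp (> 0).
#' @return List of class `SummitProfile`: `offsets` (bp, bin-spaced),
#'   `values`, `nSummits`, `nSkipped`.
#' @export
profileAroundSummits <- function(track, peaks, window) {
  if (window <= 0) stop("'window' must be positive")
  w <- binWidth(track)
  nb <- round(window / w)
  su <- summitRanges(peaks)
  sl <- seqlengths(seqinfo(track))
  vals <- trackValues(track)
  chrom <- as.character(seqnames(su))
  pos <- start(su)
  b0 <- floor((pos - 1) / w) + 1
  nBins <- lengths(vals)[chrom]
  usable <- (b0 - nb) >= 1 & (b0 + nb) <= nBins
  if (!any(usable)) stop("no summit has a full in-bounds window")
  prof <- numeric(2 * nb + 1)
  for (i in which(usable))
    prof <- prof + vals[[chrom[i]]][(b0[i] - nb):(b0[i] + nb)]
  structure(list(offsets = (-nb:nb) * w, values = prof / sum(usable),
                 nSummits = sum(usable), nSkipped = sum(!usable)),
            class = "SummitProfile")
}

#' Full width at half maximum of a summit-centred profile
#'
#' Helper for bump-shape comparisons: the extent, in bp, of the contiguous
#' region around the profile maximum whose value stays above halfway
#' between the edge baseline (mean of the outer 10% of offsets) and the
#' maximum.
#'
#' @param profile A `SummitProfile`.
#' @return Width in bp.
#' @export
profileFwhm <- function(profile) {
  v <- profile$values
  edge <- ceiling(length(v) * 0.05)
  baseline <- mean(c(utils::head(v, edge), utils::tail(v, edge)))
  half <- baseline + (max(v) - baseline) / 2
  above <- which(v >= half)
  ## contiguous run containing the maximum
  peak <- which.max(v)
  lo <- peak; while (lo > 1 && v[lo - 1] >= half) lo <- lo - 1
  hi <- peak; while (hi < length(v) && v[hi + 1] >= half) hi <- hi + 1
  profile$offsets[hi] - profile$offsets[lo]
}

#' Positional enrichment of motif occurrences around peak summits
#'
#' Summarizes motif occurrence offsets (bp relative to the peak summit) as
#' a normalized positional probability curve, optionally smoothed by a
#' centred moving-average kernel. Reports the smallest symmetric half-width
#' containing 50% of the occurrence mass, and a one-sided binomial test of
#' the count falling within `+/- centralHalfWidth` of the summit against
#' the uniform expectation `(2*centralHalfWidth + 1) / (2*window + 1)` --
#' a declared approximation for judging central (direct-binding-like)
#' versus broad (cooperative-binding-like) positional distributions.
#'
#' @param offsets Integer offsets in bp, all within `[-window, window]`.
#' @param window Half-window in bp.
#' @param centralHalfWidth Half-width for the enrichment test; defaults to
#'   the 50%-mass half-width.
#' @param smoothBins Odd moving-average kernel width in offsets (default
#'   1, i.e. no smoothing) applied to the probability curve only.
#' @return List of class `MotifPositionalProfile`: `offsets`,
#'   `probability` (sums to 1), `centralWidth50` (bp),
#'   `centralHalfWidth`, `pValue`, `nOccurrences`.
#' @export
motifCentralEnrichment <- function(offsets, window, centralHalfWidth = NULL,
                                   smoothBins = 1L) {
  if (!length(offsets)) stop("no motif occurrences supplied")
  if (any(abs(offsets) > window))
    stop("offsets must lie within +/- window")
  n <- length(offsets)
  grid <- -window:window
  counts <- tabulate(match(offsets, grid), nbins = length(grid))
  prob <- counts / n
  if (smoothBins > 1L) {
    k <- rep(1 / smoothBins, smoothBins)
    prob <- stats::filter(prob, k, sides = 2)
    prob[is.na(prob)] <- 0
    prob <- as.numeric(prob) / sum(prob)
  }
  ## smallest symmetric half-width holding >= 50% of the raw mass
  absOff <- abs(offsets)
  cw <- sort(absOff)[ceiling(n / 2)]
  if (is.null(centralHalfWidth)) centralHalfWidth <- cw
  inside <- sum(absOff <= centralHalfWidth)
  p0 <- (2 * centralHalfWidth + 1) / (2 * window + 1)
  pv <- stats::pbinom(inside - 1, n, p0, lower.tail = FALSE)
  structure(list(offsets = grid, probability = prob, centralWidth50 = cw,
                 centralHalfWidth = centralHalfWidth, pValue = pv,
                 nOccurrences = n),
            class = "MotifPositionalProfile")
}
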