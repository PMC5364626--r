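test_that("overlap test basics: self-overlap, reproducibility, audit draws", {
  g <- genGenome(c(2e6, 1e6), c(protein_coding = 60), seed = 51)
  pk <- genPeaks(g$genes, g$layout, 300, tssBias = 0.3, seed = 51)
  feats <- peakRanges(pk$peaks)

  res <- randomizedOverlapTest(pk$peaks, feats, g$layout, 200, seed = 52)
  expect_equal(res@observed, 1)
  expect_gt(res@zScore, 0)

  res2 <- randomizedOverlapTest(pk$peaks, feats, g$layout, 200, seed = 52)
  expect_identical(res2@pValue, res@pValue)
  expect_identical(res2@permMean, res@permMean)

  ## permutation preserves per-chromosome counts and interval lengths
  aud <- randomizedOverlapTest(pk$peaks, feats, g$layout, 100, seed = 53,
                               returnPermutations = TRUE)
  draw <- attr(aud, "firstDraw")
  qgr <- peakRanges(pk$peaks)
  expect_equal(table(as.character(GenomicRanges::seqnames(draw))),
               table(as.character(GenomicRanges::seqnames(qgr))))
  expect_equal(GenomicRanges::width(draw), GenomicRanges::width(qgr))
  sl <- GenomeInfoDb::seqlengths(g$layout)
  expect_true(all(GenomicRanges::end(draw) <=
                    sl[as.character(GenomicRanges::seqnames(draw))]))
  expect_length(attr(aud, "permuted"), 100)

  expect_error(randomizedOverlapTest(pk$peaks, feats, g$layout, 50), "100")
})

test_that("overlap empirical p matches a brute-force Monte-Carlo oracle", {
  ## 10-interval toy on a 1 kb chromosome
  layout <- genomeLayout("chrT", 1000L)
  set.seed(54)
  w <- sample(20:40, 10, replace = TRUE)
  qs <- sample(1:900, 10)
  query <- GenomicRanges::GRanges("chrT", IRanges::IRanges(qs, width = w),
                                  seqinfo = layout)
  feats <- GenomicRanges::GRanges("chrT",
                                  IRanges::IRanges(c(100, 400, 800),
                                                   width = c(60, 40, 50)),
                                  seqinfo = layout)
  obs <- mean(overlapsAnyGapped(query, feats))

  ## independent vectorized oracle: 1e6 uniform re-placements
  nSim <- 1e6
  fs <- GenomicRanges::start(feats); fe <- GenomicRanges::end(feats)
  hitProb <- local({
    set.seed(55)
    hits <- matrix(FALSE, nrow = nSim, ncol = 10)
    for (j in 1:10) {
      s <- floor(stats::runif(nSim, 1, 1000 - w[j] + 2))
      e <- s + w[j] - 1
      hit <- rep(FALSE, nSim)
      for (k in seq_along(fs)) hit <- hit | (s <= fe[k] & e >= fs[k])
      hits[, j] <- hit
    }
    rowMeans(hits)
  })
  pOracle <- mean(hitProb >= obs)

  res <- randomizedOverlapTest(query, feats, layout, nPermutations = 20000,
                               seed = 56)
  mcErr <- 3 * sqrt(pOracle * (1 - pOracle) / 20000) + 1e-3
  expect_lt(abs(res@pValue - pOracle), mcErr + 0.01)
})

test_that("overlap Z is calibrated under the independence null", {
  g <- genGenome(c(2e6, 1e6), c(protein_coding = 50), seed = 57)
  sl <- GenomeInfoDb::seqlengths(g$layout)
  zs <- numeric(120)
  set.seed(58)
  for (i in seq_along(zs)) {
    ## query and features drawn independently and uniformly
    qc <- sample(names(sl), 150, replace = TRUE, prob = sl / sum(sl))
    qs <- floor(stats::runif(150, 1, sl[qc] - 200))
    query <- GenomicRanges::GRanges(qc, IRanges::IRanges(qs, width = 200),
                                    seqinfo = g$layout)
    fc <- sample(names(sl), 150, replace = TRUE, prob = sl / sum(sl))
    fs <- floor(stats::runif(150, 1, sl[fc] - 3000))
    feats <- GenomicRanges::GRanges(fc, IRanges::IRanges(fs, width = 3000),
                                    seqinfo = g$layout)
    zs[i] <- randomizedOverlapTest(query, feats, g$layout, 250,
                                   seed = i)@zScore
  }
  expect_gte(mean(abs(zs) <= 3), 0.99)
})

test_that("overlap Z recovers planted enrichment monotonically", {
  g <- genGenome(c(4e6, 2e6), c(protein_coding = 150), seed = 59)
  pk <- genPeaks(g$genes, g$layout, 800, tssBias = 0.3, seed = 59)
  zs <- vapply(c(0.2, 0.5, 0.8), function(f) {
    fs <- genFeatureSet(pk$peaks, g$layout, f, 800, seed = 60)
    randomizedOverlapTest(pk$peaks, fs$features, g$layout, 200,
                          seed = 61)@zScore
  }, numeric(1))
  expect_true(all(zs > 3))
  expect_true(all(diff(zs) > 0))
})

test_that("signal correlation handles identity, negation and regions", {
  layout <- genomeLayout(c("chr1", "chr2"), c(5e5, 3e5))
  sp <- genSignalPair(layout, 100L, rho = 0.8, seed = 62)
  a <- sp$trackA; b <- sp$trackB
  expect_equal(signalCorrelation(a, a), 1)
  neg <- SignalTrack(lapply(trackValues(a), function(v) -v), 100L, layout)
  expect_equal(signalCorrelation(a, neg), -1)
  expect_equal(signalCorrelation(a, b), 0.8, tolerance = 0.05)

  ## restriction to regions covering every bin equals the unrestricted value
  allBins <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                    IRanges::IRanges(1, c(5e5, 3e5)),
                                    seqinfo = layout)
  expect_identical(signalCorrelation(a, b, regions = allBins),
                   signalCorrelation(a, b))
  ## restriction changes the usable bin count
  tiny <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 150),
                                 seqinfo = layout)
  expect_error(signalCorrelation(a, b, regions = tiny), "3 usable")

  flat <- flatTrack(2, binWidth = 100L, layout = layout)
  expect_warning(r <- signalCorrelation(a, flat), "zero variance")
  expect_true(is.na(r))
  expect_error(signalCorrelation(a, flatTrack(1, binWidth = 200L,
                                              layout = layout)),
               "bin width")
})

test_that("summit profiles recover planted bump shape and width ordering", {
  g <- genGenome(c(3e6), c(protein_coding = 50), seed = 63)
  pk <- genPeaks(g$genes, g$layout, 80, tssBias = 0, seed = 63)

  ## constant track -> flat profile at the constant
  flat <- flatTrack(3.5, binWidth = 100L, layout = g$layout)
  prof <- profileAroundSummits(flat, pk$peaks, 2000)
  expect_true(all(prof$values == 3.5))
  expect_length(prof$values, 2 * 20 + 1)

  ## planted Gaussian bumps: max at offset 0, FWHM within 2 bins, and a
  ## narrower planted bump yields a narrower recovered width
  wide <- genConservationTrack(g$layout, 100L, 0.1, 0.6, 1200, pk$peaks,
                               seed = 64)
  narrow <- genConservationTrack(g$layout, 100L, 0.1, 0.6, 500, pk$peaks,
                                 seed = 64)
  pw <- profileAroundSummits(wide$track, pk$peaks, 5000)
  pn <- profileAroundSummits(narrow$track, pk$peaks, 5000)
  expect_equal(pw$offsets[which.max(pw$values)], 0)
  expect_lte(abs(profileFwhm(pw) - 1200), 200)
  expect_lte(abs(profileFwhm(pn) - 500), 200)
  expect_lt(profileFwhm(pn), profileFwhm(pw))

  ## out-of-bounds summits are skipped with a count
  edge <- peaksAt(c(30, 50000), layout = genomeLayout("chrA", 1e5),
                  halfWidth = 20)
  tr <- flatTrack(1, binWidth = 100L, layout = genomeLayout("chrA", 1e5))
  pe <- profileAroundSummits(tr, edge, 2000)
  expect_equal(pe$nSkipped, 1L)
})

test_that("motif positional enrichment matches binomial-tail arithmetic", {
  ## all occurrences at the summit: central width 0, minimal p
  res0 <- motifCentralEnrichment(rep(0L, 12), window = 500)
  expect_equal(res0$centralWidth50, 0)
  expect_equal(res0$pValue, (1 / 1001)^12, tolerance = 1e-6)
  expect_equal(sum(res0$probability), 1)

  ## uniform offsets: not centrally enriched at alpha 0.01
  set.seed(65)
  offs <- sample(-500:500, 1000, replace = TRUE)
  resU <- motifCentralEnrichment(offs, window = 500, centralHalfWidth = 100)
  expect_gt(resU$pValue, 0.01)

  ## 30 of 40 occurrences within +/-100 of a +/-500 window: hand binomial
  offs2 <- c(sample(-100:100, 30, replace = TRUE),
             sample(c(-450:-200, 200:450), 10, replace = TRUE))
  res <- motifCentralEnrichment(offs2, window = 500, centralHalfWidth = 100)
  p0 <- 201 / 1001
  hand <- sum(stats::dbinom(30:40, 40, p0))
  expect_equal(res$pValue, hand)

  expect_error(motifCentralEnrichment(integer(), 500), "no motif")
  expect_error(motifCentralEnrichment(c(0, 600), 500), "window")
})
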