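test_that("genome generation is deterministic, honours counts and bounds", {
  a <- genGenome(c(2e6, 1e6), c(protein_coding = 80, snRNA = 15), seed = 9)
  b <- genGenome(c(2e6, 1e6), c(protein_coding = 80, snRNA = 15), seed = 9)
  expect_identical(geneIds(a$genes), geneIds(b$genes))
  expect_identical(GenomicRanges::start(geneRanges(a$genes)),
                   GenomicRanges::start(geneRanges(b$genes)))
  expect_equal(as.vector(table(geneClasses(a$genes))[c("protein_coding",
                                                       "snRNA")]),
               c(80L, 15L))
  ## genes within bounds, non-overlapping, across a seed sweep
  for (s in 1:200) {
    g <- genGenome(c(5e5, 3e5), c(protein_coding = 15, miRNA = 5),
                   minGeneGap = 200L, seed = s)
    gr <- geneRanges(g$genes)
    sl <- GenomeInfoDb::seqlengths(g$layout)
    expect_true(all(GenomicRanges::start(gr) >= 1))
    expect_true(all(GenomicRanges::end(gr) <=
                      sl[as.character(GenomicRanges::seqnames(gr))]))
    expect_equal(sum(GenomicRanges::countOverlaps(
      gr, gr, ignore.strand = TRUE) > 1), 0L)
  }
  ## infeasible packing errors with the chromosome name
  expect_error(genGenome(c(5e4), c(protein_coding = 100), seed = 1), "chr1")
})

test_that("exons are ordered, non-overlapping and inside their gene", {
  g <- genGenome(c(2e6), c(protein_coding = 60), seed = 21)
  ex <- exonsByGene(g$genes)
  gr <- geneRanges(g$genes)
  for (i in seq_along(gr)) {
    e <- ex[[i]]
    expect_true(all(GenomicRanges::start(e) >= GenomicRanges::start(gr)[i]))
    expect_true(all(GenomicRanges::end(e) <= GenomicRanges::end(gr)[i]))
    if (length(e) > 1) {
      expect_true(all(diff(GenomicRanges::start(e)) > 0))
      expect_true(all(utils::head(GenomicRanges::end(e), -1) <
                        utils::tail(GenomicRanges::start(e), -1)))
    }
  }
})

test_that("peak generator plants the requested TSS bias", {
  g <- genGenome(c(5e6, 3e6), c(protein_coding = 200, lincRNA = 50), seed = 2)
  win <- 1000L

  ## bias 1: every summit within the window of some TSS
  pk1 <- genPeaks(g$genes, g$layout, 500, tssBias = 1, proximityWindow = win,
                  seed = 3)
  d <- GenomicRanges::distanceToNearest(summitRanges(pk1$peaks),
                                        tssRanges(g$genes))
  expect_true(all(S4Vectors::mcols(d)$distance <= win))

  ## bias 0: summit positions consistent with uniformity (chi-square GOF
  ## over 20 equal genome slices, not rejected at alpha = 0.01)
  pk0 <- genPeaks(g$genes, g$layout, 2000, tssBias = 0, seed = 4)
  su <- summitRanges(pk0$peaks)
  pos <- GenomicRanges::start(su) +
    ifelse(as.character(GenomicRanges::seqnames(su)) == "chr2", 5e6, 0)
  gof <- stats::chisq.test(table(cut(pos, seq(0, 8e6, length.out = 21))))
  expect_gt(gof$p.value, 0.01)

  ## bias 0.5: TSS-proximal fraction within the 99% binomial interval
  pk5 <- genPeaks(g$genes, g$layout, 1000, tssBias = 0.5,
                  proximityWindow = win, seed = 5)
  d5 <- GenomicRanges::distanceToNearest(summitRanges(pk5$peaks),
                                         tssRanges(g$genes))
  obs <- sum(S4Vectors::mcols(d5)$distance <= win)
  ci <- stats::binom.test(500, 1000, conf.level = 0.99)$conf.int * 1000
  ## chance proximity inflates the count slightly; allow that one-sided
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2] + stats::qbinom(0.995, 500, 2 * 250 * 2 * win / 8e6))

  ## zero peaks is an empty set, not an error
  expect_length(genPeaks(g$genes, g$layout, 0, 0.5, seed = 1)$peaks, 0L)
})

test_that("feature sets reproduce the planted overlap fraction", {
  g <- genGenome(c(5e6, 3e6), c(protein_coding = 200), seed = 6)
  pk <- genPeaks(g$genes, g$layout, 1000, tssBias = 0.3, seed = 6)
  np <- length(pk$peaks)

  fs1 <- genFeatureSet(pk$peaks, g$layout, 1, np, seed = 7)
  expect_true(all(overlapsAnyGapped(pk$peaks, fs1$features)))

  fs5 <- genFeatureSet(pk$peaks, g$layout, 0.5, np, seed = 8)
  obs <- sum(overlapsAnyGapped(pk$peaks, fs5$features))
  ci <- stats::binom.test(round(np / 2), np, conf.level = 0.99)$conf.int * np
  expect_gte(obs, ci[1]); expect_lte(obs, ci[2])

  ## f = 0 places features away from every peak by construction
  fs0 <- genFeatureSet(pk$peaks, g$layout, 0, 300, seed = 9)
  expect_equal(sum(overlapsAnyGapped(pk$peaks, fs0$features)), 0L)

  expect_error(genFeatureSet(pk$peaks, g$layout, 0.5, 10, seed = 1),
               "overlapping count")
})

test_that("signal pairs carry the planted correlation", {
  layout <- genomeLayout(c("chr1", "chr2"), c(6e6, 6e6))
  sp1 <- genSignalPair(layout, 1000L, rho = 1, seed = 10)
  expect_equal(signalCorrelation(sp1$trackA, sp1$trackB), 1, tolerance = 1e-12)
  sp8 <- genSignalPair(layout, 1000L, rho = 0.8, seed = 11)  # 12000 bins
  expect_equal(signalCorrelation(sp8$trackA, sp8$trackB), 0.8, tolerance = 0.05)
  sp0 <- genSignalPair(layout, 1000L, rho = 0, seed = 12)
  expect_lt(abs(signalCorrelation(sp0$trackA, sp0$trackB)), 0.05)
  ## nonnegative after shift
  expect_gte(min(unlist(trackValues(sp8$trackA))), 0)
})

test_that("DE tables reproduce planted Venn regions and directions exactly", {
  counts <- c(A = 50, C = 40, U = 30, AC = 25, AU = 10, CU = 8, ACU = 20)
  for (s in c(1, 17, 33)) {
    sim <- genDeTables(2000, counts, oppositeCount = 7, seed = s)
    tabs <- sim$tables
    alpha <- sim$truth$alpha
    sig <- lapply(tabs, function(t) t$gene_id[bhFdr(t$pvalue) < alpha])
    inA <- tabs$NC_vs_A$gene_id %in% sig$NC_vs_A
    inC <- tabs$NC_vs_A$gene_id %in% sig$NC_vs_C
    inU <- tabs$NC_vs_A$gene_id %in% sig$UT_vs_NC
    got <- c(A = sum(inA & !inC & !inU), C = sum(!inA & inC & !inU),
             U = sum(!inA & !inC & inU), AC = sum(inA & inC & !inU),
             AU = sum(inA & !inC & inU), CU = sum(!inA & inC & inU),
             ACU = sum(inA & inC & inU))
    expect_equal(got, counts)
    ## knockdown signs agree; opposite-direction count matches from signs
    triple <- tabs$NC_vs_A$gene_id[inA & inC & inU]
    sgA <- sign(tabs$NC_vs_A$log2fc[match(triple, tabs$NC_vs_A$gene_id)])
    sgC <- sign(tabs$NC_vs_C$log2fc[match(triple, tabs$NC_vs_C$gene_id)])
    sgU <- sign(tabs$UT_vs_NC$log2fc[match(triple, tabs$UT_vs_NC$gene_id)])
    expect_true(all(sgA == sgC))
    expect_equal(sum(sgA != sgU), 7)
  }
})

test_that("all-zero Venn counts give no significant gene anywhere", {
  sim <- genDeTables(500, c(A = 0), seed = 13)
  for (t in sim$tables) expect_equal(sum(bhFdr(t$pvalue) < 0.05), 0L)
})

test_that("conservation tracks plant recoverable bumps", {
  g <- genGenome(c(2e6), c(protein_coding = 40), seed = 14)
  pk <- genPeaks(g$genes, g$layout, 60, tssBias = 0, seed = 14)

  flat <- genConservationTrack(g$layout, 100L, 0.2, 0, 800, pk$peaks,
                               seed = 15)
  v <- unlist(trackValues(flat$track))
  expect_lt(abs(mean(v) - 0.2), 0.01)
  expect_lt(stats::sd(v), 0.05)

  bumpy <- genConservationTrack(g$layout, 100L, 0.2, 0.5, 1000, pk$peaks,
                                seed = 16)
  prof <- profileAroundSummits(bumpy$track, pk$peaks, 5000)
  expect_equal(prof$offsets[which.max(prof$values)], 0)
  expect_lte(abs(profileFwhm(prof) - 1000), 200)  # within 2 bins of planted
})

test_that("truth sidecars serialize and restore", {
  sim <- genDeTables(100, c(AC = 5), seed = 20)
  f <- tempfile(fileext = ".json")
  writeSyntheticTruth(sim$truth, f)
  back <- readSyntheticTruth(f)
  expect_equal(back$vennCounts$AC, 5)
  expect_equal(back$seed, 20)
})

test_that("generated files are valid inputs to the readers", {
  g <- genGenome(c(1e6), c(protein_coding = 30, snoRNA = 10), seed = 22)
  pk <- genPeaks(g$genes, g$layout, 100, tssBias = 0.5, seed = 22)
  fbed <- tempfile(); fgtf <- tempfile()
  writePeaks(pk$peaks, fbed)
  writeGenes(g$genes, fgtf)
  expect_equal(summits(readPeaks(fbed, g$layout)), summits(pk$peaks))
  expect_equal(geneIds(readGenes(fgtf, g$layout)), geneIds(g$genes))
})

test_that("expression generator plants the silenced fraction", {
  sim <- genFpkm(sprintf("g%04d", 1:500), silencedFraction = 0.3, seed = 23)
  cls <- classifyExpression(sim$fpkm)
  expect_equal(sum(cls$class == "silenced"), sim$truth$nSilenced)
  expect_equal(sim$truth$nSilenced, 150)
})
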