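test_that("expression classification partitions genes by replicate FPKM", {
  m <- rbind(gA = c(0, 0, 0), gB = c(0, 0, 0.1), gC = c(5, 2, 1))
  cls <- classifyExpression(m)
  expect_equal(cls$class, c("silenced", "expressed", "expressed"))
  expect_setequal(cls$gene_id, rownames(m))
  expect_error(classifyExpression(rbind(c(-1, 0, 0))), "nonnegative")
  expect_error(classifyExpression(matrix(1, 2, 2)), "3 replicate")
})

test_that("binding score evaluates the distance-decay formula", {
  layout <- genomeLayout("chrA", 1e6)
  g <- GenomicRanges::GRanges("chrA", IRanges::IRanges(500000, 520000),
                              strand = "+", seqinfo = layout,
                              gene_id = "g1", gene_class = "protein_coding")
  catalog <- GeneCatalog(g)
  tss <- 500000L
  W <- 100000L

  ## no peaks in the window
  far <- peaksAt(700000, chrom = "chrA", layout = layout)
  bs0 <- bindingScore(catalog, far, W)
  expect_equal(bs0$s_binding, 0)
  expect_equal(bs0$k, 0L)

  ## single peak at the TSS: S = exp(-0.5)
  at <- peaksAt(tss, chrom = "chrA", layout = layout)
  expect_equal(bindingScore(catalog, at, W)$s_binding, exp(-0.5),
               tolerance = 1e-9)

  ## peaks at 25 kb and 50 kb: S = exp(-1.5) + exp(-2.5)
  two <- peaksAt(c(tss + 25000L, tss + 50000L), chrom = "chrA",
                 layout = layout)
  expect_equal(bindingScore(catalog, two, W)$s_binding,
               exp(-1.5) + exp(-2.5), tolerance = 1e-9)
  expect_equal(bindingScore(catalog, two, W)$k, 2L)
})

test_that("binding score is monotone in proximity and peak count", {
  layout <- genomeLayout("chrA", 1e6)
  g <- GenomicRanges::GRanges("chrA", IRanges::IRanges(500000, 520000),
                              strand = "+", seqinfo = layout,
                              gene_id = "g1", gene_class = "protein_coding")
  catalog <- GeneCatalog(g)
  dists <- c(90000, 60000, 30000, 10000, 0)
  s <- vapply(dists, function(d)
    bindingScore(catalog, peaksAt(500000 + d, chrom = "chrA",
                                  layout = layout))$s_binding, numeric(1))
  expect_true(all(diff(s) > 0))  # closer summit, larger score
  both <- peaksAt(c(500000, 530000), chrom = "chrA", layout = layout)
  expect_gt(bindingScore(catalog, both)$s_binding, max(s))
})

test_that("regulatory potential is the normalized rank product", {
  ## single gene: RP = 1
  one <- regulatoryPotential(data.frame(gene_id = "g1", s_binding = 2),
                             data.frame(gene_id = "g1", log2fc = 1,
                                        qvalue = 0.01))
  expect_equal(one$rp, 1)

  ## 3-gene toy: exact hand-ranked values
  sc <- data.frame(gene_id = c("a", "b", "c"), s_binding = c(0.6, 0.3, 0.1))
  de <- data.frame(gene_id = c("a", "b", "c"), log2fc = c(1, -1, 1),
                   qvalue = c(0.001, 0.5, 0.9))
  rp <- regulatoryPotential(sc, de)
  expect_equal(rp$rp, c(1 / 9, 4 / 9, 1))
  expect_equal(rp$direction, c("up", "static", "static"))

  ## relabeling genes permutes records without changing RP values
  perm <- c(2, 3, 1)
  rp2 <- regulatoryPotential(sc[perm, ], de[perm, ])
  expect_equal(rp2$rp, rp$rp[perm])

  ## RP in (0, 1]; q = 0 tolerated via clamping
  de0 <- de; de0$qvalue[1] <- 0
  rp0 <- regulatoryPotential(sc, de0)
  expect_true(all(rp0$rp > 0 & rp0$rp <= 1))
  expect_equal(which.min(rp0$rp), 1L)  # strongest binding + smallest q

  expect_error(regulatoryPotential(sc, de[1:2, ]), "missing")
})

test_that("KS direction test: identity gives D = 0; null is calibrated", {
  ## identical samples -> D = 0
  rec <- data.frame(rp = rep(seq(0.1, 1, 0.1), 3),
                    direction = rep(c("up", "down", "static"), each = 10))
  res <- ksDirectionTest(rec)
  expect_equal(res$up$D, 0)
  expect_equal(res$down$D, 0)

  ## all classes from one distribution: false-positive rate at 0.01 stays
  ## below 0.05 across seeds
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    rp <- stats::runif(600)
    dir <- sample(rep(c("up", "down", "static"), each = 200))
    r <- ksDirectionTest(data.frame(rp = rp, direction = dir))
    hits <- hits + (r$up$pValue < 0.01) + (r$down$pValue < 0.01)
  }
  expect_lte(hits / 200, 0.05)

  expect_error(ksDirectionTest(data.frame(rp = 0.5, direction = "up")),
               "empty direction class")
})

test_that("planted binding->downregulation dependency is detected", {
  g <- genGenome(c(10e6, 6e6), c(protein_coding = 500), seed = 71)
  ## sparse binding so that promoter binding discriminates genes
  pk <- genPeaks(g$genes, g$layout, 150, tssBias = 0.8,
                 proximityWindow = 500L, seed = 71)
  sim <- genBindingLinkedDe(g$genes, pk$peaks, nUp = 60, nDown = 60,
                            beta = 5, window = 1000L, seed = 72)
  bs <- bindingScore(g$genes, pk$peaks)
  rp <- regulatoryPotential(bs, sim$table)
  res <- ksDirectionTest(rp)
  expect_lt(res$down$pValue, 0.01)
  expect_gt(res$downStrongerFraction, 0.5)
})

test_that("independent binding and DE produce no spurious direction bias", {
  g <- genGenome(c(10e6, 6e6), c(protein_coding = 400), seed = 73)
  pk <- genPeaks(g$genes, g$layout, 150, tssBias = 0.5, seed = 73)
  bs <- bindingScore(g$genes, pk$peaks)
  ps <- numeric(40)
  for (s in seq_along(ps)) {
    sim <- genBindingLinkedDe(g$genes, pk$peaks, nUp = 60, nDown = 60,
                              beta = 1, seed = s)  # no dependency
    rp <- regulatoryPotential(bs, sim$table)
    ps[s] <- suppressWarnings(stats::ks.test(rp$rp[rp$direction == "up"],
                                             rp$rp[rp$direction == "down"]))$p.value
  }
  ## up-vs-down KS p-values behave like a null sample: no excess below 0.01
  expect_lte(mean(ps < 0.01), 0.05)
  expect_gt(mean(ps), 0.2)
})

test_that("TSS binding enrichment has unit null and closed-form extreme", {
  g <- genGenome(c(4e6, 2e6), c(protein_coding = 100), seed = 74)
  ids <- geneIds(g$genes)
  sets <- list(X = ids[1:50], Y = ids[51:100])

  ## uniform peaks -> fold about 1
  pk0 <- genPeaks(g$genes, g$layout, 3000, tssBias = 0, seed = 75)
  enr0 <- tssBindingEnrichment(pk0$peaks, sets, g$genes, 5000L, g$layout)
  expect_true(all(abs(enr0 - 1) < 0.35))  # ~3 MC standard errors

  ## all peaks inside set X windows -> fold = genome bp / footprint bp
  win <- 2000L
  tssX <- tssRanges(g$genes[ids[1:50]])
  merged <- GenomicRanges::reduce(suppressWarnings(
    GenomicRanges::trim(tssX + win)))
  set.seed(76)
  pos <- unlist(lapply(seq_along(merged), function(i)
    sample(GenomicRanges::start(merged)[i]:GenomicRanges::end(merged)[i], 4)))
  chroms <- rep(as.character(GenomicRanges::seqnames(merged)), each = 4)
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(pos - 20, pos + 20),
                               seqinfo = g$layout, summit = as.integer(pos))
  gr <- gr[!duplicated(paste(chroms, pos - 20))]
  pkX <- PeakSet(gr)
  enrX <- tssBindingEnrichment(pkX, sets["X"], g$genes, win, g$layout)
  expect_equal(unname(enrX["X"]),
               sum(as.numeric(GenomeInfoDb::seqlengths(g$layout))) /
                 sum(as.numeric(GenomicRanges::width(merged))))

  ## no peaks at all -> fold 0 for every label
  none <- genPeaks(g$genes, g$layout, 0, 0, seed = 1)$peaks
  expect_true(all(tssBindingEnrichment(none, sets, g$genes, win,
                                       g$layout) == 0))
  expect_error(tssBindingEnrichment(pk0$peaks, list(Z = character()),
                                    g$genes, win, g$layout), "empty gene set")
})

test_that("expressed-gene TSS binding out-enriches silenced genes", {
  g <- genGenome(c(6e6), c(protein_coding = 300), seed = 77)
  expr <- genFpkm(g$genes, silencedFraction = 0.4, seed = 77)
  cls <- classifyExpression(expr$fpkm)
  expressed <- cls$gene_id[cls$class == "expressed"]
  ## plant peaks only at expressed-gene TSSs
  pk <- genPeaks(g$genes[expressed], g$layout, 600, tssBias = 1,
                 proximityWindow = 300L, seed = 78)
  enr <- tssBindingEnrichment(pk$peaks, split(cls$gene_id, cls$class),
                              g$genes, 1000L, g$layout)
  expect_gt(enr[["expressed"]], enr[["silenced"]])
  expect_gt(enr[["expressed"]], 2)
})

test_that("regulome classification counts promoter-bound genes per class", {
  ## toy: 10 genes, 4 DE of which 3 bound; 6 static of which 1 bound
  layout <- genomeLayout("chrA", 1e6)
  starts <- seq(50000, by = 80000, length.out = 10)
  g <- GenomicRanges::GRanges("chrA", IRanges::IRanges(starts, width = 5000),
                              strand = "+", seqinfo = layout,
                              gene_id = sprintf("g%02d", 1:10),
                              gene_class = "protein_coding")
  catalog <- GeneCatalog(g)
  cls <- stats::setNames(rep("static", 10), sprintf("g%02d", 1:10))
  cls[1:4] <- c("up", "up", "down", "down")
  ## bind genes 1-3 (DE) and gene 5 (static) at their TSSs
  pk <- peaksAt(starts[c(1, 2, 3, 5)], chrom = "chrA", layout = layout)
  res <- regulomeClassify(pk, catalog, cls, promoterWindow = 1000L)
  expect_equal(unname(res$fractions["up"]), 1)
  expect_equal(unname(res$fractions["down"]), 0.5)
  expect_equal(unname(res$fractions["static"]), 1 / 6)
  expect_equal(nrow(res$regulome), 3)
  expect_setequal(res$regulome$gene_id, c("g01", "g02", "g03"))

  ## no peaks -> all fractions 0, empty regulome
  empty <- genPeaks(catalog, layout, 0, 0, seed = 1)$peaks
  res0 <- regulomeClassify(empty, catalog, cls)
  expect_true(all(res0$fractions == 0))
  expect_equal(nrow(res0$regulome), 0)

  expect_error(regulomeClassify(pk, catalog, cls[1:5]), "cover")
})

test_that("planted DE/static bound-fraction gap is recovered", {
  g <- genGenome(c(6e6), c(protein_coding = 300), seed = 79)
  ids <- geneIds(g$genes)
  set.seed(80)
  deGenes <- sample(ids, 60)
  ## bind 90% of DE genes, 20% of static genes
  boundIds <- c(sample(deGenes, 54), sample(setdiff(ids, deGenes), 48))
  pk <- genPeaks(g$genes[boundIds], g$layout, 2000, tssBias = 1,
                 proximityWindow = 500L, seed = 81)
  cls <- stats::setNames(rep("static", length(ids)), ids)
  cls[deGenes] <- sample(c("up", "down"), 60, replace = TRUE)
  res <- regulomeClassify(pk$peaks, g$genes, cls, promoterWindow = 1000L)
  deFrac <- stats::weighted.mean(res$fractions[c("up", "down")],
                                 c(sum(cls == "up"), sum(cls == "down")))
  ## recovered fractions near the planted 0.9 / 0.2 within binomial CI
  expect_lt(abs(deFrac - 0.9), 0.12)
  expect_lt(abs(res$fractions[["static"]] - 0.2), 0.1)
  expect_gt(deFrac, res$fractions[["static"]])
})
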