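#' Build a validated pipeline configuration
#'
#' Collects every tunable of the synthetic-to-report pipeline: the
#' synthetic genome scale, planted parameters, analysis thresholds and
#' windows, permutation counts, and stage toggles. Every random stage
#' derives its own subseed from the single `seed` by a fixed splitting
#' rule, so a config determines the whole run.
#'
#' @param seed Global integer seed.
#' @param chromLengths Chromosome lengths in bp.
#' @param genesPerClass Named gene counts per class.
#' @param nPeaks,tssBias,proximityWindow Peak generator parameters.
#' @param overlapFraction,nFeatures Feature-set generator parameters.
#' @param rho,binWidth Signal-pair generator parameters.
#' @param vennCounts,oppositeCount,alpha DE-table generator / shortlist
#'   parameters.
#' @param silencedFraction Expression generator parameter.
#' @param nPermutations Overlap-test permutations.
#' @param gap Overlap-test feature expansion in bp.
#' @param promoterWindow,proximalWindow,downstreamWindow Annotation
#'   windows in bp.
#' @param bodyBins,flankBp,flankBins Metagene parameters.
#' @param rpWindow Binding-score half-window W in bp.
#' @param regulomeWindow Promoter window for regulome classification in bp.
#' @param conservationWindow Summit-profile half-window in bp.
#' @param bumpHeight,bumpWidth Conservation-track plant parameters.
#' @param stages Named logical toggles: simulate, shortlist, annotate,
#'   overlap, integrate.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L,
                           chromLengths = c(10e6, 10e6),
                           genesPerClass = c(protein_coding = 1600,
                                             snRNA = 100, snoRNA = 100,
                                             lincRNA = 150, miRNA = 50),
                           nPeaks = 5000L, tssBias = 0.6,
                           proximityWindow = 1000L,
                           overlapFraction = 0.5, nFeatures = 5000L,
                           rho = 0.8, binWidth = 1000L,
                           vennCounts = c(A = 200, C = 200, U = 150,
                                          AC = 46, AU = 20, CU = 20,
                                          ACU = 61),
                           oppositeCount = 21L, alpha = 0.05,
                           silencedFraction = 0.3,
                           nPermutations = 1000L, gap = 0L,
                           promoterWindow = 3000L, proximalWindow = 1000L,
                           downstreamWindow = 3000L,
                           bodyBins = 60L, flankBp = 2000L, flankBins = 20L,
                           rpWindow = 100000L, regulomeWindow = 1000L,
                           conservationWindow = 5000L,
                           bumpHeight = 0.4, bumpWidth = 1000L,
                           stages = c(simulate = TRUE, shortlist = TRUE,
                                      annotate = TRUE, overlap = TRUE,
                                      integrate = TRUE)) {
  cfg <- as.list(environment())
  need <- c("simulate", "shortlist", "annotate", "overlap", "integrate")
  if (!all(need %in% names(cfg$stages)))
    stop("stages must name: ", paste(need, collapse = ", "))
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("an explicit seed is required")
  structure(cfg, class = "PipelineConfig")
}

## order-invariant 64-bit-ish FNV-1a hash of the serialized config
.hashConfig <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic-to-report analysis pipeline
#'
#' Wires the stages together: *simulate* (genome, peaks, feature set,
#' signal pair, conservation track, DE tables, expression), *shortlist*
#' (consensus core regulome), *annotate* (feature assignment, metagene
#' profile, chromosome correlations), *overlap* (randomization overlap
#' test, signal correlation, conservation summit profile), and *integrate*
#' (binding scores, regulatory potential, KS direction test, regulome
#' classification, TSS binding enrichment by expression class). Writes
#' `summary.json`, `tables/*.tsv` and `profiles/*.tsv` under `outDir` and
#' returns the summary invisibly. Deterministic given the config: the same
#' config yields a byte-identical `summary.json`.
#'
#' @param config A [pipelineConfig()].
#' @param outDir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return Invisibly, the summary list (headline statistics per stage plus
#'   the synthetic-truth sidecars and the config hash).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  st <- config$stages
  summary <- list(config_hash = .hashConfig(config), seed = config$seed,
                  stages = as.list(st))
  tables <- list(); profiles <- list()
  sim <- NULL
  if (st[["simulate"]]) {
    genome <- genGenome(config$chromLengths, config$genesPerClass,
                        seed = config$seed)
    pk <- genPeaks(genome$genes, genome$layout, config$nPeaks,
                   config$tssBias, config$proximityWindow,
                   seed = config$seed)
    fs <- genFeatureSet(pk$peaks, genome$layout, config$overlapFraction,
                        config$nFeatures, seed = config$seed)
    sp <- genSignalPair(genome$layout, config$binWidth, config$rho,
                        seed = config$seed)
    cons <- genConservationTrack(genome$layout, 100L, 0.1,
                                 config$bumpHeight, config$bumpWidth,
                                 pk$peaks, seed = config$seed)
    de <- genDeTables(genome$genes, config$vennCounts, config$oppositeCount,
                      alpha = config$alpha, seed = config$seed)
    expr <- genFpkm(genome$genes, config$silencedFraction,
                    seed = config$seed)
    sim <- list(genome = genome, peaks = pk, features = fs, signals = sp,
                conservation = cons, de = de, expr = expr)
    summary$simulate <- list(
      n_genes = length(genome$genes), n_peaks = length(pk$peaks),
      n_features = length(fs$features),
      truth = list(genome = unclass(genome$truth),
                   peaks = unclass(pk$truth),
                   features = unclass(fs$truth),
                   signals = unclass(sp$truth),
                   conservation = unclass(cons$truth),
                   de = unclass(de$truth), expr = unclass(expr$truth)))
  } else summary$simulate <- "skipped"
  .need <- function(stage) {
    if (is.null(sim))
      stop("stage '", stage, "' requires the simulate stage (disabled)")
  }
  if (st[["shortlist"]]) {
    .need("shortlist")
    core <- consensusShortlist(sim$de$tables, alpha = config$alpha)
    summary$shortlist <- writeCoreRegulome(core)
    tables$core_regulome <- data.frame(
      gene_id = shortlistedGenes(core),
      category = rep(c("reproducible", "rescued"),
                     c(length(reproducibleGenes(core)),
                       length(rescuedGenes(core)))),
      direction = unname(shortlistDirections(core)[shortlistedGenes(core)]))
  } else summary$shortlist <- "skipped"
  if (st[["annotate"]]) {
    .need("annotate")
    ann <- assignFeatures(sim$peaks$peaks, sim$genome$genes,
                          annotationConfig(config$promoterWindow,
                                           config$proximalWindow,
                                           config$downstreamWindow))
    mg <- metageneProfile(sim$peaks$peaks, sim$genome$genes,
                          config$bodyBins, config$flankBp, config$flankBins)
    cc <- if (length(seqlengths(sim$genome$layout)) >= 3)
      chromCorrelation(sim$peaks$peaks, sim$genome$genes, sim$genome$layout)
    else list(rGenes = "undefined (needs >= 3 chromosomes)",
              rLength = "undefined (needs >= 3 chromosomes)")
    summary$annotate <- list(
      percentages = as.list(ann$percentages),
      promoter_proximal_fraction = ann$promoterProximalFraction,
      r_genes = cc$rGenes, r_length = cc$rLength)
    tables$annotation <- data.frame(category = names(ann$counts),
                                    count = unname(ann$counts),
                                    percentage = unname(ann$percentages))
    profiles$metagene <- data.frame(bin = mg$bin,
                                    region = as.character(mg$region),
                                    value = mg$values)
  } else summary$annotate <- "skipped"
  if (st[["overlap"]]) {
    .need("overlap")
    ot <- randomizedOverlapTest(sim$peaks$peaks, sim$features$features,
                                sim$genome$layout, config$nPermutations,
                                config$gap, seed = config$seed)
    sc <- signalCorrelation(sim$signals$trackA, sim$signals$trackB)
    prof <- profileAroundSummits(sim$conservation$track, sim$peaks$peaks,
                                 config$conservationWindow)
    summary$overlap <- list(
      observed_fraction = ot@observed, z_score = ot@zScore,
      p_value = ot@pValue, perm_mean = ot@permMean, perm_sd = ot@permSd,
      signal_correlation = sc, conservation_fwhm = profileFwhm(prof))
    profiles$conservation <- data.frame(offset = prof$offsets,
                                        value = prof$values)
  } else summary$overlap <- "skipped"
  if (st[["integrate"]]) {
    .need("integrate")
    bs <- bindingScore(sim$genome$genes, sim$peaks$peaks, config$rpWindow)
    rp <- regulatoryPotential(bs, sim$de$tables$NC_vs_A, config$alpha)
    ks <- tryCatch(ksDirectionTest(rp), error = function(e) NULL)
    cls <- stats::setNames(rp$direction, rp$gene_id)
    rc <- regulomeClassify(sim$peaks$peaks, sim$genome$genes, cls,
                           config$regulomeWindow)
    ec <- classifyExpression(sim$expr$fpkm)
    sets <- split(ec$gene_id, ec$class)
    enr <- tssBindingEnrichment(sim$peaks$peaks, sets, sim$genome$genes,
                                config$regulomeWindow, sim$genome$layout)
    summary$integrate <- list(
      ks = if (is.null(ks)) "undefined (empty class)" else list(
        up_d = ks$up$D, up_p = ks$up$pValue,
        down_d = ks$down$D, down_p = ks$down$pValue,
        down_stronger_fraction = ks$downStrongerFraction),
      bound_fractions = as.list(rc$fractions),
      regulome_size = nrow(rc$regulome),
      tss_enrichment = as.list(enr))
    tables$regulatory_potential <- rp
    tables$regulome <- rc$regulome
  } else summary$integrate <- "skipped"
  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "tables"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outDir, "profiles"), recursive = TRUE,
               showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(tables))
      utils::write.table(tables[[nm]],
                         file.path(outDir, "tables", paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(profiles))
      utils::write.table(profiles[[nm]],
                         file.path(outDir, "profiles", paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(summary)
}
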