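#' Classify genes as expressed or silenced from replicate FPKM values
#'
#' A gene is *expressed* when its FPKM exceeds zero in at least one of the
#' three biological replicates and *silenced* when FPKM is zero in all
#' three; the two classes partition the gene universe.
#'
#' @param fpkm Numeric matrix (genes x 3 replicates), rownames = gene ids,
#'   all values nonnegative.
#' @return Data frame `gene_id, class` with `class` in
#'   `{expressed, silenced}`.
#' @export
classifyExpression <- function(fpkm) {
  if (is.null(dim(fpkm)) || ncol(fpkm) != 3L)
    stop("'fpkm' must be a genes x 3 replicate matrix")
  if (any(fpkm < 0)) stop("FPKM values must be nonnegative")
  data.frame(gene_id = rownames(fpkm),
             class = ifelse(rowSums(fpkm > 0) >= 1L, "expressed", "silenced"))
}

#' Distance-decay binding score around gene TSSs
#'
#' For each gene, every peak whose summit lies within `window` bp of the
#' TSS contributes `exp(-(0.5 + 4 * Delta))`, where
#' `Delta = |summit - TSS| / window` is the normalized distance in [0, 1];
#' the gene's binding score is the sum over its k in-window peaks. A peak
#' at the TSS contributes `exp(-0.5)`; the score is monotone in both peak
#' proximity and peak count.
#'
#' @param genes A [GeneCatalog-class].
#' @param peaks A [PeakSet-class].
#' @param window Half-window W in bp (default 100000); `Delta` is
#'   normalized by this same W so the decay is dimensionless.
#' @return Data frame `gene_id, k, s_binding`.
#' @examples
#' ## a single peak at the TSS scores exp(-0.5) = 0.6065...
#' @export
bindingScore <- function(genes, peaks, window = 100000L) {
  if (window <= 0) stop("'window' must be positive")
  tssW <- .expandTrim(tssRanges(genes), window)
  su <- summitRanges(peaks)
  hits <- findOverlaps(tssW, su, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(hits)
  delta <- abs(start(su)[S4Vectors::subjectHits(hits)] -
               tssSites(genes)[gi]) / window
  keep <- delta <= 1  # trim() can leave windows asymmetric at chromosome ends
  contrib <- exp(-(0.5 + 4 * delta[keep]))
  n <- length(genes)
  s <- numeric(n); k <- integer(n)
  if (any(keep)) {
    agg <- rowsum(contrib, gi[keep])
    cnt <- table(gi[keep])
    s[as.integer(rownames(agg))] <- agg[, 1]
    k[as.integer(names(cnt))] <- as.integer(cnt)
  }
  data.frame(gene_id = geneIds(genes), k = k, s_binding = s)
}

#' Rank-product regulatory potential
#'
#' Combines binding evidence with differential-expression significance:
#' binding scores are ranked descending (rank 1 = strongest binding) and
#' DE q-values ascending (rank 1 = most significant), ties receiving
#' average ranks; the regulatory potential is the product of the two
#' normalized ranks, `RP = (rank_binding / n) * (rank_DE / n)`, in (0, 1],
#' with smaller values meaning stronger evidence of regulation. Each gene
#' also carries a direction class from its DE row: `up`/`down` when
#' q < `alpha` (by fold-change sign), else `static`. q-values of exactly 0
#' are clamped to the smallest positive double before ranking (rank-based,
#' so only the tie structure matters).
#'
#' @param scores Data frame from [bindingScore()] (`gene_id, s_binding`).
#' @param de DE table (`gene_id, log2fc, qvalue`) over the same genes.
#' @param alpha Significance level for the direction class (default 0.05).
#' @return Data frame `gene_id, s_binding, qvalue, rank_binding, rank_de,
#'   rp, direction`.
#' @export
regulatoryPotential <- function(scores, de, alpha = 0.05) {
  miss <- union(setdiff(scores$gene_id, de$gene_id),
                setdiff(de$gene_id, scores$gene_id))
  if (length(miss))
    stop("gene(s) missing from one input: ",
         paste(utils::head(miss, 5), collapse = ", "))
  de <- de[match(scores$gene_id, de$gene_id), ]
  n <- nrow(scores)
  q <- pmax(de$qvalue, .Machine$double.xmin)
  rankB <- rank(-scores$s_binding, ties.method = "average")
  rankD <- rank(q, ties.method = "average")
  sig <- de$qvalue < alpha
  direction <- ifelse(!sig, "static", ifelse(de$log2fc > 0, "up", "down"))
  data.frame(gene_id = scores$gene_id, s_binding = scores$s_binding,
             qvalue = de$qvalue, rank_binding = rankB, rank_de = rankD,
             rp = (rankB / n) * (rankD / n), direction = direction)
}

#' Kolmogorov-Smirnov test of activating versus repressive action
#'
#' Compares the regulatory-potential distributions of up- and
#' down-regulated genes against the static (not significantly changed)
#' genes with two-sample two-sided KS tests, and reports the fraction of
#' down-regulated genes whose RP is stronger (smaller) than the median RP
#' of the up-regulated genes. Cumulative-fraction curves are returned for
#' plotting.
#'
#' @param records Data frame from [regulatoryPotential()].
#' @return List of class `KSDirectionResult`: `up` and `down` (each with
#'   `D` and `pValue` vs static), `downStrongerFraction`, `curves` (data
#'   frame `rp, cumulative_fraction, direction`).
#' @export
ksDirectionTest <- function(records) {
  rpBy <- split(records$rp, records$direction)
  for (cl in c("up", "down", "static"))
    if (!length(rpBy[[cl]])) stop("empty direction class: ", cl)
  ksUp <- suppressWarnings(stats::ks.test(rpBy$up, rpBy$static))
  ksDown <- suppressWarnings(stats::ks.test(rpBy$down, rpBy$static))
  frac <- mean(rpBy$down < stats::median(rpBy$up))
  curves <- do.call(rbind, lapply(names(rpBy), function(cl) {
    x <- sort(rpBy[[cl]])
    data.frame(rp = x, cumulative_fraction = seq_along(x) / length(x),
               direction = cl)
  }))
  structure(list(up = list(D = unname(ksUp$statistic),
                           pValue = ksUp$p.value),
                 down = list(D = unname(ksDown$statistic),
                             pValue = ksDown$p.value),
                 downStrongerFraction = frac, curves = curves),
            class = "KSDirectionResult")
}

#' Fold enrichment of summits near the TSSs of gene sets
#'
#' For each labelled gene set, merges the TSS +/- `window` windows of its
#' members, counts peak summits per bp of that merged footprint, and
#' divides by the genome-background summit density (total summits per bp
#' of genome, the uniform background model).
#'
#' @param peaks A [PeakSet-class].
#' @param geneSets Named list of gene-id character vectors.
#' @param genes A [GeneCatalog-class] providing the TSS anchors.
#' @param window TSS half-window in bp (default 1000).
#' @param layout `Seqinfo`.
#' @return Named numeric vector of fold enrichments (0 everywhere when
#'   there are no peaks).
#' @export
tssBindingEnrichment <- function(peaks, geneSets, genes, window = 1000L,
                                 layout = seqinfo(geneRanges(genes))) {
  if (window <= 0) stop("'window' must be positive")
  su <- summitRanges(peaks)
  total <- length(su)
  genomeBp <- sum(as.numeric(seqlengths(layout)))
  bg <- total / genomeBp
  tss <- tssRanges(genes)
  ids <- geneIds(genes)
  vapply(geneSets, function(set) {
    if (!length(set)) stop("empty gene set")
    idx <- match(set, ids)
    if (anyNA(idx)) stop("gene set contains unknown ids")
    merged <- reduce(.expandTrim(tss[idx], window))
    obs <- sum(countOverlaps(merged, su)) / sum(as.numeric(width(merged)))
    if (total == 0) 0 else obs / bg
  }, numeric(1))
}

#' Promoter-binding fractions per DE class and the bound regulome
#'
#' For each differential-expression class (`up`, `down`, `static` -- a
#' partition of the gene universe), the fraction of genes with at least
#' one peak summit within `promoterWindow` bp of their own TSS. The
#' regulome is the set of bound, differentially expressed genes, returned
#' with direction labels.
#'
#' @param peaks A [PeakSet-class].
#' @param genes A [GeneCatalog-class].
#' @param deClasses Named character vector (gene id -> class in
#'   `{up, down, static}`) partitioning the catalog's genes.
#' @param promoterWindow TSS half-window in bp (default 1000).
#' @return List with `fractions` (named numeric per class), `regulome`
#'   (data frame `gene_id, direction`), `boundGenes` (character).
#' @export
regulomeClassify <- function(peaks, genes, deClasses, promoterWindow = 1000L) {
  ids <- geneIds(genes)
  if (!setequal(names(deClasses), ids))
    stop("deClasses must cover the gene universe exactly")
  if (anyDuplicated(names(deClasses)))
    stop("deClasses assigns a gene to more than one class")
  cls <- deClasses[ids]
  if (!all(cls %in% c("up", "down", "static")))
    stop("classes must be 'up', 'down' or 'static'")
  bound <- IRanges::overlapsAny(.expandTrim(tssRanges(genes), promoterWindow),
                                summitRanges(peaks))
  fractions <- vapply(c(up = "up", down = "down", static = "static"),
                      function(cl) {
    sel <- cls == cl
    if (!any(sel)) NA_real_ else mean(bound[sel])
  }, numeric(1))
  inReg <- bound & cls != "static"
  list(fractions = fractions,
       regulome = data.frame(gene_id = ids[inReg],
                             direction = unname(cls[inReg])),
       boundGenes = ids[bound])
}
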