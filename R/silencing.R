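# Gene-silencing classification during differentiation relative to Setdb1
# peaks, class-level knockdown comparisons, repeat-class enrichment, and the
# 2^-ddCt qRT-PCR formula.

#' Reads per kilobase per million mapped reads
#'
#' @param counts numeric vector/matrix of gene read counts (genes x samples)
#' @param lengthsBp gene exonic lengths in bp
#' @param librarySizes total mapped reads per sample
#' @return RPKM of the same shape: count / (length_kb x library_millions)
#' @export
rpkm <- function(counts, lengthsBp, librarySizes) {
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  if (any(lengthsBp <= 0)) stop("gene lengths must be positive")
  counts <- as.matrix(counts)
  t(t(counts / (lengthsBp / 1e3)) / (librarySizes / 1e6))
}

#' Classify genes by silencing behaviour relative to Setdb1 peaks
#'
#' Applied to replicate-averaged control (Nons) expression at day 0 / 3 / 5:
#' \itemize{
#'   \item maintained_silent: expression below `silentBelow` at every
#'     timepoint;
#'   \item silenced_d0_d3 / silenced_d3_d5: log2((prev + pc)/(next + pc)) >
#'     `silencedLfc` over the interval AND the gene body lies within
#'     `proximityBp` of a Setdb1 peak edge (0 if overlapping); the earlier
#'     interval takes precedence;
#'   \item stable: max pairwise |log2FC| across timepoints < `stableLfc`;
#'   \item unclassified otherwise (including genes missing a timepoint,
#'     which are logged).
#' }
#' Precedence: maintained_silent > silenced > stable, so every gene gets
#' exactly one label.
#'
#' @param expr data.frame/matrix: rows = genes (rownames = gene ids), columns
#'   `day0`, `day3`, `day5` of replicate-averaged Nons expression
#' @param genes `GRanges` with `gene_id` (gene bodies)
#' @param setdb1Peaks `GRanges` of Setdb1 peaks
#' @param proximityBp peak-proximity rule in bp, default 200 kb
#' @param silencedLfc,stableLfc,silentBelow rule thresholds (2, 0.5, 0.5)
#' @param pc pseudocount for fold changes, default 0.1 expression units
#' @return data.frame: gene_id, class, dist_setdb1 (bp, NA if no peaks)
#' @export
classifyGenes <- function(expr, genes, setdb1Peaks, proximityBp = 200000,
                          silencedLfc = 2, stableLfc = 0.5, silentBelow = 0.5,
                          pc = 0.1) {
  expr <- as.data.frame(expr)
  .assertCols(expr, c("day0", "day3", "day5"))
  ids <- rownames(expr)
  m <- match(ids, genes$gene_id)
  dist <- rep(NA_real_, length(ids))
  if (length(setdb1Peaks)) {
    ok <- !is.na(m)
    dist[ok] <- suppressWarnings(
      distance(genes[m[ok]], setdb1Peaks[GenomicRanges::nearest(
        genes[m[ok]], setdb1Peaks)]))
  }
  proximal <- !is.na(dist) & dist <= proximityBp

  lfc <- function(a, b) log2((a + pc) / (b + pc))
  e0 <- expr$day0; e3 <- expr$day3; e5 <- expr$day5
  missing_ <- !stats::complete.cases(expr[, c("day0", "day3", "day5")])
  if (any(missing_)) xiLog("classifyGenes: %d genes missing a timepoint",
                           sum(missing_))
  maintained <- e0 < silentBelow & e3 < silentBelow & e5 < silentBelow
  sil03 <- lfc(e0, e3) > silencedLfc & proximal
  sil35 <- lfc(e3, e5) > silencedLfc & proximal
  maxAbs <- pmax(abs(lfc(e0, e3)), abs(lfc(e3, e5)), abs(lfc(e0, e5)))
  stable <- maxAbs < stableLfc

  class <- rep("unclassified", length(ids))
  class[stable] <- "stable"
  class[sil35] <- "silenced_d3_d5"
  class[sil03] <- "silenced_d0_d3"
  class[maintained] <- "maintained_silent"
  class[missing_] <- "unclassified"
  data.frame(gene_id = ids, class = class, dist_setdb1 = dist,
             stringsAsFactors = FALSE)
}

#' Compare knockdown vs control expression within silencing classes
#'
#' Per class and differentiation interval, reports mean expression under each
#' condition at the interval's end timepoint and a two-tailed t test
#' (knockdown vs Nons across the class's genes, on log2(expr + pc)).
#'
#' @param exprNons,exprKd data.frames: rows = genes (shared rownames),
#'   columns `day0`, `day3`, `day5`
#' @param classes data.frame from [classifyGenes()]
#' @param pc pseudocount, default 0.1
#' @return data.frame: class, interval, n_genes, mean_nons, mean_kd, p_value,
#'   flag ("too_few" for classes with < 2 genes)
#' @export
compareClasses <- function(exprNons, exprKd, classes, pc = 0.1) {
  shared <- intersect(rownames(exprNons), rownames(exprKd))
  res <- list()
  for (cl in unique(classes$class)) {
    gids <- intersect(classes$gene_id[classes$class == cl], shared)
    for (iv in c("d0_d3", "d3_d5")) {
      tp <- if (iv == "d0_d3") "day3" else "day5"
      a <- log2(exprNons[gids, tp] + pc)
      b <- log2(exprKd[gids, tp] + pc)
      tt <- .safeT(a, b)
      res[[length(res) + 1L]] <- data.frame(
        class = cl, interval = iv, n_genes = length(gids),
        mean_nons = mean(exprNons[gids, tp]),
        mean_kd = mean(exprKd[gids, tp]),
        p_value = tt$p, flag = tt$flag, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Repeat-class enrichment among differentially expressed repeats
#'
#' A repeat is differentially expressed iff |log2((kd + pc)/(nons + pc))| >
#' `threshold` on replicate-averaged expression. The class x {DE, not-DE}
#' contingency table is tested for independence with a chi-square test;
#' per-class standardized residuals localise the enrichment.
#'
#' @param repeats data.frame: repeat_id, repClass, nons, kd
#'   (replicate-averaged expression)
#' @param threshold |log2FC| cutoff, default 1
#' @param pc pseudocount, default 0.1
#' @return list: `de` (input with log2fc, de flag), `table` (contingency),
#'   `p_value`, `stdres` (standardized residuals), `warning` (set when > 20%
#'   of expected cells are < 1, suggesting an exact-test fallback)
#' @export
repeatDe <- function(repeats, threshold = 1, pc = 0.1) {
  .assertCols(repeats, c("repClass", "nons", "kd"))
  repeats$log2fc <- log2((repeats$kd + pc) / (repeats$nons + pc))
  repeats$de <- abs(repeats$log2fc) > threshold
  tab <- table(class = repeats$repClass, de = factor(repeats$de,
                                                     c(FALSE, TRUE),
                                                     c("notDE", "DE")))
  warn <- NULL
  if (length(unique(repeats$de)) < 2L || nrow(tab) < 2L) {
    return(list(de = repeats, table = tab, p_value = 1, stdres = NULL,
                warning = "degenerate table: all repeats in one DE group"))
  }
  ct <- suppressWarnings(chisq.test(tab))
  if (mean(ct$expected < 1) > 0.2) {
    warn <- "more than 20% of expected cells < 1; consider an exact test"
    xiLog("repeatDe: %s", warn)
  }
  list(de = repeats, table = tab, p_value = ct$p.value,
       stdres = ct$stdres, warning = warn)
}

#' Relative expression by the 2^-ddCt method
#'
#' dCt = Ct_target - Ct_housekeeping per sample (for several housekeeping
#' genes, their Ct values enter as an arithmetic mean of dCt, i.e. a
#' geometric-mean reference); relative expression = 2^-(dCt_sample - dCt_ref).
#'
#' @param ctTarget named numeric of target-gene Ct per sample
#' @param ctHousekeeping numeric vector (same samples) or matrix (samples x
#'   housekeeping genes)
#' @param reference name/index of the reference sample
#' @return named numeric of fold changes relative to `reference` (which is 1)
#' @export
ddct <- function(ctTarget, ctHousekeeping, reference = 1L) {
  hk <- if (is.matrix(ctHousekeeping)) rowMeans(ctHousekeeping) else ctHousekeeping
  stopifnot(all(is.finite(ctTarget)), all(is.finite(hk)),
            length(hk) == length(ctTarget))
  dct <- ctTarget - hk
  2^(-(dct - dct[[reference]]))
}
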