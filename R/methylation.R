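# eRRBS differential methylation: coverage filtering, per-CpG replicate
# t tests, Xi-vs-Xa log2(mC/C) contrast, CGI-level calls and CGI-length-
# normalized profiles.

.addMethDerived <- function(sites) {
  sites$coverage <- sites$meth_count + sites$unmeth_count
  sites$pct_mc <- ifelse(sites$coverage > 0,
                         100 * sites$meth_count / sites$coverage, NA_real_)
  sites
}

#' Filter CpG sites by coverage
#'
#' Retains CpGs covered by more than `minCoverageExclusive` reads (strict:
#' coverage 20 is removed, 21 retained, at the default).
#'
#' @param sites data.frame with `meth_count`, `unmeth_count` (and typically
#'   chrom, pos, allele, condition, replicate)
#' @param minCoverageExclusive exclusive lower bound on coverage, default 20
#' @return surviving rows with `coverage` and `pct_mc` columns appended
#' @export
filterCpgs <- function(sites, minCoverageExclusive = 20) {
  .assertCols(sites, c("meth_count", "unmeth_count"))
  sites <- .addMethDerived(sites)
  keep <- sites$coverage > minCoverageExclusive
  out <- sites[keep, , drop = FALSE]
  if ("condition" %in% names(sites)) {
    for (cond in unique(sites$condition)) {
      xiLog("filterCpgs[%s]: kept %d of %d", cond,
            sum(out$condition == cond), sum(sites$condition == cond))
    }
  }
  xiLog("filterCpgs: kept %d of %d sites (coverage > %g)",
        nrow(out), nrow(sites), minCoverageExclusive)
  out
}

#' Per-CpG differential methylation across replicates
#'
#' For every CpG with at least `minReps` replicates in each condition, the
#' per-replicate %mC values are compared with a two-tailed t test (Welch by
#' default). Significant iff p < alpha; direction is the sign of the
#' (condition B - condition A) mean difference.
#'
#' @param sites filtered sites from [filterCpgs()] with columns chrom, pos,
#'   condition, replicate, pct_mc (allele-restricted upstream if desired)
#' @param conditionA,conditionB condition labels (A = control)
#' @param alpha significance threshold (no multiple-testing correction, the
#'   workflow's convention; apply [stats::p.adjust()] downstream if wanted)
#' @param minReps minimum replicates per condition, default 2
#' @param pooledVar pooled-variance t instead of Welch
#' @return data.frame: chrom, pos, mean_a, mean_b, delta (B - A), p_value,
#'   significant, direction ("gain"/"loss"/"none"), flag. CpGs with too few
#'   replicates are excluded (logged); zero-variance-both-sides CpGs get
#'   p = 1 when means agree and are flagged "degenerate" (p = 0 limit)
#'   otherwise.
#' @export
differentialCpgs <- function(sites, conditionA, conditionB, alpha = 0.05,
                             minReps = 2L, pooledVar = FALSE) {
  .assertCols(sites, c("chrom", "pos", "condition", "replicate", "pct_mc"))
  sites <- sites[sites$condition %in% c(conditionA, conditionB), ]
  dt <- data.table::as.data.table(sites)
  agg <- dt[, list(
    n_a = sum(condition == conditionA),
    n_b = sum(condition == conditionB)), by = c("chrom", "pos")]
  ok <- agg$n_a >= minReps & agg$n_b >= minReps
  xiLog("differentialCpgs: %d of %d CpGs have >= %d replicates per condition",
        sum(ok), nrow(agg), minReps)
  keyOk <- paste(agg$chrom[ok], agg$pos[ok])
  sites <- sites[paste(sites$chrom, sites$pos) %in% keyOk, ]
  dt <- data.table::as.data.table(sites)
  wide <- data.table::dcast(dt, chrom + pos ~ condition + replicate,
                            value.var = "pct_mc")
  condOf <- sub("_[0-9]+$", "", names(wide)[-(1:2)])
  mA <- as.matrix(wide[, which(condOf == conditionA) + 2L, with = FALSE])
  mB <- as.matrix(wide[, which(condOf == conditionB) + 2L, with = FALSE])
  tt <- lapply(seq_len(nrow(wide)), function(i) {
    .safeT(mA[i, ], mB[i, ], pooled = pooledVar)
  })
  out <- data.frame(chrom = wide$chrom, pos = wide$pos,
                    mean_a = rowMeans(mA, na.rm = TRUE),
                    mean_b = rowMeans(mB, na.rm = TRUE),
                    p_value = vapply(tt, `[[`, 0, "p"),
                    flag = vapply(tt, `[[`, "", "flag"),
                    stringsAsFactors = FALSE)
  out$delta <- out$mean_b - out$mean_a
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$delta > 0, "gain", "loss"))
  xiLog("differentialCpgs: %d significant at alpha=%g (%d gain, %d loss)",
        sum(out$significant), alpha, sum(out$direction == "gain"),
        sum(out$direction == "loss"))
  out
}

#' Xi-vs-Xa methylation contrast as log2(mC/C)
#'
#' Computes per-CpG log2((meth + 1) / (unmeth + 1)) (pseudocounts avoid
#' zeros; disable with `pseudocount = 0` when counts are never zero),
#' summarises the distribution per allele and condition (the median is the
#' reference line in the source display), and tests the condition contrast
#' within each allele with a two-tailed t test.
#'
#' @param sites filtered sites with columns allele, condition, meth_count,
#'   unmeth_count (restrict to X CGI CpGs upstream)
#' @param conditionA,conditionB condition labels
#' @param pseudocount added to both counts, default 1
#' @return list: `summary` (data.frame allele, condition, n, median, mean),
#'   `tests` (per allele: p-value of A vs B on log2 ratios), `values`
#'   (input with `log2_ratio` appended)
#' @export
xiXaContrast <- function(sites, conditionA, conditionB, pseudocount = 1) {
  .assertCols(sites, c("allele", "condition", "meth_count", "unmeth_count"))
  if (!any(sites$allele == "Xi")) stop("no Xi-assigned CpGs")
  sites$log2_ratio <- log2((sites$meth_count + pseudocount) /
                           (sites$unmeth_count + pseudocount))
  sum_ <- do.call(rbind, lapply(split(
    sites, list(sites$allele, sites$condition), drop = TRUE), function(d) {
      data.frame(allele = d$allele[1L], condition = d$condition[1L],
                 n = nrow(d), median = median(d$log2_ratio),
                 mean = mean(d$log2_ratio), stringsAsFactors = FALSE)
    }))
  rownames(sum_) <- NULL
  tests <- vapply(unique(sites$allele), function(al) {
    a <- sites$log2_ratio[sites$allele == al & sites$condition == conditionA]
    b <- sites$log2_ratio[sites$allele == al & sites$condition == conditionB]
    .safeT(a, b)$p
  }, 0)
  list(summary = sum_, tests = tests, values = sites)
}

#' CGI-level differential methylation calls
#'
#' Pools the per-replicate %mC of all member CpGs per CGI, tests condition A
#' vs B two-tailed, and classes each CGI from its control mean: methylated
#' iff mean %mC > 20 (strict). A CGI is called reduced iff significant with
#' a negative (B - A) mean difference.
#'
#' @param sites filtered sites (chrom, pos, condition, replicate, pct_mc)
#' @param cgis `GRanges` of CGI intervals
#' @param conditionA,conditionB condition labels (A = control)
#' @param alpha significance threshold
#' @param methylatedAbove class boundary on control %mC (strict >), default 20
#' @return data.frame: cgi index/coords, n_cpgs, mean_a, mean_b, p_value,
#'   class, reduced; CGIs with 0 passing CpGs keep n_cpgs = 0 and NA test
#' @export
cgiCalls <- function(sites, cgis, conditionA, conditionB, alpha = 0.05,
                     methylatedAbove = 20) {
  .assertCols(sites, c("chrom", "pos", "condition", "pct_mc"))
  gr <- positionsToGRanges(sites$chrom, sites$pos)
  ov <- findOverlaps(gr, cgis)
  res <- lapply(seq_along(cgis), function(i) {
    d <- sites[queryHits(ov)[subjectHits(ov) == i], , drop = FALSE]
    nC <- length(unique(d$pos))
    if (nC == 0L) {
      return(data.frame(cgi = i, chrom = as.character(seqnames(cgis))[i],
                        start = start(cgis)[i], end = end(cgis)[i],
                        n_cpgs = 0L, mean_a = NA_real_, mean_b = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    a <- d$pct_mc[d$condition == conditionA]
    b <- d$pct_mc[d$condition == conditionB]
    data.frame(cgi = i, chrom = as.character(seqnames(cgis))[i],
               start = start(cgis)[i], end = end(cgis)[i],
               n_cpgs = nC, mean_a = mean(a), mean_b = mean(b),
               p_value = .safeT(a, b)$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$class <- ifelse(!is.na(out$mean_a) & out$mean_a > methylatedAbove,
                      "methylated", "unmethylated")
  out$reduced <- !is.na(out$p_value) & out$p_value < alpha &
    out$mean_b < out$mean_a
  xiLog("cgiCalls: %d of %d CGIs significantly reduced at alpha=%g",
        sum(out$reduced), nrow(out), alpha)
  out
}

#' Average %mC along length-normalized CGIs
#'
#' Maps each CpG to its relative position (pos - start)/(end - start) within
#' its CGI and averages %mC in `nPositions` equal relative-width bins across
#' CGIs, per condition. CGIs with fewer than 2 distinct CpGs are skipped.
#'
#' @param sites filtered sites (chrom, pos, condition, pct_mc)
#' @param cgis `GRanges`
#' @param nPositions number of relative bins, default 100
#' @return data.frame: condition, rel_pos (bin midpoint), mean_pct_mc, n
#' @export
cgiMetaProfile <- function(sites, cgis, nPositions = 100) {
  .assertCols(sites, c("chrom", "pos", "condition", "pct_mc"))
  gr <- positionsToGRanges(sites$chrom, sites$pos)
  ov <- findOverlaps(gr, cgis)
  d <- sites[queryHits(ov), , drop = FALSE]
  ci <- subjectHits(ov)
  nDistinct <- tapply(d$pos, ci, function(p) length(unique(p)))
  ok <- as.integer(names(nDistinct))[nDistinct >= 2L]
  if (length(ok) < length(nDistinct)) {
    xiLog("cgiMetaProfile: %d single-CpG CGIs skipped",
          length(nDistinct) - length(ok))
  }
  keep <- ci %in% ok
  d <- d[keep, , drop = FALSE]; ci <- ci[keep]
  rel <- (d$pos - start(cgis)[ci]) / (end(cgis)[ci] - start(cgis)[ci])
  bin <- pmin(pmax(ceiling(rel * nPositions), 1L), nPositions)
  agg <- stats::aggregate(d$pct_mc,
                          by = list(condition = d$condition, bin = bin),
                          FUN = function(x) c(mean(x), length(x)))
  data.frame(condition = agg$condition,
             rel_pos = (agg$bin - 0.5) / nPositions,
             mean_pct_mc = agg$x[, 1], n = agg$x[, 2])
}
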