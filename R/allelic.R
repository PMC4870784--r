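# Allele-specific RNA-seq analyses: Xi/Xa ratios, the rule-based reactivation
# classifier, informative-SNP calling in the PGK MEF system, and gene-level
# allelic exact testing.

#' Filter allelic SNP counts
#'
#' Retains exonic SNPs covered by at least `minTotal` reads in the sample
#' (xi + xa), applied per SNP-sample pair.
#'
#' @param counts data.frame with columns `xi_count`, `xa_count`, `exonic`
#' @param minTotal minimum total coverage (inclusive), default 10
#' @param exonicOnly require the exonic flag
#' @return the surviving rows; survivor counts are logged
#' @export
filterSnps <- function(counts, minTotal = 10, exonicOnly = TRUE) {
  .assertCols(counts, c("xi_count", "xa_count"))
  keep <- (counts$xi_count + counts$xa_count) >= minTotal
  if (exonicOnly) {
    .assertCols(counts, "exonic")
    keep <- keep & counts$exonic
  }
  out <- counts[keep, , drop = FALSE]
  xiLog("filterSnps: kept %d of %d records (minTotal=%g, exonicOnly=%s)",
        nrow(out), nrow(counts), minTotal, exonicOnly)
  out
}

#' Xi/Xa expression ratio with pseudocount
#'
#' ratio = (xi + 1) / (xa + 1); the added 1 avoids division by zero.
#'
#' @param counts filtered allelic counts (see [filterSnps()])
#' @return `counts` with columns `total` and `ratio` appended
#' @export
xiXaRatio <- function(counts) {
  .assertCols(counts, c("xi_count", "xa_count"))
  counts$total <- counts$xi_count + counts$xa_count
  counts$ratio <- (counts$xi_count + 1) / (counts$xa_count + 1)
  counts
}

#' Classify reactivating SNPs under Setdb1 knockdown
#'
#' A SNP is reactivating in a replicate iff its Xi/Xa ratio is strictly larger
#' under both knockdown hairpins than under the non-silencing control at the
#' tested timepoint; ties fail. The consensus set contains SNPs reactivating
#' in every replicate. SNPs missing any of the three conditions in a replicate
#' are excluded from that replicate (and logged).
#'
#' @param ratios data.frame from [xiXaRatio()] with columns `chrom`, `pos`,
#'   `gene_id`, `condition`, `timepoint`, `replicate`, `ratio`
#' @param nons,sh4,sh6 condition labels
#' @param timepoint timepoint at which reactivation is assessed
#' @return list with `calls` (per replicate: chrom, pos, gene_id, replicate,
#'   is_reactivating) and `consensus` (data.frame chrom, pos, gene_id of SNPs
#'   reactivating in all replicates)
#' @export
classifyReactivating <- function(ratios, nons = "Nons", sh4 = "shSetdb1.4",
                                 sh6 = "shSetdb1.6", timepoint = "day5") {
  .assertCols(ratios, c("chrom", "pos", "condition", "timepoint",
                        "replicate", "ratio"))
  keep <- ratios$timepoint == timepoint & ratios$condition %in% c(nons, sh4, sh6)
  dt <- data.table::as.data.table(ratios[keep, , drop = FALSE])
  hasGene <- "gene_id" %in% names(dt)
  idcols <- c("chrom", "pos", if (hasGene) "gene_id", "replicate")
  wide <- data.table::dcast(dt, formula = stats::as.formula(
    paste(paste(idcols, collapse = " + "), "~ condition")),
    value.var = "ratio")
  complete <- stats::complete.cases(wide[, c(nons, sh4, sh6), with = FALSE])
  xiLog("classifyReactivating: %d of %d SNP-replicates have all 3 conditions",
        sum(complete), nrow(wide))
  wide <- wide[complete]
  wide$is_reactivating <- wide[[sh4]] > wide[[nons]] & wide[[sh6]] > wide[[nons]]
  calls <- as.data.frame(wide[, c(idcols, "is_reactivating"), with = FALSE])
  # consensus is over every replicate in the experiment: a SNP unscorable in
  # a replicate (missing condition) cannot be consensus-reactivating
  reps <- sort(unique(dt$replicate))
  cd <- data.table::as.data.table(calls)
  agg <- cd[, list(n_rep = data.table::uniqueN(replicate),
                   n_pos = sum(is_reactivating)),
            by = c("chrom", "pos", if (hasGene) "gene_id")]
  cons <- as.data.frame(agg[agg$n_rep == length(reps) & agg$n_pos == agg$n_rep,
                            c("chrom", "pos", if (hasGene) "gene_id"),
                            with = FALSE])
  xiLog("classifyReactivating: %d consensus reactivating SNPs across %d replicates",
        nrow(cons), length(reps))
  list(calls = calls, consensus = cons)
}

#' Per-replicate reactivating gene sets and their intersection
#'
#' A gene belongs to a replicate's set iff at least one of its SNPs is
#' reactivating in that replicate. Also reports the intersection across
#' replicates and its fraction of all SNP-containing genes.
#'
#' @param calls per-replicate calls from [classifyReactivating()]
#' @param snpGenes character vector of all genes with at least one filtered
#'   SNP (the denominator universe)
#' @return list: `perReplicate` (named list of gene id vectors),
#'   `intersection`, `sizes`, `fractionOfSnpGenes`
#' @export
reactivatingGenes <- function(calls, snpGenes) {
  .assertCols(calls, c("gene_id", "replicate", "is_reactivating"))
  reps <- sort(unique(calls$replicate))
  perRep <- lapply(reps, function(r) {
    sort(unique(calls$gene_id[calls$replicate == r & calls$is_reactivating]))
  })
  names(perRep) <- paste0("replicate_", reps)
  inter <- Reduce(intersect, perRep)
  list(perReplicate = perRep,
       intersection = inter,
       sizes = c(vapply(perRep, length, 0L), intersection = length(inter)),
       fractionOfSnpGenes = length(inter) / length(unique(snpGenes)))
}

#' Putative-Xi expression summaries and two-group comparison
#'
#' Summarises a per-SNP (or per-gene) Xi quantity by group and compares two
#' groups with a two-tailed two-sample t test (Welch by default).
#'
#' @param values numeric vector (e.g. Xi/Xa ratios or Xi expression)
#' @param group factor/character of the same length with exactly 2 levels
#' @param pooledVar use the pooled-variance (classic Student) test
#' @return list: `means` (per group), `p` (NA with `flag` if a group has < 2
#'   values), `flag`
#' @export
meanXiExpression <- function(values, group, pooledVar = FALSE) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  sp <- split(values, g)
  tt <- .safeT(sp[[1L]], sp[[2L]], pooled = pooledVar)
  list(means = vapply(sp, mean, 0, na.rm = TRUE), p = tt$p, flag = tt$flag)
}

#' Identify informative SNPs in the PGK MEF system
#'
#' A variant is informative iff its reference-allele count in the PGK sample
#' is exactly zero and the alternate allele does not predominate in the pooled
#' control samples (alt fraction <= `predominanceThreshold`). Variants with
#' zero pooled control coverage are excluded (logged).
#'
#' @param counts long data.frame: chrom, pos, sample_id, ref_count, alt_count
#' @param pgkSample sample id of the PGK sample
#' @param controlSamples sample ids pooled as the control
#' @param predominanceThreshold maximum pooled control alt fraction
#' @return data.frame chrom, pos of informative variants
#' @export
callInformativeSnps <- function(counts, pgkSample, controlSamples,
                                predominanceThreshold = 0.5) {
  .assertCols(counts, c("chrom", "pos", "sample_id", "ref_count", "alt_count"))
  key <- function(d) paste(d$chrom, d$pos)
  pgk <- counts[counts$sample_id == pgkSample, ]
  ctl <- counts[counts$sample_id %in% controlSamples, ]
  cagg <- stats::aggregate(cbind(ref_count, alt_count) ~ chrom + pos, data = ctl, sum)
  m <- match(key(pgk), key(cagg))
  ctlTot <- cagg$ref_count[m] + cagg$alt_count[m]
  noCov <- !is.na(m) & ctlTot == 0
  if (any(noCov)) xiLog("callInformativeSnps: %d variants excluded (zero control coverage)",
                        sum(noCov))
  altFrac <- ifelse(ctlTot > 0, cagg$alt_count[m] / ctlTot, NA_real_)
  keep <- pgk$ref_count == 0 & !is.na(altFrac) & altFrac <= predominanceThreshold
  out <- pgk[keep, c("chrom", "pos")]
  xiLog("callInformativeSnps: %d of %d variants informative", nrow(out), nrow(pgk))
  out
}

#' Gene-level allelic test by pooled Fisher's exact test
#'
#' Allele counts of all informative variants inside each gene's start-end
#' interval are summed into a 2x2 table (ref/alt x control/treated) and tested
#' two-sided with Fisher's exact (hypergeometric) test; p-values are
#' BH-adjusted across genes.
#'
#' @param counts long data.frame: chrom, pos, sample_id, ref_count, alt_count
#' @param informative data.frame chrom, pos from [callInformativeSnps()]
#' @param genes `GRanges` with `gene_id`
#' @param controlSamples,treatedSamples sample id vectors (pooled)
#' @return data.frame: gene_id, ref_control, alt_control, ref_treated,
#'   alt_treated, odds_ratio, p_value, q_value, flag ("degenerate" when a
#'   margin is all zero, then p = 1)
#' @export
geneLevelAllelicTest <- function(counts, informative, genes,
                                 controlSamples, treatedSamples) {
  .assertCols(counts, c("chrom", "pos", "sample_id", "ref_count", "alt_count"))
  ikey <- paste(informative$chrom, informative$pos)
  counts <- counts[paste(counts$chrom, counts$pos) %in% ikey, ]
  gr <- positionsToGRanges(counts$chrom, counts$pos)
  ov <- findOverlaps(gr, genes)
  counts <- counts[queryHits(ov), ]
  counts$gene_id <- genes$gene_id[subjectHits(ov)]
  counts$grp <- ifelse(counts$sample_id %in% controlSamples, "control",
                ifelse(counts$sample_id %in% treatedSamples, "treated", NA))
  counts <- counts[!is.na(counts$grp), ]
  agg <- stats::aggregate(cbind(ref_count, alt_count) ~ gene_id + grp,
                          data = counts, sum)
  gids <- sort(unique(agg$gene_id))
  res <- lapply(gids, function(g) {
    sub <- agg[agg$gene_id == g, ]
    getc <- function(grp, col) {
      v <- sub[[col]][sub$grp == grp]; if (length(v)) v else 0
    }
    tab <- matrix(c(getc("control", "ref_count"), getc("control", "alt_count"),
                    getc("treated", "ref_count"), getc("treated", "alt_count")),
                  nrow = 2,
                  dimnames = list(c("ref", "alt"), c("control", "treated")))
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      p <- 1; or <- NA_real_
    } else {
      ft <- stats::fisher.test(tab)
      p <- ft$p.value; or <- unname(ft$estimate)
    }
    data.frame(gene_id = g,
               ref_control = tab[1, 1], alt_control = tab[2, 1],
               ref_treated = tab[1, 2], alt_treated = tab[2, 2],
               odds_ratio = or, p_value = p,
               flag = if (degenerate) "degenerate" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
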