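# Pooled shRNA screen readout: hairpin/barcode tallying, the 1000-read
# abundance filter, and conditional exact differential-abundance testing
# with BH FDR.

#' Tally hairpin counts from sequencing reads
#'
#' Each read is matched to a sample by its barcode and to a hairpin by its
#' hairpin sequence, both as exact substrings at fixed offsets (the construct
#' design): barcode at `barcodeStart`, hairpin at `hairpinStart`. A read
#' contributes to at most one (hairpin, sample) cell; unmatched reads are
#' counted and logged.
#'
#' @param reads character vector of read sequences, or a FASTQ/one-column
#'   text file path (plain text)
#' @param hairpins data.frame: `hairpin_id`, `sequence` (unique)
#' @param barcodes data.frame: `sample_id`, `sequence` (unique)
#' @param barcodeStart,hairpinStart 1-based offsets of the two fields
#' @return list: `counts` (data.frame hairpin_id x one column per sample),
#'   `matched`, `unmatched` (read counts; matched + unmatched = total)
#' @export
tallyHairpins <- function(reads, hairpins, barcodes,
                          barcodeStart = 1L, hairpinStart = NULL) {
  .assertCols(hairpins, c("hairpin_id", "sequence"))
  .assertCols(barcodes, c("sample_id", "sequence"))
  if (anyDuplicated(hairpins$sequence)) stop("duplicate hairpin sequences")
  if (anyDuplicated(barcodes$sequence)) stop("duplicate barcode sequences")
  if (length(reads) == 1L && file.exists(reads)) {
    lines <- readLines(reads)
    reads <- if (length(lines) >= 4L && startsWith(lines[1L], "@")) {
      lines[seq(2L, length(lines), by = 4L)]  # FASTQ sequence lines
    } else lines
  }
  bcLen <- unique(nchar(barcodes$sequence))
  hpLen <- unique(nchar(hairpins$sequence))
  if (length(bcLen) != 1L || length(hpLen) != 1L) {
    stop("barcode and hairpin sequences must each have a single length")
  }
  hairpinStart <- hairpinStart %||% (barcodeStart + bcLen)
  bc <- substr(reads, barcodeStart, barcodeStart + bcLen - 1L)
  hp <- substr(reads, hairpinStart, hairpinStart + hpLen - 1L)
  si <- match(bc, barcodes$sequence)
  hi <- match(hp, hairpins$sequence)
  ok <- !is.na(si) & !is.na(hi)
  tab <- table(factor(hairpins$hairpin_id[hi[ok]], hairpins$hairpin_id),
               factor(barcodes$sample_id[si[ok]], barcodes$sample_id))
  counts <- data.frame(hairpin_id = hairpins$hairpin_id,
                       as.data.frame.matrix(unclass(tab)),
                       check.names = FALSE, stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  xiLog("tallyHairpins: matched %d of %d reads", sum(ok), length(reads))
  list(counts = counts, matched = sum(ok), unmatched = sum(!ok))
}

#' Abundance filter on initial-timepoint counts
#'
#' A hairpin is retained iff it has at least `minInitial` reads in every
#' initial replicate (strict: 999 in any replicate excludes).
#'
#' @param counts data.frame with `hairpin_id` and one column per sample
#' @param initialSamples column names of the initial replicates
#' @param minInitial inclusive threshold, default 1000
#' @return the surviving rows (logged)
#' @export
filterHairpins <- function(counts, initialSamples, minInitial = 1000) {
  .assertCols(counts, c("hairpin_id", initialSamples))
  m <- as.matrix(counts[, initialSamples, drop = FALSE])
  keep <- apply(m >= minInitial, 1L, all)
  out <- counts[keep, , drop = FALSE]
  xiLog("filterHairpins: kept %d of %d hairpins (>= %g in all %d initial reps)",
        nrow(out), nrow(counts), minInitial, length(initialSamples))
  out
}

# two-sided conditional exact p for (y1, y2) given total, binomial at
# success probability pi1 (dispersion 0): sum of all outcome probabilities
# not exceeding the observed one (minlike rule)
.exactBinomP <- function(y1, total, pi1) {
  if (total == 0L) return(1)
  d <- dbinom(0:total, total, pi1)
  obs <- d[y1 + 1L]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

# NB double-tail exact p conditional on the total, equal group sizes:
# probability mass of splits as extreme as observed under NB(mu, size=1/disp)
.exactNbP <- function(y1, total, dispersion, n1 = 1L, n2 = 1L) {
  if (total == 0L) return(1)
  size1 <- n1 / dispersion; size2 <- n2 / dispersion
  mu <- total / (n1 + n2)
  d <- dnbinom(0:total, size = size1, mu = mu * n1) *
    dnbinom(total - (0:total), size = size2, mu = mu * n2)
  d <- d / sum(d)
  obs <- d[y1 + 1L]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Conditional exact test of hairpin abundance between sample groups
#'
#' Per hairpin, the group sums (e.g. GFP+ vs GFP-) are tested conditional on
#' the hairpin's total. With `dispersion = 0` this is the two-sided exact
#' binomial test with success probability equal to the GFP+ share of the
#' summed library sizes; with `dispersion > 0` a negative-binomial double
#' tail on library-size-equalized counts. P-values are BH-adjusted; a
#' hairpin is a hit iff p < `alpha` and its fold change is positive in the
#' first group.
#'
#' @param counts filtered count data.frame (see [filterHairpins()])
#' @param groupA,groupB column names of the two groups (A = GFP+)
#' @param dispersion negative-binomial dispersion; 0 = binomial
#' @param alpha hit threshold on the unadjusted p, default 0.1
#' @return data.frame: hairpin_id, sum_a, sum_b, log2_fc (library-size
#'   adjusted, pseudocount 0.5), p_value, fdr, is_hit
#' @export
screenExactTest <- function(counts, groupA, groupB, dispersion = 0,
                            alpha = 0.1) {
  .assertCols(counts, c("hairpin_id", groupA, groupB))
  a <- rowSums(counts[, groupA, drop = FALSE])
  b <- rowSums(counts[, groupB, drop = FALSE])
  libA <- sum(a); libB <- sum(b)
  pi1 <- libA / (libA + libB)
  total <- a + b
  p <- vapply(seq_along(a), function(i) {
    if (dispersion == 0) .exactBinomP(a[i], total[i], pi1)
    else .exactNbP(round(a[i] / libA * (libA + libB) / 2),
                   round(a[i] / libA * (libA + libB) / 2) +
                     round(b[i] / libB * (libA + libB) / 2),
                   dispersion,
                   n1 = length(groupA), n2 = length(groupB))
  }, 0)
  log2fc <- log2(((a + 0.5) / libA) / ((b + 0.5) / libB))
  out <- data.frame(hairpin_id = counts$hairpin_id, sum_a = a, sum_b = b,
                    log2_fc = log2fc, p_value = p,
                    fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$is_hit <- out$p_value < alpha & out$log2_fc > 0
  xiLog("screenExactTest: %d of %d hairpins are hits (p < %g, positive fold)",
        sum(out$is_hit), nrow(out), alpha)
  out[order(out$p_value), ]
}
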