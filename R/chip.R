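# Windowed broad-domain analysis of histone ChIP-seq against an H3 control:
# Poisson peak calling, peak density, bin-coverage correlation, allele-split
# peak enrichment, match normalization, meta-profiles and TMM library sizes.

.readStartsToGRanges <- function(reads) {
  if (is(reads, "GRanges")) return(reads)
  .assertCols(reads, c("chrom", "pos"))
  positionsToGRanges(reads$chrom, reads$pos)
}

# per-chromosome counts of read starts in non-overlapping windows
.windowCounts <- function(reads, chromLengths, window) {
  gr <- .readStartsToGRanges(reads)
  lapply(setNames(names(chromLengths), names(chromLengths)), function(chrom) {
    L <- chromLengths[[chrom]]
    nW <- ceiling(L / window)
    p <- start(gr)[as.character(seqnames(gr)) == chrom]
    p <- p[p >= 1 & p <= L]
    tabulate(pmin((p - 1L) %/% window + 1L, nW), nbins = nW)
  })
}

#' Upper-tail Poisson window p-value
#'
#' P(X >= observed | lambda), the enrichment probability the broad peak
#' caller assigns to each window.
#'
#' @param observed window read count(s)
#' @param lambda expected count(s) under the control model
#' @return numeric vector of upper-tail probabilities
#' @export
windowPoissonP <- function(observed, lambda) {
  ppois(observed - 1L, lambda, lower.tail = FALSE)
}

#' Windowed Poisson broad peak calling against an H3 control
#'
#' The genome is tiled with non-overlapping windows of `window` bp. Per
#' window, the expected mark count is the library-size-scaled control count,
#' taken as the maximum of the window's own control count, the local control
#' average over `localFactor` windows, and the genome-wide mean control rate
#' (the background floor); a window is significant iff the upper-tail Poisson
#' probability P(X >= observed | lambda) is below `pThreshold`. Runs of
#' significant windows separated by at most `mergeGap` non-significant
#' windows merge into one peak scored by its best window's -log10 p.
#'
#' @param markReads,controlReads read-start tables (data.frame chrom/pos or
#'   `GRanges`) for the mark and the H3 control
#' @param chromLengths named chromosome lengths in bp
#' @param window window width in bp (default 10 kb)
#' @param pThreshold per-window Poisson p-value cutoff (default 1e-5)
#' @param mergeGap number of non-significant windows tolerated inside a peak
#' @param localFactor width of the local control average, in windows
#' @param markLibrary,controlLibrary library sizes; default: total read count
#' @param mark,sampleGroup labels for the returned [PeakSet-class]
#' @return a [PeakSet-class]; each peak's `score` is max -log10 p
#' @export
callBroadPeaks <- function(markReads, controlReads, chromLengths,
                           window = 10000, pThreshold = 1e-5, mergeGap = 0,
                           localFactor = 5,
                           markLibrary = NULL, controlLibrary = NULL,
                           mark = "mark", sampleGroup = "all") {
  mc <- .windowCounts(markReads, chromLengths, window)
  cc <- .windowCounts(controlReads, chromLengths, window)
  mLib <- markLibrary %||% sum(vapply(mc, sum, 0))
  cLib <- controlLibrary %||% sum(vapply(cc, sum, 0))
  if (cLib <= 0) stop("control library size is zero")
  scale <- mLib / cLib
  floorRate <- mean(unlist(cc))  # genome-wide mean control count per window

  peaks <- list()
  for (chrom in names(chromLengths)) {
    m <- mc[[chrom]]; ctl <- cc[[chrom]]
    nW <- length(m)
    if (nW == 0L) next
    half <- floor(localFactor / 2)
    local <- vapply(seq_len(nW), function(i) {
      mean(ctl[max(1L, i - half):min(nW, i + half)])
    }, 0)
    lambda <- pmax(ctl, local, floorRate) * scale
    p <- windowPoissonP(m, lambda)
    sig <- p < pThreshold
    if (!any(sig)) next
    # merge runs of significant windows, tolerating gaps of mergeGap windows
    idx <- which(sig)
    brk <- c(TRUE, diff(idx) > (mergeGap + 1L))
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      s0 <- (min(ii) - 1L) * window + 1L
      e0 <- min(max(ii) * window, chromLengths[[chrom]])
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom, start = s0, end = e0,
        score = max(-log10(pmax(p[ii], .Machine$double.xmin))))
    }
  }
  if (length(peaks) == 0L) {
    gr <- GRanges(); gr$score <- numeric(0)
    return(PeakSet(gr, mark = mark, sampleGroup = sampleGroup))
  }
  df <- do.call(rbind, peaks)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  gr$score <- df$score
  PeakSet(gr, mark = mark, sampleGroup = sampleGroup)
}

#' Peak density per Mb, X vs pooled autosomes
#'
#' @param peakSet a [PeakSet-class]
#' @param chromLengths named lengths in bp for every chromosome with peaks
#' @return list: `perChromosome` (data.frame chrom, n_peaks, mb, peaks_per_mb)
#'   and `grouped` (X vs autosomes pooled: total peaks / total length)
#' @export
peaksPerMb <- function(peakSet, chromLengths) {
  gr <- peakRanges(peakSet)
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), names(chromLengths))
  if (length(unknown)) stop("peaks on chromosome(s) of unknown length: ",
                            paste(unknown, collapse = ", "))
  perChr <- data.frame(chrom = names(chromLengths),
                       n_peaks = vapply(names(chromLengths),
                                        function(c) sum(chr == c), 0L),
                       mb = unname(chromLengths) / 1e6)
  perChr$peaks_per_mb <- perChr$n_peaks / perChr$mb
  isX <- grepl("X$", perChr$chrom)
  grouped <- data.frame(
    group = c("X", "autosomes"),
    n_peaks = c(sum(perChr$n_peaks[isX]), sum(perChr$n_peaks[!isX])),
    mb = c(sum(perChr$mb[isX]), sum(perChr$mb[!isX])))
  grouped$peaks_per_mb <- ifelse(grouped$mb > 0,
                                 grouped$n_peaks / grouped$mb, 0)
  list(perChromosome = perChr, grouped = grouped)
}

#' Fixed-width bins tiling chromosomes
#' @param chromLengths named lengths in bp
#' @param width bin width in bp (default 50 kb)
#' @return `GRanges` of bins (last bin of a chromosome may be shorter)
#' @export
tileBins <- function(chromLengths, width = 50000) {
  do.call(c, lapply(names(chromLengths), function(chrom) {
    L <- chromLengths[[chrom]]
    s <- seq(1L, L, by = width)
    GRanges(chrom, IRanges(s, pmin(s + width - 1L, L)))
  }))
}

#' Percentage coverage of intervals over fixed bins
#'
#' @param intervals `GRanges` (e.g. peaks or genes); overlapping intervals are
#'   flattened first so no bp is counted twice
#' @param bins `GRanges` of bins (see [tileBins()])
#' @return numeric vector, per bin: 100 x (bp overlapped) / bin width
#' @export
binCoverage <- function(intervals, bins) {
  flat <- reduce(intervals)
  ov <- findOverlaps(bins, flat)
  covered <- numeric(length(bins))
  if (length(ov)) {
    w <- width(pintersect(bins[queryHits(ov)], flat[subjectHits(ov)]))
    agg <- tapply(w, queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  100 * covered / width(bins)
}

#' Pearson correlation between two per-bin vectors
#'
#' Bins with an undefined value in either vector are dropped pairwise.
#'
#' @param a,b numeric vectors on the same bin grid
#' @return list: `r`, `n` (bins used), `flag` ("zero_variance" with `r = NA`
#'   when either vector is constant)
#' @export
correlateBins <- function(a, b) {
  if (length(a) != length(b)) stop("bin grids differ in length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, n = length(a), flag = "zero_variance"))
  }
  list(r = cor(a, b), n = length(a), flag = "ok")
}

#' Allele-split read enrichment at peaks
#'
#' Sums Xi- and Xa-assigned informative reads per peak (peaks without
#' informative SNPs are excluded and logged) and compares Xi vs Xa totals
#' across peaks with a paired two-tailed t test. Optionally repeats the
#' quantitation on size-matched random non-peak regions.
#'
#' @param allelic data.frame: chrom, pos, xi_count, xa_count (per-SNP
#'   allele-tagged read counts)
#' @param peakSet a [PeakSet-class]
#' @param chromLengths named lengths (needed for non-peak sampling)
#' @param nonPeakControl also quantify size-matched non-peak regions
#' @param seed RNG seed for non-peak placement
#' @return list: `peaks` (data.frame chrom, start, end, xi, xa), `test`
#'   (paired t p-value and mean Xi/Xa fold at peaks), and when requested
#'   `nonPeak` (same layout) with `nonPeakTest`
#' @export
allelicPeakEnrichment <- function(allelic, peakSet, chromLengths = NULL,
                                  nonPeakControl = FALSE, seed = 1L) {
  .assertCols(allelic, c("chrom", "pos", "xi_count", "xa_count"))
  snp <- positionsToGRanges(allelic$chrom, allelic$pos)
  quantify <- function(regions) {
    ov <- findOverlaps(snp, regions)
    xi <- xa <- numeric(length(regions))
    if (length(ov)) {
      xi <- unname(tapply(allelic$xi_count[queryHits(ov)],
                          factor(subjectHits(ov), seq_along(regions)), sum,
                          default = 0))
      xa <- unname(tapply(allelic$xa_count[queryHits(ov)],
                          factor(subjectHits(ov), seq_along(regions)), sum,
                          default = 0))
      xi[is.na(xi)] <- 0; xa[is.na(xa)] <- 0
    }
    informative <- countOverlaps(regions, snp) > 0
    data.frame(chrom = as.character(seqnames(regions)),
               start = start(regions), end = end(regions),
               xi = xi, xa = xa)[informative, , drop = FALSE]
  }
  pk <- peakRanges(peakSet)
  peakQ <- quantify(pk)
  xiLog("allelicPeakEnrichment: %d of %d peaks have informative SNPs",
        nrow(peakQ), length(pk))
  testOf <- function(q) {
    if (nrow(q) < 2L) return(list(p = NA_real_, meanFold = NA_real_,
                                  flag = "too_few_regions"))
    tt <- .safeT(q$xi, q$xa, paired = TRUE)
    list(p = tt$p, meanFold = mean((q$xi + 1) / (q$xa + 1)), flag = tt$flag)
  }
  out <- list(peaks = peakQ, test = testOf(peakQ))
  if (nonPeakControl) {
    if (is.null(chromLengths)) stop("chromLengths needed for non-peak regions")
    set.seed(seed)
    np <- do.call(c, lapply(seq_along(pk), function(i) {
      chrom <- as.character(seqnames(pk))[i]; w <- width(pk)[i]
      L <- chromLengths[[chrom]]
      for (try in 1:50) {
        s <- sample.int(max(1L, L - w), 1L)
        cand <- GRanges(chrom, IRanges(s, s + w - 1L))
        if (!overlapsAny(cand, pk)) return(cand)
      }
      GRanges()
    }))
    npQ <- quantify(np)
    out$nonPeak <- npQ
    out$nonPeakTest <- testOf(npQ)
  }
  out
}

#' Match normalization of windowed tracks with H3 subtraction
#'
#' Distribution-matching ("Match") normalization replaces each sample's
#' window values by the average of the samples' order statistics at equal
#' ranks (ties receive the mean of their rank range), making every sample's
#' value distribution identical while preserving within-sample ranks. The H3
#' control track (matched jointly with the marks) is then subtracted
#' windowwise.
#'
#' @param tracks named list of [BinnedTrack-class] on one grid (marks)
#' @param h3Track the H3 [BinnedTrack-class] on the same grid
#' @return named list of h3-subtracted [BinnedTrack-class] objects
#' @export
normalizeTracks <- function(tracks, h3Track) {
  all <- c(tracks, list(.h3 = h3Track))
  vals <- lapply(all, trackValues)
  n <- unique(lengths(vals))
  if (length(n) != 1L) stop("tracks are not on the same bin grid")
  grids <- lapply(all, function(t) {
    paste(as.character(seqnames(trackBins(t))), start(trackBins(t)))
  })
  if (!all(vapply(grids[-1], identical, TRUE, grids[[1]]))) {
    stop("tracks are not on the same bin grid")
  }
  matched <- matchNormalize(do.call(cbind, vals))
  h3 <- matched[, ncol(matched)]
  out <- lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    bins <- trackBins(t)
    bins$score <- matched[, i] - h3
    BinnedTrack(bins, windowWidth(t), stepWidth(t), "h3_subtracted")
  })
  names(out) <- names(tracks)
  out
}

#' Match (average-of-order-statistics) normalization of a value matrix
#'
#' @param m numeric matrix, one column per sample
#' @return matrix of the same shape; every column has the same empirical
#'   distribution (the columnwise-sorted mean), ranks preserved within column
#' @export
matchNormalize <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  cref <- c(0, cumsum(ref))
  apply(m, 2L, function(x) {
    rmin <- rank(x, ties.method = "min")
    n <- stats::ave(x, x, FUN = length)  # tie-group sizes
    # each tie group takes the mean of ref over its whole rank range
    (cref[rmin + n] - cref[rmin]) / n
  })
}

#' Meta-profile of windowed mark signal across length-normalized features
#'
#' Each feature is quantified in sliding windows, window centers are mapped
#' to relative position within the feature, values are averaged in equal
#' relative-width bins across features, and the identically-computed H3
#' profile (scaled to the mark's library size) is subtracted. Features
#' shorter than one window are skipped and logged.
#'
#' @param markReads,h3Reads read-start tables
#' @param features `GRanges`
#' @param window,step sliding window geometry in bp
#' @param nPositions number of relative-position bins
#' @return data.frame: rel_pos (bin midpoints in (0,1)), mark, h3, profile
#'   (mark - scaled h3)
#' @export
trendProfile <- function(markReads, h3Reads, features, window = 10000,
                         step = 5000, nPositions = 20) {
  if (length(features) == 0L) stop("feature list is empty")
  short <- width(features) < window
  if (any(short)) xiLog("trendProfile: %d features shorter than window skipped",
                       sum(short))
  features <- features[!short]
  if (length(features) == 0L) stop("no feature is at least one window long")
  mGr <- .readStartsToGRanges(markReads)
  hGr <- .readStartsToGRanges(h3Reads)
  scale <- length(mGr) / length(hGr)
  sumM <- matrix(0, nrow = nPositions, ncol = 2)
  cnt <- numeric(nPositions)
  mPos <- split(start(mGr), as.character(seqnames(mGr)))
  hPos <- split(start(hGr), as.character(seqnames(hGr)))
  for (i in seq_along(features)) {
    chrom <- as.character(seqnames(features))[i]
    fs <- start(features)[i]; fe <- end(features)[i]
    ws <- seq(fs, fe - window + 1L, by = step)
    centers <- (ws + window / 2 - fs) / (fe - fs + 1)
    bin <- pmin(pmax(ceiling(centers * nPositions), 1L), nPositions)
    mp <- mPos[[chrom]]; hp <- hPos[[chrom]]
    cm <- vapply(ws, function(s) sum(mp >= s & mp < s + window), 0)
    ch <- vapply(ws, function(s) sum(hp >= s & hp < s + window), 0)
    for (k in seq_along(bin)) {
      sumM[bin[k], 1] <- sumM[bin[k], 1] + cm[k]
      sumM[bin[k], 2] <- sumM[bin[k], 2] + ch[k]
      cnt[bin[k]] <- cnt[bin[k]] + 1
    }
  }
  mark <- ifelse(cnt > 0, sumM[, 1] / cnt, NA)
  h3 <- ifelse(cnt > 0, sumM[, 2] / cnt, NA)
  data.frame(rel_pos = (seq_len(nPositions) - 0.5) / nPositions,
             mark = mark, h3 = h3, profile = mark - scale * h3)
}

#' TMM effective library size factors from binned counts
#'
#' Counts reads per library in fixed genomic bins (10 kb in the source
#' workflow) and computes trimmed-mean-of-M-values normalization factors;
#' effective library size = raw library size x factor. Delegates to
#' edgeR's TMM implementation (log-ratio trim 30%, intensity trim 5%,
#' reference chosen by upper quartile), whose factors are centered to
#' geometric mean 1.
#'
#' @param binCounts numeric matrix, bins x libraries
#' @return list: `factors`, `librarySizes` (column sums), `effectiveSizes`
#' @export
tmmLibrarySizes <- function(binCounts) {
  binCounts <- as.matrix(binCounts)
  if (ncol(binCounts) < 2L) stop("at least two libraries are required")
  libs <- colSums(binCounts)
  if (any(libs == 0)) stop("library of all zeros")
  f <- edgeR::calcNormFactors(binCounts, method = "TMM")
  list(factors = f, librarySizes = libs, effectiveSizes = libs * f)
}
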