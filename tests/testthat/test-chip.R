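grX <- function(s, e) GenomicRanges::GRanges("chrX", IRanges::IRanges(s, e))

test_that("window Poisson p-values match the gamma-tail oracle", {
  set.seed(2)
  obs <- rpois(1000, 50) + sample(0:40, 1000, TRUE)
  lam <- runif(1000, 0.5, 80)
  p <- windowPoissonP(obs, lam)
  oracle <- pgamma(lam, shape = obs)  # P(X >= k | lambda) = P(Gamma(k) <= lambda)
  expect_lt(max(abs(p - oracle)), 1e-10)
})

test_that("adjacent significant windows merge into a single peak", {
  set.seed(3)
  lens <- c(chrX = 1e5)
  ctl <- data.frame(chrom = "chrX", pos = sample.int(1e5, 5000, TRUE))
  enriched <- data.frame(chrom = "chrX",
                         pos = 20000L + sample.int(20000, 30000, TRUE))
  mk <- rbind(ctl, enriched)
  ps <- callBroadPeaks(mk, ctl, lens, window = 10000)
  expect_equal(length(ps), 1L)
  pk <- peakRanges(ps)
  expect_equal(start(pk), 20001L)
  expect_equal(end(pk), 40000L)
  expect_gt(pk$score, 5)
})

test_that("a null run produces no peaks and zero control library errors", {
  set.seed(6)
  lens <- c(chrX = 5e6)
  mk <- data.frame(chrom = "chrX", pos = sample.int(5e6, 250000, TRUE))
  ctl <- data.frame(chrom = "chrX", pos = sample.int(5e6, 250000, TRUE))
  expect_equal(length(callBroadPeaks(mk, ctl, lens)), 0L)
  expect_error(callBroadPeaks(mk, ctl[0, ], lens), "control library")
})

test_that("peak density handles grouping, empties and unknown chromosomes", {
  gr <- GenomicRanges::GRanges(rep(c("chrX", "chr1", "chr2"), c(300, 100, 50)),
                               IRanges::IRanges(seq(1, by = 2000,
                                                    length.out = 450),
                                                width = 1000))
  gr$score <- 1
  ps <- PeakSet(gr)
  d <- peaksPerMb(ps, c(chrX = 1e8, chr1 = 5e7, chr2 = 5e7))
  expect_equal(d$grouped$peaks_per_mb[d$grouped$group == "X"], 3)
  auto <- d$grouped[d$grouped$group == "autosomes", ]
  expect_equal(auto$peaks_per_mb, 150 / 100)
  # pooled autosome density equals the length-weighted mean of per-chromosome
  perChr <- d$perChromosome[d$perChromosome$chrom != "chrX", ]
  expect_equal(auto$peaks_per_mb,
               sum(perChr$peaks_per_mb * perChr$mb) / sum(perChr$mb))
  empty <- PeakSet({g <- GenomicRanges::GRanges(); g$score <- numeric(0); g})
  expect_equal(sum(peaksPerMb(empty, c(chrX = 1e6))$perChromosome$n_peaks), 0L)
  expect_error(peaksPerMb(ps, c(chrX = 1e8)), "unknown")
})

test_that("bin coverage is exact and matches a per-bp oracle", {
  bins <- tileBins(c(chrX = 2e5), width = 50000)
  expect_equal(binCoverage(grX(1, 25000), bins), c(50, 0, 0, 0))
  expect_equal(binCoverage(grX(50001, 200000), bins), c(0, 100, 100, 100))
  # random peaks vs brute-force bp counting on a 1-Mb toy
  set.seed(10)
  s <- sort(sample.int(1e6 - 5000, 200))
  peaks <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(s, s + sample.int(5000, 200))))
  bins <- tileBins(c(chrX = 1e6), width = 50000)
  got <- binCoverage(peaks, bins)
  bp <- logical(1e6)
  for (i in seq_along(peaks)) bp[start(peaks)[i]:end(peaks)[i]] <- TRUE
  oracle <- vapply(seq_along(bins), function(i) {
    100 * sum(bp[start(bins)[i]:end(bins)[i]]) / width(bins)[i]
  }, 0)
  expect_equal(got, oracle, tolerance = 1e-12)
  # coverage conservation: covered bp summed over bins == total peak bp
  expect_equal(sum(got / 100 * width(bins)), sum(width(peaks)))
})

test_that("bin correlation handles the exact and degenerate cases", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(correlateBins(x, x)$r, 1)
  expect_equal(correlateBins(x, -x)$r, -1)
  flag <- correlateBins(x, rep(3, 5))
  expect_true(is.na(flag$r))
  expect_equal(flag$flag, "zero_variance")
  expect_error(correlateBins(x, 1:3), "grids")
  # pairwise deletion of undefined bins
  y <- c(1, 4, NA, 8, 5)
  expect_equal(correlateBins(x, y)$n, 4L)
})

test_that("allelic peak enrichment detects a planted Xi skew", {
  set.seed(12)
  peaks <- GenomicRanges::GRanges("chrX",
    IRanges::IRanges(seq(1, by = 20000, length.out = 50), width = 10000))
  peaks$score <- 1
  ps <- PeakSet(peaks)
  pos <- rep(start(peaks) + 5000, each = 2) + rep(c(0, 100), 50)
  depth <- rpois(100, 40)
  xi <- rbinom(100, depth, 2 / 3)  # 2x Xi skew
  skewed <- data.frame(chrom = "chrX", pos = pos, xi_count = xi,
                       xa_count = depth - xi)
  res <- allelicPeakEnrichment(skewed, ps)
  expect_lt(res$test$p, 0.01)
  expect_gt(res$test$meanFold, 1.5)

  balanced <- data.frame(chrom = "chrX", pos = pos, xi_count = 5L, xa_count = 5L)
  resB <- allelicPeakEnrichment(balanced, ps)
  expect_equal(resB$test$p, 1)
  # peaks without informative SNPs are excluded
  few <- data.frame(chrom = "chrX", pos = 5001L, xi_count = 5L, xa_count = 3L)
  resF <- allelicPeakEnrichment(few, ps)
  expect_equal(nrow(resF$peaks), 1L)
  expect_equal(resF$test$flag, "too_few_regions")
})

test_that("match normalization equalises distributions and preserves ranks", {
  set.seed(20)
  x <- rnorm(500)
  m <- cbind(a = x, b = 2 * x + 1, c = rnorm(500))
  mn <- matchNormalize(m)
  # post-matching distributions identical (Kolmogorov distance 0)
  expect_equal(sort(mn[, 1]), sort(mn[, 2]), tolerance = 1e-12)
  expect_equal(sort(mn[, 1]), sort(mn[, 3]), tolerance = 1e-12)
  # rank preservation within sample
  expect_equal(rank(mn[, 3]), rank(m[, 3]))
  # idempotence
  expect_equal(matchNormalize(mn), mn, tolerance = 1e-12)
  # identical tracks unchanged
  same <- cbind(x, x)
  expect_equal(matchNormalize(same), same, ignore_attr = TRUE)
})

test_that("H3 subtraction of matched tracks zeroes a mark equal to H3", {
  mkTrack <- function(v) {
    s <- seq(1, by = 50000, length.out = length(v))
    gr <- GenomicRanges::GRanges("chrX", IRanges::IRanges(s, s + 49999))
    gr$score <- v
    BinnedTrack(gr, windowWidth = 50000)
  }
  set.seed(30)
  v <- rpois(20, 50)
  out <- normalizeTracks(list(mark = mkTrack(v)), mkTrack(v))
  expect_equal(trackValues(out$mark), rep(0, 20))
  expect_equal(normalization(out$mark), "h3_subtracted")
  expect_error(normalizeTracks(list(mark = mkTrack(v)),
                               mkTrack(v[1:19])), "grid")
})

test_that("trend profile is flat at zero for mark == H3 and peaks centrally", {
  set.seed(31)
  feats <- GenomicRanges::GRanges("chrX",
    IRanges::IRanges(c(1e5, 5e5, 9e5), width = 1e5))
  h3 <- data.frame(chrom = "chrX", pos = sample.int(1.2e6, 1e5, TRUE))
  flat <- trendProfile(h3, h3, feats, nPositions = 10)
  expect_equal(flat$profile, rep(0, 10))
  mid <- do.call(rbind, lapply(seq_along(feats), function(i)
    data.frame(chrom = "chrX",
               pos = start(feats)[i] + 40000 + sample.int(20000, 20000, TRUE))))
  mk <- rbind(h3, mid)
  tp <- trendProfile(mk, h3, feats, nPositions = 10)
  expect_equal(which.max(tp$profile), 5)
  expect_error(trendProfile(mk, h3, feats[0]), "empty")
  # features shorter than a window are skipped
  shortF <- c(feats, GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 500)))
  expect_equal(nrow(trendProfile(h3, h3, shortF, nPositions = 10)), 10L)
})

test_that("TMM factors recover a pure scale change and center to 1", {
  set.seed(40)
  base <- rnbinom(2000, mu = 100, size = 5)
  m <- cbind(lib1 = base, lib2 = 3L * base)
  tm <- tmmLibrarySizes(m)
  expect_equal(tm$effectiveSizes[["lib2"]] / tm$effectiveSizes[["lib1"]], 3,
               tolerance = 0.01)
  expect_lt(abs(exp(mean(log(tm$factors))) - 1), 1e-12)
  # identical libraries -> all factors 1
  same <- cbind(base, base, base)
  expect_equal(unname(tmmLibrarySizes(same)$factors), rep(1, 3))
  expect_error(tmmLibrarySizes(cbind(base, 0 * base)), "zero")
  expect_error(tmmLibrarySizes(matrix(base, ncol = 1)), "two")
})
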