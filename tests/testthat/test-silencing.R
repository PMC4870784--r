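test_that("RPKM follows its definition and scaling", {
  expect_equal(rpkm(100, 2000, 1e6)[1, 1], 50)
  expect_equal(rpkm(0, 2000, 1e6)[1, 1], 0)
  expect_equal(rpkm(100, 2000, 2e6)[1, 1], 25)   # doubling library halves RPKM
  m <- rpkm(matrix(c(100, 200, 100, 200), 2), c(1000, 4000), c(1e6, 2e6))
  expect_equal(m[, 1], c(100, 50))
  expect_equal(m[, 2], c(50, 25))
  expect_error(rpkm(1, 100, 0), "library")
})

.mkGenes <- function(n, chrom = "chrX", by = 1e5, width = 1e4) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(seq(1, by = by, length.out = n), width = width))
  gr$gene_id <- paste0("g", seq_len(n))
  gr
}

test_that("silencing classes follow the fold-change and proximity rules", {
  genes <- .mkGenes(5)
  # one Setdb1 peak: 150 kb downstream of gene 1 end, overlapping gene 3
  peaks <- GenomicRanges::GRanges("chrX",
    IRanges::IRanges(c(160000, 200001), width = c(1000, 5000)))
  expr <- data.frame(
    day0 = c(8,   0.4, 8,   4.0, 8),
    day3 = c(1,   0.2, 8,   4.1, 8),
    day5 = c(1,   0.1, 1,   3.9, 1),
    row.names = paste0("g", 1:5))
  # g1: log2FC(d0->d3) = 3 > 2, peak at 150 kb -> silenced_d0_d3
  # g2: below 0.5 throughout -> maintained_silent
  # g3: drops d3->d5, peak overlaps (distance 0) -> silenced_d3_d5
  # g4: max |log2FC| < 0.5 -> stable
  # g5: drops d3->d5 but nearest peak ~100+ kb... within 200 kb -> silenced
  cls <- classifyGenes(expr, genes, peaks)
  expect_equal(cls$class[cls$gene_id == "g1"], "silenced_d0_d3")
  expect_equal(cls$class[cls$gene_id == "g2"], "maintained_silent")
  expect_equal(cls$class[cls$gene_id == "g3"], "silenced_d3_d5")
  expect_equal(cls$class[cls$gene_id == "g4"], "stable")
  expect_equal(cls$dist_setdb1[cls$gene_id == "g3"], 0)

  # out of proximity: push the peaks 300 kb beyond every gene
  far <- GenomicRanges::shift(peaks, 2e6)
  clsF <- classifyGenes(expr, genes, far)
  expect_equal(clsF$class[clsF$gene_id == "g1"], "unclassified")

  # proximity matches a brute-force nearest-interval scan
  brute <- vapply(seq_along(genes), function(i) {
    min(vapply(seq_along(peaks), function(j) {
      g <- genes[i]; p <- peaks[j]
      if (start(p) <= end(g) && end(p) >= start(g)) 0
      else min(abs(start(p) - end(g)), abs(start(g) - end(p))) - 1
    }, 0))
  }, 0)
  expect_equal(cls$dist_setdb1, brute)
})

test_that("every gene receives exactly one class label", {
  set.seed(50)
  genes <- .mkGenes(60)
  peaks <- GenomicRanges::GRanges("chrX",
    IRanges::IRanges(sort(sample.int(6e6, 10)), width = 2000))
  expr <- data.frame(day0 = rlnorm(60, 1), day3 = rlnorm(60, 0.5),
                     day5 = rlnorm(60, 0), row.names = paste0("g", 1:60))
  cls <- classifyGenes(expr, genes, peaks)
  expect_equal(nrow(cls), 60L)
  expect_true(all(cls$class %in% c("silenced_d0_d3", "silenced_d3_d5", "stable",
                                   "maintained_silent", "unclassified")))
  expect_false(any(duplicated(cls$gene_id)))
})

test_that("class comparison flags small classes and detects failed silencing", {
  set.seed(51)
  n <- 71  # silenced-class size mirrors the X-linked cohort analysed
  sil <- paste0("s", 1:n); sta <- paste0("t", 1:n)
  classes <- data.frame(gene_id = c(sil, sta),
                        class = rep(c("silenced_d3_d5", "stable"), each = n))
  nons <- data.frame(day0 = rep(8, 2 * n), day3 = rep(8, 2 * n),
                     day5 = c(rep(1, n), rep(8, n)),
                     row.names = c(sil, sta))
  kd <- nons
  # knockdown: silenced genes fail to silence (2x higher at day 5), noise on all
  kd$day5 <- kd$day5 * c(rep(2, n), rep(1, n)) * rlnorm(2 * n, 0, 0.3)
  nons$day5 <- nons$day5 * rlnorm(2 * n, 0, 0.3)
  cmp <- compareClasses(nons, kd, classes)
  silP <- cmp$p_value[cmp$class == "silenced_d3_d5" & cmp$interval == "d3_d5"]
  staP <- cmp$p_value[cmp$class == "stable" & cmp$interval == "d3_d5"]
  expect_lt(silP, 0.05)
  expect_gt(staP, 0.05)

  tiny <- data.frame(gene_id = "s1", class = "maintained_silent")
  cmpT <- compareClasses(nons, kd, tiny)
  expect_true(all(cmpT$flag == "too_few"))
})

test_that("repeat DE calling and chi-square enrichment localise to LTRs", {
  # |log2FC| > 1 is strict
  reps <- data.frame(repeat_id = c("r1", "r2"), repClass = c("LTR", "LINE"),
                     nons = c(10, 10), kd = c(10 * 2^1.2, 10 * 2^0.8))
  de <- repeatDe(reps)
  expect_equal(de$de$de, c(TRUE, FALSE))

  set.seed(52)
  n <- 600
  cls <- sample(c("LTR", "LINE", "SINE", "DNA"), n, TRUE)
  nons <- rep(10, n)
  kd <- ifelse(cls == "LTR" & runif(n) < 0.5, 50, 10 * rlnorm(n, 0, 0.1))
  tab <- repeatDe(data.frame(repeat_id = seq_len(n), repClass = cls,
                             nons = nons, kd = kd))
  expect_lt(tab$p_value, 0.001)
  expect_equal(rownames(tab$stdres)[which.max(tab$stdres[, "DE"])], "LTR")

  # equal DE proportions across classes -> p ~ 1
  even <- data.frame(repeat_id = 1:400,
                     repClass = rep(c("LTR", "LINE", "SINE", "DNA"), each = 100),
                     nons = 10, kd = rep(c(50, 10), 200))
  expect_gt(repeatDe(even)$p_value, 0.99)

  # chi-square statistic matches hand computation on a printed 2xk table
  printed <- matrix(c(30, 70, 10, 90, 20, 80), nrow = 3, byrow = TRUE,
                    dimnames = list(c("LTR", "LINE", "SINE"), c("DE", "notDE")))
  ct <- suppressWarnings(chisq.test(printed))
  E <- outer(rowSums(printed), colSums(printed)) / sum(printed)
  expect_lt(abs(ct$statistic - sum((printed - E)^2 / E)), 1e-10)
})

test_that("2^-ddCt returns unit fold change at the reference", {
  ct <- c(ref = 20, s1 = 19, s2 = 21)
  hk <- c(ref = 15, s1 = 15, s2 = 15)
  fc <- ddct(ct, hk, "ref")
  expect_equal(unname(fc), c(1, 2, 0.5))
  # two housekeeping genes enter as an arithmetic mean of Ct
  hk2 <- cbind(h1 = hk + 1, h2 = hk - 1)
  expect_equal(ddct(ct, hk2, "ref"), fc)
})
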