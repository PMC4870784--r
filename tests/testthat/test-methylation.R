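test_that("the CpG coverage filter is strictly greater-than", {
  sites <- data.frame(chrom = "chrX", pos = 1:3 * 100,
                      meth_count = c(10L, 11L, 30L),
                      unmeth_count = c(10L, 10L, 5L))
  out <- filterCpgs(sites)
  expect_equal(out$pos, c(200L, 300L))   # coverage 20 removed, 21 retained
  expect_equal(out$pct_mc, c(100 * 11 / 21, 100 * 30 / 35))
  expect_equal(nrow(filterCpgs(sites[0, ])), 0L)
})

.cpgSites <- function(valsA, valsB, pos = 100L) {
  rbind(
    data.frame(chrom = "chrX", pos = pos, condition = "A",
               replicate = seq_along(valsA), pct_mc = valsA),
    data.frame(chrom = "chrX", pos = pos, condition = "B",
               replicate = seq_along(valsB), pct_mc = valsB))
}

test_that("per-CpG differential tests across replicates behave correctly", {
  # identical replicate values on both sides -> not significant
  same <- differentialCpgs(.cpgSites(c(50, 52, 48), c(50, 52)), "A", "B")
  expect_false(same$significant)
  # planted 30-point drop, sd ~2, n = 3 vs 2 -> significant
  drop <- differentialCpgs(.cpgSites(c(60, 62, 58), c(30, 32)), "A", "B")
  expect_true(drop$significant)
  expect_equal(drop$direction, "loss")
  expect_lt(drop$delta, -25)
  # a CpG with one replicate in a group is excluded
  few <- differentialCpgs(rbind(.cpgSites(c(60, 62, 58), 30),
                                .cpgSites(c(60, 62, 58), c(30, 32), pos = 200L)),
                          "A", "B")
  expect_equal(few$pos, 200L)
  # constant equal groups are flagged, p = 1
  const <- differentialCpgs(.cpgSites(c(50, 50, 50), c(50, 50)), "A", "B")
  expect_equal(const$p_value, 1)
  expect_equal(const$flag, "constant_equal")
})

test_that("log2(mC/C) uses pseudocounts and separates Xi from Xa", {
  sites <- data.frame(
    chrom = "chrX", pos = c(1L, 2L, 3L, 4L),
    allele = c("Xi", "Xi", "Xa", "Xa"),
    condition = c("A", "B", "A", "B"), replicate = 1L,
    meth_count = c(5L, 8L, 0L, 1L), unmeth_count = c(5L, 2L, 10L, 9L))
  res <- xiXaContrast(sites, "A", "B")
  v <- res$values
  expect_equal(v$log2_ratio[v$pos == 1], 0)           # meth == unmeth
  expect_equal(v$log2_ratio[v$pos == 2], log2(3))     # (8+1)/(2+1)
  expect_error(xiXaContrast(sites[sites$allele == "Xa", ], "A", "B"), "Xi")

  set.seed(3)
  big <- data.frame(
    chrom = "chrX", pos = 1:2000, allele = rep(c("Xi", "Xa"), each = 1000),
    condition = "A", replicate = 1L,
    meth_count = c(rbinom(1000, 50, 0.8), rbinom(1000, 50, 0.05)))
  big$unmeth_count <- 50L - big$meth_count
  res <- xiXaContrast(big, "A", "A")
  s <- res$summary
  expect_gt(s$median[s$allele == "Xi"], s$median[s$allele == "Xa"] + 3)
})

test_that("CGI calls pool member CpGs and class on the 20% boundary", {
  cgis <- GenomicRanges::GRanges("chrX", IRanges::IRanges(c(1, 1000, 2000), width = 500))
  mkCgi <- function(offset, a, b) {
    do.call(rbind, lapply(1:4, function(i)
      .cpgSites(a, b, pos = offset + i * 50L)))
  }
  sites <- rbind(mkCgi(0L, c(25, 26, 24), c(25, 26)),      # methylated, no change
                 mkCgi(1000L, c(20, 20, 20), c(20, 20)))   # boundary: exactly 20%
  res <- cgiCalls(sites, cgis, "A", "B")
  expect_equal(res$class, c("methylated", "unmethylated", "unmethylated"))
  expect_equal(res$n_cpgs, c(4L, 4L, 0L))
  expect_true(is.na(res$p_value[3]))
  expect_false(any(res$reduced))
  # planted uniform drop is called reduced
  lost <- rbind(mkCgi(0L, c(60, 61, 59), c(40, 41)))
  resL <- cgiCalls(lost, cgis[1], "A", "B")
  expect_true(resL$reduced)
  # n_cpgs equals an interval-overlap oracle count
  gr <- positionsToGRanges(sites$chrom, sites$pos)
  expect_equal(res$n_cpgs[1],
               length(unique(start(gr)[IRanges::overlapsAny(gr, cgis[1])])))
})

test_that("the CGI meta-profile is flat for uniform methylation and U-shaped
           for edge-only methylation", {
  cgis <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 1000))
  pos <- seq(10L, 990L, by = 20L)
  uni <- data.frame(chrom = "chrX", pos = pos, condition = "A",
                    replicate = 1L, pct_mc = 50)
  prof <- cgiMetaProfile(uni, cgis, nPositions = 10)
  expect_equal(prof$mean_pct_mc, rep(50, 10))
  edge <- within(uni, pct_mc <- ifelse(pos < 150 | pos > 850, 90, 10))
  profE <- cgiMetaProfile(edge, cgis, nPositions = 10)
  expect_gt(profE$mean_pct_mc[1], 80)
  expect_gt(profE$mean_pct_mc[10], 80)
  expect_lt(max(profE$mean_pct_mc[4:7]), 20)
  # single-CpG CGIs are skipped
  two <- c(cgis, GenomicRanges::GRanges("chrX", IRanges::IRanges(5000, 5100)))
  single <- rbind(uni, data.frame(chrom = "chrX", pos = 5050L, condition = "A",
                                  replicate = 1L, pct_mc = 99))
  profS <- cgiMetaProfile(single, two, nPositions = 10)
  expect_equal(profS$mean_pct_mc, rep(50, 10))
})

test_that("pct_mc and log2 ratio are both monotone in the methylated count", {
  cov <- 30L
  meth <- 0:30
  sites <- data.frame(chrom = "chrX", pos = 1L, allele = "Xi", condition = "A",
                      replicate = 1L, meth_count = meth,
                      unmeth_count = cov - meth)
  pct <- 100 * meth / cov
  lr <- xiXaContrast(sites, "A", "A")$values$log2_ratio
  expect_true(all(diff(pct) > 0))
  expect_true(all(diff(lr) > 0))
})
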