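# independent oracles used across the suite

# two-sided Fisher p by full hypergeometric enumeration (minlike rule)
enumFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# pure-R brute-force version of the profile peak rule: checks every index
# with explicit loops, then resolves extent overlaps left to right
bruteFindPeaks <- function(y, m = mean(y)) {
  n <- length(y)
  rows <- list()
  lastEnd <- 0L
  for (i in seq_len(n)) {
    if (i < 3L || i > n - 2L) next
    if (!(y[i - 2] < y[i - 1] && y[i - 1] < y[i] &&
          y[i] > y[i + 1] && y[i + 1] > y[i + 2] && y[i] > m)) next
    s <- i
    while (s > 1L && y[s - 1] < y[s]) s <- s - 1L
    e <- i
    while (e < n && y[e + 1] < y[e]) e <- e + 1L
    if (s <= lastEnd) s <- lastEnd + 1L
    rows[[length(rows) + 1L]] <- c(apex = i, start = s, end = e)
    lastEnd <- e
  }
  if (length(rows) == 0L) {
    return(data.frame(apex = integer(0), start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, rows))
}

# toy allelic SNP table straddling every filter threshold (hand-counted)
toySnpTable <- function() {
  data.frame(
    chrom = "chrX",
    pos = 1:20 * 100,
    gene_id = rep(c("g1", "g2"), each = 10),
    exonic = c(rep(TRUE, 15), rep(FALSE, 5)),
    sample_id = "s1",
    #            1   2   3   4   5   6   7   8   9  10 11 12 13 14 15 16 17 18 19 20
    xi_count = c(4L, 5L, 0L, 10L, 3L, 6L, 0L, 50L, 2L, 9L, 5L, 1L, 7L, 0L, 3L, 60L, 5L, 9L, 2L, 0L),
    xa_count = c(5L, 5L, 10L, 0L, 6L, 5L, 9L, 50L, 7L, 0L, 4L, 8L, 2L, 11L, 8L, 40L, 6L, 1L, 3L, 9L))
}
# exonic rows 1:15; totals: 9,10,10,10,9,11,9,100,9,9,9,9,9,11,11 -> pass rows
# with total >= 10 among exonic: rows 2,3,4,6,8,14,15 = 7 survivors
toySnpSurvivors <- 7L
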