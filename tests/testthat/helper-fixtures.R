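# Shared constructed fixtures.

# Six-site QC fixture: one site per designed failure mode plus one clean
# site, used by the filter-order and acceptance tests.
.qcToyFixture <- function() {
  ids <- sprintf("s%d", 1:5)
  sitesDf <- data.frame(
    chrom = "c1", pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = "A",
    alt = c("T", "T", "T", "T,G", "T", "T"),
    anc = "A",
    qual = c(10, 50, 50, 50, 50, 50))
  g <- rbind(
    c(0L, 1L, 1L, 0L, 2L),   # fails QUAL only
    c(0L, 1L, 1L, 0L, 2L),   # mean depth 300
    c(0L, NA, NA, NA, 2L),   # 60% missing
    c(0L, 0L, 1L, 0L, 1L),   # triallelic ALT
    c(0L, 1L, 0L, 0L, 0L),   # singleton
    c(0L, 1L, 1L, 0L, 2L))   # clean
  colnames(g) <- ids
  dp <- matrix(20L, 6, 5, dimnames = list(NULL, ids))
  dp[2, ] <- 300L
  dp[3, 2:4] <- NA
  GenotypeDataset(sitesDf, g, depth = dp, chromLengths = c(c1 = 1000))
}

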