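# Polarization, SFS projection, the escape-and-drag sweep spectrum against
# enumeration and Monte-Carlo oracles, the CLR scan, region clustering,
# the alpha -> s conversion and the locus-overlap permutation test.

test_that("polarization assigns derived counts and exclusion reasons", {
  g <- rbind(c(1L, 1L, 1L, 0L, 0L, 0L),   # outgroup REF-fixed: k = alt count
             c(0L, 2L, 0L, 1L, 1L, 0L),   # outgroup polymorphic at 0.5
             c(1L, 0L, 1L, 2L, 2L, 2L),   # outgroup ALT-fixed: derived = REF
             c(0L, 0L, 0L, 0L, 0L, 0L))   # ingroup monomorphic
  colnames(g) <- c("i1", "i2", "i3", "o1", "o2", "o3")
  ds <- GenotypeDataset(data.frame(chrom = "c1", pos = c(10L, 20L, 30L, 40L),
                                   ref = "A", alt = "T", anc = NA, qual = 50),
                        g)
  meta <- sampleMetadata(data.frame(sample = colnames(g),
                                    group = rep(c("zea", "outgroup"), each = 3),
                                    deme = NA, lat = NA, lon = NA, year = NA))
  pol <- polarizeSites(ds, meta, "outgroup")
  expect_equal(pol$sites$pos, c(10L, 30L))
  expect_equal(pol$sites$k, c(3L, 4L))    # site 30: derived = REF count = 6-2
  expect_equal(pol$sites$n, c(6L, 6L))
  expect_setequal(pol$excluded$reason,
                  c("ambiguous ancestral", "monomorphic ingroup"))
  expect_error(polarizeSites(ds, meta, "nosuch"), "outgroup")
})

test_that("background SFS recovers the 1/i law and handles point masses", {
  ds <- simBackgroundGenotypes(simConfig(10, 8000, 1e6, seed = 101))
  pol <- data.frame(chrom = "sim1", pos = sites(ds)$pos,
                    k = as.integer(rowSums(genotypes(ds))), n = 20L)
  bg <- backgroundSfs(pol)
  pExp <- (1 / (1:19)) / sum(1 / (1:19))
  expect_lt(max(abs(bg$p - pExp)), 0.02)
  one <- backgroundSfs(data.frame(chrom = "c", pos = 1L, k = 1L, n = 6L))
  expect_equal(one$p, c(1, 0, 0, 0, 0))
})

test_that("SFS projection of a point mass is the conditioned hypergeometric", {
  n <- 12; m <- 6; i <- n / 2
  bg <- structure(list(n = n, p = replace(numeric(n - 1), i, 1)),
                  class = "BackgroundSFS")
  got <- projectSfs(bg, m)
  hyper <- dhyper(1:(m - 1), i, n - i, m)
  expect_equal(got$p, hyper / sum(hyper), tolerance = 1e-12)
  # projecting sites with mixed n: the background builder matches direct
  # projection arithmetic
  pol <- data.frame(chrom = "c", pos = 1:2, k = c(6L, 3L), n = c(12L, 6L))
  bgMix <- backgroundSfs(pol)
  expect_equal(bgMix$n, 6L)
  expect_equal(sum(bgMix$p), 1, tolerance = 1e-12)
})

test_that("sweep spectrum is a probability vector and hits its limits", {
  for (n in c(4, 6, 20)) {
    bg <- neutralSfs(n)
    for (alpha in c(1e-6, 1e-4)) for (d in c(0, 1e3, 1e5)) {
      sp <- sweepSpectrum(bg, alpha, d)
      expect_equal(sum(sp), 1, tolerance = 1e-12)
      expect_true(all(sp >= 0))
    }
    # full escape: equals background
    expect_lt(sum(abs(sweepSpectrum(bg, 1, 1e9) - bg$p)), 1e-6)
  }
  # two haplotypes: every polymorphic outcome has k = 1
  bg2 <- neutralSfs(2)
  for (alpha in c(1e-7, 1e-3)) for (d in c(0, 100, 1e6))
    expect_equal(sweepSpectrum(bg2, alpha, d), 1)
  expect_error(sweepSpectrum(neutralSfs(6), 0, 100), "alpha")
})

test_that("sweep spectrum equals direct enumeration for n <= 6", {
  for (n in 3:6) {
    bg <- neutralSfs(n)
    for (pe in c(0, 0.1, 0.3, 0.7, 0.95)) {
      d <- if (pe == 0) 0 else -log(1 - pe)   # alpha = 1 per bp
      got <- sweepSpectrum(bg, 1, d)
      expect_equal(got, enumSweepSpectrum(bg, pe), tolerance = 1e-9)
    }
  }
  # and with a non-neutral background
  bgSkew <- structure(list(n = 5L, p = c(0.7, 0.1, 0.1, 0.1)),
                      class = "BackgroundSFS")
  expect_equal(sweepSpectrum(bgSkew, 1, -log(1 - 0.4)),
               enumSweepSpectrum(bgSkew, 0.4), tolerance = 1e-9)
})

test_that("sweep spectrum matches Monte-Carlo of the generative process", {
  bg6 <- neutralSfs(6)
  mc6 <- mcSweepSpectrum(bg6, 0.3, nAccept = 1e5, seed = 7)
  expect_lt(sum(abs(sweepSpectrum(bg6, 1, -log(0.7)) - mc6)), 0.01)
  bg20 <- neutralSfs(20)
  mc20 <- mcSweepSpectrum(bg20, 0.4, nAccept = 4e5, seed = 8)
  expect_lt(sum(abs(sweepSpectrum(bg20, 1, -log(0.6)) - mc20)), 0.01)
  # near-complete drag: extreme-frequency classes dominate
  mc0 <- mcSweepSpectrum(bg20, 0.01, nAccept = 1e5, seed = 9)
  expect_lt(sum(abs(sweepSpectrum(bg20, 1, -log(1 - 0.01)) - mc0)), 0.02)
})

test_that("distortion decreases with distance at fixed alpha", {
  bg <- neutralSfs(10)
  tv <- vapply(c(0, 1e3, 1e4, 5e4, 1e5, 1e6), function(d)
    0.5 * sum(abs(sweepSpectrum(bg, 1e-5, d) - bg$p)), numeric(1))
  expect_true(all(diff(tv) <= 1e-9))
})

test_that("null scan is calibrated and spiked scans recover the sweep", {
  cfg <- simConfig(10, 2000, 1e6, seed = 111)
  ds <- simBackgroundGenotypes(cfg)
  polNull <- data.frame(chrom = "sim1", pos = sites(ds)$pos,
                        k = as.integer(rowSums(genotypes(ds))), n = 20L)
  bg <- neutralSfs(20)
  scanNull <- clrScan(polNull, bg, span = c(0, 1e6))
  expect_true(all(scanNull@clr >= 0))
  expect_lt(quantile(scanNull@clr, 0.99), 10)
  expect_length(defineSweepRegions(scanNull), 0)
  # spiked: alpha = 1.58e-5 (s ~ 0.05 at the study's r and Ne)
  dsS <- spikeSweepSignal(ds, 5e5, 1.58e-5, seed = 112)
  polS <- data.frame(chrom = "sim1", pos = sites(dsS)$pos,
                     k = as.integer(rowSums(genotypes(dsS))), n = 20L)
  scanS <- clrScan(polS, bg, span = c(0, 1e6))
  peak <- scanS@positions[which.max(scanS@clr)]
  aHat <- scanS@alphaHat[which.max(scanS@clr)]
  expect_lt(abs(peak - 5e5), 5e4)
  expect_lt(abs(log(aHat / 1.58e-5)), log(3))
})

test_that("sweep regions follow the merge/extend arithmetic and tie rule", {
  mkScan <- function(clr, step = 1000) {
    new("SweepScan", chrom = "c1",
        positions = seq(0, by = step, length.out = length(clr)),
        clr = clr, alphaHat = rep(1e-5, length(clr)),
        span = c(0, step * (length(clr) - 1)), gridStep = step)
  }
  clr <- rep(0, 20001)                  # grid 0..20 Mbp at 1 kbp
  clr[c(100, 115) * 1 + 1] <- 100       # outliers at 100 kbp and 115 kbp
  scan <- mkScan(clr)
  reg <- defineSweepRegions(scan, percentile = 99.99)
  expect_length(reg, 1)
  expect_equal(GenomicRanges::start(reg), 80000)
  expect_equal(GenomicRanges::end(reg), 135000)
  clr2 <- rep(0, 20001)
  clr2[c(100, 130) + 1] <- 100          # gap 30 kbp > 20 kbp: two regions
  reg2 <- defineSweepRegions(mkScan(clr2), percentile = 99.99)
  expect_length(reg2, 2)
  # constant CLR: threshold equals the constant, all positions tied in
  constReg <- defineSweepRegions(mkScan(rep(5, 10001)), percentile = 99.99)
  expect_length(constReg, 1)
  expect_equal(GenomicRanges::start(constReg), 0)
  expect_equal(GenomicRanges::end(constReg), 1e7)
  # small scans have no outliers at this percentile
  expect_length(defineSweepRegions(mkScan(c(rep(0, 100), 50))), 0)
})

test_that("selection coefficient from alpha matches the printed arithmetic", {
  expect_equal(estimateS(1.6195e-5, 5.447e-8, 1.03e6), 0.0489,
               tolerance = 1e-3)
  a <- c(1e-6, 1e-5, 1e-4)
  s <- estimateS(a, 5e-8, 1e6)
  expect_true(all(diff(s) < 0))                      # decreasing in alpha
  expect_equal(estimateS(1e-5, 1e-7, 1e6) / estimateS(1e-5, 5e-8, 1e6), 2)
  expect_error(estimateS(-1, 1e-8, 1e6), "positive")
})

test_that("locus overlap permutation behaves at its fixed points", {
  clr <- rep(0, 101); clr[51] <- 100
  scan <- new("SweepScan", chrom = "c1",
              positions = seq(0, 1e5, by = 1000), clr = clr,
              alphaHat = rep(1e-5, 101), span = c(0, 1e5), gridStep = 1000)
  whole <- locusOverlapPermutation(scan, 0, 1e5, nPerm = 99, seed = 1)
  expect_equal(whole$pMean, 1)
  expect_equal(whole$pMax, 1)
  hit <- locusOverlapPermutation(scan, 49500, 50500, nPerm = 999, seed = 2)
  expect_lt(hit$pMax, 0.05)   # ~ locus length / span plus the add-one term
  expect_identical(hit,
                   locusOverlapPermutation(scan, 49500, 50500,
                                           nPerm = 999, seed = 2))
  expect_error(locusOverlapPermutation(scan, 0, 2e5), "longer")
})
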