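# Windowed pi / dxy / Hudson FST against hand arithmetic and a phased
# haplotype-pair oracle, LD decay, and the Welch test.

.oneSiteDs <- function(dosages, pos = 50L, L = 100) {
  g <- matrix(as.integer(dosages), 1, dimnames = list(NULL,
              sprintf("s%d", seq_along(dosages))))
  GenotypeDataset(data.frame(chrom = "c1", pos = pos, ref = "A", alt = "T",
                             anc = "A", qual = 50),
                  g, chromLengths = c(c1 = L))
}

test_that("site pi matches the pairwise-difference formula", {
  # 4 chromosomes, derived count 2, callable 1 bp: 2*2*2/(4*3)
  ds <- .oneSiteDs(c(1, 1))
  w <- data.frame(chrom = "c1", start = 0, end = 100)
  out <- windowPi(ds, NULL, w, callable = 1, minSites = 1)
  expect_equal(out$pi, 2 * 2 * 2 / (4 * 3), tolerance = 1e-12)
  # monomorphic window
  dsMono <- .oneSiteDs(c(0, 0))
  expect_equal(windowPi(dsMono, NULL, w, callable = 1, minSites = 1)$pi, 0)
})

test_that("window pi equals mean pairwise haplotype differences per bp", {
  for (seed in c(1, 2, 3)) {
    fix <- hapFixture(6, 80, L = 5000, seed = seed)
    w <- data.frame(chrom = "c1", start = 0, end = 5000)
    out <- windowPi(fix$ds, NULL, w, minSites = 1)
    oracle <- sum(piSiteHapOracle(fix)) / 5000
    expect_equal(out$pi, oracle, tolerance = 1e-12)
  }
  # missing-aware: per-site oracle enumerates chromosome pairs among
  # non-missing individuals only
  fixM <- hapFixture(8, 60, L = 4000, seed = 9, missProb = 0.2)
  w <- data.frame(chrom = "c1", start = 0, end = 4000)
  out <- windowPi(fixM$ds, NULL, w, minSites = 1)
  oracle <- sum(piSiteHapOracle(fixM), na.rm = TRUE) / 4000
  expect_equal(out$pi, oracle, tolerance = 1e-12)
})

test_that("dxy handles fixed differences, intermediate frequencies, and
           reduces to pi for identical pools", {
  w <- data.frame(chrom = "c1", start = 0, end = 100)
  dsFix <- .oneSiteDs(c(2, 2, 0, 0))
  out <- windowDxy(dsFix, c("s1", "s2"), c("s3", "s4"), w, callable = 1,
                   minSites = 1)
  expect_equal(out$dxy, 1)
  dsHalf <- .oneSiteDs(c(1, 1, 1, 1))
  out2 <- windowDxy(dsHalf, c("s1", "s2"), c("s3", "s4"), w, callable = 1,
                    minSites = 1)
  expect_equal(out2$dxy, 0.5)
  # two halves of one panmictic pool: dxy ~ pi
  ds <- simBackgroundGenotypes(simConfig(20, 3000, 1e5, seed = 71))
  ids <- sampleIds(ds)
  wBig <- data.frame(chrom = "sim1", start = 0, end = 1e5)
  dxy <- windowDxy(ds, ids[1:10], ids[11:20], wBig, minSites = 1)$dxy
  pi <- windowPi(ds, NULL, wBig, minSites = 1)$pi
  expect_lt(abs(dxy - pi) / pi, 0.05)
})

test_that("Hudson FST matches hand arithmetic and its fixed points", {
  w <- data.frame(chrom = "c1", start = 0, end = 100)
  # pA=0.2, pB=0.8, nA=nB=10 chromosomes
  dsAB <- .oneSiteDs(c(1, 1, 0, 0, 0, 2, 2, 2, 1, 1))
  out <- windowFst(dsAB, sprintf("s%d", 1:5), sprintf("s%d", 6:10), w,
                   minSites = 1)
  expect_equal(out$fst, (0.36 - 2 * 0.16 / 9) / 0.68, tolerance = 1e-12)
  dsFix <- .oneSiteDs(c(2, 2, 0, 0))
  expect_equal(windowFst(dsFix, c("s1", "s2"), c("s3", "s4"), w,
                         minSites = 1)$fst, 1)
  # same pool split: FST ~ 0
  ds <- simBackgroundGenotypes(simConfig(20, 5000, 1e5, seed = 72))
  ids <- sampleIds(ds)
  wBig <- data.frame(chrom = "sim1", start = 0, end = 1e5)
  f <- windowFst(ds, ids[1:10], ids[11:20], wBig, minSites = 1)$fst
  expect_lt(abs(f), 0.02)
})

test_that("windows below the informative-site minimum are missing, never zero", {
  ds <- simBackgroundGenotypes(simConfig(5, 300, 1e5, seed = 73))
  w20 <- tileWindows(c(sim1 = 1e5), 20000)   # ~60 sites per 20 kbp window
  out <- windowPi(ds, NULL, w20)             # default rule needs 200
  expect_true(all(is.na(out$pi)))
  expect_true(all(out$nSites > 0))
  out2 <- windowPi(ds, NULL, w20, minSites = 10)
  expect_true(all(!is.na(out2$pi)))
})

test_that("window statistics are invariant to site order permutation", {
  ds <- simBackgroundGenotypes(simConfig(8, 400, 5e4, seed = 74))
  w <- tileWindows(ds, 10000)
  ref <- windowFst(ds, sampleIds(ds)[1:4], sampleIds(ds)[5:8], w,
                   minSites = 5)
  set.seed(1); perm <- sample(nSites(ds))
  st <- sites(ds)[perm, ]; g <- genotypes(ds)[perm, ]
  ord <- order(st$pos)
  dsP <- GenotypeDataset(st[ord, ], g[ord, ], chromLengths = chromLengths(ds))
  got <- windowFst(dsP, sampleIds(ds)[1:4], sampleIds(ds)[5:8], w,
                   minSites = 5)
  expect_equal(got$fst, ref$fst, tolerance = 1e-12)
})

test_that("LD decay: duplicated sites give r2 = 1; independent sites sit at
           the 1/(n-1) sampling level; crossing distance is monotone", {
  set.seed(75)
  n <- 50
  # a duplicated site pair alone in its distance bin: r2 exactly 1
  dupDos <- rbinom(n, 2, 0.5)
  gDup <- rbind(dupDos, dupDos, rbinom(n, 2, 0.5))
  colnames(gDup) <- sprintf("s%02d", 1:n)
  dsDup <- GenotypeDataset(
    data.frame(chrom = "c1", pos = c(100L, 1600L, 45000L), ref = "A",
               alt = "T", anc = "A", qual = 50),
    gDup, chromLengths = c(c1 = 5e4))
  outDup <- ldDecay(dsDup, maxDist = 2e4, binWidth = 1000)
  expect_equal(outDup$decay$meanR2[2], 1, tolerance = 1e-9)
  # independent sites: mean r2 at the 1/(n-1) sampling bias level
  m <- 120
  g <- matrix(rbinom(n * m, 2, 0.5), m, n,
              dimnames = list(NULL, sprintf("s%02d", 1:n)))
  pos <- sort(sample(2000:50000, m))
  ds <- GenotypeDataset(data.frame(chrom = "c1", pos = pos, ref = "A",
                                   alt = "T", anc = "A", qual = 50),
                        g, chromLengths = c(c1 = 5e4))
  out <- ldDecay(ds, maxDist = 2e4, binWidth = 1000)
  meanR2 <- mean(out$decay$meanR2, na.rm = TRUE)
  expect_lt(abs(meanR2 - 1 / (n - 1)), 2 / (n - 1))
  d1 <- ldDecay(ds, maxDist = 2e4, binWidth = 1000, background = 0.05)
  d2 <- ldDecay(ds, maxDist = 2e4, binWidth = 1000, background = 0.5)
  expect_true(is.na(d1$backgroundDist) ||
                d2$backgroundDist <= d1$backgroundDist)
})

test_that("Welch test: worked example, identical inputs, formula oracle", {
  w <- welchTest(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(w$t, -2.191, tolerance = 1e-3)
  expect_equal(w$df, 6.0, tolerance = 1e-9)
  same <- welchTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$pTwoSided, 1)
  set.seed(76)
  for (i in 1:100) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    got <- welchTest(a, b); exp <- welchOracle(a, b)
    expect_equal(got$t, exp$t, tolerance = 1e-10)
    expect_equal(got$df, exp$df, tolerance = 1e-10)
    expect_equal(got$pTwoSided, exp$p, tolerance = 1e-10)
  }
})
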