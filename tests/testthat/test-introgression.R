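# ABBA-BABA statistics: site-pattern arithmetic, windowed D and fd-hat on
# constructed introgression fixtures, per-individual tract recovery, and
# the segment contrast.

test_that("site pattern weights match plug-in arithmetic", {
  p <- sitePatterns(0, 1, 1, 0)
  expect_equal(unlist(p), c(abba = 1, baba = 0, abbaD = 1, babaD = 0))
  p2 <- sitePatterns(0.2, 0.8, 0.6, 0)
  expect_equal(p2$abba, 0.384, tolerance = 1e-12)
  expect_equal(p2$baba, 0.024, tolerance = 1e-12)
  expect_equal(p2$abbaD, 0.512, tolerance = 1e-12)
  expect_equal(p2$babaD, 0.032, tolerance = 1e-12)
  # p2 = p1 contributes zero to the D numerator
  p3 <- sitePatterns(0.3, 0.3, 0.7, 0)
  expect_equal(p3$abba - p3$baba, 0, tolerance = 1e-12)
})

.fourTaxonDs <- function(p1, p2, p3, pO, positions) {
  # 2 diploids per pool, dosages chosen to hit the target frequencies
  stopifnot(all(c(p1, p2, p3, pO) %in% c(0, 0.5, 1)))
  dos <- function(p) switch(as.character(p), "0" = c(0L, 0L),
                            "0.5" = c(1L, 1L), "1" = c(2L, 2L))
  g <- t(vapply(seq_along(positions), function(i)
    c(dos(p1[i]), dos(p2[i]), dos(p3[i]), dos(pO[i])), integer(8)))
  colnames(g) <- c("p1a", "p1b", "p2a", "p2b", "p3a", "p3b", "oa", "ob")
  GenotypeDataset(data.frame(chrom = "c1", pos = positions, ref = "A",
                             alt = "T", anc = "A", qual = 50),
                  g, chromLengths = c(c1 = max(positions) + 10))
}

test_that("a window of pure ABBA sites gives D = 1 and fd-hat = 1", {
  n <- 30
  ds <- .fourTaxonDs(rep(0, n), rep(1, n), rep(1, n), rep(0, n),
                     seq(100, by = 50, length.out = n))
  w <- data.frame(chrom = "c1", start = 0, end = 2000)
  out <- windowDFd(ds, c("p1a", "p1b"), c("p2a", "p2b"), c("p3a", "p3b"),
                   c("oa", "ob"), w, minSnps = 10)
  expect_equal(out$d, 1)
  expect_equal(out$fd, 1)
})

test_that("fd-hat is missing (never negative) when window D <= 0", {
  n <- 30
  # pure BABA sites: derived shared by P1 and P3
  ds <- .fourTaxonDs(rep(1, n), rep(0, n), rep(1, n), rep(0, n),
                     seq(100, by = 50, length.out = n))
  w <- data.frame(chrom = "c1", start = 0, end = 2000)
  out <- windowDFd(ds, c("p1a", "p1b"), c("p2a", "p2b"), c("p3a", "p3b"),
                   c("oa", "ob"), w, minSnps = 10)
  expect_equal(out$d, -1)
  expect_true(is.na(out$fd))
  outZ <- windowDFd(ds, c("p1a", "p1b"), c("p2a", "p2b"), c("p3a", "p3b"),
                    c("oa", "ob"), w, minSnps = 10, dNonPos = "zero")
  expect_equal(outZ$fd, 0)
})

test_that("null fixture: fd-hat distribution is centred near zero", {
  sc <- introgressionScenario(divergence = 0.05)
  r <- simIntrogressionDataset(sc, simConfig(1, 23000, 2e6, seed = 81))
  m <- r$meta
  w <- tileWindows(r$ds, 20000)
  fd <- windowDFd(r$ds, groupSamples(m, "P1"), groupSamples(m, "P2"),
                  groupSamples(m, "P3"), groupSamples(m, "outgroup"),
                  w, dNonPos = "zero")
  expect_lt(abs(mean(fd$fd, na.rm = TRUE)), 0.02)
  expect_lt(abs(mean(fd$d, na.rm = TRUE)), 0.05)
  expect_true(all(fd$fd >= 0 & fd$fd <= 1, na.rm = TRUE))
})

test_that("homozygous and heterozygous donor tracts give fd-hat near 1 and 0.5", {
  base <- list(divergence = 0.1, admixedSamples = "P2_01",
               tracts = list(P2_01 = cbind(2e5, 4e5)),
               polyMix = c(shared = 0, recipient = 1, donor = 0))
  cfg <- simConfig(1, 12000, 1e6, seed = 82)
  for (case in list(list(pl = 2, target = 1), list(pl = 1, target = 0.5))) {
    sc <- introgressionScenario(base$divergence,
                                admixedSamples = base$admixedSamples,
                                tracts = base$tracts,
                                donorTractPloidy = case$pl,
                                polyMix = base$polyMix)
    r <- simIntrogressionDataset(sc, cfg)
    m <- r$meta
    w <- tileWindows(r$ds, 20000)
    fd <- perIndividualFd(r$ds, "P2_01", groupSamples(m, "P1"),
                          groupSamples(m, "P3"), groupSamples(m, "outgroup"),
                          w, minSnps = 50, dNonPos = "zero")
    inT <- fd$start >= 2e5 & fd$end <= 4e5
    expect_lt(abs(mean(fd$fd[inT], na.rm = TRUE) - case$target), 0.1)
    expect_lt(mean(abs(fd$fd[!inT]), na.rm = TRUE), 0.1)
  }
})

test_that("population fd-hat estimates the admixed fraction", {
  sc <- introgressionScenario(divergence = 0.05, admixedSamples = "P2_01",
                              tracts = list(P2_01 = cbind(2e5, 4e5)))
  r <- simIntrogressionDataset(sc, simConfig(1, 12000, 1e6, seed = 83))
  m <- r$meta
  w <- tileWindows(r$ds, 20000)
  fd <- windowDFd(r$ds, groupSamples(m, "P1"), groupSamples(m, "P2"),
                  groupSamples(m, "P3"), groupSamples(m, "outgroup"),
                  w, minSnps = 100)
  inT <- fd$start >= 2e5 & fd$end <= 4e5
  # 1 homozygous carrier of 10 P2 diploids: admixture fraction 0.1
  expect_lt(abs(mean(fd$fd[inT], na.rm = TRUE) - 0.1), 0.05)
})

test_that("per-individual fd-hat > 0.5 recovers truth-tract windows", {
  tr <- list(P2_02 = cbind(3e5, 5e5))   # 10 windows of 20 kbp
  sc <- introgressionScenario(divergence = 0.05, admixedSamples = "P2_02",
                              tracts = tr)
  r <- simIntrogressionDataset(sc, simConfig(1, 24000, 2e6, seed = 84))
  m <- r$meta
  w <- tileWindows(r$ds, 20000)
  truthWin <- w$start >= 3e5 & w$end <= 5e5
  hits <- matrix(FALSE, nrow(w), length(groupSamples(m, "P2")))
  for (j in seq_along(groupSamples(m, "P2"))) {
    id <- groupSamples(m, "P2")[j]
    fd <- perIndividualFd(r$ds, id, groupSamples(m, "P1"),
                          groupSamples(m, "P3"), groupSamples(m, "outgroup"),
                          w, minSnps = 100, dNonPos = "zero")
    hits[, j] <- !is.na(fd$fd) & fd$fd > 0.5
  }
  carrier <- match("P2_02", groupSamples(m, "P2"))
  sens <- mean(hits[truthWin, carrier])
  fp <- mean(hits[!truthWin, ] | FALSE)
  expect_gte(sens, 0.9)
  expect_lte(fp, 0.05)
})

test_that("segment contrast: identical segments give p = 1; distinct
           Balding-Nichols F are separated; means are plain means", {
  wA <- data.frame(fst = c(0.05, 0.06, 0.04))
  same <- segmentCompare(wA, wA, "fst")
  expect_equal(same$t, 0)
  expect_equal(same$pTwoSided, 1)
  expect_equal(same$meanA, mean(wA$fst))
  coords <- data.frame(lat = c(30, 32), lon = c(-95, -93))
  cfgA <- simConfig(1, 9000, 6e6, seed = 85)
  cfgB <- simConfig(1, 9000, 6e6, seed = 86)
  rA <- simStructuredDemes(demeScenario(coords, function(km) 0.05, 15), cfgA)
  rB <- simStructuredDemes(demeScenario(coords, function(km) 0.11, 15), cfgB)
  w <- tileWindows(c(sim1 = 6e6), 20000)
  fA <- windowFst(rA$ds, rA$meta$sample[rA$meta$deme == "D01"],
                  rA$meta$sample[rA$meta$deme == "D02"], w, minSites = 20)
  fB <- windowFst(rB$ds, rB$meta$sample[rB$meta$deme == "D01"],
                  rB$meta$sample[rB$meta$deme == "D02"], w, minSites = 20)
  out <- segmentCompare(fA, fB, "fst")
  expect_lt(out$pTwoSided, 0.01)
  expect_lt(out$meanA, out$meanB)
})
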