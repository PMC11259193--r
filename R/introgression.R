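# Frequency-based ABBA-BABA statistics. Sites are polarized against the
# outgroup (major outgroup allele = ancestral; intermediate outgroup
# frequencies excluded); D is the normalized ABBA-BABA imbalance and
# fd-hat normalizes the same numerator by its value under complete sharing
# with the donor (pD = max(p2, p3) substituted for both p2 and p3), giving
# a windowed estimator of the admixture fraction.

#' ABBA/BABA site pattern weights
#'
#' From per-site derived-allele frequencies in P1, P2, P3 and the outgroup:
#' ABBA = (1-p1) p2 p3 (1-pO), BABA = p1 (1-p2) p3 (1-pO); the donor terms
#' substitute pD = max(p2, p3) for both p2 and p3.
#'
#' @param p1,p2,p3,pO derived-allele frequencies (vectors)
#' @return data.frame with columns `abba`, `baba`, `abbaD`, `babaD`
#' @export
sitePatterns <- function(p1, p2, p3, pO) {
  pD <- pmax(p2, p3)
  data.frame(abba = (1 - p1) * p2 * p3 * (1 - pO),
             baba = p1 * (1 - p2) * p3 * (1 - pO),
             abbaD = (1 - p1) * pD * pD * (1 - pO),
             babaD = p1 * (1 - pD) * pD * (1 - pO))
}

# Derived-allele frequencies for the four pools, polarized to the outgroup
# major allele. Sites with outgroup frequency strictly inside
# (1-fixedFreq, fixedFreq), with a missing outgroup state, or with fewer
# than 2 non-missing chromosomes in P1/P2/P3 are dropped.
.derivedFreqs <- function(ds, p1Samples, p2Samples, p3Samples,
                          outgroupSamples, fixedFreq = 0.8) {
  c1 <- .alleleCounts(ds, p1Samples)
  c2 <- .alleleCounts(ds, p2Samples)
  c3 <- .alleleCounts(ds, p3Samples)
  fO <- alleleFreqs(ds, outgroupSamples)
  keep <- !is.na(fO) & (fO <= 1 - fixedFreq | fO >= fixedFreq) &
    c1$an >= 2 & c2$an >= 2 & c3$an >= 2
  flip <- !is.na(fO) & fO >= fixedFreq   # ALT is ancestral
  p1 <- ifelse(flip, 1 - c1$ac / c1$an, c1$ac / c1$an)
  p2 <- ifelse(flip, 1 - c2$ac / c2$an, c2$ac / c2$an)
  p3 <- ifelse(flip, 1 - c3$ac / c3$an, c3$ac / c3$an)
  pO <- ifelse(flip, 1 - fO, fO)
  list(p1 = p1, p2 = p2, p3 = p3, pO = pO, keep = keep)
}

#' Windowed D and fd-hat
#'
#' Per window, D = sum(ABBA - BABA) / sum(ABBA + BABA) and
#' fd-hat = sum(ABBA - BABA) / sum(ABBA_D - BABA_D). fd-hat is reported
#' missing (or zero, with `dNonPos = "zero"`) whenever the window's D <= 0
#' or a denominator is non-positive; windows with fewer than `minSnps`
#' usable sites are missing entirely.
#'
#' @param ds a [GenotypeDataset-class]
#' @param p1Samples,p2Samples,p3Samples,outgroupSamples sample ids of the
#'   non-admixed recipient reference (P1), test (P2), donor (P3) and
#'   outgroup pools
#' @param windows window table from [tileWindows()]
#' @param minSnps minimum usable SNPs per window (default 200, the rule
#'   used for 20 kbp windows)
#' @param dNonPos `"missing"` (default) or `"zero"`: how to report fd-hat
#'   when D <= 0
#' @param fixedFreq outgroup consensus threshold for polarization
#' @return `windows` with added columns `nSnps`, `sumAbba`, `sumBaba`, `d`,
#'   `fd`
#' @export
windowDFd <- function(ds, p1Samples, p2Samples, p3Samples, outgroupSamples,
                      windows, minSnps = 200,
                      dNonPos = c("missing", "zero"), fixedFreq = 0.8) {
  dNonPos <- match.arg(dNonPos)
  fr <- .derivedFreqs(ds, p1Samples, p2Samples, p3Samples, outgroupSamples,
                      fixedFreq)
  pat <- sitePatterns(fr$p1, fr$p2, fr$p3, fr$pO)
  idx <- .windowIndex(sites(ds), windows)
  ok <- fr$keep & !is.na(idx)
  agg <- function(v) {
    out <- numeric(nrow(windows))
    s <- rowsum(v[ok], idx[ok])
    out[as.integer(rownames(s))] <- s[, 1]
    out
  }
  windows$nSnps <- agg(rep(1, length(idx)))
  windows$sumAbba <- agg(pat$abba)
  windows$sumBaba <- agg(pat$baba)
  sumNum <- windows$sumAbba - windows$sumBaba
  sumTot <- windows$sumAbba + windows$sumBaba
  sumDen <- agg(pat$abbaD) - agg(pat$babaD)
  d <- ifelse(sumTot > 0, sumNum / sumTot, NA_real_)
  fd <- ifelse(!is.na(d) & d > 0 & sumDen > 0, sumNum / sumDen, NA_real_)
  if (dNonPos == "zero")
    fd[is.na(fd) & windows$nSnps > 0] <- 0
  low <- windows$nSnps < minSnps
  d[low] <- NA_real_; fd[low] <- NA_real_
  windows$d <- d
  windows$fd <- fd
  windows
}

#' Per-individual windowed fd-hat
#'
#' As [windowDFd()] with a single diploid as P2, so p2 takes values in
#' \{0, 0.5, 1\}. Windows where the individual is entirely missing are
#' missing.
#'
#' @inheritParams windowDFd
#' @param individual one sample id, used as the P2 set
#' @return `windows` with D/fd-hat columns for this individual
#' @export
perIndividualFd <- function(ds, individual, p1Samples, p3Samples,
                            outgroupSamples, windows, minSnps = 200,
                            dNonPos = c("missing", "zero"), fixedFreq = 0.8) {
  stopifnot(length(individual) == 1)
  windowDFd(ds, p1Samples, individual, p3Samples, outgroupSamples,
            windows, minSnps = minSnps, dNonPos = dNonPos,
            fixedFreq = fixedFreq)
}

#' Compare a window statistic between two genomic segments
#'
#' Welch two-sample t test (see [welchTest()]) on the per-window values of
#' the chosen statistic between two coordinate-defined segments, as used
#' for the chromosome-15 segment A/B contrasts.
#'
#' @param windowsA,windowsB window record data.frames (e.g. from
#'   [windowFst()]) for the two segments
#' @param statistic name of the column to compare (e.g. `"fst"`, `"dxy"`)
#' @return list as from [welchTest()]
#' @export
segmentCompare <- function(windowsA, windowsB, statistic = "fst") {
  vA <- windowsA[[statistic]]; vB <- windowsB[[statistic]]
  if (is.null(vA) || is.null(vB))
    stop("statistic column not found: ", statistic)
  vA <- vA[!is.na(vA)]; vB <- vB[!is.na(vB)]
  if (length(vA) < 2 || length(vB) < 2)
    stop("need at least 2 non-missing windows per segment")
  welchTest(vA, vB)
}
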