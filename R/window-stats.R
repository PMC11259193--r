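# Windowed summary statistics: nucleotide diversity, absolute divergence,
# Hudson FST (ratio of averages), LD decay and the Welch contrast used for
# segment comparisons. Windows are tiled, non-overlapping and aligned to
# multiples of the window size; sub-threshold windows are reported missing,
# never zero.

#' Tile non-overlapping analysis windows across chromosomes
#'
#' Windows are 0-based half-open `[start, end)` and aligned to multiples of
#' `size` from position 0.
#'
#' @param chromLengths named chromosome lengths in bp (or a
#'   [GenotypeDataset-class], whose `chromLengths` are used)
#' @param size window size in bp (20000 and 100000 are the sizes used for
#'   the study's figures)
#' @return data.frame with columns `chrom`, `start`, `end`
#' @export
tileWindows <- function(chromLengths, size = 20000) {
  if (is(chromLengths, "GenotypeDataset"))
    chromLengths <- chromLengths(chromLengths)
  stopifnot(size >= 1, length(chromLengths) >= 1, !is.null(names(chromLengths)))
  out <- lapply(names(chromLengths), function(ch) {
    L <- chromLengths[[ch]]
    starts <- seq(0, max(0, L - 1), by = size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, L))
  })
  do.call(rbind, out)
}

# Map 1-based site positions onto 0-based half-open windows; returns the
# window row index per site (NA when outside every window).
.windowIndex <- function(st, windows) {
  idx <- rep(NA_integer_, nrow(st))
  for (w in seq_len(nrow(windows))) {
    sel <- st$chrom == windows$chrom[w] &
      st$pos > windows$start[w] & st$pos <= windows$end[w]
    idx[sel] <- w
  }
  idx
}

# Default minimum informative-site rule by window length class: 20 kbp
# windows require 200 sites, 100 kbp windows 100; other sizes get a
# proportional 20 kbp-equivalent rule.
.defaultMinSites <- function(windows) {
  len <- windows$end - windows$start
  ifelse(len >= 1e5, 100L, 200L)
}

#' Windowed nucleotide diversity
#'
#' Per site, pi = 2 i (n - i) / (n (n - 1)) with i the derived/ALT count
#' among n non-missing chromosomes (the mean pairwise difference at the
#' site); window pi is the sum over sites divided by the window's callable
#' length.
#'
#' @param ds a [GenotypeDataset-class]
#' @param samples sample ids of the population (default all)
#' @param windows window table from [tileWindows()]
#' @param callable callable bp per window: a scalar, a vector matching
#'   `windows`, or `NULL` to use each window's full length
#' @param minSites minimum sites per window; below it the window value is
#'   `NA`. Default 200 for 20 kbp windows, 100 for 100 kbp windows.
#' @return `windows` with added columns `nSites` and `pi`
#' @export
windowPi <- function(ds, samples = NULL, windows, callable = NULL,
                     minSites = NULL) {
  cnt <- .alleleCounts(ds, samples)
  i <- cnt$ac; n <- cnt$an
  piSite <- ifelse(n >= 2, 2 * i * (n - i) / (n * (n - 1)), NA_real_)
  idx <- .windowIndex(sites(ds), windows)
  if (is.null(minSites)) minSites <- .defaultMinSites(windows)
  minSites <- rep_len(minSites, nrow(windows))
  if (is.null(callable)) callable <- windows$end - windows$start
  callable <- rep_len(callable, nrow(windows))
  ok <- !is.na(idx) & !is.na(piSite)
  sums <- rowsum(piSite[ok], idx[ok])
  ns <- rowsum(rep(1L, sum(ok)), idx[ok])
  windows$nSites <- 0L
  windows$nSites[as.integer(rownames(ns))] <- ns[, 1]
  windows$pi <- NA_real_
  wIdx <- as.integer(rownames(sums))
  windows$pi[wIdx] <- sums[, 1] / callable[wIdx]
  windows$pi[windows$nSites < minSites | callable <= 0] <- NA_real_
  windows
}

#' Windowed absolute divergence (dxy)
#'
#' Per site, d = pA (1 - pB) + pB (1 - pA) from non-missing allele
#' frequencies in the two populations; window dxy is the sum over sites
#' divided by callable length. Sites entirely missing in either population
#' are skipped.
#'
#' @inheritParams windowPi
#' @param samplesA,samplesB sample ids of the two populations
#' @return `windows` with added columns `nSites` and `dxy`
#' @export
windowDxy <- function(ds, samplesA, samplesB, windows, callable = NULL,
                      minSites = NULL) {
  pA <- alleleFreqs(ds, samplesA)
  pB <- alleleFreqs(ds, samplesB)
  dSite <- pA * (1 - pB) + pB * (1 - pA)
  idx <- .windowIndex(sites(ds), windows)
  if (is.null(minSites)) minSites <- .defaultMinSites(windows)
  minSites <- rep_len(minSites, nrow(windows))
  if (is.null(callable)) callable <- windows$end - windows$start
  callable <- rep_len(callable, nrow(windows))
  ok <- !is.na(idx) & !is.na(dSite)
  sums <- rowsum(dSite[ok], idx[ok])
  ns <- rowsum(rep(1L, sum(ok)), idx[ok])
  windows$nSites <- 0L
  windows$nSites[as.integer(rownames(ns))] <- ns[, 1]
  windows$dxy <- NA_real_
  wIdx <- as.integer(rownames(sums))
  windows$dxy[wIdx] <- sums[, 1] / callable[wIdx]
  windows$dxy[windows$nSites < minSites | callable <= 0] <- NA_real_
  windows
}

#' Windowed Hudson FST (ratio of averages)
#'
#' Per site, numerator = (pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)
#' and denominator = pA(1-pB) + pB(1-pA); the window estimate is the ratio
#' of the sums. Sites need at least 2 non-missing chromosomes in each
#' population; windows whose denominator sum is zero are missing.
#'
#' @inheritParams windowDxy
#' @return `windows` with added columns `nSites` and `fst`
#' @export
windowFst <- function(ds, samplesA, samplesB, windows, minSites = NULL) {
  cA <- .alleleCounts(ds, samplesA)
  cB <- .alleleCounts(ds, samplesB)
  pA <- cA$ac / cA$an; pB <- cB$ac / cB$an
  usable <- cA$an >= 2 & cB$an >= 2
  num <- (pA - pB)^2 - pA * (1 - pA) / (cA$an - 1) - pB * (1 - pB) / (cB$an - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  num[!usable] <- NA_real_; den[!usable] <- NA_real_
  idx <- .windowIndex(sites(ds), windows)
  if (is.null(minSites)) minSites <- .defaultMinSites(windows)
  minSites <- rep_len(minSites, nrow(windows))
  ok <- !is.na(idx) & !is.na(num)
  numS <- rowsum(num[ok], idx[ok])
  denS <- rowsum(den[ok], idx[ok])
  ns <- rowsum(rep(1L, sum(ok)), idx[ok])
  windows$nSites <- 0L
  windows$nSites[as.integer(rownames(ns))] <- ns[, 1]
  windows$fst <- NA_real_
  wIdx <- as.integer(rownames(numS))
  fst <- numS[, 1] / denS[, 1]
  fst[denS[, 1] <= 0] <- NA_real_
  windows$fst[wIdx] <- fst
  windows$fst[windows$nSites < minSites] <- NA_real_
  windows
}

#' Linkage disequilibrium decay
#'
#' Composite (genotype-dosage) r-squared between site pairs, binned by
#' pairwise bp distance. r-squared is the squared Pearson correlation of
#' dosage vectors over samples non-missing at both sites; monomorphic
#' pairs are skipped. Also reports the smallest bin midpoint whose mean
#' r-squared is at or below `background`.
#'
#' @param ds a [GenotypeDataset-class]
#' @param maxDist maximum pairwise distance in bp
#' @param binWidth distance bin width in bp
#' @param background background r-squared level for the crossing distance
#' @param maxPairs cap on the number of site pairs examined (pairs are
#'   enumerated nearest-first per site)
#' @return list with `decay` (data.frame `dist`, `meanR2`, `nPairs`) and
#'   `backgroundDist` (bp, `NA` if never reached)
#' @export
ldDecay <- function(ds, maxDist = 50000, binWidth = 1000,
                    background = 0.002, maxPairs = 2e6) {
  st <- sites(ds)
  g <- genotypes(ds)
  if (nrow(st) < 2) stop("need at least 2 sites")
  nb <- ceiling(maxDist / binWidth)
  sumR2 <- numeric(nb); nP <- numeric(nb)
  total <- 0
  for (i in seq_len(nrow(st) - 1)) {
    j <- i + 1L
    while (j <= nrow(st) && st$chrom[j] == st$chrom[i] &&
           (d <- st$pos[j] - st$pos[i]) <= maxDist) {
      r <- suppressWarnings(stats::cor(g[i, ], g[j, ],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r)) {
        b <- min(nb, ceiling(d / binWidth))
        sumR2[b] <- sumR2[b] + r * r
        nP[b] <- nP[b] + 1
        total <- total + 1
      }
      j <- j + 1L
    }
    if (total >= maxPairs) break
  }
  decay <- data.frame(dist = (seq_len(nb) - 0.5) * binWidth,
                      meanR2 = ifelse(nP > 0, sumR2 / nP, NA_real_),
                      nPairs = nP)
  below <- which(!is.na(decay$meanR2) & decay$meanR2 <= background)
  list(decay = decay,
       backgroundDist = if (length(below)) decay$dist[min(below)] else NA_real_)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' via [stats::t.test()]. The one-sided p-value is for the alternative
#' mean(A) > mean(B).
#'
#' @param valuesA,valuesB numeric vectors (at least 2 values each)
#' @return list with `t`, `df`, `pTwoSided`, `pOneSided`, `meanA`, `meanB`
#' @export
welchTest <- function(valuesA, valuesB) {
  valuesA <- valuesA[!is.na(valuesA)]
  valuesB <- valuesB[!is.na(valuesB)]
  stopifnot(length(valuesA) >= 2, length(valuesB) >= 2)
  vA <- stats::var(valuesA); vB <- stats::var(valuesB)
  if (vA == 0 && vB == 0) {
    if (mean(valuesA) == mean(valuesB))
      return(list(t = 0, df = NA_real_, pTwoSided = 1, pOneSided = 0.5,
                  meanA = mean(valuesA), meanB = mean(valuesB)))
    # degenerate: zero variance, unequal means
    t <- if (mean(valuesA) > mean(valuesB)) Inf else -Inf
    return(list(t = t, df = NA_real_, pTwoSided = 0,
                pOneSided = if (t > 0) 0 else 1,
                meanA = mean(valuesA), meanB = mean(valuesB)))
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = FALSE)
  t <- unname(tt$statistic); df <- unname(tt$parameter)
  list(t = t, df = df, pTwoSided = tt$p.value,
       pOneSided = stats::pt(t, df, lower.tail = FALSE),
       meanA = mean(valuesA), meanB = mean(valuesB))
}
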