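# Composite-likelihood sweep scan on the unfolded site frequency spectrum.
# The background (genome-wide) spectrum is the null model; near a selected
# site the spectrum is distorted by hitchhiking: each of the n sampled
# lineages escapes the sweep by recombination with probability
# p_e = 1 - exp(-alpha d) at distance d, and non-escaped lineages are
# dragged to the state of the single sweeping ancestor. Only polymorphic
# sites are modelled; the distorted spectrum is conditioned on polymorphism.

#' Neutral unfolded site frequency spectrum
#'
#' @param nChrom number of chromosomes (haploid sample size)
#' @return a `BackgroundSFS`: list with `n` and probabilities `p` over
#'   derived counts 1..n-1, proportional to 1/i
#' @export
neutralSfs <- function(nChrom) {
  stopifnot(nChrom >= 2)
  i <- seq_len(nChrom - 1)
  structure(list(n = as.integer(nChrom), p = (1 / i) / sum(1 / i)),
            class = "BackgroundSFS")
}

# Full hypergeometric projection of probabilities over 1..n-1 down to
# counts 0..m when m lineages are drawn without replacement from n.
.projFull <- function(p, n, m) {
  out <- numeric(m + 1)
  for (i in seq_len(n - 1))
    out <- out + p[i] * stats::dhyper(0:m, i, n - i, m)
  out
}

#' Project a background spectrum to a smaller sample size
#'
#' Hypergeometric expectation projection: the probability of j derived among
#' m sampled lineages is the average over source classes i of
#' C(i,j) C(n-i, m-j) / C(n,m). The projected spectrum is re-conditioned on
#' polymorphism (classes 1..m-1).
#'
#' @param bg a `BackgroundSFS`
#' @param m target number of chromosomes (2 <= m <= bg$n)
#' @return a `BackgroundSFS` at sample size m
#' @export
projectSfs <- function(bg, m) {
  stopifnot(inherits(bg, "BackgroundSFS"), m >= 2, m <= bg$n)
  if (m == bg$n) return(bg)
  full <- .projFull(bg$p, bg$n, m)
  p <- full[2:m]
  structure(list(n = as.integer(m), p = p / sum(p)), class = "BackgroundSFS")
}

#' Polarize sites against outgroup samples
#'
#' The ancestral allele is the allele at frequency at least `fixedFreq` in
#' the outgroup consensus. Sites with an ambiguous (intermediate-frequency)
#' or entirely missing outgroup state are excluded with a reason, as are
#' sites monomorphic in the ingroup after polarization.
#'
#' @param ds a [GenotypeDataset-class]
#' @param meta sample metadata
#' @param outgroupGroups group labels treated as outgroups
#' @param ingroupSamples ingroup sample ids; default all samples not in an
#'   outgroup group
#' @param fixedFreq consensus frequency required to call the ancestral
#'   state (default 0.8)
#' @return list with `sites` (data.frame `chrom`, `pos`, `k`, `n`: derived
#'   count and non-missing chromosomes) and `excluded` (data.frame with a
#'   `reason` per dropped site)
#' @export
polarizeSites <- function(ds, meta, outgroupGroups,
                          ingroupSamples = NULL, fixedFreq = 0.8) {
  og <- groupSamples(meta, outgroupGroups)
  if (!length(og)) stop("no outgroup samples found")
  if (is.null(ingroupSamples))
    ingroupSamples <- setdiff(sampleIds(ds), og)
  fO <- alleleFreqs(ds, og)
  cnt <- .alleleCounts(ds, ingroupSamples)
  st <- sites(ds)
  reason <- rep(NA_character_, nSites(ds))
  reason[is.na(fO)] <- "missing outgroup"
  amb <- !is.na(fO) & fO > 1 - fixedFreq & fO < fixedFreq
  reason[amb] <- "ambiguous ancestral"
  derivedIsAlt <- !is.na(fO) & fO <= 1 - fixedFreq
  derivedIsRef <- !is.na(fO) & fO >= fixedFreq
  k <- ifelse(derivedIsAlt, cnt$ac, cnt$an - cnt$ac)
  mono <- is.na(reason) & (k == 0 | k == cnt$an | cnt$an < 2)
  reason[mono] <- "monomorphic ingroup"
  keep <- is.na(reason)
  list(
    sites = data.frame(chrom = st$chrom[keep], pos = st$pos[keep],
                       k = as.integer(k[keep]), n = as.integer(cnt$an[keep])),
    excluded = data.frame(chrom = st$chrom[!keep], pos = st$pos[!keep],
                          reason = reason[!keep])
  )
}

#' Background unfolded SFS from polarized sites
#'
#' Sites observed at a larger sample size than `nTarget` are projected down
#' by hypergeometric expectation; the result is normalized over derived
#' counts 1..nTarget-1.
#'
#' @param polSites polarized site table from [polarizeSites()] (`$sites`)
#' @param nTarget common sample size; default the smallest per-site n
#' @return a `BackgroundSFS`
#' @export
backgroundSfs <- function(polSites, nTarget = NULL) {
  if (is.data.frame(polSites) == FALSE && !is.null(polSites$sites))
    polSites <- polSites$sites
  if (!nrow(polSites)) stop("no polarized sites")
  if (is.null(nTarget)) nTarget <- min(polSites$n)
  stopifnot(nTarget >= 2, all(polSites$n >= nTarget))
  counts <- numeric(nTarget - 1)
  for (nn in unique(polSites$n)) {
    sel <- polSites$n == nn
    tab <- tabulate(polSites$k[sel], nbins = nn - 1)
    if (nn == nTarget) {
      counts <- counts + tab
    } else {
      p <- tab / sum(tab)
      full <- .projFull(p, nn, nTarget)
      counts <- counts + sum(tab) * full[2:nTarget] / sum(full[2:nTarget])
    }
  }
  structure(list(n = as.integer(nTarget), p = counts / sum(counts)),
            class = "BackgroundSFS")
}

# Sweep-distorted spectrum at a given escape probability. Mixture over the
# number of escaped lineages e ~ Binomial(n, pe); for e < n, m = e + 1
# exchangeable lineages (the escapees plus the sweeping ancestor) are drawn
# from the background by hypergeometric projection; the ancestor's state is
# copied to the n - e dragged lineages. Conditioned on polymorphism.
.sweepSpectrumPe <- function(bg, pe) {
  n <- bg$n
  # at pe = 0 every outcome is monomorphic; conditioning on polymorphism is
  # then the pe -> 0+ limit (mass at the extreme frequency classes), taken
  # numerically by flooring pe
  pe <- max(pe, 1e-12)
  out <- numeric(n - 1)
  w <- stats::dbinom(0:n, n, pe)
  if (w[n + 1] > 0) out <- out + w[n + 1] * bg$p
  for (e in 0:(n - 1)) {
    we <- w[e + 1]
    if (we < 1e-300) next
    m <- e + 1L
    q <- .projFull(bg$p, n, m)      # j = 0..m derived among the m lineages
    drag <- n - e
    for (j in 0:m) {
      pj <- q[j + 1]
      if (pj == 0) next
      k1 <- j - 1L + drag           # ancestor derived, probability j/m
      if (j > 0 && k1 >= 1 && k1 <= n - 1)
        out[k1] <- out[k1] + we * pj * (j / m)
      if (j >= 1 && j <= n - 1)     # ancestor ancestral
        out[j] <- out[j] + we * pj * (1 - j / m)
    }
  }
  out / sum(out)
}

#' Sweep-distorted site frequency spectrum
#'
#' Escape-and-drag transform of the background spectrum at physical
#' distance `d` from the selected site with per-bp intensity `alpha`; the
#' per-lineage escape probability is `1 - exp(-alpha d)`. In the full
#' escape limit the output equals the background.
#'
#' @param bg a `BackgroundSFS`
#' @param alpha per-bp sweep intensity (> 0)
#' @param d distance from the sweep in bp (>= 0)
#' @return probabilities over derived counts 1..n-1
#' @export
sweepSpectrum <- function(bg, alpha, d) {
  stopifnot(inherits(bg, "BackgroundSFS"))
  if (length(bg$p) == 0) stop("empty background spectrum")
  if (alpha <= 0) stop("alpha must be > 0")
  if (d < 0) stop("d must be >= 0")
  pe <- -expm1(-alpha * d)
  .sweepSpectrumPe(bg, pe)
}

#' Composite-likelihood sweep scan
#'
#' For each grid position x, the composite log likelihood of the observed
#' derived counts is maximized over the sweep intensity alpha, with the
#' spectrum at each site evaluated at its distance from x:
#' CLR(x) = 2 (max_alpha l(alpha) - l0), floored at 0, where l0 is the
#' composite log likelihood under the background spectrum.
#'
#' Spectra are precomputed on a discretized grid of escape probabilities
#' (the spectrum depends on alpha and d only through p_e), which makes the
#' scan linear in sites x grid positions x alpha values.
#'
#' @param polSites polarized site table (`chrom`, `pos`, `k`, `n`); a
#'   single chromosome
#' @param bg background spectrum ([backgroundSfs()] or [neutralSfs()])
#' @param gridStep scan grid spacing in bp (default 1000)
#' @param alphaGrid candidate alpha values; default 41 log-spaced points on
#'   `[1e-8, 1e-1]`
#' @param span scanned interval `c(start, end)` in bp; default covers the
#'   sites
#' @param refine logical; golden-section refinement of alpha around the
#'   grid argmax to relative tolerance 1e-3 (default TRUE)
#' @param peBins number of escape-probability bins for spectrum lookup
#' @return a [SweepScan-class]
#' @export
clrScan <- function(polSites, bg, gridStep = 1000,
                    alphaGrid = 10^seq(-8, -1, length.out = 41),
                    span = NULL, refine = TRUE, peBins = 1000) {
  if (!is.data.frame(polSites) && !is.null(polSites$sites))
    polSites <- polSites$sites
  if (nrow(polSites) < 10) stop("need at least 10 polarized sites")
  if (length(unique(polSites$chrom)) != 1)
    stop("clrScan expects a single chromosome; scan chromosomes separately")
  if (is.null(span)) span <- c(0, max(polSites$pos))
  ns <- sort(unique(polSites$n))
  # per sample size: background and log-spectrum lookup over pe bins
  peGrid <- seq(0, 1, length.out = peBins + 1)
  tabs <- list(); bgs <- list()
  for (nn in ns) {
    bgn <- projectSfs(bg, nn)
    logTab <- vapply(peGrid, function(pe) log(.sweepSpectrumPe(bgn, pe)),
                     numeric(nn - 1))
    tabs[[as.character(nn)]] <- logTab
    bgs[[as.character(nn)]] <- bgn
  }
  kBySize <- split(polSites$k, polSites$n)
  posBySize <- split(polSites$pos, polSites$n)
  ll0 <- sum(vapply(names(kBySize), function(nm)
    sum(log(bgs[[nm]]$p[kBySize[[nm]]])), numeric(1)))
  llAt <- function(x, alpha) {
    tot <- 0
    for (nm in names(kBySize)) {
      pe <- -expm1(-alpha * abs(posBySize[[nm]] - x))
      idx <- as.integer(round(pe * peBins)) + 1L
      tot <- tot + sum(tabs[[nm]][cbind(kBySize[[nm]], idx)])
    }
    tot
  }
  gridPos <- seq(span[1], span[2], by = gridStep)
  clr <- numeric(length(gridPos))
  aHat <- numeric(length(gridPos))
  la <- log(alphaGrid)
  gr <- (sqrt(5) - 1) / 2
  for (gi in seq_along(gridPos)) {
    x <- gridPos[gi]
    ll <- vapply(alphaGrid, function(a) llAt(x, a), numeric(1))
    best <- which.max(ll)
    bestLl <- ll[best]
    bestLa <- la[best]
    if (refine) {
      lo <- la[max(1, best - 1)]; hi <- la[min(length(la), best + 1)]
      a1 <- hi - gr * (hi - lo); a2 <- lo + gr * (hi - lo)
      f1 <- llAt(x, exp(a1)); f2 <- llAt(x, exp(a2))
      while ((hi - lo) > 1e-3) {
        if (f1 < f2) {
          lo <- a1; a1 <- a2; f1 <- f2
          a2 <- lo + gr * (hi - lo); f2 <- llAt(x, exp(a2))
        } else {
          hi <- a2; a2 <- a1; f2 <- f1
          a1 <- hi - gr * (hi - lo); f1 <- llAt(x, exp(a1))
        }
      }
      mid <- (lo + hi) / 2
      fm <- llAt(x, exp(mid))
      if (fm > bestLl) { bestLl <- fm; bestLa <- mid }
    }
    clr[gi] <- max(0, 2 * (bestLl - ll0))
    aHat[gi] <- exp(bestLa)
  }
  new("SweepScan", chrom = as.character(polSites$chrom[1]),
      positions = gridPos, clr = clr, alphaHat = aHat,
      span = as.numeric(span), gridStep = as.numeric(gridStep))
}

#' SweepScan: per-position composite likelihood ratios
#'
#' @slot chrom scanned chromosome label
#' @slot positions scan grid positions (bp)
#' @slot clr composite likelihood ratio, floored at 0
#' @slot alphaHat maximizing sweep intensity per position
#' @slot span scanned interval `c(start, end)` in bp
#' @slot gridStep grid spacing in bp
#' @export
setClass("SweepScan", slots = c(chrom = "character", positions = "numeric",
                                clr = "numeric", alphaHat = "numeric",
                                span = "numeric", gridStep = "numeric"))

setMethod("show", "SweepScan", function(object) {
  cat(sprintf("SweepScan on %s: %d grid points (step %g bp), span [%g, %g]\n",
              object@chrom, length(object@positions), object@gridStep,
              object@span[1], object@span[2]))
  cat(sprintf("  max CLR %.2f at %g bp (alpha-hat %.3g)\n",
              max(object@clr), object@positions[which.max(object@clr)],
              object@alphaHat[which.max(object@clr)]))
})

#' Scan results as a data.frame
#'
#' @param x a [SweepScan-class]
#' @param row.names,optional,... passed over for S3 compatibility, ignored
#' @return data.frame with `chrom`, `pos`, `clr`, `alphaHat`
#' @export
as.data.frame.SweepScan <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(chrom = x@chrom, pos = x@positions, clr = x@clr,
             alphaHat = x@alphaHat)
}

#' Cluster outlier CLR positions into sweep regions
#'
#' The top `100 - percentile` percent of grid positions by CLR (ties at the
#' boundary all included) are outliers; outliers within `mergeGap` bp of one
#' another are merged, and each region is extended by `extend` bp on both
#' sides of its terminal outlier positions, clipped to the scanned span.
#' The outlier count is `floor((1 - percentile/100) * n_grid)`; when that is
#' zero (small scans) no regions are reported.
#'
#' @param scan a [SweepScan-class]
#' @param percentile CLR percentile defining outliers (default 99.99, i.e.
#'   the top 0.01 percent of grid positions)
#' @param mergeGap merge outliers separated by at most this many bp
#' @param extend extension beyond terminal outliers, bp
#' @return a [GenomicRanges::GRanges] of sweep regions with a `maxClr`
#'   metadata column (empty when there are no outliers)
#' @export
defineSweepRegions <- function(scan, percentile = 99.99, mergeGap = 20000,
                               extend = 20000) {
  stopifnot(is(scan, "SweepScan"))
  nOut <- floor((1 - percentile / 100) * length(scan@clr))
  empty <- GenomicRanges::GRanges(seqnames = character(),
                                  ranges = IRanges::IRanges(),
                                  maxClr = numeric())
  if (nOut < 1) return(empty)
  thr <- sort(scan@clr, decreasing = TRUE)[nOut]
  sel <- scan@clr >= thr    # boundary ties all included
  if (!any(sel)) return(empty)
  gr <- GenomicRanges::GRanges(scan@chrom,
                               IRanges::IRanges(start = scan@positions[sel],
                                                width = 1))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = mergeGap + 1)
  st <- pmax(scan@span[1], GenomicRanges::start(merged) - extend)
  en <- pmin(scan@span[2], GenomicRanges::end(merged) + extend)
  out <- GenomicRanges::GRanges(scan@chrom, IRanges::IRanges(st, en))
  out$maxClr <- vapply(seq_along(out), function(i) {
    inR <- scan@positions >= st[i] & scan@positions <= en[i]
    max(scan@clr[inR])
  }, numeric(1))
  out
}

#' Selection coefficient from sweep intensity
#'
#' s = r ln(2 Ne) / alpha, inverting the per-bp sweep intensity
#' alpha = r ln(2 Ne) / s.
#'
#' @param alphaHat estimated per-bp sweep intensity (> 0)
#' @param r per-bp per-generation recombination rate (> 0)
#' @param Ne effective population size (> 0)
#' @return selection coefficient estimate (vectorized over `alphaHat`)
#' @export
estimateS <- function(alphaHat, r, Ne) {
  if (any(alphaHat <= 0) || r <= 0 || Ne <= 0)
    stop("alphaHat, r and Ne must be positive")
  r * log(2 * Ne) / alphaHat
}

#' Permutation test for locus overlap with sweep signal
#'
#' Places `nPerm` intervals of the same length as the query locus uniformly
#' at random fully inside the scanned span and records the mean and maximum
#' CLR over the grid points they cover, giving empirical p-values
#' `(1 + #{null >= observed}) / (nPerm + 1)` for the observed mean and
#' maximum.
#'
#' @param scan a [SweepScan-class]
#' @param locusStart,locusEnd query interval in bp (within the span)
#' @param nPerm number of random placements
#' @param seed integer seed
#' @return list with `pMean`, `pMax`, `obsMean`, `obsMax` and the null
#'   tables `nullMean`, `nullMax`
#' @export
locusOverlapPermutation <- function(scan, locusStart, locusEnd,
                                    nPerm = 999, seed = 1) {
  stopifnot(is(scan, "SweepScan"), locusEnd > locusStart)
  len <- locusEnd - locusStart
  if (len > diff(scan@span)) stop("locus longer than scanned span")
  if (locusStart < scan@span[1] || locusEnd > scan@span[2])
    stop("locus outside scanned span")
  statsIn <- function(s, e) {
    v <- scan@clr[scan@positions >= s & scan@positions <= e]
    if (!length(v)) c(NA_real_, NA_real_) else c(mean(v), max(v))
  }
  obs <- statsIn(locusStart, locusEnd)
  .withSeed(seed, {
    starts <- stats::runif(nPerm, scan@span[1], scan@span[2] - len)
    nullTab <- vapply(starts, function(s) statsIn(s, s + len), numeric(2))
    nullMean <- nullTab[1, ]; nullMax <- nullTab[2, ]
    list(pMean = (1 + sum(nullMean >= obs[1], na.rm = TRUE)) / (nPerm + 1),
         pMax = (1 + sum(nullMax >= obs[2], na.rm = TRUE)) / (nPerm + 1),
         obsMean = obs[1], obsMax = obs[2],
         nullMean = nullMean, nullMax = nullMax)
  })
}
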