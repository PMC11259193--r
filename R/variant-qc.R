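# Site- and genotype-level filters mirroring a resequencing QC pipeline:
# per-genotype depth masking, then site QUAL / mean-depth / missingness /
# biallelic / singleton filters (in that order, so singleton status is
# evaluated after masking), a Hardy-Weinberg exact-test filter applied per
# species group, and a Z-chromosome-heterozygosity association filter for
# sex-linked mis-mapping.

#' Filter configuration
#'
#' Defaults follow the study pipeline: genotype quality/QUAL >= 20, depth
#' in `[2, 200]`, site missingness <= 50%, biallelic SNPs only, singletons
#' removed, HWE exact-test p < 0.01 in at least 2 groups, top 1% of
#' Z-heterozygosity association excluded, 95% confidence for genotype
#' calls.
#'
#' @param minQual minimum phred site QUAL
#' @param minDepth,maxDepth per-genotype and site-mean depth bounds
#' @param maxMissing maximum fraction of missing genotypes per site
#' @param dropSingletons remove sites with minor allele count 1
#' @param hwePCutoff HWE exact-test p-value cutoff
#' @param hweMinViolatingGroups groups violating HWE required for removal
#' @param zAssocTopPercentile percent of most-associated SNPs to drop
#' @param confidenceLevel genotype-call confidence level
#' @return a list of class `FilterConfig`
#' @export
filterConfig <- function(minQual = 20, minDepth = 2, maxDepth = 200,
                         maxMissing = 0.5, dropSingletons = TRUE,
                         hwePCutoff = 0.01, hweMinViolatingGroups = 2,
                         zAssocTopPercentile = 1.0,
                         confidenceLevel = 0.95) {
  stopifnot(minQual >= 0, minDepth >= 0, maxDepth >= minDepth,
            maxMissing >= 0, maxMissing <= 1,
            hwePCutoff > 0, hwePCutoff <= 1,
            hweMinViolatingGroups >= 1,
            zAssocTopPercentile > 0, zAssocTopPercentile <= 100,
            confidenceLevel > 0, confidenceLevel < 1)
  structure(list(minQual = minQual, minDepth = minDepth, maxDepth = maxDepth,
                 maxMissing = maxMissing, dropSingletons = dropSingletons,
                 hwePCutoff = hwePCutoff,
                 hweMinViolatingGroups = hweMinViolatingGroups,
                 zAssocTopPercentile = zAssocTopPercentile,
                 confidenceLevel = confidenceLevel),
            class = "FilterConfig")
}

#' Apply site and genotype filters
#'
#' Genotypes with depth outside `[minDepth, maxDepth]` are set missing
#' first; then sites are removed, in order, for: QUAL below `minQual`,
#' site mean depth (over genotypes with depth data) outside the bounds,
#' missingness above `maxMissing`, not being a biallelic SNP, and (when
#' enabled) minor allele count exactly 1. Each removed site is counted
#' under the first rule it fails, so the report sums to the number of
#' sites removed.
#'
#' @param ds a [GenotypeDataset-class]
#' @param cfg a [filterConfig()]
#' @return list with `ds` (filtered dataset) and `report` (named removal
#'   counts: `qual`, `depth`, `missing`, `biallelic`, `singleton`, plus
#'   `genotypesMasked`)
#' @export
filterVariants <- function(ds, cfg = filterConfig()) {
  report <- c(qual = 0L, depth = 0L, missing = 0L,
              biallelic = 0L, singleton = 0L)
  if (nSites(ds) == 0)
    return(list(ds = ds, report = c(report, genotypesMasked = 0L)))
  g <- genotypes(ds)
  dp <- depths(ds)
  masked <- 0L
  meanDepth <- rep(NA_real_, nrow(g))
  if (length(dp)) {
    meanDepth <- rowMeans(dp, na.rm = TRUE)
    bad <- !is.na(dp) & (dp < cfg$minDepth | dp > cfg$maxDepth)
    masked <- sum(bad & !is.na(g))
    g[bad] <- NA_integer_
  }
  st <- sites(ds)
  keep <- rep(TRUE, nrow(st))
  drop1 <- keep & !is.na(st$qual) & st$qual < cfg$minQual
  report["qual"] <- sum(drop1); keep <- keep & !drop1
  drop2 <- keep & !is.na(meanDepth) &
    (meanDepth < cfg$minDepth | meanDepth > cfg$maxDepth)
  report["depth"] <- sum(drop2); keep <- keep & !drop2
  missFrac <- rowMeans(is.na(g))
  drop3 <- keep & missFrac > cfg$maxMissing
  report["missing"] <- sum(drop3); keep <- keep & !drop3
  multi <- grepl(",", st$alt) | nchar(st$ref) != 1 | nchar(st$alt) != 1
  drop4 <- keep & multi
  report["biallelic"] <- sum(drop4); keep <- keep & !drop4
  if (cfg$dropSingletons) {
    ac <- rowSums(g, na.rm = TRUE)
    an <- 2 * rowSums(!is.na(g))
    mac <- pmin(ac, an - ac)
    drop5 <- keep & mac == 1
    report["singleton"] <- sum(drop5); keep <- keep & !drop5
  }
  dsOut <- GenotypeDataset(st[keep, , drop = FALSE],
                           g[keep, , drop = FALSE],
                           depth = if (length(dp)) dp[keep, , drop = FALSE],
                           chromLengths = chromLengths(ds))
  list(ds = dsOut, report = c(report, genotypesMasked = masked))
}

#' Hardy-Weinberg exact test
#'
#' Levene/Haldane exact conditional test: conditioning on the observed
#' allele counts, the p-value is the total probability of heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed count.
#'
#' @param nAA,nAa,naa genotype counts (non-negative integers)
#' @return exact p-value in (0, 1]
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hMax <- min(nA, na)
  hs <- seq(hMax %% 2, hMax, by = 2)   # heterozygote counts share nA parity
  logP <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logP - max(logP))
  p <- p / sum(p)
  pObs <- p[match(nAa, hs)]
  sum(p[p <= pObs * (1 + 1e-12)])
}

#' Hardy-Weinberg filter across groups
#'
#' Per group, the exact test is applied only at sites with no missing
#' genotypes in that group; sites with p below the cutoff in at least
#' `hweMinViolatingGroups` groups are removed.
#'
#' @param ds a [GenotypeDataset-class]
#' @param meta sample metadata
#' @param groups group labels to test (at least 2)
#' @param cfg a [filterConfig()] supplying `hwePCutoff` and
#'   `hweMinViolatingGroups`
#' @return list with `ds` (filtered) and `removed` (data.frame `chrom`,
#'   `pos`, `nViolating`)
#' @export
hweFilter <- function(ds, meta, groups, cfg = filterConfig()) {
  if (length(groups) < 2) stop("need at least 2 groups")
  g <- genotypes(ds)
  viol <- matrix(FALSE, nrow(g), length(groups))
  for (gi in seq_along(groups)) {
    ids <- groupSamples(meta, groups[gi])
    gg <- g[, ids, drop = FALSE]
    complete <- rowSums(is.na(gg)) == 0
    for (s in which(complete)) {
      nAa <- sum(gg[s, ] == 1)
      nAA <- sum(gg[s, ] == 0)
      naa <- sum(gg[s, ] == 2)
      if (nAA + nAa + naa == 0) next
      viol[s, gi] <- hweExactTest(nAA, nAa, naa) < cfg$hwePCutoff
    }
  }
  nViol <- rowSums(viol)
  drop <- nViol >= cfg$hweMinViolatingGroups
  st <- sites(ds)
  list(ds = ds[!drop, ],
       removed = data.frame(chrom = st$chrom[drop], pos = st$pos[drop],
                            nViolating = nViol[drop]))
}

#' Z-heterozygosity association filter
#'
#' For each autosomal SNP, ordinary least squares regression of per-sample
#' Z-chromosome heterozygosity on allele dosage (non-missing pairs); the
#' Wald t-test p-value on the slope is the Pearson correlation test
#' p-value. SNPs in the smallest `zAssocTopPercentile` percent of p-values
#' are removed, with boundary ties all removed.
#'
#' @param ds a [GenotypeDataset-class] of autosomal SNPs
#' @param zHet named per-sample heterozygosity fraction on Z scaffolds
#' @param cfg a [filterConfig()] supplying `zAssocTopPercentile`
#' @return list with `ds`, `removed` (data.frame `chrom`, `pos`, `p`) and
#'   `constantTrait` flag (TRUE when zHet has no variance: nothing removable)
#' @export
zAssocFilter <- function(ds, zHet, cfg = filterConfig()) {
  idsMissing <- setdiff(sampleIds(ds), names(zHet))
  if (length(idsMissing))
    stop("zHet missing for samples: ", paste(idsMissing, collapse = ", "))
  z <- zHet[sampleIds(ds)]
  st <- sites(ds)
  if (stats::sd(z) == 0) {
    warning("Z heterozygosity constant across samples; no sites removable")
    return(list(ds = ds,
                removed = data.frame(chrom = character(), pos = integer(),
                                     p = numeric()),
                constantTrait = TRUE))
  }
  g <- genotypes(ds)
  pvals <- apply(g, 1, function(dos) {
    ok <- !is.na(dos)
    if (sum(ok) < 3 || stats::sd(dos[ok]) == 0) return(NA_real_)
    stats::cor.test(dos[ok], z[ok])$p.value
  })
  testable <- which(!is.na(pvals))
  m <- length(testable)
  if (m == 0)
    return(list(ds = ds,
                removed = data.frame(chrom = character(), pos = integer(),
                                     p = numeric()),
                constantTrait = FALSE))
  k <- ceiling(cfg$zAssocTopPercentile / 100 * m)
  thr <- sort(pvals[testable])[k]
  drop <- !is.na(pvals) & pvals <= thr
  list(ds = ds[!drop, ],
       removed = data.frame(chrom = st$chrom[drop], pos = st$pos[drop],
                            p = pvals[drop]),
       constantTrait = FALSE)
}

#' Phred QUAL threshold from a confidence level
#'
#' A call made with confidence `level` corresponds to an error probability
#' 1 - level, i.e. a phred threshold of -10 log10(1 - level); 95%
#' confidence gives 13.0103.
#'
#' @param level confidence level in (0, 1)
#' @return phred-scaled quality threshold
#' @export
confidenceToQual <- function(level) {
  if (any(level <= 0) || any(level >= 1)) stop("level must lie in (0, 1)")
  -10 * log10(1 - level)
}

#' Select a proxy SNP for a locus
#'
#' Among sites inside the interval with missing fraction at most
#' `maxMissing`, returns the site with the lowest major-allele frequency
#' (the best-supported polymorphism); ties break to the lowest position.
#'
#' @param ds a [GenotypeDataset-class]
#' @param chrom chromosome of the locus
#' @param start,end 1-based inclusive interval
#' @param maxMissing maximum per-site missing fraction (default 0.25)
#' @return one-row data.frame: `chrom`, `pos`, `majorFreq`, `altFreq`,
#'   `missingFrac`
#' @export
selectProxySnp <- function(ds, chrom, start, end, maxMissing = 0.25) {
  st <- sites(ds)
  sel <- which(st$chrom == chrom & st$pos >= start & st$pos <= end)
  if (!length(sel)) stop("no sites in interval")
  g <- genotypes(ds)[sel, , drop = FALSE]
  missFrac <- rowMeans(is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  ok <- missFrac <= maxMissing & !is.na(p)
  if (!any(ok)) stop("no site passes the missingness threshold")
  major <- pmax(p, 1 - p)
  cand <- which(ok)
  best <- cand[order(major[cand], st$pos[sel][cand])][1]
  data.frame(chrom = chrom, pos = st$pos[sel][best],
             majorFreq = major[best], altFreq = p[best],
             missingFrac = missFrac[best])
}
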