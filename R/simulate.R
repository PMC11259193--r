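# Synthetic genotype data with the statistical structure each analysis stage
# assumes: frequency-law generators (exact SFS control, no linkage) rather
# than coalescent simulation, because the downstream statistics under test
# (CLR scan, fd-hat, Hudson FST) are functions of site frequencies and
# tract-level allele sharing only.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; every generator is a pure function of (scenario, config, seed).
.withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' @param nIndividuals number of diploid individuals
#' @param nSites number of polymorphic sites to simulate
#' @param regionLength simulated region length in bp
#' @param seed integer seed; a fixed seed gives byte-identical output
#' @param callableLength callable bp per analysis window (defaults to the
#'   window length downstream)
#' @return a validated list of class `SimConfig`
#' @export
simConfig <- function(nIndividuals, nSites, regionLength, seed = 1,
                      callableLength = NULL) {
  stopifnot(nIndividuals >= 1, nSites >= 1, regionLength >= 1)
  if (nSites > regionLength)
    stop("nSites must not exceed regionLength")
  structure(list(nIndividuals = as.integer(nIndividuals),
                 nSites = as.integer(nSites),
                 regionLength = as.integer(regionLength),
                 seed = as.integer(seed),
                 callableLength = callableLength),
            class = "SimConfig")
}

# Derived-allele counts under the neutral unfolded SFS, p(i) proportional
# to 1/i for i in 1..nh-1.
.neutralCounts <- function(nh, S) {
  i <- seq_len(nh - 1)
  sample(i, S, replace = TRUE, prob = 1 / i)
}

# Distribute derived counts k over 2n haplotypes uniformly at random;
# genotypes are haplotype sums. Returns an S x n dosage matrix.
.assignHaplotypes <- function(k, n) {
  S <- length(k)
  g <- matrix(0L, S, n)
  nh <- 2L * n
  for (s in seq_len(S)) {
    hap <- sample.int(nh, k[s])
    g[s, ] <- tabulate((hap + 1L) %/% 2L, n)
  }
  g
}

.siteLetters <- function(S) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Generate a neutral background genotype dataset
#'
#' Each site's derived-allele count over the 2n haplotypes is drawn from the
#' neutral unfolded site frequency spectrum (probability proportional to 1/i)
#' and the derived alleles are assigned to haplotypes uniformly at random,
#' so the dataset has exactly the spectrum the sweep scan assumes under the
#' null. The ancestral allele equals REF and is recorded per site.
#'
#' @param cfg a [simConfig()]
#' @param chrom chromosome label
#' @return a [GenotypeDataset-class]
#' @examples
#' ds <- simBackgroundGenotypes(simConfig(10, 200, 1e5, seed = 1))
#' nSites(ds)
#' @export
simBackgroundGenotypes <- function(cfg, chrom = "sim1") {
  stopifnot(inherits(cfg, "SimConfig"))
  .withSeed(cfg$seed, {
    n <- cfg$nIndividuals
    S <- cfg$nSites
    pos <- sort(sample.int(cfg$regionLength, S))
    k <- .neutralCounts(2L * n, S)
    geno <- .assignHaplotypes(k, n)
    al <- .siteLetters(S)
    colnames(geno) <- sprintf("S%03d", seq_len(n))
    depth <- matrix(2L + stats::rpois(S * n, 18), S, n,
                    dimnames = list(NULL, colnames(geno)))
    sitesDf <- data.frame(chrom = chrom, pos = pos, ref = al$ref,
                          alt = al$alt, anc = al$ref,
                          qual = round(stats::runif(S, 30, 60), 1))
    GenotypeDataset(sitesDf, geno, depth = depth,
                    chromLengths = stats::setNames(cfg$regionLength, chrom))
  })
}

#' Overwrite site frequencies with the sweep-distorted spectrum
#'
#' Re-draws every site's derived-allele count from the escape-and-drag sweep
#' spectrum (see [sweepSpectrum()]) at its physical distance from
#' `sweepPos` with per-bp intensity `alpha`, conditioned on polymorphism,
#' and reassigns alleles to haplotypes uniformly. Positions, QC fields and
#' sample ids are preserved.
#'
#' @param ds a polarized [GenotypeDataset-class] (ancestral allele known)
#' @param sweepPos focal position of the sweep in bp
#' @param alpha per-bp sweep intensity (> 0); equals r ln(2 Ne)/s
#' @param seed integer seed
#' @param bg background spectrum as returned by [neutralSfs()] or
#'   [backgroundSfs()]; defaults to the neutral 1/i law at this sample size
#' @return a new [GenotypeDataset-class]
#' @export
spikeSweepSignal <- function(ds, sweepPos, alpha, seed = 1, bg = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (all(is.na(sites(ds)$anc)))
    stop("dataset must be polarized (ancestral allele known)")
  n <- nSamples(ds)
  nh <- 2L * n
  if (is.null(bg)) bg <- neutralSfs(nh)
  .withSeed(seed, {
    d <- abs(sites(ds)$pos - sweepPos)
    pe <- -expm1(-alpha * d)
    idx <- pmin(1000L, pmax(0L, as.integer(round(pe * 1000)))) + 1L
    uidx <- sort(unique(idx))
    k <- integer(nSites(ds))
    for (u in uidx) {
      sel <- which(idx == u)
      sp <- .sweepSpectrumPe(bg, (u - 1L) / 1000)
      if (bg$n != nh) stop("background spectrum sample size mismatch")
      k[sel] <- sample(seq_len(nh - 1L), length(sel), replace = TRUE,
                       prob = sp)
    }
    geno <- .assignHaplotypes(k, n)
    colnames(geno) <- sampleIds(ds)
    GenotypeDataset(sites(ds), geno, depth = depths(ds),
                    chromLengths = chromLengths(ds))
  })
}

#' Deme scenario for structured-population simulation
#'
#' @param demeCoords data.frame with columns `lat`, `lon`, one row per deme
#' @param FofDistance monotone function mapping km (distance from the first
#'   deme) to a Balding-Nichols F in `[0, 1)`
#' @param nPerDeme diploid individuals per deme
#' @return a validated list of class `DemeScenario`
#' @export
demeScenario <- function(demeCoords, FofDistance, nPerDeme) {
  demeCoords <- as.data.frame(demeCoords)
  stopifnot(nrow(demeCoords) >= 2, nPerDeme >= 1,
            all(abs(demeCoords$lat) <= 90), all(abs(demeCoords$lon) <= 180))
  structure(list(demeCoords = demeCoords, FofDistance = FofDistance,
                 nPerDeme = as.integer(nPerDeme)),
            class = "DemeScenario")
}

#' Generate Balding-Nichols structured demes
#'
#' Per site a global ALT frequency p is drawn from the neutral law; each
#' deme's frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' deme-specific F given by `FofDistance` evaluated at the deme's distance
#' from the first deme (F = 0 means the deme frequency equals p exactly);
#' genotypes are binomial, i.e. Hardy-Weinberg within demes.
#'
#' @param sc a [demeScenario()]
#' @param cfg a [simConfig()]; `nIndividuals` is ignored in favour of
#'   `sc$nPerDeme` x number of demes
#' @param chrom chromosome label
#' @return list with elements `ds` ([GenotypeDataset-class]), `meta`
#'   (sample metadata with deme labels and coordinates) and `F` (the
#'   per-deme F values actually used)
#' @export
simStructuredDemes <- function(sc, cfg, chrom = "sim1") {
  stopifnot(inherits(sc, "DemeScenario"), inherits(cfg, "SimConfig"))
  D <- nrow(sc$demeCoords)
  km <- vapply(seq_len(D), function(i)
    haversineKm(sc$demeCoords$lat[1], sc$demeCoords$lon[1],
                sc$demeCoords$lat[i], sc$demeCoords$lon[i]), numeric(1))
  Fd <- vapply(km, sc$FofDistance, numeric(1))
  if (any(Fd < 0) || any(Fd >= 1)) stop("F values must lie in [0, 1)")
  .withSeed(cfg$seed, {
    S <- cfg$nSites
    nTot <- D * sc$nPerDeme
    nh <- 2L * nTot
    p <- .neutralCounts(nh, S) / nh
    geno <- matrix(0L, S, nTot)
    for (d in seq_len(D)) {
      pd <- if (Fd[d] == 0) p else
        stats::rbeta(S, p * (1 - Fd[d]) / Fd[d],
                     (1 - p) * (1 - Fd[d]) / Fd[d])
      cols <- (d - 1L) * sc$nPerDeme + seq_len(sc$nPerDeme)
      geno[, cols] <- stats::rbinom(S * sc$nPerDeme, 2L, pd)
    }
    ids <- sprintf("D%02dS%03d", rep(seq_len(D), each = sc$nPerDeme),
                   rep(seq_len(sc$nPerDeme), D))
    colnames(geno) <- ids
    pos <- sort(sample.int(cfg$regionLength, S))
    al <- .siteLetters(S)
    sitesDf <- data.frame(chrom = chrom, pos = pos, ref = al$ref,
                          alt = al$alt, anc = al$ref,
                          qual = round(stats::runif(S, 30, 60), 1))
    ds <- GenotypeDataset(sitesDf, geno,
                          chromLengths = stats::setNames(cfg$regionLength, chrom))
    meta <- sampleMetadata(data.frame(
      sample = ids, group = "zea",
      deme = sprintf("D%02d", rep(seq_len(D), each = sc$nPerDeme)),
      lat = rep(sc$demeCoords$lat, each = sc$nPerDeme),
      lon = rep(sc$demeCoords$lon, each = sc$nPerDeme),
      year = 2019L))
    list(ds = ds, meta = meta, F = Fd)
  })
}

#' Introgression scenario with explicit donor tracts
#'
#' @param divergence per-site probability that a site is a fixed difference
#'   between the donor and recipient pools, in `[0, 1]`
#' @param admixedSamples character vector of P2 sample ids that carry donor
#'   tracts
#' @param tracts named list (one element per admixed sample) of two-column
#'   matrices of half-open `[start, end)` bp intervals
#' @param donorTractPloidy 1 (heterozygous tract) or 2 (homozygous tract)
#' @param nP1,nP2,nP3,nOut diploid sample sizes of the recipient reference
#'   (P1), recipient test (P2), donor (P3) and outgroup pools
#' @param polyMix proportions (normalized over 1 - divergence) of the three
#'   polymorphic site classes: `shared` ancestral polymorphism segregating
#'   in P1, P2 and P3 alike (the incomplete-lineage-sorting noise that
#'   makes D fluctuate around zero under the null), `recipient`-private
#'   and `donor`-private polymorphism
#' @return a validated list of class `IntrogressionScenario`
#' @export
introgressionScenario <- function(divergence, admixedSamples = character(),
                                  tracts = list(), donorTractPloidy = 2,
                                  nP1 = 10, nP2 = 10, nP3 = 10, nOut = 4,
                                  polyMix = c(shared = 0.5,
                                              recipient = 0.25,
                                              donor = 0.25)) {
  stopifnot(divergence >= 0, divergence <= 1,
            donorTractPloidy %in% 1:2,
            all(c("shared", "recipient", "donor") %in% names(polyMix)),
            all(polyMix >= 0), sum(polyMix) > 0)
  for (nm in admixedSamples) {
    tr <- tracts[[nm]]
    if (is.null(tr)) stop("no tracts given for admixed sample ", nm)
    tr <- tr[order(tr[, 1]), , drop = FALSE]
    if (any(tr[, 2] <= tr[, 1]))
      stop("tract intervals must have positive length")
    if (nrow(tr) > 1 && any(tr[-1, 1] < tr[-nrow(tr), 2]))
      stop("overlapping tracts in sample ", nm)
  }
  structure(list(divergence = divergence, admixedSamples = admixedSamples,
                 tracts = tracts, donorTractPloidy = as.integer(donorTractPloidy),
                 nP1 = nP1, nP2 = nP2, nP3 = nP3, nOut = nOut,
                 polyMix = polyMix / sum(polyMix)),
            class = "IntrogressionScenario")
}

#' Generate a four-taxon dataset with donor haplotype tracts
#'
#' Builds recipient (P1, P2) and donor (P3) pools plus an outgroup fixed for
#' the ancestral allele. Sites fall in four classes: shared ancestral
#' polymorphism (segregating in P1, P2 and P3 around a common frequency,
#' producing balanced ABBA/BABA noise), recipient-private polymorphism
#' (donor fixed ancestral), donor-private polymorphism (recipient fixed
#' ancestral) and, at rate `divergence`, fixed differences (donor fixed
#' derived). Designated P2 individuals carry donor alleles across their
#' tract intervals on 1 or 2 haplotypes; the injected truth tracts are
#' returned.
#'
#' @param sc an [introgressionScenario()]
#' @param cfg a [simConfig()]; `nIndividuals` is ignored in favour of the
#'   scenario pool sizes
#' @param chrom chromosome label
#' @return list with elements `ds`, `meta` and `tracts` (the truth tracts,
#'   exactly as injected)
#' @export
simIntrogressionDataset <- function(sc, cfg, chrom = "sim1") {
  stopifnot(inherits(sc, "IntrogressionScenario"), inherits(cfg, "SimConfig"))
  .withSeed(cfg$seed, {
    S <- cfg$nSites
    pos <- sort(sample.int(cfg$regionLength, S))
    mix <- sc$polyMix * (1 - sc$divergence)
    cls <- sample(c("fixed", "shared", "recipient", "donor"), S,
                  replace = TRUE,
                  prob = c(sc$divergence, mix["shared"],
                           mix["recipient"], mix["donor"]))
    nhR <- 2L * (sc$nP1 + sc$nP2)
    nhD <- 2L * sc$nP3
    x <- .neutralCounts(nhR, S) / nhR   # recipient-pool / shared frequency
    y <- .neutralCounts(max(nhD, 4L), S) / max(nhD, 4L)  # donor-pool frequency
    ids <- c(sprintf("P1_%02d", seq_len(sc$nP1)),
             sprintf("P2_%02d", seq_len(sc$nP2)),
             sprintf("P3_%02d", seq_len(sc$nP3)),
             sprintf("OUT_%02d", seq_len(sc$nOut)))
    grp <- rep(c("P1", "P2", "P3", "outgroup"),
               c(sc$nP1, sc$nP2, sc$nP3, sc$nOut))
    nTot <- length(ids)
    geno <- matrix(0L, S, nTot, dimnames = list(NULL, ids))
    recCols <- which(grp %in% c("P1", "P2"))
    donCols <- which(grp == "P3")
    iSha <- cls == "shared"
    iRec <- cls == "recipient"
    iDon <- cls == "donor"
    iFix <- cls == "fixed"
    for (j in recCols) {
      geno[iRec, j] <- stats::rbinom(sum(iRec), 2L, x[iRec])
      geno[iSha, j] <- stats::rbinom(sum(iSha), 2L, x[iSha])
    }
    for (j in donCols) {
      geno[iDon, j] <- stats::rbinom(sum(iDon), 2L, y[iDon])
      geno[iSha, j] <- stats::rbinom(sum(iSha), 2L, x[iSha])
      geno[iFix, j] <- 2L
    }
    # overlay donor tracts on admixed P2 individuals; shared-polymorphism
    # sites need no overlay (the donor pool segregates at the same
    # frequency there)
    pl <- sc$donorTractPloidy
    for (nm in sc$admixedSamples) {
      j <- match(nm, ids)
      if (is.na(j) || grp[j] != "P2")
        stop("admixed sample not in P2: ", nm)
      tr <- sc$tracts[[nm]]
      inTract <- rep(FALSE, S)
      for (r in seq_len(nrow(tr)))
        inTract <- inTract | (pos >= tr[r, 1] & pos < tr[r, 2])
      selRec <- inTract & iRec
      selDon <- inTract & iDon
      selFix <- inTract & iFix
      # non-donor haplotypes keep recipient-pool alleles
      geno[selRec, j] <- stats::rbinom(sum(selRec), 2L - pl, x[selRec])
      geno[selDon, j] <- stats::rbinom(sum(selDon), pl, y[selDon])
      geno[selFix, j] <- pl
    }
    al <- .siteLetters(S)
    sitesDf <- data.frame(chrom = chrom, pos = pos, ref = al$ref,
                          alt = al$alt, anc = al$ref,
                          qual = round(stats::runif(S, 30, 60), 1))
    ds <- GenotypeDataset(sitesDf, geno,
                          chromLengths = stats::setNames(cfg$regionLength, chrom))
    meta <- sampleMetadata(data.frame(
      sample = ids, group = grp, deme = NA_character_,
      lat = NA_real_, lon = NA_real_, year = 2019L))
    list(ds = ds, meta = meta, tracts = sc$tracts[sc$admixedSamples])
  })
}

#' Generate allele-frequency observations from the selection recursion
#'
#' Propagates the deterministic single-locus selection recursion (see
#' [selectionStep()]) generation by generation, with optional binomial
#' Wright-Fisher drift of census size `N` per generation (off by default,
#' `N = Inf`) and binomial observation noise from sampling `nChrom`
#' chromosomes in each listed year.
#'
#' @param s selection coefficient (derived homozygote fitness 1+s)
#' @param h dominance coefficient in `[0, 1]`
#' @param q0 initial derived-allele frequency in (0, 1) at `years[1]`
#' @param years calendar years at which frequencies are observed; the first
#'   is the anchor year
#' @param gensPerYear generations per calendar year
#' @param N census size for drift; `Inf` disables drift
#' @param nChrom chromosomes sampled per observation; `Inf` disables noise
#' @param seed integer seed
#' @return data.frame with columns `year` and `q_obs`
#' @export
simTrajectoryObservations <- function(s, h, q0, years, gensPerYear,
                                      N = Inf, nChrom = Inf, seed = 1) {
  if (q0 <= 0 || q0 >= 1) stop("q0 must lie in (0, 1)")
  stopifnot(h >= 0, h <= 1, s >= 0, length(years) >= 1,
            !is.unsorted(years, strictly = TRUE))
  .withSeed(seed, {
    gTarget <- round((years - years[1]) * gensPerYear)
    q <- q0
    qAt <- numeric(length(years))
    qAt[1] <- q0
    for (g in seq_len(max(gTarget))) {
      q <- selectionStep(q, s, h)
      if (is.finite(N)) q <- stats::rbinom(1, 2 * N, q) / (2 * N)
      hit <- which(gTarget == g)
      if (length(hit)) qAt[hit] <- q
    }
    obs <- if (is.finite(nChrom))
      stats::rbinom(length(qAt), nChrom, qAt) / nChrom else qAt
    data.frame(year = years, q_obs = obs)
  })
}
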