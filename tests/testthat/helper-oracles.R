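# Independent oracles used across the suite. These re-derive expected
# values by brute force (explicit enumeration or Monte-Carlo of the stated
# generative process) along code paths disjoint from the implementation.

# Monte-Carlo simulation of the escape-and-drag process: e ~ Binom(n, pe)
# lineages escape; the e escapees plus the sweeping ancestor are m = e + 1
# draws from a background configuration (K derived of n, K ~ bg); the
# ancestor state is copied to the n - e dragged lineages; condition on
# polymorphism by rejection.
mcSweepSpectrum <- function(bg, pe, nAccept = 1e5, seed = 1) {
  set.seed(seed)
  n <- bg$n
  counts <- numeric(n - 1)
  got <- 0
  while (got < nAccept) {
    todo <- nAccept - got
    e <- rbinom(todo, n, pe)
    K <- sample(seq_len(n - 1), todo, replace = TRUE, prob = bg$p)
    m <- pmin(e + 1L, n)               # e = n: all escape, k = K directly
    j <- rhyper(todo, K, n - K, m)
    ancDerived <- runif(todo) < j / m
    k <- ifelse(e == n, K, ifelse(ancDerived, j - 1L + (n - e), j))
    ok <- k >= 1 & k <= n - 1
    tab <- tabulate(k[ok], nbins = n - 1)
    counts <- counts + tab
    got <- got + sum(ok)
  }
  counts / sum(counts)
}

# Direct enumeration of the same process: sum probabilities over
# (e, K, j, ancestor-state) outcomes with explicit combinatorial weights.
# Exact to machine precision for small n.
enumSweepSpectrum <- function(bg, pe, peFloor = 1e-12) {
  n <- bg$n
  pe <- max(pe, peFloor)
  out <- numeric(n - 1)
  for (e in 0:n) {
    we <- choose(n, e) * pe^e * (1 - pe)^(n - e)
    if (e == n) {
      out <- out + we * bg$p
      next
    }
    m <- e + 1L
    for (K in seq_len(n - 1)) {
      pK <- bg$p[K]
      for (j in 0:m) {
        hyp <- choose(K, j) * choose(n - K, m - j) / choose(n, m)
        if (hyp == 0) next
        w <- we * pK * hyp
        kAnc <- j - 1L + (n - e)        # ancestor derived
        if (j > 0 && kAnc >= 1 && kAnc <= n - 1)
          out[kAnc] <- out[kAnc] + w * j / m
        if (j >= 1 && j <= n - 1)       # ancestor ancestral
          out[j] <- out[j] + w * (1 - j / m)
      }
    }
  }
  out / sum(out)
}

# Monte-Carlo pmf of the heterozygote count conditional on allele counts:
# random pairing of the 2n alleles into n diploids.
mcHetPmf <- function(nA, na, nSim = 2e5, seed = 1) {
  set.seed(seed)
  n <- (nA + na) / 2
  alleles <- rep(c(1L, 0L), c(nA, na))
  h <- replicate(nSim, {
    x <- sample(alleles)
    sum(x[seq(1, 2 * n, by = 2)] != x[seq(2, 2 * n, by = 2)])
  })
  tabulate(h + 1L, nbins = min(nA, na) + 1L) / nSim   # P(h = 0..min)
}

# Welch statistic from first principles.
welchOracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Random haplotype fixture: returns explicit phased haplotypes plus the
# GenotypeDataset built from their sums, for missing-aware pi oracles.
hapFixture <- function(nInd, nSitesF, L = 1e4, seed = 1, missProb = 0) {
  set.seed(seed)
  H <- matrix(rbinom(2 * nInd * nSitesF, 1, runif(nSitesF, 0.05, 0.95)),
              nrow = nSitesF)                  # sites x 2n haplotypes
  g <- H[, seq(1, 2 * nInd, 2), drop = FALSE] +
    H[, seq(2, 2 * nInd, 2), drop = FALSE]
  if (missProb > 0) {
    drop <- matrix(runif(length(g)) < missProb, nrow = nSitesF)
    g[drop] <- NA
  } else drop <- matrix(FALSE, nSitesF, nInd)
  colnames(g) <- sprintf("I%02d", seq_len(nInd))
  pos <- sort(sample.int(L, nSitesF))
  ds <- GenotypeDataset(
    data.frame(chrom = "c1", pos = pos, ref = "A", alt = "T",
               anc = "A", qual = 50),
    g, chromLengths = c(c1 = L))
  list(H = H, ds = ds, missing = drop, pos = pos)
}

# Per-site mean pairwise difference over non-missing chromosomes, from the
# haplotype matrix directly (enumerating chromosome pairs).
piSiteHapOracle <- function(fix) {
  H <- fix$H
  nh <- ncol(H)
  indOf <- (seq_len(nh) + 1L) %/% 2L
  vapply(seq_len(nrow(H)), function(s) {
    keep <- which(!fix$missing[s, indOf])
    if (length(keep) < 2) return(NA_real_)
    d <- 0; np <- 0
    for (a in seq_along(keep)[-length(keep)])
      for (b in (a + 1):length(keep)) {
        d <- d + (H[s, keep[a]] != H[s, keep[b]])
        np <- np + 1
      }
    d / np
  }, numeric(1))
}

# Codon translation oracle: substring lookup in Biostrings' GENETIC_CODE
# table (independent of the translate() code path used by the package).
translateOracle <- function(seqStr) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(seqStr) / 3
  paste(vapply(seq_len(n), function(i) {
    cod <- substr(seqStr, 3 * i - 2, 3 * i)
    unname(gc[[cod]])
  }, character(1)), collapse = "")
}

revcompOracle <- function(seqStr) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(seqStr, "")[[1]]]), collapse = "")
}
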