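# Deterministic single-locus selection with dominance, calendar-time
# retrodiction, and the random-search fit of (s, h) to observed allele
# frequencies; plus the effective-population-size and recombination-unit
# helpers the selection-coefficient estimate composes with.

#' Effective population size from nucleotide diversity
#'
#' Under neutrality E[theta_pi] = 4 Ne mu, so Ne = theta_pi / (4 mu).
#'
#' @param thetaPi mean windowed nucleotide diversity (> 0)
#' @param mu per-bp per-generation mutation rate (> 0); the default is the
#'   Drosophila melanogaster rate 8.4e-9
#' @param thetaSd optional standard deviation of theta_pi; when given, Ne
#'   bounds from theta +/- 1 SD are included
#' @return list with `Ne`, `thetaPi`, `mu` and optionally `NeLower`,
#'   `NeUpper`
#' @export
estimateNe <- function(thetaPi, mu = 8.4e-9, thetaSd = NULL) {
  if (thetaPi <= 0 || mu <= 0) stop("thetaPi and mu must be > 0")
  out <- list(Ne = thetaPi / (4 * mu), thetaPi = thetaPi, mu = mu)
  if (!is.null(thetaSd)) {
    out$NeLower <- max(0, thetaPi - thetaSd) / (4 * mu)
    out$NeUpper <- (thetaPi + thetaSd) / (4 * mu)
  }
  out
}

#' Recombination-rate unit conversions
#'
#' Solves rho = 4 Ne c given any two of (rho, Ne, c) and converts the
#' per-bp crossover probability c to map units with Haldane's function
#' cM = 50 ln(1 / (1 - 2c)).
#'
#' @param rho population-scaled recombination rate per bp
#' @param Ne effective population size
#' @param c per-bp per-generation crossover probability (< 0.5)
#' @return list with `rho`, `Ne`, `c`, `cMPerBp`
#' @export
convertRates <- function(rho = NULL, Ne = NULL, c = NULL) {
  have <- !vapply(list(rho, Ne, c), is.null, logical(1))
  if (sum(have) < 2) stop("supply at least two of rho, Ne, c")
  if (is.null(c)) c <- rho / (4 * Ne)
  else if (is.null(rho)) rho <- 4 * Ne * c
  else if (is.null(Ne)) Ne <- rho / (4 * c)
  if (any(c < 0)) stop("c must be >= 0")
  if (any(c >= 0.5)) stop("c must be < 0.5 (map function undefined)")
  list(rho = rho, Ne = Ne, c = c, cMPerBp = 50 * log(1 / (1 - 2 * c)))
}

#' One generation of selection with dominance
#'
#' Genotypic fitnesses are wAA = 1, wAa = 1 + h s, waa = 1 + s with A the
#' ancestral and a the derived allele. With p = 1 - q the ancestral
#' frequency and mean fitness wbar = p^2 + 2pq(1+hs) + q^2(1+s), the
#' ancestral allele changes by
#' dp = p q (p (wAA - wAa) + q (wAa - waa)) / wbar,
#' and the derived frequency updates as q' = q - dp. Vectorized over `q`
#' (and over `s`, `h` when of matching length).
#'
#' @param q derived-allele frequency in `[0, 1]`
#' @param s selection coefficient (>= 0)
#' @param h dominance coefficient in `[0, 1]`
#' @return q after one generation
#' @export
selectionStep <- function(q, s, h) {
  p <- 1 - q
  wAa <- 1 + h * s
  waa <- 1 + s
  wbar <- p^2 + 2 * p * q * wAa + q^2 * waa
  dp <- p * q * (p * (1 - wAa) + q * (wAa - waa)) / wbar
  pmin(1, pmax(0, q - dp))
}

#' Predict a calendar-time allele-frequency trajectory
#'
#' Iterates [selectionStep()] for (yearEnd - year0) x gensPerYear
#' generations starting from `q0` at `year0`, reporting q at every
#' generation with its fractional calendar year.
#'
#' @param q0 initial derived frequency at `year0`
#' @param year0 anchor calendar year
#' @param yearEnd final calendar year (> year0)
#' @param gensPerYear generations per year (2..12 is the plausible range
#'   for a multivoltine noctuid)
#' @param s selection coefficient
#' @param h dominance coefficient
#' @return data.frame with columns `generation`, `year`, `q`
#' @export
predictCalendar <- function(q0, year0, yearEnd, gensPerYear, s, h) {
  if (yearEnd <= year0) stop("yearEnd must exceed year0")
  if (gensPerYear < 1) stop("gensPerYear must be >= 1")
  if (q0 < 0 || q0 > 1) stop("q0 must lie in [0, 1]")
  G <- round((yearEnd - year0) * gensPerYear)
  q <- numeric(G + 1)
  q[1] <- q0
  for (g in seq_len(G)) q[g + 1] <- selectionStep(q[g], s, h)
  data.frame(generation = 0:G, year = year0 + (0:G) / gensPerYear, q = q)
}

#' Random-search fit of selection (and dominance) to observed frequencies
#'
#' Draws `nIter` uniform candidates for s (and for h when `h = "free"`),
#' propagates the deterministic recursion from the first observation
#' (the anchor) and scores each candidate as 1 minus the mean absolute
#' difference between observed and expected frequencies over the remaining
#' observation years, retaining the argmax. The search is vectorized over
#' candidates, so the cost is generations x nIter element updates.
#'
#' @param observations data.frame with columns `year` and `q_obs`, ordered
#'   in time; the first row anchors the trajectory
#' @param gensPerYear generations per calendar year
#' @param h fixed dominance coefficient, or `"free"` to fit it jointly
#' @param nIter number of random candidates (the study used 1e6)
#' @param seed integer seed; the fit is bit-reproducible given the seed
#' @param sRange,hRange uniform search ranges
#' @return list of class `TrajectoryFit`: `sFit`, `hFit`, `score`,
#'   `nIterations`, `seed`, `sRange`, `hRange`, `anchor`, `predicted`
#'   (expected frequency at each non-anchor observation year)
#' @export
fitSelection <- function(observations, gensPerYear, h = 1, nIter = 1e5,
                         seed = 1, sRange = c(0, 1), hRange = c(0, 1)) {
  stopifnot(nrow(observations) >= 2)
  if (is.unsorted(observations$year, strictly = TRUE))
    stop("observations must be strictly ordered in time")
  hFree <- identical(h, "free")
  year0 <- observations$year[1]
  q0 <- observations$q_obs[1]
  gTarget <- round((observations$year[-1] - year0) * gensPerYear)
  .withSeed(seed, {
    sCand <- stats::runif(nIter, sRange[1], sRange[2])
    hCand <- if (hFree) stats::runif(nIter, hRange[1], hRange[2])
             else rep(h, nIter)
    q <- rep(q0, nIter)
    absErr <- matrix(0, nIter, length(gTarget))
    for (g in seq_len(max(gTarget))) {
      q <- selectionStep(q, sCand, hCand)
      hit <- which(gTarget == g)
      for (j in hit) absErr[, j] <- abs(q - observations$q_obs[j + 1])
    }
    score <- 1 - rowMeans(absErr)
    best <- which.max(score)
    pred <- vapply(gTarget, function(g) {
      qq <- q0
      for (i in seq_len(g)) qq <- selectionStep(qq, sCand[best], hCand[best])
      qq
    }, numeric(1))
    structure(list(sFit = sCand[best],
                   hFit = hCand[best],
                   score = score[best],
                   nIterations = nIter, seed = seed,
                   sRange = sRange,
                   hRange = if (hFree) hRange else NULL,
                   anchor = c(year = year0, q = q0),
                   predicted = data.frame(year = observations$year[-1],
                                          q_obs = observations$q_obs[-1],
                                          q_exp = pred)),
              class = "TrajectoryFit")
  })
}

#' @export
print.TrajectoryFit <- function(x, ...) {
  cat(sprintf("TrajectoryFit: s = %.4f%s, score = %.4f (%g iterations, seed %d)\n",
              x$sFit,
              if (!is.null(x$hRange)) sprintf(", h = %.4f", x$hFit)
              else sprintf(" (h fixed at %.2f)", x$hFit),
              x$score, x$nIterations, x$seed))
  print(x$predicted, row.names = FALSE)
  invisible(x)
}
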