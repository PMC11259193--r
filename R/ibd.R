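# Isolation by distance: pairwise great-circle distances between sampling
# demes, pairwise mean windowed Hudson FST, and the regression of
# linearized FST, FST/(1-FST), on log geographic distance (Rousset's
# method). A positive one-sided Pearson correlation indicates restricted
# dispersal; its absence indicates effective panmixia.

#' Great-circle distance in km
#'
#' Haversine distance on a sphere with mean Earth radius 6371.0088 km,
#' via [geosphere::distHaversine()].
#'
#' @param lat1,lon1,lat2,lon2 decimal-degree coordinates (vectorized)
#' @return distance in km
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("invalid coordinates")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Pairwise mean windowed FST between demes
#'
#' For each deme pair, the unweighted mean of non-missing window Hudson FST
#' values (see [windowFst()]) across all chromosomes.
#'
#' @param ds a [GenotypeDataset-class]
#' @param meta sample metadata with a `deme` column
#' @param windowSize window size in bp (default 20000)
#' @param minSites minimum sites per window (default the window-class rule;
#'   lower it for sparse simulated data)
#' @return list with `fst` (symmetric deme x deme matrix, diagonal `NA`)
#'   and `km` (pairwise great-circle distances from deme mean coordinates)
#' @export
pairwiseMeanFst <- function(ds, meta, windowSize = 20000, minSites = NULL) {
  meta <- meta[!is.na(meta$deme), , drop = FALSE]
  demes <- unique(meta$deme)
  if (length(demes) < 2) stop("need at least 2 demes")
  keep <- vapply(demes, function(d)
    sum(meta$deme == d) >= 2, logical(1))
  if (!all(keep)) {
    warning("demes with < 2 samples excluded: ",
            paste(demes[!keep], collapse = ", "))
    demes <- demes[keep]
  }
  windows <- tileWindows(chromLengths(ds), windowSize)
  D <- length(demes)
  fst <- matrix(NA_real_, D, D, dimnames = list(demes, demes))
  km <- matrix(NA_real_, D, D, dimnames = list(demes, demes))
  coords <- t(vapply(demes, function(d) {
    sel <- meta$deme == d
    c(lat = mean(meta$lat[sel]), lon = mean(meta$lon[sel]))
  }, numeric(2)))
  for (a in seq_len(D - 1)) for (b in (a + 1):D) {
    sA <- meta$sample[meta$deme == demes[a]]
    sB <- meta$sample[meta$deme == demes[b]]
    w <- windowFst(ds, sA, sB, windows, minSites = minSites)
    fst[a, b] <- fst[b, a] <- mean(w$fst, na.rm = TRUE)
    km[a, b] <- km[b, a] <- haversineKm(coords[a, "lat"], coords[a, "lon"],
                                        coords[b, "lat"], coords[b, "lon"])
  }
  list(fst = fst, km = km)
}

#' Isolation-by-distance regression
#'
#' Regresses linearized differentiation y = FST/(1-FST) on x = ln(km) by
#' ordinary least squares and tests the Pearson correlation, reporting both
#' the one-sided (positive-correlation) and two-sided p-values. Pairs with
#' FST = 1 (infinite y) are dropped with a warning.
#'
#' @param fstMatrix symmetric deme x deme mean-FST matrix
#' @param kmMatrix symmetric deme x deme distance matrix (km, all > 0)
#' @return list of class `IbdResult`: `pairs` (data.frame demeA, demeB, km,
#'   fst, y), `slope`, `intercept`, `r`, `t`, `df`, `pOneSided`,
#'   `pTwoSided`, `constantY` flag
#' @export
ibdRegression <- function(fstMatrix, kmMatrix) {
  stopifnot(identical(dim(fstMatrix), dim(kmMatrix)))
  demes <- rownames(fstMatrix)
  ut <- which(upper.tri(fstMatrix), arr.ind = TRUE)
  pairs <- data.frame(demeA = demes[ut[, 1]], demeB = demes[ut[, 2]],
                      km = kmMatrix[ut], fst = fstMatrix[ut])
  if (nrow(pairs) < 3) stop("need at least 3 deme pairs")
  if (any(pairs$km <= 0)) stop("all pairwise distances must be > 0")
  inf <- pairs$fst >= 1
  if (any(inf)) {
    warning(sum(inf), " pair(s) with FST = 1 dropped")
    pairs <- pairs[!inf, , drop = FALSE]
  }
  pairs$y <- pairs$fst / (1 - pairs$fst)
  x <- log(pairs$km)
  if (stats::sd(pairs$y) == 0) {
    return(structure(list(pairs = pairs, slope = 0,
                          intercept = mean(pairs$y), r = NA_real_,
                          t = NA_real_, df = nrow(pairs) - 2,
                          pOneSided = NA_real_, pTwoSided = NA_real_,
                          constantY = TRUE), class = "IbdResult"))
  }
  fit <- stats::lm(pairs$y ~ x)
  ct2 <- stats::cor.test(x, pairs$y, alternative = "two.sided")
  ct1 <- stats::cor.test(x, pairs$y, alternative = "greater")
  structure(list(pairs = pairs,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(ct2$estimate),
                 t = unname(ct2$statistic),
                 df = unname(ct2$parameter),
                 pOneSided = ct1$p.value,
                 pTwoSided = ct2$p.value,
                 constantY = FALSE),
            class = "IbdResult")
}

#' @export
print.IbdResult <- function(x, ...) {
  cat(sprintf("Isolation-by-distance regression on %d deme pairs\n",
              nrow(x$pairs)))
  if (x$constantY) {
    cat("  linearized FST constant across pairs; correlation undefined\n")
  } else {
    cat(sprintf("  slope %.4g, intercept %.4g (y = FST/(1-FST) on ln km)\n",
                x$slope, x$intercept))
    cat(sprintf("  Pearson r = %.3f, t = %.3f, df = %d\n", x$r, x$t, x$df))
    cat(sprintf("  p (one-sided, positive) = %.4g; p (two-sided) = %.4g\n",
                x$pOneSided, x$pTwoSided))
  }
  invisible(x)
}
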