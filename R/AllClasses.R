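#' @importFrom methods new setClass setGeneric setMethod setValidity validObject is
NULL

#' GenotypeDataset: diploid biallelic genotype matrix with per-site metadata
#'
#' The common currency of all analysis stages: an ordered site table
#' (chromosome, 1-based position, REF, ALT, ancestral allele when known,
#' phred-scaled site QUAL), a sites x samples allele-dosage matrix
#' (0/1/2, `NA` = missing), an optional per-genotype depth matrix of the
#' same shape, and named chromosome lengths used to tile analysis windows.
#'
#' @slot sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, `anc`
#'   (ancestral allele, `NA` when unknown) and `qual`; rows are ordered by
#'   chromosome then strictly increasing position.
#' @slot geno integer matrix, sites in rows, samples in columns (column
#'   names are sample ids); entries are ALT-allele dosages in \{0, 1, 2\}
#'   or `NA` for missing genotypes.
#' @slot depth numeric matrix of per-genotype sequencing depth, same
#'   dimensions as `geno`, or a 0 x 0 matrix when depth is unavailable.
#' @slot chromLengths named numeric vector of chromosome lengths in bp.
#'
#' @export
setClass("GenotypeDataset",
  slots = c(
    sites = "data.frame",
    geno = "matrix",
    depth = "matrix",
    chromLengths = "numeric"
  )
)

setValidity("GenotypeDataset", function(object) {
  msgs <- character()
  need <- c("chrom", "pos", "ref", "alt", "anc", "qual")
  if (!all(need %in% names(object@sites)))
    msgs <- c(msgs, paste("sites must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@sites) != nrow(object@geno))
      msgs <- c(msgs, "sites and geno row counts differ")
    for (ch in unique(object@sites$chrom)) {
      p <- object@sites$pos[object@sites$chrom == ch]
      if (any(diff(p) <= 0))
        msgs <- c(msgs, sprintf("positions not strictly increasing on %s", ch))
    }
  }
  g <- object@geno
  if (length(g) && !all(g[!is.na(g)] %in% 0:2))
    msgs <- c(msgs, "geno entries must be 0, 1, 2 or NA")
  if (length(object@depth) &&
      !identical(dim(object@depth), dim(object@geno)))
    msgs <- c(msgs, "depth must match geno dimensions (or be empty)")
  if (is.null(colnames(object@geno)) && ncol(object@geno) > 0)
    msgs <- c(msgs, "geno must have sample ids as column names")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeDataset
#'
#' @param sites data.frame of site annotations (see
#'   [GenotypeDataset-class]); a missing `anc` or `qual` column is filled
#'   with `NA`.
#' @param geno sites x samples dosage matrix with sample ids as column names.
#' @param depth optional per-genotype depth matrix.
#' @param chromLengths named chromosome lengths in bp; defaults to the
#'   maximum observed position per chromosome.
#' @return A [GenotypeDataset-class] object.
#' @export
GenotypeDataset <- function(sites, geno, depth = NULL,
                            chromLengths = NULL) {
  sites <- as.data.frame(sites)
  if (is.null(sites$anc)) sites$anc <- NA_character_
  if (is.null(sites$qual)) sites$qual <- NA_real_
  rownames(sites) <- NULL
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(depth)) depth <- matrix(numeric(), 0, 0)
  if (is.null(chromLengths)) {
    chromLengths <- vapply(split(sites$pos, sites$chrom), max, numeric(1))
    if (!nrow(sites)) chromLengths <- numeric()
  }
  new("GenotypeDataset", sites = sites, geno = geno,
      depth = as.matrix(depth), chromLengths = chromLengths)
}

#' @describeIn GenotypeDataset-class number of sites
#' @param object,x a `GenotypeDataset`
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("nSites", "GenotypeDataset", function(object) nrow(object@sites))

#' @describeIn GenotypeDataset-class number of samples
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("nSamples", "GenotypeDataset", function(object) ncol(object@geno))

#' @describeIn GenotypeDataset-class sample identifiers
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("sampleIds", "GenotypeDataset", function(object) colnames(object@geno))

#' @describeIn GenotypeDataset-class site annotation table
#' @export
setGeneric("sites", function(object) standardGeneric("sites"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("sites", "GenotypeDataset", function(object) object@sites)

#' @describeIn GenotypeDataset-class dosage matrix (sites x samples)
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("genotypes", "GenotypeDataset", function(object) object@geno)

#' @describeIn GenotypeDataset-class per-genotype depth matrix
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("depths", "GenotypeDataset", function(object) object@depth)

#' @describeIn GenotypeDataset-class named chromosome lengths (bp)
#' @export
setGeneric("chromLengths", function(object) standardGeneric("chromLengths"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("chromLengths", "GenotypeDataset", function(object) object@chromLengths)

#' @rdname GenotypeDataset-class
#' @param i site index (logical or integer)
#' @param j sample index or sample ids
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "GenotypeDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@sites))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  d <- if (length(x@depth)) x@depth[i, j, drop = FALSE] else x@depth
  GenotypeDataset(x@sites[i, , drop = FALSE],
                  x@geno[i, j, drop = FALSE],
                  depth = d, chromLengths = x@chromLengths)
})

setMethod("show", "GenotypeDataset", function(object) {
  cat(sprintf("GenotypeDataset: %d sites x %d samples\n",
              nSites(object), nSamples(object)))
  cat(sprintf("  chromosomes: %s\n",
              paste(names(object@chromLengths), collapse = ", ")))
  nm <- sum(is.na(object@geno))
  cat(sprintf("  missing genotypes: %d (%.1f%%)\n", nm,
              if (length(object@geno)) 100 * nm / length(object@geno) else 0))
  if (any(!is.na(object@sites$anc)))
    cat(sprintf("  ancestral allele known at %d sites\n",
                sum(!is.na(object@sites$anc))))
})

#' Validate a sample metadata table
#'
#' Sample metadata maps each sample id to its analysis group (e.g. P1, P2,
#' P3, outgroup), sampling deme, decimal latitude/longitude and collection
#' year. Extra columns are kept.
#'
#' @param df data.frame with columns `sample`, `group`, `deme`, `lat`,
#'   `lon`, `year` (`deme`, `lat`, `lon`, `year` may be NA where unused).
#' @return The validated data.frame (invisibly the same object).
#' @export
sampleMetadata <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample", "group", "deme", "lat", "lon", "year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicated sample ids in metadata")
  ok <- is.na(df$lat) | abs(df$lat) <= 90
  ok2 <- is.na(df$lon) | abs(df$lon) <= 180
  if (!all(ok) || !all(ok2))
    stop("latitude/longitude out of range")
  rownames(df) <- NULL
  df
}

#' Sample ids belonging to one or more metadata groups
#'
#' @param meta metadata table from [sampleMetadata()]
#' @param groups character vector of group labels
#' @return character vector of sample ids
#' @export
groupSamples <- function(meta, groups) {
  meta$sample[meta$group %in% groups]
}

# Internal: ALT-allele count and non-missing chromosome count per site for a
# sample subset. Returns list(ac, an).
.alleleCounts <- function(ds, samples = NULL) {
  g <- ds@geno
  if (!is.null(samples)) {
    bad <- setdiff(samples, colnames(g))
    if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
    g <- g[, samples, drop = FALSE]
  }
  list(ac = rowSums(g, na.rm = TRUE), an = 2 * rowSums(!is.na(g)))
}

#' ALT-allele frequencies per site for a sample subset
#'
#' @param ds a [GenotypeDataset-class]
#' @param samples sample ids (default all)
#' @param minChrom minimum non-missing chromosomes; sites below return `NA`
#' @return numeric vector of ALT frequencies
#' @export
alleleFreqs <- function(ds, samples = NULL, minChrom = 1) {
  cnt <- .alleleCounts(ds, samples)
  out <- cnt$ac / cnt$an
  out[cnt$an < minChrom] <- NA_real_
  out
}
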