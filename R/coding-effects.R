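# Coding-variant effect classification: translation of (possibly
# minus-strand, multi-exon) coding regions, per-SNP synonymous /
# nonsynonymous / stop-gain classification, a biochemical-property-change
# flag, and the confident nonsingleton nonsynonymous variant report.

# Residue classes used for the biochemical-change flag. The partition is a
# standard five-class scheme (configurable in biochemicalChange()).
.aaClasses <- list(
  nonpolar = c("A", "V", "L", "I", "M", "F", "W"),
  polar_uncharged = c("S", "T", "C", "Y", "N", "Q"),
  positive = c("K", "R", "H"),
  negative = c("D", "E"),
  special = c("G", "P"),
  stop = "*"
)

#' Define a coding region
#'
#' `sequence` is the spliced coding sequence in plus-strand (genomic)
#' orientation; for minus-strand genes it is reverse-complemented before
#' translation. Exons are genomic 1-based inclusive intervals whose total
#' width must equal the sequence length, and the spliced length must be a
#' multiple of 3.
#'
#' @param sequence spliced coding sequence (A/C/G/T), plus-strand
#'   orientation
#' @param exons data.frame or matrix of exon `start`, `end` (1-based,
#'   inclusive, genomic); a single-exon gene may omit it, in which case the
#'   exon is `[start, start + nchar - 1]`
#' @param strand `"+"` or `"-"`
#' @param start genomic start of the first exon (used when `exons` is
#'   omitted)
#' @param chrom chromosome label
#' @param allowInternalStop keep reference in-frame stops instead of
#'   erroring
#' @return a list of class `CodingRegion`
#' @export
codingRegion <- function(sequence, exons = NULL, strand = "+", start = 1,
                         chrom = "chr", allowInternalStop = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty coding sequence")
  if (grepl("[^ACGT]", sequence)) stop("non-ACGT base in coding sequence")
  if (nchar(sequence) %% 3 != 0)
    stop("spliced length must be divisible by 3")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.null(exons))
    exons <- data.frame(start = start, end = start + nchar(sequence) - 1)
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons")
  if (sum(exons$end - exons$start + 1) != nchar(sequence))
    stop("exon widths do not sum to the sequence length")
  region <- structure(list(sequence = sequence, exons = exons,
                           strand = strand, chrom = chrom),
                      class = "CodingRegion")
  prot <- translateCds(region)
  internal <- substr(prot, 1, nchar(prot) - 1)
  if (!allowInternalStop && grepl("\\*", internal, fixed = FALSE))
    stop("internal stop codon in reference frame")
  region
}

#' Translate a coding region
#'
#' Standard nuclear codon table via [Biostrings::translate()]; minus-strand
#' regions are reverse-complemented first; a terminal stop is rendered
#' `*`.
#'
#' @param region a [codingRegion()] or a plain coding sequence string (in
#'   which case `strand` applies)
#' @param strand strand for plain-string input
#' @return the protein sequence as a character string
#' @export
translateCds <- function(region, strand = "+") {
  if (inherits(region, "CodingRegion")) {
    seqStr <- region$sequence
    strand <- region$strand
  } else {
    seqStr <- toupper(region)
  }
  if (nchar(seqStr) == 0) stop("empty coding sequence")
  if (grepl("[^ACGT]", seqStr)) stop("non-ACGT base in coding sequence")
  if (nchar(seqStr) %% 3 != 0) stop("length must be divisible by 3")
  dna <- Biostrings::DNAString(seqStr)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  as.character(Biostrings::translate(dna, no.init.codon = TRUE))
}

# Map a genomic position to the 1-based offset in the plus-strand spliced
# sequence; NA when the position falls outside every exon.
.splicedOffset <- function(region, pos) {
  off <- 0L
  for (e in seq_len(nrow(region$exons))) {
    st <- region$exons$start[e]; en <- region$exons$end[e]
    if (pos >= st && pos <= en) return(off + (pos - st + 1L))
    off <- off + (en - st + 1L)
  }
  NA_integer_
}

#' Classify the coding effect of a SNP
#'
#' Substitutes the (plus-strand) alternate base at the genomic position in
#' the spliced frame, translates strand-aware, and assigns the effect
#' class: synonymous, nonsynonymous, stop_gain (which supersedes
#' nonsynonymous) or stop_loss.
#'
#' @param region a [codingRegion()]
#' @param pos genomic position (1-based)
#' @param alt alternate base on the plus strand
#' @return list with `pos`, `codon` (1-based codon index in the protein),
#'   `aaRef`, `aaAlt`, `class`, `refBase`, `altBase`
#' @export
classifySnp <- function(region, pos, alt) {
  stopifnot(inherits(region, "CodingRegion"))
  alt <- toupper(alt)
  if (!alt %in% c("A", "C", "G", "T")) stop("alt must be a single base")
  off <- .splicedOffset(region, pos)
  if (is.na(off)) stop("non-coding: position outside exons")
  refBase <- substr(region$sequence, off, off)
  altSeq <- region$sequence
  substr(altSeq, off, off) <- alt
  protRef <- translateCds(region)
  protAlt <- translateCds(altSeq, strand = region$strand)
  L <- nchar(region$sequence)
  cdsPos <- if (region$strand == "+") off else L - off + 1L
  codon <- ceiling(cdsPos / 3)
  aaRef <- substr(protRef, codon, codon)
  aaAlt <- substr(protAlt, codon, codon)
  cls <- if (aaRef == aaAlt) "synonymous"
  else if (aaAlt == "*") "stop_gain"
  else if (aaRef == "*") "stop_loss"
  else "nonsynonymous"
  list(pos = pos, codon = codon, aaRef = aaRef, aaAlt = aaAlt,
       class = cls, refBase = refBase, altBase = alt)
}

#' Biochemical-property change between residues
#'
#' TRUE iff the two residues fall in different classes of the partition:
#' nonpolar \{A,V,L,I,M,F,W\}, polar-uncharged \{S,T,C,Y,N,Q\}, positive
#' \{K,R,H\}, negative \{D,E\}, special \{G,P\} (and `*` as its own class).
#'
#' @param aaRef,aaAlt one-letter amino-acid codes
#' @param classes optional alternative partition (named list of character
#'   vectors)
#' @return logical
#' @export
biochemicalChange <- function(aaRef, aaAlt, classes = .aaClasses) {
  lookup <- function(aa) {
    hit <- which(vapply(classes, function(cl) aa %in% cl, logical(1)))
    if (!length(hit)) stop("unknown amino-acid code: ", aa)
    names(classes)[hit[1]]
  }
  lookup(aaRef) != lookup(aaAlt)
}

#' Report confident nonsynonymous coding variants
#'
#' Sites below the QUAL threshold are masked; remaining biallelic SNPs
#' inside the region's exons are classified, and nonsynonymous variants
#' (stop-gains included) with a biochemical-property change and ALT allele
#' count of at least `minCount` are reported, with the allele frequency
#' computed over confidently called chromosomes.
#'
#' @param ds a [GenotypeDataset-class] in the region's coordinates
#' @param region a [codingRegion()]
#' @param qualThreshold minimum site QUAL (default 13.0103, i.e. 95%
#'   confidence; see [confidenceToQual()])
#' @param minCount minimum ALT allele count (default 2: nonsingletons)
#' @return data.frame with one row per reported variant: `chrom`, `pos`,
#'   `codon`, `aaRef`, `aaAlt`, `class`, `alleleCount`, `calledChrom`,
#'   `frequency`
#' @export
codingVariantReport <- function(ds, region, qualThreshold = 13.0103,
                                minCount = 2) {
  st <- sites(ds)
  inExon <- vapply(st$pos, function(p) !is.na(.splicedOffset(region, p)),
                   logical(1)) & st$chrom == region$chrom
  snp <- nchar(st$ref) == 1 & nchar(st$alt) == 1 & !grepl(",", st$alt)
  confident <- !is.na(st$qual) & st$qual >= qualThreshold
  sel <- which(inExon & snp & confident)
  rows <- list()
  for (i in sel) {
    eff <- classifySnp(region, st$pos[i], st$alt[i])
    if (!eff$class %in% c("nonsynonymous", "stop_gain")) next
    change <- eff$class == "stop_gain" ||
      biochemicalChange(eff$aaRef, eff$aaAlt)
    if (!change) next
    g <- genotypes(ds)[i, ]
    ac <- sum(g, na.rm = TRUE)
    an <- 2 * sum(!is.na(g))
    if (ac < minCount) next
    rows[[length(rows) + 1]] <- data.frame(
      chrom = st$chrom[i], pos = st$pos[i], codon = eff$codon,
      aaRef = eff$aaRef, aaAlt = eff$aaAlt, class = eff$class,
      alleleCount = ac, calledChrom = an, frequency = ac / an)
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      codon = integer(), aaRef = character(),
                      aaAlt = character(), class = character(),
                      alleleCount = integer(), calledChrom = integer(),
                      frequency = numeric()))
  do.call(rbind, rows)
}
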