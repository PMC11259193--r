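# VCF 4.2 input/output. Reading goes through vcfR; writing formats the
# fixed biallelic-SNP record layout directly (GT:DP genotypes, site QUAL,
# ancestral allele in INFO/AA) so that read_vcf(write_vcf(ds)) is the
# identity on genotypes, positions and ancestral alleles.

#' Write a GenotypeDataset as VCF 4.2
#'
#' Emits unphased GT plus per-genotype DP, site QUAL, and the ancestral
#' allele as INFO key `AA` where known. Missing genotypes become `./.`.
#'
#' @param ds a [GenotypeDataset-class]
#' @param path output file path
#' @param meta optional sample metadata written as a sibling
#'   `<path>.meta.tsv` table
#' @return `path`, invisibly
#' @export
writeVcfFile <- function(ds, path, meta = NULL) {
  st <- sites(ds)
  g <- genotypes(ds)
  dp <- depths(ds)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chromLengths(ds)),
                   as.integer(chromLengths(ds))),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(ds)), collapse = "\t"))
  writeLines(hdr, con)
  if (nSites(ds) > 0) {
    gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow(g), ncol(g))
    ok <- !is.na(g)
    gt[ok] <- gtCode[as.character(g[ok])]
    if (length(dp)) {
      dps <- matrix(".", nrow(g), ncol(g))
      dps[!is.na(dp)] <- as.character(dp[!is.na(dp)])
      gt <- matrix(paste(gt, dps, sep = ":"), nrow(g), ncol(g))
    }
    info <- ifelse(is.na(st$anc), ".", paste0("AA=", st$anc))
    qual <- ifelse(is.na(st$qual), ".", format(st$qual, trim = TRUE))
    fmt <- if (length(dp)) "GT:DP" else "GT"
    body <- paste(st$chrom, st$pos, ".", st$ref, st$alt, qual, "PASS",
                  info, fmt,
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  if (!is.null(meta))
    utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VCF (and optional sample metadata) into a GenotypeDataset
#'
#' Dosages are computed from GT; multiallelic records and indels are
#' excluded and counted in the report; INFO key `AA` is parsed as the
#' ancestral allele when present; contig lengths are taken from the
#' header.
#'
#' @param path VCF file path (plain or bgzipped)
#' @param metadataPath optional TSV with columns `sample`, `group`,
#'   `deme`, `lat`, `lon`, `year`; sample ids must be a subset of the VCF
#'   samples
#' @return list with `ds` ([GenotypeDataset-class]), `meta` (or `NULL`)
#'   and `report` (counts of excluded `multiallelic` and `indel` records)
#' @export
readVcfDataset <- function(path, metadataPath = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  contigs <- grep("^##contig=", vcf@meta, value = TRUE)
  chromLengths <- NULL
  if (length(contigs)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", contigs)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                            contigs)))
    if (!anyNA(lens)) chromLengths <- stats::setNames(lens, ids)
  }
  sampleNames <- colnames(vcf@gt)[-1]
  if (is.null(fix) || nrow(fix) == 0) {
    ds <- GenotypeDataset(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), anc = character(), qual = numeric()),
      matrix(integer(), 0, length(sampleNames),
             dimnames = list(NULL, sampleNames)),
      chromLengths = chromLengths %||% numeric())
    meta <- if (!is.null(metadataPath)) .readMeta(metadataPath, sampleNames)
    return(list(ds = ds, meta = meta,
                report = c(multiallelic = 0L, indel = 0L)))
  }
  alt <- fix[, "ALT"]; ref <- fix[, "REF"]
  multi <- grepl(",", alt)
  indel <- !multi & (nchar(ref) != 1 | nchar(alt) != 1)
  keep <- !multi & !indel
  gt <- vcfR::extract.gt(vcf, element = "GT")
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA
  dp <- NULL
  if (any(grepl("DP", vcf@gt[, "FORMAT"])))
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  aa <- rep(NA_character_, nrow(fix))
  hasAA <- grepl("(^|;)AA=", fix[, "INFO"])
  aa[hasAA] <- sub(".*AA=([^;]+).*", "\\1", fix[hasAA, "INFO"])
  sitesDf <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = ref, alt = alt, anc = aa,
                        qual = suppressWarnings(as.numeric(fix[, "QUAL"])))
  dos <- matrix(as.integer(dos), nrow(fix),
                dimnames = list(NULL, sampleNames))
  ds <- GenotypeDataset(sitesDf[keep, , drop = FALSE],
                        dos[keep, , drop = FALSE],
                        depth = if (!is.null(dp)) dp[keep, , drop = FALSE],
                        chromLengths = chromLengths)
  meta <- if (!is.null(metadataPath)) .readMeta(metadataPath, sampleNames)
  list(ds = ds, meta = meta,
       report = c(multiallelic = sum(multi), indel = sum(indel)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readMeta <- function(path, vcfSamples) {
  meta <- sampleMetadata(utils::read.delim(path))
  unknown <- setdiff(meta$sample, vcfSamples)
  if (length(unknown))
    stop("metadata samples not in VCF: ", paste(unknown, collapse = ", "))
  meta
}
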