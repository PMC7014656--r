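#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file, retains biallelic records passing the QUAL
#' threshold, and codes diploid genotypes as alternate-allele dosages
#' (0/1/2, `NA` for missing). Multiallelic records are dropped by default so
#' that dosage coding stays well defined.
#'
#' @param path Path to a VCF file (plain or bgzip/gzip).
#' @param min_qual Minimum QUAL to retain a record (default 20, the
#'   conventional calling threshold); records with missing QUAL are kept.
#' @param drop_multiallelic Drop records with more than one ALT allele
#'   (default `TRUE`).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, min_qual = 20, drop_multiallelic = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  keep <- rep(TRUE, nrow(fix))
  if (drop_multiallelic) keep <- keep & !grepl(",", alt, fixed = TRUE)
  keep <- keep & (is.na(qual) | qual >= min_qual)
  keep <- keep & !is.na(alt) & alt != "." & fix[, "REF"] != alt

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no genotype (GT) data")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dosage <- t(gt_to_dosage(gt))
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
  )
  genotype_matrix(sites, dosage)
}

# "0/1", "1|0", "./." (sites x samples character matrix) -> dosage matrix.
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  ok <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  d[ok] <- (a1[ok] == "1") + (a2[ok] == "1")
  d
}

#' Write a genotype matrix as a plain-text VCF v4.2 file
#'
#' Deterministic writer used by the synthetic-cohort generator; output
#' round-trips through [read_vcf()] reproducing chrom/pos/ref/alt and dosages
#' exactly. Dosage 1 is written as the unphased heterozygote `0/1`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lotuscan",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(gm), ncol = n_samples(gm))
  d <- t(gm$dosage)
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  qual <- if ("qual" %in% names(gm$sites)) {
    ifelse(is.na(gm$sites$qual), ".", format(gm$sites$qual, trim = TRUE))
  } else "."
  body <- paste(
    gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
    qual, "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}
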