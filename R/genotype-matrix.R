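#' Genotype matrix container
#'
#' The central data structure: biallelic variant sites with per-sample diploid
#' allele dosages. Dosage is the count of alternate alleles carried by a
#' diploid sample (0, 1 or 2), with `NA` for missing genotypes. Sites are kept
#' sorted by (chromosome, position) and carry their variant class:
#' `snp` (same-length ref/alt of length 1), `indel` (length difference of
#' 1-5 bp) or `sv` (length difference > 5 bp). Diversity, differentiation and
#' LD statistics use SNP sites only; indels and SVs are carried for
#' annotation and accounting.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   and optionally `qual`. A `variant_class` column is derived if absent.
#' @param dosage Integer matrix, samples in rows, sites in columns; entries in
#'   `{0, 1, 2, NA}`. Row names are sample ids.
#' @return An object of class `genotype_matrix` with elements `sites`
#'   (tibble), `samples` (character) and `dosage` (matrix).
#' @export
#' @examples
#' sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L),
#'                         ref = c("A", "C"), alt = c("G", "T"))
#' dos <- matrix(c(0L, 1L, 2L, 0L), nrow = 2,
#'               dimnames = list(c("s1", "s2"), NULL))
#' gm <- genotype_matrix(sites, dos)
#' n_sites(gm)
genotype_matrix <- function(sites, dosage) {
  sites <- tibble::as_tibble(sites)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("sites is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    abort("dosage must have sample ids as row names")
  }
  if (ncol(dosage) != nrow(sites)) {
    abort(sprintf("dosage has %d columns but sites has %d rows",
                  ncol(dosage), nrow(sites)))
  }
  bad <- !is.na(dosage) & !(dosage %in% c(0L, 1L, 2L))
  if (any(bad)) abort("dosage entries must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"

  if (any(sites$pos < 1L)) abort("site positions must be >= 1 (1-based)")
  if (any(sites$ref == sites$alt)) abort("ref and alt alleles must differ")
  if (!"variant_class" %in% names(sites)) {
    sites$variant_class <- classify_variant(sites$ref, sites$alt)
  }

  ord <- site_order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]

  structure(
    list(sites = sites, samples = rownames(dosage), dosage = dosage),
    class = "genotype_matrix"
  )
}

#' Classify variants by ref/alt length difference
#'
#' `snp`: equal-length single-base alleles; `indel`: length difference of
#' 1-5 bp; `sv`: length difference above 5 bp.
#'
#' @param ref,alt Character vectors of alleles.
#' @return Character vector of classes.
#' @export
classify_variant <- function(ref, alt) {
  d <- abs(nchar(ref) - nchar(alt))
  dplyr::case_when(
    d == 0 & nchar(ref) == 1L ~ "snp",
    d == 0 ~ "mnp",
    d <= 5 ~ "indel",
    TRUE ~ "sv"
  )
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cls <- table(x$sites$variant_class)
  cat(sprintf("<genotype_matrix> %d samples x %d sites (%s)\n",
              length(x$samples), nrow(x$sites),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm A `genotype_matrix`.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname genotype_matrix
#' @export
n_samples <- function(gm) length(gm$samples)

# Subset a genotype matrix to a logical/integer site index, keeping order.
subset_sites <- function(gm, keep) {
  gm$sites <- gm$sites[keep, , drop = FALSE]
  gm$dosage <- gm$dosage[, keep, drop = FALSE]
  gm
}

# Subset to named samples (order preserved as given).
subset_samples <- function(gm, samples) {
  missing_s <- setdiff(samples, gm$samples)
  if (length(missing_s) > 0) {
    abort(paste0("unknown sample(s): ", paste(missing_s, collapse = ", ")))
  }
  gm$dosage <- gm$dosage[samples, , drop = FALSE]
  gm$samples <- samples
  gm
}

# SNP-only view, used by the diversity / FST / LD statistics.
snp_only <- function(gm) subset_sites(gm, gm$sites$variant_class == "snp")

# Per-site alternate-allele count and non-missing allele total over a set of
# sample rows. Workhorse for pi / FST / MAF.
allele_counts <- function(gm, samples = gm$samples) {
  d <- gm$dosage[samples, , drop = FALSE]
  alt <- colSums(d, na.rm = TRUE)
  n <- 2L * colSums(!is.na(d))
  list(alt = alt, n = n)
}

#' Filter sites on minor allele frequency and missingness
#'
#' Minor allele frequency is computed on non-missing alleles across all
#' samples. Sites with MAF below `min_maf` or a missing-genotype fraction
#' above `max_missing` are dropped; the sample set is unchanged. Idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param min_maf Minimum minor allele frequency in `[0, 0.5]` (default 0.1,
#'   the conventional site filter for resequencing scans).
#' @param max_missing Maximum fraction of missing genotypes per site.
#' @return A filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, min_maf = 0.1, max_missing = 1) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_missing >= 0, max_missing <= 1)
  ac <- allele_counts(gm)
  p <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
  maf <- pmin(p, 1 - p)
  miss_frac <- colMeans(is.na(gm$dosage))
  keep <- !is.na(maf) & maf >= min_maf & miss_frac <= max_missing
  if (!any(keep)) warn("all sites removed by filter; returning empty matrix")
  subset_sites(gm, keep)
}

#' Read a sample-to-group assignment table
#'
#' Two-column tab-separated file (`sample<TAB>group`, no header). Every sample
#' in the genotype matrix must be assigned exactly one group.
#'
#' @param path Path to the TSV file.
#' @param gm A [genotype_matrix()] to validate against (optional).
#' @return Tibble with columns `sample`, `group`; groups ordered by first
#'   appearance, then samples.
#' @export
read_grouping <- function(path, gm = NULL) {
  tab <- readr::read_tsv(path, col_names = c("sample", "group"),
                         col_types = "cc", progress = FALSE)
  dup <- tab |>
    dplyr::distinct(.data$sample, .data$group) |>
    dplyr::count(.data$sample) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("conflicting group labels for sample(s): ",
                 paste(dup$sample, collapse = ", ")))
  }
  tab <- dplyr::distinct(tab)
  if (!is.null(gm)) {
    missing_s <- setdiff(gm$samples, tab$sample)
    if (length(missing_s) > 0) {
      abort(paste0("samples present in genotypes but absent from grouping: ",
                   paste(missing_s, collapse = ", ")))
    }
    tab <- tab[tab$sample %in% gm$samples, , drop = FALSE]
  }
  tab$group <- factor(tab$group, levels = unique(tab$group))
  dplyr::arrange(tab, .data$group, .data$sample) |>
    dplyr::mutate(group = as.character(.data$group))
}

# Sample ids belonging to one group; errors on unknown group label.
group_samples <- function(grouping, group) {
  s <- grouping$sample[grouping$group == group]
  if (length(s) == 0) abort(paste0("unknown or empty group: ", group))
  s
}
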