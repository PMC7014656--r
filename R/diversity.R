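#' Per-site nucleotide diversity
#'
#' Unbiased pairwise heterozygosity at a biallelic site:
#' `2 p (1 - p) n / (n - 1)` with `p = alt_count / allele_total` and `n` the
#' number of non-missing alleles. Equals the mean number of pairwise
#' differences among the `n` sampled alleles. Sites with fewer than two
#' non-missing alleles contribute 0.
#'
#' @param alt_count Integer vector of alternate-allele counts.
#' @param allele_total Integer vector of non-missing allele totals.
#' @return Numeric vector of per-site diversity values.
#' @export
#' @examples
#' site_pi(2, 4)  # 2/3: 4 of 6 allele pairs differ
site_pi <- function(alt_count, allele_total) {
  stopifnot(all(alt_count >= 0), all(alt_count <= allele_total))
  p <- ifelse(allele_total > 0, alt_count / allele_total, 0)
  ifelse(allele_total >= 2,
         2 * p * (1 - p) * allele_total / (allele_total - 1),
         0)
}

#' Group nucleotide diversity (theta-pi) over a sequence length
#'
#' Sums per-site diversity over all SNP sites for the group's samples and
#' divides by the total sequence length (not the number of variant sites),
#' so the result is diversity per base pair; monomorphic positions contribute
#' zero to the numerator. Reported on the per-bp scale and as
#' `theta_pi_e3` (x 10^-3), the conventional presentation scale.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Grouping tibble from [read_grouping()].
#' @param group Group label.
#' @param seq_length Total length (bp) of the analyzed sequence.
#' @return One-row tibble: `group`, `theta_pi_per_bp`, `theta_pi_e3`,
#'   `callable_length`, `n_snps_used`.
#' @export
group_theta_pi <- function(gm, grouping, group, seq_length) {
  stopifnot(seq_length > 0)
  rows <- group_samples(grouping, group)
  if (length(rows) < 2) {
    abort(paste0("group '", group, "' has fewer than 2 samples; ",
                 "diversity is undefined"))
  }
  gm_s <- snp_only(subset_samples(gm, rows))
  ac <- allele_counts(gm_s)
  pi_vals <- site_pi(ac$alt, ac$n)
  used <- ac$n >= 2 & ac$alt > 0 & ac$alt < ac$n
  tibble::tibble(
    group = group,
    theta_pi_per_bp = sum(pi_vals) / seq_length,
    theta_pi_e3 = 1000 * sum(pi_vals) / seq_length,
    callable_length = seq_length,
    n_snps_used = sum(used)
  )
}

#' Per-sample heterozygosity rate
#'
#' Number of heterozygous SNP calls divided by total sequence length,
#' expressed in percent.
#'
#' @param gm A [genotype_matrix()].
#' @param genome_length Total sequence length in bp.
#' @param samples Samples to report (default all).
#' @return Tibble: `sample`, `het_snp_count`, `genome_length`, `het_rate`
#'   (percent).
#' @export
heterozygosity_rate <- function(gm, genome_length, samples = gm$samples) {
  stopifnot(genome_length > 0)
  unknown <- setdiff(samples, gm$samples)
  if (length(unknown) > 0) {
    abort(paste0("unknown sample(s): ", paste(unknown, collapse = ", ")))
  }
  gm_s <- snp_only(gm)
  het <- rowSums(gm_s$dosage[samples, , drop = FALSE] == 1L, na.rm = TRUE)
  het <- unname(het)
  tibble::tibble(
    sample = samples,
    het_snp_count = as.integer(het),
    genome_length = genome_length,
    het_rate = 100 * het / genome_length
  )
}

#' Windowed nucleotide diversity per group
#'
#' Per-window diversity is the sum of per-site diversity of SNPs inside the
#' window divided by the window length. Windows with fewer than `min_snps`
#' SNPs are flagged unusable (`usable = FALSE`).
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Grouping tibble.
#' @param windows Window tibble from [make_windows()].
#' @param groups Group labels to compute (default all in `grouping`).
#' @param min_snps Minimum SNPs for a usable window (default 10).
#' @return Tibble: `chrom`, `start`, `end`, `group`, `pi` (per bp),
#'   `n_snps`, `usable`.
#' @export
windowed_pi <- function(gm, grouping, windows, groups = NULL, min_snps = 10) {
  groups <- groups %||% unique(grouping$group)
  gm_s <- snp_only(gm)
  swm <- site_window_map(gm_s$sites, windows)
  n_w <- nrow(windows)
  win_len <- windows$end - windows$start
  out <- purrr::map(groups, function(g) {
    rows <- group_samples(grouping, g)
    ac <- allele_counts(subset_samples(gm_s, rows))
    pv <- site_pi(ac$alt, ac$n)
    informative <- ac$n >= 2  # genotyped in the group; segregation not required
    pi_sum <- rep(0, n_w)
    n_in <- rep(0L, n_w)
    if (nrow(swm) > 0) {
      agg <- rowsum(cbind(pv[swm$site], as.integer(informative[swm$site])),
                    group = swm$window)
      idx <- as.integer(rownames(agg))
      pi_sum[idx] <- agg[, 1]
      n_in[idx] <- as.integer(agg[, 2])
    }
    tibble::tibble(
      chrom = windows$chrom, start = windows$start, end = windows$end,
      group = g, pi = pi_sum / win_len, n_snps = n_in,
      usable = n_in >= min_snps
    )
  })
  dplyr::bind_rows(out)
}
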