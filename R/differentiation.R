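#' Weir-Cockerham variance components for a biallelic site
#'
#' Two-population Weir & Cockerham (1984) variance components computed from
#' sample allele counts, in the allele-level (ANOVA) form: `a` is the
#' between-population component and `b` the within-population component; the
#' per-site estimate is `a / (a + b)`. Sites monomorphic in both samples, or
#' with fewer than two non-missing alleles in either, are unusable.
#'
#' @param alt1,n1 Alternate-allele count and non-missing allele total in
#'   population 1 (vectors allowed).
#' @param alt2,n2 Same for population 2.
#' @return Tibble: `a`, `b`, `denom` (`a + b`), `fst` (per-site estimate,
#'   `NA` when unusable), `usable`.
#' @export
#' @examples
#' site_fst_components(10, 10, 0, 10)  # fixed difference: fst = 1
site_fst_components <- function(alt1, n1, alt2, n2) {
  p1 <- ifelse(n1 > 0, alt1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, alt2 / n2, NA_real_)
  N <- n1 + n2
  r <- 2
  pbar <- (alt1 + alt2) / N
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  msb <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - r)
  a <- (msb - msw) / nc
  b <- msw
  usable <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1
  denom <- a + b
  fst <- ifelse(usable & denom != 0, a / denom, NA_real_)
  tibble::tibble(a = ifelse(usable, a, NA_real_),
                 b = ifelse(usable, b, NA_real_),
                 denom = ifelse(usable, denom, NA_real_),
                 fst = fst,
                 usable = usable)
}

#' Windowed FST (ratio of averages)
#'
#' Window FST is `sum(a) / sum(a + b)` over usable sites in the window --
#' the ratio-of-averages aggregation, which is the standard for sliding
#' -window resequencing scans. Negative estimates are clamped to 0 when
#' `clamp = TRUE` (default). Windows with fewer than `min_snps` usable
#' sites, or a zero denominator, are unusable.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Grouping tibble.
#' @param group1,group2 Group labels to contrast.
#' @param windows Window tibble from [make_windows()].
#' @param min_snps Minimum usable SNPs per window (default 10).
#' @param clamp Clamp negative window estimates to 0 (default `TRUE`).
#' @return Tibble: `chrom`, `start`, `end`, `n_snps`, `fst`, `usable`.
#' @export
windowed_fst <- function(gm, grouping, group1, group2, windows,
                         min_snps = 10, clamp = TRUE) {
  gm_s <- snp_only(gm)
  ac1 <- allele_counts(subset_samples(gm_s, group_samples(grouping, group1)))
  ac2 <- allele_counts(subset_samples(gm_s, group_samples(grouping, group2)))
  comp <- site_fst_components(ac1$alt, ac1$n, ac2$alt, ac2$n)
  swm <- site_window_map(gm_s$sites, windows)
  n_w <- nrow(windows)
  a_sum <- rep(0, n_w); d_sum <- rep(0, n_w); n_in <- rep(0L, n_w)
  ok <- comp$usable[swm$site]
  if (any(ok)) {
    swm_ok <- swm[ok, , drop = FALSE]
    agg <- rowsum(cbind(comp$a[swm_ok$site], comp$denom[swm_ok$site], 1),
                  group = swm_ok$window)
    idx <- as.integer(rownames(agg))
    a_sum[idx] <- agg[, 1]
    d_sum[idx] <- agg[, 2]
    n_in[idx] <- as.integer(agg[, 3])
  }
  usable <- n_in >= min_snps & d_sum != 0
  fst <- ifelse(usable, a_sum / d_sum, NA_real_)
  if (clamp) fst <- pmax(fst, 0)
  tibble::tibble(chrom = windows$chrom, start = windows$start,
                 end = windows$end, n_snps = n_in, fst = fst,
                 usable = usable)
}

#' Z-standardize a vector of windowed statistics
#'
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation, computed
#' genome-wide over the supplied (usable) values.
#'
#' @param values Numeric vector with at least two finite values.
#' @return Numeric vector of z-scores (same length; `NA` in, `NA` out).
#' @export
#' @examples
#' z_transform(c(1, 2, 3))
z_transform <- function(values) {
  finite <- is.finite(values)
  if (sum(finite) < 2) abort("need at least 2 finite values to standardize")
  s <- sd(values[finite])
  if (s == 0) abort("zero variance: degenerate scan, z-scores undefined")
  (values - mean(values[finite])) / s
}
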