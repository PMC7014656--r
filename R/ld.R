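#' Squared genotype correlation between two sites
#'
#' Composite (genotype-level) linkage disequilibrium: the squared Pearson
#' correlation of the two dosage vectors over samples with both sites
#' non-missing. Appropriate for unphased diploid calls.
#'
#' @param dosages_a,dosages_b Integer dosage vectors of equal length.
#' @return The squared correlation, or `NA` if fewer than two complete pairs
#'   remain or either site is monomorphic among them.
#' @export
#' @examples
#' pair_r2(c(0, 1, 2, 1), c(2, 1, 0, 1))  # perfect repulsion: 1
pair_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2) return(NA_real_)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' LD decay curve for one group
#'
#' Computes r-squared for all intra-chromosome SNP pairs closer than
#' `max_dist` among the group's samples, bins pairs by distance, and reports
#' the mean r-squared per bin. When the number of qualifying pairs exceeds
#' `max_pairs`, a seeded uniform subsample is taken, keeping the curve
#' deterministic for a given seed.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Grouping tibble.
#' @param group Group label (needs at least 4 samples).
#' @param max_dist Maximum pair distance in bp (default 50000).
#' @param bin_width Distance bin width in bp (default 100).
#' @param max_pairs Cap on evaluated pairs (default 1e6).
#' @param seed Seed for pair subsampling (default 1).
#' @return Tibble of bins: `distance_lo`, `distance_hi`, `mid`, `mean_r2`,
#'   `n_pairs` (bins with no pairs are dropped).
#' @export
ld_decay <- function(gm, grouping, group, max_dist = 50000, bin_width = 100,
                     max_pairs = 1e6, seed = 1) {
  rows <- group_samples(grouping, group)
  if (length(rows) < 4) {
    abort(paste0("group '", group, "' has fewer than 4 samples; ",
                 "LD estimates would be meaningless"))
  }
  gm_s <- snp_only(subset_samples(gm, rows))
  pairs <- candidate_pairs(gm_s$sites, max_dist)
  if (nrow(pairs) > max_pairs) {
    withr_seed <- derive_seed(seed, "ld_subsample")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(withr_seed)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    return(tibble::tibble(distance_lo = numeric(), distance_hi = numeric(),
                          mid = numeric(), mean_r2 = numeric(),
                          n_pairs = integer()))
  }
  d <- gm_s$dosage
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    pair_r2(d[, pairs$i[k]], d[, pairs$j[k]])
  }, numeric(1))
  dist <- pairs$dist
  keep <- !is.na(r2)
  bin <- floor(dist[keep] / bin_width)
  agg <- rowsum(cbind(r2[keep], 1), group = bin)
  b <- as.numeric(rownames(agg))
  tibble::tibble(
    distance_lo = b * bin_width,
    distance_hi = (b + 1) * bin_width,
    mid = (b + 0.5) * bin_width,
    mean_r2 = unname(agg[, 1] / agg[, 2]),
    n_pairs = as.integer(agg[, 2])
  ) |> dplyr::arrange(.data$mid)
}

# All intra-chromosome site pairs with 0 < distance < max_dist.
candidate_pairs <- function(sites, max_dist) {
  pieces <- purrr::map(split(seq_len(nrow(sites)), sites$chrom), function(ix) {
    pos <- sites$pos[ix]
    n <- length(ix)
    if (n < 2) return(NULL)
    # sites are sorted by pos; partners of i are the run i+1..hi within range
    hi <- findInterval(pos + max_dist - 1, pos)
    reps <- pmax(0L, hi - seq_len(n))
    i <- rep(seq_len(n), reps)
    j <- unlist(purrr::map(seq_len(n), function(k) {
      if (hi[k] <= k) integer() else seq(k + 1L, hi[k])
    }))
    tibble::tibble(i = ix[i], j = ix[j], dist = pos[j] - pos[i])
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  }
  out[out$dist > 0, , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Distance at which an LD curve decays to a fraction of its maximum
#'
#' Finds the smallest bin midpoint at which the mean r-squared first drops to
#' or below `fraction * max(mean_r2)` (relative mode, the default) or to an
#' absolute r-squared threshold (`absolute = TRUE`), linearly interpolating
#' between the two adjacent bins.
#'
#' @param curve LD curve from [ld_decay()].
#' @param fraction Relative decay fraction in (0, 1) (default 0.5,
#'   "half-maximum"), or an absolute r-squared when `absolute = TRUE`.
#' @param absolute Interpret `fraction` as an absolute r-squared threshold.
#' @return Distance in bp, or `NA` with a warning if the curve never reaches
#'   the threshold within its range.
#' @export
ld_decay_distance <- function(curve, fraction = 0.5, absolute = FALSE) {
  stopifnot(nrow(curve) > 0)
  if (!absolute) stopifnot(fraction > 0, fraction < 1)
  thr <- if (absolute) fraction else fraction * max(curve$mean_r2)
  below <- which(curve$mean_r2 <= thr)
  if (length(below) == 0) {
    warn("curve never decays to the threshold within max_dist")
    return(NA_real_)
  }
  k <- below[1]
  if (k == 1) return(curve$mid[1])
  x0 <- curve$mid[k - 1]; x1 <- curve$mid[k]
  y0 <- curve$mean_r2[k - 1]; y1 <- curve$mean_r2[k]
  if (y0 == y1) return(x1)
  x0 + (y0 - thr) / (y0 - y1) * (x1 - x0)
}

#' Fit the correlation length of an exponential LD decay curve
#'
#' Fits `mean_r2(d) = r0 * exp(-2 d / Lc)` by nonlinear least squares
#' (weighted by pair counts), falling back to a log-linear fit if the
#' nonlinear fit fails. Under a haplotype-copying model in which allelic
#' correlation decays as `exp(-d / Lc)`, genotype r-squared decays as
#' `exp(-2 d / Lc)`, so the fitted `Lc` estimates the haplotype correlation
#' length itself.
#'
#' @param curve LD curve from [ld_decay()].
#' @return Named list: `Lc` (bp), `r0`.
#' @export
ld_fit_decay_length <- function(curve) {
  stopifnot(nrow(curve) >= 3)
  df <- data.frame(d = curve$mid, y = curve$mean_r2, w = curve$n_pairs)
  fit <- tryCatch(
    stats::nls(y ~ r0 * exp(-2 * d / Lc), data = df, weights = df$w,
               start = list(r0 = max(df$y), Lc = max(df$d) / 4)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    return(list(Lc = unname(co["Lc"]), r0 = unname(co["r0"])))
  }
  pos <- df$y > 0
  lf <- stats::lm(log(y) ~ d, data = df[pos, ], weights = df$w[pos])
  list(Lc = -2 / unname(stats::coef(lf)[2]),
       r0 = exp(unname(stats::coef(lf)[1])))
}
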