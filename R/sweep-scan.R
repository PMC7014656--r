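#' Log2 diversity ratio of a window
#'
#' `log2(pi_wild / pi_cult)`, oriented so that diversity *loss* in the
#' cultivated group gives large positive values and lands in the right tail
#' of the scan. A window with `pi_cult = 0` and `pi_wild > 0` maps to `+Inf`
#' (ranks above every finite value); the reverse maps to `-Inf`; both zero is
#' undefined (`NA`, window unusable).
#'
#' @param pi_wild,pi_cult Window diversity in the wild and cultivated group.
#' @return Numeric vector of log2 ratios.
#' @export
#' @examples
#' log2_pi_ratio(4e-3, 1e-3)  # 2
log2_pi_ratio <- function(pi_wild, pi_cult) {
  dplyr::case_when(
    pi_wild == 0 & pi_cult == 0 ~ NA_real_,
    pi_cult == 0 ~ Inf,
    pi_wild == 0 ~ -Inf,
    TRUE ~ log2(pi_wild / pi_cult)
  )
}

#' Flag joint right-tail outlier windows
#'
#' Thresholds are the empirical `1 - tail_quantile` quantiles (type-7 order
#' statistics) of the log2 pi-ratio and Z(FST) over usable windows; a window
#' is flagged iff **both** statistics are strictly above their thresholds.
#' Ties at a threshold are not flagged.
#'
#' @param stats Window tibble with columns `log2_pi_ratio`, `z_fst`,
#'   `usable`.
#' @param tail_quantile Right-tail mass (default 0.05).
#' @return `stats` with a logical `flagged` column; the two thresholds are
#'   attached as the `thresholds` attribute (named list).
#' @export
flag_outliers <- function(stats, tail_quantile = 0.05) {
  stopifnot(tail_quantile > 0, tail_quantile < 0.5)
  ok <- stats$usable & !is.na(stats$log2_pi_ratio) & !is.na(stats$z_fst)
  if (sum(ok) < 20) {
    abort("fewer than 20 usable windows: tail quantiles are meaningless")
  }
  thr_ratio <- quantile(stats$log2_pi_ratio[ok], 1 - tail_quantile,
                        type = 7, names = FALSE)
  thr_z <- quantile(stats$z_fst[ok], 1 - tail_quantile, type = 7,
                    names = FALSE)
  if (!is.finite(thr_ratio)) {
    warn(paste0("log2 pi-ratio threshold is infinite: more than ",
                "tail_quantile of usable windows have zero cultivated ",
                "diversity; no window can exceed it strictly"))
  }
  stats$flagged <- ok & stats$log2_pi_ratio > thr_ratio & stats$z_fst > thr_z
  attr(stats, "thresholds") <- list(log2_pi_ratio = thr_ratio, z_fst = thr_z)
  stats
}

#' Merge flagged windows into selected regions
#'
#' Overlapping or book-ended (touching) flagged windows on one chromosome
#' merge into a single region; a gap of one or more bp splits regions.
#' Region-level FST and log2 ratio are SNP-weighted means over member
#' windows.
#'
#' @param flagged Tibble of flagged windows (columns `chrom`, `start`,
#'   `end`, `n_snps`, `fst`, `log2_pi_ratio`).
#' @return Tibble of regions: `chrom`, `start`, `end`, `n_windows_merged`,
#'   `mean_fst`, `mean_log2_ratio`.
#' @export
merge_regions <- function(flagged) {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows_merged = integer(),
                          mean_fst = numeric(), mean_log2_ratio = numeric())
  if (nrow(flagged) == 0) return(empty)
  flagged <- dplyr::arrange(flagged, .data$chrom, .data$start)
  region_id <- integer(nrow(flagged))
  cur <- 1L
  cur_end <- flagged$end[1]
  cur_chrom <- flagged$chrom[1]
  region_id[1] <- cur
  if (nrow(flagged) > 1) {
    for (i in 2:nrow(flagged)) {
      if (flagged$chrom[i] == cur_chrom && flagged$start[i] <= cur_end) {
        cur_end <- max(cur_end, flagged$end[i])
      } else {
        cur <- cur + 1L
        cur_chrom <- flagged$chrom[i]
        cur_end <- flagged$end[i]
      }
      region_id[i] <- cur
    }
  }
  flagged$region_id <- region_id
  flagged |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_windows_merged = dplyr::n(),
      mean_fst = stats::weighted.mean(.data$fst, pmax(.data$n_snps, 1)),
      mean_log2_ratio = stats::weighted.mean(.data$log2_pi_ratio,
                                             pmax(.data$n_snps, 1)),
      .groups = "drop"
    ) |>
    dplyr::select(-"region_id")
}

#' Attach overlapping genes to selected regions
#'
#' A gene belongs to a region iff its span and the region overlap by at
#' least 1 bp (regions are 0-based half-open; gene spans 1-based inclusive).
#'
#' @param regions Region tibble from [merge_regions()].
#' @param genes Gene models from [read_gff()].
#' @return `regions` with list-column `genes` and integer `n_genes`.
#' @export
assign_genes <- function(regions, genes) {
  hits <- purrr::map(seq_len(nrow(regions)), function(i) {
    g <- genes[genes$chrom == regions$chrom[i] &
               genes$start <= regions$end[i] &
               genes$end >= regions$start[i] + 1, , drop = FALSE]
    g$gene_id
  })
  regions$genes <- hits
  regions$n_genes <- vapply(hits, length, integer(1))
  regions
}

#' Mean genes per selected region
#'
#' Total gene-in-region assignments divided by the region count, rounded to
#' two decimals (half-up).
#'
#' @param n_assignments Total number of gene-region assignments.
#' @param n_regions Number of regions.
#' @return Numeric scalar (NA for zero regions).
#' @export
#' @examples
#' mean_genes_per_region(2176, 1214)  # 1.79
mean_genes_per_region <- function(n_assignments, n_regions) {
  if (n_regions == 0) return(NA_real_)
  round_half_up(n_assignments / n_regions, 2)
}

#' Selective-sweep scan for one wild/cultivated contrast
#'
#' The joint diversity-differentiation scan: tile the genome in sliding
#' windows, compute per-window diversity in both groups, Weir-Cockerham FST
#' (ratio of averages), the genome-wide Z transform of window FST, and the
#' log2 pi-ratio oriented wild-over-cultivated; flag windows falling in the
#' right `tail_quantile` tail of *both* distributions; merge flagged windows
#' into selected regions and attach overlapping genes.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Grouping tibble from [read_grouping()].
#' @param wild,cultivated Group labels for the contrast.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param genes Optional gene models from [read_gff()].
#' @param window_size,step Window geometry in bp (defaults 10000 / 5000).
#' @param tail_quantile Right-tail mass for both thresholds (default 0.05).
#' @param min_snps Minimum usable SNPs per window (default 10).
#' @param clamp Clamp negative window FST to 0 before Z-scoring (default
#'   `TRUE`).
#' @return An object of class `sweep_scan`: list with `windows` (per-window
#'   tibble: `chrom`, `start`, `end`, `n_snps`, `pi_wild`, `pi_cult`,
#'   `fst`, `z_fst`, `log2_pi_ratio`, `usable`, `flagged`), `thresholds`,
#'   `regions` (merged, gene-annotated), `wild`, `cultivated`, `config`.
#' @seealso [tidy.sweep_scan()], [glance.sweep_scan()],
#'   [autoplot.sweep_scan()]
#' @export
sweep_scan <- function(gm, grouping, wild, cultivated, chrom_lengths,
                       genes = NULL, window_size = 10000, step = 5000,
                       tail_quantile = 0.05, min_snps = 10, clamp = TRUE) {
  windows <- make_windows(chrom_lengths, window_size, step)
  pi_tab <- windowed_pi(gm, grouping, windows,
                        groups = c(wild, cultivated), min_snps = min_snps)
  pi_w <- pi_tab$pi[pi_tab$group == wild]
  pi_c <- pi_tab$pi[pi_tab$group == cultivated]
  fst_tab <- windowed_fst(gm, grouping, wild, cultivated, windows,
                          min_snps = min_snps, clamp = clamp)
  ratio <- log2_pi_ratio(pi_w, pi_c)
  usable <- fst_tab$usable & !is.na(ratio)
  z <- rep(NA_real_, nrow(windows))
  z[usable] <- z_transform(fst_tab$fst[usable])

  stats <- tibble::tibble(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    n_snps = fst_tab$n_snps, pi_wild = pi_w, pi_cult = pi_c,
    fst = fst_tab$fst, z_fst = z, log2_pi_ratio = ratio, usable = usable
  )
  stats <- flag_outliers(stats, tail_quantile)
  thresholds <- attr(stats, "thresholds")
  regions <- merge_regions(stats[stats$flagged, , drop = FALSE])
  if (!is.null(genes)) regions <- assign_genes(regions, genes)

  structure(
    list(windows = stats, thresholds = thresholds, regions = regions,
         wild = wild, cultivated = cultivated,
         config = list(window_size = window_size, step = step,
                       tail_quantile = tail_quantile, min_snps = min_snps,
                       clamp = clamp)),
    class = "sweep_scan"
  )
}

#' @exportS3Method base::print
print.sweep_scan <- function(x, ...) {
  cat(sprintf(
    "<sweep_scan> %s vs %s: %d windows (%d usable, %d flagged), %d regions\n",
    x$wild, x$cultivated, nrow(x$windows), sum(x$windows$usable),
    sum(x$windows$flagged), nrow(x$regions)))
  cat(sprintf("  thresholds: log2 pi-ratio > %.3f, Z(FST) > %.3f\n",
              x$thresholds$log2_pi_ratio, x$thresholds$z_fst))
  invisible(x)
}

#' Tidy a sweep scan into its per-window table
#'
#' @param x A [sweep_scan()] object.
#' @param ... Unused.
#' @return The per-window tibble.
#' @export
tidy.sweep_scan <- function(x, ...) {
  tibble::as_tibble(x$windows)
}

#' One-row summary of a sweep scan
#'
#' @param x A [sweep_scan()] object.
#' @param ... Unused.
#' @return One-row tibble: contrast labels, window/region counts, flagged
#'   count, both thresholds, and mean genes per region (when genes were
#'   assigned).
#' @export
glance.sweep_scan <- function(x, ...) {
  tibble::tibble(
    wild = x$wild, cultivated = x$cultivated,
    n_windows = nrow(x$windows),
    n_usable = sum(x$windows$usable),
    n_flagged = sum(x$windows$flagged),
    n_regions = nrow(x$regions),
    threshold_log2_ratio = x$thresholds$log2_pi_ratio,
    threshold_z_fst = x$thresholds$z_fst,
    genes_per_region = if ("n_genes" %in% names(x$regions)) {
      mean_genes_per_region(sum(x$regions$n_genes), nrow(x$regions))
    } else NA_real_
  )
}

#' Per-group summary of selected regions
#'
#' For one scan: SNP count inside selected regions, diversity of the
#' cultivated group inside regions (per bp), nonsynonymous and synonymous
#' counts of SNPs inside regions and their ratio, and region/gene counts.
#'
#' @param scan A [sweep_scan()] object (with genes assigned).
#' @param gm A [genotype_matrix()].
#' @param grouping Grouping tibble.
#' @param ann Annotation tibble from [annotate_variants()] (optional; effect
#'   counts are `NA` without it).
#' @return One-row tibble: `group`, `n_snp`, `theta_pi`, `nonsynonymous`,
#'   `synonymous`, `nonsyn_syn_ratio`, `n_regions`, `n_genes`.
#' @export
region_summary <- function(scan, gm, grouping, ann = NULL) {
  regions <- scan$regions
  gm_s <- snp_only(gm)
  in_region <- rep(FALSE, n_sites(gm_s))
  for (i in seq_len(nrow(regions))) {
    in_region <- in_region |
      (gm_s$sites$chrom == regions$chrom[i] &
       gm_s$sites$pos - 1 >= regions$start[i] &
       gm_s$sites$pos - 1 < regions$end[i])
  }
  total_len <- sum(regions$end - regions$start)
  rows <- group_samples(grouping, scan$cultivated)
  theta <- if (total_len > 0) {
    ac <- allele_counts(subset_sites(subset_samples(gm_s, rows), in_region))
    sum(site_pi(ac$alt, ac$n)) / total_len
  } else NA_real_
  nonsyn <- syn <- NA_integer_
  if (!is.null(ann)) {
    ann_s <- ann[ann$variant_class == "snp", , drop = FALSE]
    eff <- ann_s$effect_class[in_region]
    nonsyn <- sum(eff == "nonsynonymous")
    syn <- sum(eff == "synonymous")
  }
  tibble::tibble(
    group = scan$cultivated,
    n_snp = sum(in_region),
    theta_pi = theta,
    nonsynonymous = nonsyn,
    synonymous = syn,
    nonsyn_syn_ratio = if (!is.na(syn) && syn > 0) {
      nonsyn_syn_ratio(nonsyn, syn)
    } else NA_real_,
    n_regions = nrow(regions),
    n_genes = if ("genes" %in% names(regions)) {
      length(unique(unlist(regions$genes, use.names = FALSE)))
    } else NA_integer_
  )
}
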