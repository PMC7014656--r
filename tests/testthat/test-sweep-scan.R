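test_that("window tiling matches the documented geometry", {
  w <- make_windows(c(chr1 = 25000))
  expect_equal(w$start, c(0, 5000, 10000, 15000))
  expect_equal(w$end, c(10000, 15000, 20000, 25000))
  # chromosome shorter than one window
  w2 <- make_windows(c(chr1 = 8000))
  expect_equal(nrow(w2), 1)
  expect_equal(c(w2$start, w2$end), c(0, 8000))
  # truncated tail window appears when the remainder is >= one step
  w3 <- make_windows(c(chr1 = 23000))
  expect_equal(utils::tail(w3$end, 1), 23000)
})

test_that("windows cover every base pair of the chromosome", {
  L <- 1e5
  w <- make_windows(c(chr1 = L))
  covered <- rep(FALSE, L)
  for (i in seq_len(nrow(w))) {
    covered[(w$start[i] + 1):w$end[i]] <- TRUE
  }
  expect_true(all(covered))
})

test_that("sites map to exactly the windows containing them", {
  w <- make_windows(c(chr1 = 30000))
  sites <- tibble::tibble(chrom = "chr1",
                          pos = c(1L, 4999L, 5001L, 10000L, 29999L))
  m <- lotuscan:::site_window_map(sites, w)
  # brute-force membership
  for (k in seq_len(nrow(sites))) {
    expected <- which(w$start <= sites$pos[k] - 1 & sites$pos[k] - 1 < w$end)
    expect_setequal(m$window[m$site == k], expected)
  }
})

test_that("log2 pi-ratio is oriented wild-over-cultivated with zero rules", {
  expect_equal(log2_pi_ratio(4e-3, 1e-3), 2)
  expect_equal(log2_pi_ratio(2e-3, 2e-3), 0)
  expect_equal(log2_pi_ratio(1e-3, 0), Inf)
  expect_equal(log2_pi_ratio(0, 1e-3), -Inf)
  expect_true(is.na(log2_pi_ratio(0, 0)))
})

test_that("joint flagging respects strict thresholds and marginal tails", {
  # perfectly correlated scores: joint flag count equals the marginal tail
  n <- 100
  scores <- tibble::tibble(
    chrom = "chr1", start = (seq_len(n) - 1) * 5000,
    end = (seq_len(n) - 1) * 5000 + 10000,
    n_snps = 10L, fst = NA_real_,
    log2_pi_ratio = seq_len(n) / 10, z_fst = seq_len(n) / 5,
    usable = TRUE)
  flagged <- flag_outliers(scores, 0.05)
  # type-7 95% quantile of 1..100 is 95.05 -> exactly 5 strictly above
  expect_equal(sum(flagged$flagged), 5)
  # anti-correlated scores: no window in both right tails
  scores2 <- dplyr::mutate(scores, z_fst = rev(z_fst))
  expect_equal(sum(flag_outliers(scores2, 0.05)$flagged), 0)
  # identical values everywhere: nothing is strictly above the threshold
  scores3 <- dplyr::mutate(scores, log2_pi_ratio = 1, z_fst = 1)
  expect_equal(sum(flag_outliers(scores3, 0.05)$flagged), 0)
  # a unique joint maximum among many is always flagged
  set.seed(41)
  n2 <- 1000
  scores4 <- tibble::tibble(
    chrom = "chr1", start = (seq_len(n2) - 1) * 5000,
    end = (seq_len(n2) - 1) * 5000 + 10000, n_snps = 10L, fst = NA_real_,
    log2_pi_ratio = c(rnorm(n2 - 1), 50), z_fst = c(rnorm(n2 - 1), 50),
    usable = TRUE)
  f4 <- flag_outliers(scores4, 0.05)
  expect_true(f4$flagged[n2])
  # joint flags are a subset of each marginal 5% tail
  expect_lte(sum(f4$flagged), ceiling(0.05 * n2))
  expect_error(flag_outliers(scores[1:10, ], 0.05), "fewer than 20")
})

test_that("region merging equals an interval-union oracle", {
  mk <- function(starts, chrom = "chr1") {
    tibble::tibble(chrom = chrom, start = starts, end = starts + 10000,
                   n_snps = 10L, fst = 0.5, log2_pi_ratio = 1)
  }
  # overlapping windows merge
  r1 <- merge_regions(mk(c(0, 5000)))
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$start, r1$end), c(0, 15000))
  # a gap splits
  r2 <- merge_regions(mk(c(0, 20000)))
  expect_equal(nrow(r2), 2)
  # book-ended windows merge
  r3 <- merge_regions(mk(c(0, 10000)))
  expect_equal(nrow(r3), 1)
  # random flag patterns vs brute-force bp-level union
  set.seed(42)
  for (rep in 1:20) {
    starts <- sort(sample(seq(0, 400000, by = 5000),
                          sample(3:25, 1)))
    got <- merge_regions(mk(starts))
    covered <- rep(FALSE, 420000)
    for (s in starts) covered[(s + 1):(s + 10000)] <- TRUE
    runs <- rle(covered)
    expect_equal(nrow(got), sum(runs$values), label = paste("rep", rep))
    expect_equal(sum(got$end - got$start), sum(runs$lengths[runs$values]))
  }
})

test_that("gene assignment and the per-region mean follow the overlap rule", {
  genes <- dplyr::bind_rows(
    toy_gene("gIn", cds = cbind(12001, 12300)),
    toy_gene("gEdge", cds = cbind(19999, 20298)),
    toy_gene("gOut", cds = cbind(50001, 50300))
  )
  regions <- tibble::tibble(chrom = "chr1", start = 10000, end = 20000,
                            n_windows_merged = 2L, mean_fst = 0.5,
                            mean_log2_ratio = 1)
  res <- assign_genes(regions, genes)
  # gEdge starts at the last covered bp (0-based 19998) -> overlaps by 2 bp
  expect_setequal(res$genes[[1]], c("gIn", "gEdge"))
  expect_equal(res$n_genes, 2L)
  # desert region
  res0 <- assign_genes(dplyr::mutate(regions, start = 30000, end = 40000),
                       genes)
  expect_equal(res0$n_genes, 0L)
  expect_equal(mean_genes_per_region(0, 0), NA_real_)
})

test_that("full scan flags implanted sweeps and is order-invariant", {
  # sweeps cover ~3% of windows, well inside the 5% tail regime
  cfg <- sim_config(seed = 8, n_chroms = 2, chrom_length = 5e5,
                    n_sites = 8000,
                    groups = tibble::tibble(label = c("wild", "cult"),
                                            n = c(15L, 15L), F = 0.05),
                    sweeps = tibble::tibble(chrom = c("chr1", "chr2"),
                                            start = c(1e5, 3e5),
                                            end = c(1.25e5, 3.25e5),
                                            group = "cult", gamma = 8),
                    ld_correlation_length = 0, missing_rate = 0.02,
                    n_genes = 20, n_indels = 0)
  co <- simulate_cohort(cfg)
  scan <- sweep_scan(co$gm, co$grouping, "wild", "cult", co$chrom_lengths,
                     genes = co$genes)
  expect_s3_class(scan, "sweep_scan")
  # every region contains at least one flagged window; regions disjoint
  expect_true(all(scan$regions$n_windows_merged >= 1))
  regs <- dplyr::arrange(scan$regions, chrom, start)
  by_chrom <- split(regs, regs$chrom)
  for (rc in by_chrom) {
    if (nrow(rc) > 1) expect_true(all(rc$start[-1] > rc$end[-nrow(rc)]))
  }
  # both implanted sweeps are recovered
  hit1 <- any(regs$chrom == "chr1" & regs$start < 1.25e5 & regs$end > 1e5)
  hit2 <- any(regs$chrom == "chr2" & regs$start < 3.25e5 & regs$end > 3e5)
  expect_true(hit1 && hit2)
  # flagged counts are bounded by each marginal tail
  n_usable <- sum(scan$windows$usable)
  expect_lte(sum(scan$windows$flagged), 0.05 * n_usable + 1)
  # scan invariant to chromosome processing order (site order is canonical)
  ord <- rev(seq_len(n_sites(co$gm)))
  gm_rev <- genotype_matrix(co$gm$sites[ord, ], co$gm$dosage[, ord])
  scan2 <- sweep_scan(gm_rev, co$grouping, "wild", "cult", co$chrom_lengths,
                      genes = co$genes)
  expect_equal(scan2$windows, scan$windows)
  # tidy/glance interfaces
  expect_equal(nrow(tidy(scan)), nrow(scan$windows))
  gl <- glance(scan)
  expect_equal(gl$n_regions, nrow(scan$regions))
})

test_that("region summaries aggregate SNPs, effects and genes", {
  co <- shared_cohort()
  scan <- sweep_scan(co$gm, co$grouping, "wild", "cult", co$chrom_lengths,
                     genes = co$genes, min_snps = 5)
  ann <- annotate_variants(co$gm, co$genes, co$ref)
  rs <- region_summary(scan, co$gm, co$grouping, ann)
  expect_equal(rs$group, "cult")
  expect_equal(rs$n_regions, nrow(scan$regions))
  if (rs$n_regions > 0) {
    expect_gte(rs$n_snp, 0)
    expect_true(is.na(rs$nonsyn_syn_ratio) ||
                  rs$nonsyn_syn_ratio ==
                    round_half_up(rs$nonsynonymous / rs$synonymous, 2))
  }
  # empty region set gives an all-zero row
  scan0 <- scan
  scan0$regions <- scan$regions[0, ]
  rs0 <- region_summary(scan0, co$gm, co$grouping, ann)
  expect_equal(rs0$n_snp, 0)
  expect_equal(rs0$n_regions, 0)
})
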