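test_that("Balding-Nichols frequencies respect the divergence parameter", {
  cfg <- sim_config(seed = 61, n_chroms = 1, chrom_length = 1e5,
                    n_sites = 500,
                    groups = tibble::tibble(label = c("a", "b"),
                                            n = c(5L, 5L), F = c(0, 0.2)),
                    sweeps = NULL, n_genes = 0, n_indels = 0)
  fr <- simulate_frequencies(cfg)
  # F = 0 copies the ancestral frequencies exactly
  expect_equal(fr$freq[, "a"], fr$ancestral)
  expect_false(isTRUE(all.equal(fr$freq[, "b"], fr$ancestral)))
  # fixed seed reproduces identical arrays
  fr2 <- simulate_frequencies(cfg)
  expect_identical(fr$freq, fr2$freq)
  expect_true(all(fr$freq >= 0 & fr$freq <= 1))
})

test_that("sweep transform pushes frequencies toward the nearer boundary", {
  cfg <- sim_config(seed = 62, n_chroms = 1, chrom_length = 1e4,
                    n_sites = 20,
                    groups = tibble::tibble(label = "g", n = 5L, F = 0),
                    sweeps = tibble::tibble(chrom = "chr1", start = 0,
                                            end = 1e4, group = "g",
                                            gamma = 8),
                    n_genes = 0, n_indels = 0)
  fr <- simulate_frequencies(cfg)
  fr$freq[, "g"] <- 0.5
  sw <- implant_sweep(fr, cfg)
  expect_equal(unique(sw$freq[, "g"]), 0.5^8)
  # heterozygosity collapses accordingly
  expect_lt(2 * 0.5^8 * (1 - 0.5^8), 0.01)
  # gamma = 1 is the identity
  cfg1 <- cfg
  cfg1$sweeps$gamma <- 1
  fr1 <- simulate_frequencies(cfg1)
  expect_equal(implant_sweep(fr1, cfg1)$freq, fr1$freq)
  # above 0.5 the push is upward
  fr$freq[, "g"] <- 0.9
  expect_equal(unique(implant_sweep(fr, cfg)$freq[, "g"]), 1 - 0.1^8)
})

test_that("genotype simulation honours fixed frequencies and missingness", {
  cfg <- sim_config(seed = 63, n_chroms = 1, chrom_length = 1e5,
                    n_sites = 1000,
                    groups = tibble::tibble(label = "g", n = 50L, F = 0),
                    sweeps = NULL, ld_correlation_length = 0,
                    missing_rate = 0.1, n_genes = 0, n_indels = 0)
  fr <- simulate_frequencies(cfg)
  fr$freq[, "g"] <- 1
  d <- simulate_genotypes(fr, cfg)
  # p = 1 everywhere: every non-missing dosage is 2
  expect_true(all(d[!is.na(d)] == 2L))
  # observed missing fraction within the binomial window around 0.1
  miss <- mean(is.na(d))
  expect_gt(miss, 0.09)
  expect_lt(miss, 0.11)
})

test_that("LD-structured haplotypes decay with distance", {
  cfg <- sim_config(seed = 64, n_chroms = 1, chrom_length = 2e5,
                    n_sites = 2000,
                    groups = tibble::tibble(label = "g", n = 40L, F = 0),
                    sweeps = NULL, ld_correlation_length = 500,
                    missing_rate = 0, n_genes = 0, n_indels = 0)
  co <- simulate_cohort(cfg)
  curve <- ld_decay(co$gm, co$grouping, "g", max_dist = 2500, bin_width = 200)
  r2_near <- curve$mean_r2[curve$mid < 300][1]
  r2_far <- curve$mean_r2[curve$mid > 1900][1]
  expect_gt(r2_near, r2_far)
})

test_that("implanted sweeps depress measured diversity far below background", {
  cfg <- sim_config(seed = 65, n_chroms = 1, chrom_length = 4e5,
                    n_sites = 4000,
                    groups = tibble::tibble(label = c("wild", "cult"),
                                            n = c(22L, 20L), F = 0.05),
                    sweeps = tibble::tibble(chrom = "chr1", start = 1e5,
                                            end = 1.5e5, group = "cult",
                                            gamma = 8),
                    ld_correlation_length = 0, missing_rate = 0.02,
                    n_genes = 0, n_indels = 0)
  co <- simulate_cohort(cfg)
  gm <- co$gm
  in_sweep <- gm$sites$pos - 1 >= 1e5 & gm$sites$pos - 1 < 1.5e5
  rows <- co$grouping$sample[co$grouping$group == "cult"]
  ac_in <- lotuscan:::allele_counts(lotuscan:::subset_sites(
    lotuscan:::subset_samples(gm, rows), in_sweep))
  ac_out <- lotuscan:::allele_counts(lotuscan:::subset_sites(
    lotuscan:::subset_samples(gm, rows), !in_sweep))
  pi_in <- mean(site_pi(ac_in$alt, ac_in$n))
  pi_out <- mean(site_pi(ac_out$alt, ac_out$n))
  expect_lt(pi_in, 0.25 * pi_out)
})

test_that("emitted datasets are consistent and byte-deterministic", {
  cfg <- sim_config(seed = 66, n_chroms = 1, chrom_length = 1e5,
                    n_sites = 400,
                    groups = tibble::tibble(label = c("w", "c"),
                                            n = c(6L, 6L), F = 0.1),
                    sweeps = NULL, ld_correlation_length = 0,
                    missing_rate = 0.02, n_genes = 5, n_indels = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_dataset(cfg, d1)
  p2 <- emit_dataset(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = paste("file", k))
  }
  # the full ingest path validates with zero errors
  gm <- read_vcf(p1$vcf)
  genes <- read_gff(p1$gff)
  ref <- read_reference(p1$fasta)
  grp <- read_grouping(p1$groups, gm)
  expect_equal(nrow(grp), 12)
  expect_equal(nrow(genes), 5)
  # VCF REF alleles match the emitted FASTA
  chars <- strsplit(as.character(ref[["chr1"]]), "")[[1]]
  expect_true(all(substr(gm$sites$ref, 1, 1) == chars[gm$sites$pos]))
  # annotation runs cleanly on the emitted bundle
  ann <- annotate_variants(gm, genes, ref)
  expect_true(all(ann$region_class %in%
    c("intergenic", "intronic", "utr5", "utr3", "utr5_utr3", "cds")))
  # CDS SNPs are present so the codon-effect path is exercised
  expect_gt(sum(ann$region_class == "cds" & ann$variant_class == "snp"), 0)
  expect_false(any(ann$effect_class[ann$region_class == "cds" &
                                      ann$variant_class == "snp"] ==
                     "unknown"))
})

test_that("a gene-free genome annotates everything as intergenic", {
  cfg <- sim_config(seed = 67, n_chroms = 1, chrom_length = 5e4,
                    n_sites = 100,
                    groups = tibble::tibble(label = "g", n = 4L, F = 0),
                    sweeps = NULL, n_genes = 0, n_indels = 0)
  d <- withr::local_tempdir()
  p <- emit_dataset(cfg, d)
  gm <- read_vcf(p$vcf)
  genes <- read_gff(p$gff)
  ann <- annotate_variants(gm, genes, read_reference(p$fasta))
  expect_true(all(ann$region_class == "intergenic"))
})
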