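#' Configuration for the synthetic-cohort generator
#'
#' Defines every parameter of a simulated resequencing cohort: a random
#' reference genome with genic architecture (UTR/CDS/intron/intergenic),
#' ancestral allele frequencies, per-group Balding-Nichols divergence,
#' implanted selective sweeps (frequency pushed toward fixation in the
#' target group), distance-decaying LD via a haplotype-copying Markov chain,
#' and genotype missingness.
#'
#' The defaults emulate a five-group domestication cohort (wild n = 22,
#' seed n = 21, rhizome n = 13, flower n = 11, american n = 2 diploids) at
#' desk scale: a 1 Mb genome (2 chromosomes) with ~8 SNPs/kb, which puts
#' per-group diversity on the 10^-3-per-bp scale typical of resequencing
#' panels, one implanted 30 kb sweep per cultivated group, a 500 bp LD
#' correlation length and 2% missing genotypes.
#'
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_sites Total SNP count across the genome.
#' @param ancestral_range Uniform range for ancestral allele frequencies.
#' @param groups Tibble with columns `label`, `n` (diploids), `F`
#'   (Balding-Nichols divergence in `[0, 1)`; 0 means identical to
#'   ancestral).
#' @param sweeps Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `group` (target), `gamma` (intensity >= 1; 1 = no sweep),
#'   or `NULL`.
#' @param ld_correlation_length LD correlation length `Lc` in bp; adjacent
#'   haplotype alleles at distance `d` are copied with probability
#'   `exp(-d / Lc)`. 0 disables LD (independent binomial dosages).
#' @param missing_rate Per-genotype missing probability.
#' @param n_genes Genes per chromosome (0 for a gene-free genome).
#' @param gene_length Gene span in bp (> 510).
#' @param cds_fraction Fraction of the gene span that is coding.
#' @param n_indels Indel/SV records added for annotation exercises.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2,
                       chrom_length = 5e5,
                       n_sites = 8000,
                       ancestral_range = c(0.05, 0.95),
                       groups = tibble::tibble(
                         label = c("wild", "seed", "rhizome", "flower",
                                   "american"),
                         n = c(22L, 21L, 13L, 11L, 2L),
                         F = c(0.05, 0.25, 0.45, 0.10, 0.60)
                       ),
                       sweeps = tibble::tibble(
                         chrom = c("chr1", "chr1", "chr2"),
                         start = c(1e5, 3e5, 2e5),
                         end = c(1.3e5, 3.3e5, 2.3e5),
                         group = c("seed", "rhizome", "flower"),
                         gamma = 8
                       ),
                       ld_correlation_length = 500,
                       missing_rate = 0.02,
                       n_genes = 60,
                       gene_length = 3000,
                       cds_fraction = 0.5,
                       n_indels = 60) {
  stopifnot(n_chroms >= 1, chrom_length > 0, n_sites >= 1,
            all(groups$F >= 0), all(groups$F < 1), all(groups$n >= 1),
            missing_rate >= 0, missing_rate < 1,
            ld_correlation_length >= 0)
  if (!is.null(sweeps) && nrow(sweeps) > 0) {
    stopifnot(all(sweeps$gamma >= 1),
              all(sweeps$start >= 0), all(sweeps$end <= chrom_length),
              all(sweeps$group %in% groups$label))
  }
  if (n_genes > 0) stopifnot(gene_length > 510)
  structure(
    list(seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
         n_sites = n_sites, ancestral_range = ancestral_range,
         groups = groups, sweeps = sweeps,
         ld_correlation_length = ld_correlation_length,
         missing_rate = missing_rate, n_genes = n_genes,
         gene_length = gene_length, cds_fraction = cds_fraction,
         n_indels = n_indels),
    class = "sim_config"
  )
}

#' Standard sweep-recovery scenario
#'
#' The benchmark scenario for end-to-end sweep recovery: a 20 Mb genome
#' (2 x 10 Mb) carrying 540,000 SNPs (27 SNPs/kb, the density typical of
#' deep plant resequencing panels), two groups (wild n = 22, cultivated
#' n = 20, Balding-Nichols F = 0.05 each), ten implanted 50 kb sweeps of
#' intensity gamma = 8 in the cultivated group, no LD, 2% missingness,
#' gene-free.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
sweep_scenario_config <- function(seed = 1) {
  starts <- rep(c(1e6, 3e6, 5e6, 7e6, 9e6), 2)
  sim_config(
    seed = seed, n_chroms = 2, chrom_length = 1e7, n_sites = 540000,
    groups = tibble::tibble(label = c("wild", "cultivated"),
                            n = c(22L, 20L), F = c(0.05, 0.05)),
    sweeps = tibble::tibble(
      chrom = rep(c("chr1", "chr2"), each = 5),
      start = starts, end = starts + 5e4,
      group = "cultivated", gamma = 8
    ),
    ld_correlation_length = 0, missing_rate = 0.02,
    n_genes = 0, n_indels = 0
  )
}

chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

#' Draw per-group allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on `cfg$ancestral_range`; each group's
#' frequency is drawn from `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` around
#' the ancestral `p`, so that the expected Weir-Cockerham FST between groups
#' is approximately `F`. `F = 0` copies the ancestral frequency exactly.
#'
#' @param cfg A [sim_config()].
#' @return List: `sites` (tibble `chrom`, `pos`), `ancestral` (vector),
#'   `freq` (matrix sites x groups).
#' @export
simulate_frequencies <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, "frequencies"))
  chroms <- chrom_names(cfg)
  per_chrom <- diff(round(seq(0, cfg$n_sites, length.out = cfg$n_chroms + 1)))
  pieces <- purrr::map2(chroms, per_chrom, function(ch, k) {
    tibble::tibble(chrom = ch,
                   pos = sort(sample.int(cfg$chrom_length, k)))
  })
  sites <- dplyr::bind_rows(pieces)
  # guarantee CDS coverage at all three codon positions when genes exist
  if (cfg$n_genes > 0) {
    layout <- gene_layout(cfg)
    first_cds <- layout$cds[[1]]$start[1]
    forced <- tibble::tibble(chrom = layout$chrom[1],
                             pos = first_cds + 0:5)
    sites <- dplyr::bind_rows(sites, forced) |>
      dplyr::distinct(.data$chrom, .data$pos)
    sites <- sites[site_order(sites$chrom, sites$pos), ]
  }
  n <- nrow(sites)
  p <- runif(n, cfg$ancestral_range[1], cfg$ancestral_range[2])
  freq <- vapply(seq_len(nrow(cfg$groups)), function(g) {
    f <- cfg$groups$F[g]
    if (f == 0) return(p)
    rbeta(n, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }, numeric(n))
  colnames(freq) <- cfg$groups$label
  list(sites = sites, ancestral = p, freq = freq)
}

#' Implant selective sweeps into group frequencies
#'
#' Inside each sweep interval, the target group's frequency is pushed toward
#' its nearer boundary: `p' = p^gamma` for `p <= 0.5`, else
#' `p' = 1 - (1 - p)^gamma`. Expected heterozygosity strictly decreases for
#' `gamma > 1` at interior frequencies; `gamma = 1` changes nothing.
#'
#' @param freqs Result of [simulate_frequencies()].
#' @param cfg A [sim_config()].
#' @return `freqs` with modified `freq` matrix.
#' @export
implant_sweep <- function(freqs, cfg) {
  sweeps <- cfg$sweeps
  if (is.null(sweeps) || nrow(sweeps) == 0) return(freqs)
  for (i in seq_len(nrow(sweeps))) {
    g <- sweeps$group[i]
    in_ivl <- freqs$sites$chrom == sweeps$chrom[i] &
      freqs$sites$pos - 1 >= sweeps$start[i] &
      freqs$sites$pos - 1 < sweeps$end[i]
    p <- freqs$freq[in_ivl, g]
    freqs$freq[in_ivl, g] <- ifelse(p <= 0.5, p^sweeps$gamma[i],
                                    1 - (1 - p)^sweeps$gamma[i])
  }
  freqs
}

#' Simulate diploid genotypes from group frequencies
#'
#' Without LD (`ld_correlation_length = 0`), each dosage is
#' `Binomial(2, p_group)`. With LD, each haplotype is generated by a
#' site-ordered Markov chain per chromosome: the allele at a site copies the
#' previous site's allele with probability `exp(-d / Lc)` (d = inter-site
#' distance), otherwise it is drawn fresh from the site's group frequency;
#' the two haplotypes are summed to a dosage. Genotypes are then masked
#' missing at `missing_rate`.
#'
#' @param freqs Result of [simulate_frequencies()] (after any
#'   [implant_sweep()]).
#' @param cfg A [sim_config()].
#' @return A dosage matrix (samples x sites) with sample ids
#'   `<group>_<k>`; attribute `grouping` holds the sample-to-group tibble.
#' @export
simulate_genotypes <- function(freqs, cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, "genotypes"))
  n_sites <- nrow(freqs$sites)
  lc <- cfg$ld_correlation_length
  chrom_idx <- split(seq_len(n_sites), freqs$sites$chrom)

  group_mats <- purrr::map(seq_len(nrow(cfg$groups)), function(g) {
    ng <- cfg$groups$n[g]
    p <- freqs$freq[, cfg$groups$label[g]]
    if (lc == 0) {
      d <- matrix(rbinom(ng * n_sites, 2, rep(p, each = ng)), nrow = ng)
    } else {
      h <- matrix(0L, nrow = 2L * ng, ncol = n_sites)
      for (ix in chrom_idx) {
        pos <- freqs$sites$pos[ix]
        h[, ix[1]] <- rbinom(2L * ng, 1, p[ix[1]])
        if (length(ix) > 1) {
          cpy <- exp(-diff(pos) / lc)
          for (k in 2:length(ix)) {
            fresh <- rbinom(2L * ng, 1, p[ix[k]])
            take <- runif(2L * ng) < cpy[k - 1]
            h[, ix[k]] <- ifelse(take, h[, ix[k - 1]], fresh)
          }
        }
      }
      d <- h[seq(1, 2 * ng, by = 2), , drop = FALSE] +
        h[seq(2, 2 * ng, by = 2), , drop = FALSE]
    }
    rownames(d) <- sprintf("%s_%02d", cfg$groups$label[g], seq_len(ng))
    d
  })
  dosage <- do.call(rbind, group_mats)
  if (cfg$missing_rate > 0) {
    dosage[runif(length(dosage)) < cfg$missing_rate] <- NA_integer_
  }
  storage.mode(dosage) <- "integer"
  attr(dosage, "grouping") <- tibble::tibble(
    sample = rownames(dosage),
    group = rep(cfg$groups$label, cfg$groups$n)
  )
  dosage
}

# Deterministic gene architecture: genes tiled along each chromosome, with
# UTR / CDS / intron / CDS / UTR blocks and alternating strand. All
# coordinates 1-based inclusive; CDS total length is a codon multiple.
gene_layout <- function(cfg) {
  if (cfg$n_genes == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), cds_valid = logical(),
                          cds = list(), utr5 = list(), utr3 = list(),
                          exons = list(), introns = list()))
  }
  gl <- cfg$gene_length
  cds_total <- 3L * floor(cfg$cds_fraction * gl / 3)
  utr_a <- 150L
  intron_len <- 200L
  utr_b <- gl - utr_a - intron_len - cds_total
  stopifnot(cds_total >= 6, utr_b >= 1)
  cds1 <- floor(cds_total * 2 / 3)
  cds2 <- cds_total - cds1
  tile <- floor(cfg$chrom_length / cfg$n_genes)
  stopifnot(tile > gl + 200)

  rows <- purrr::map(seq_len(cfg$n_chroms), function(ci) {
    purrr::map(seq_len(cfg$n_genes), function(gi) {
      s <- (gi - 1L) * tile + 101L
      strand <- if ((gi + ci) %% 2 == 0) "+" else "-"
      b_utr_a <- c(s, s + utr_a - 1L)
      b_c1 <- c(s + utr_a, s + utr_a + cds1 - 1L)
      b_int <- c(b_c1[2] + 1L, b_c1[2] + intron_len)
      b_c2 <- c(b_int[2] + 1L, b_int[2] + cds2)
      b_utr_b <- c(b_c2[2] + 1L, b_c2[2] + utr_b)
      ivl <- function(b) tibble::tibble(start = b[1], end = b[2])
      cds <- dplyr::bind_rows(ivl(b_c1), ivl(b_c2))
      exons <- dplyr::bind_rows(
        tibble::tibble(start = b_utr_a[1], end = b_c1[2]),
        tibble::tibble(start = b_c2[1], end = b_utr_b[2])
      )
      tibble::tibble(
        gene_id = sprintf("gene_c%d_%03d", ci, gi),
        chrom = paste0("chr", ci), strand = strand,
        start = s, end = b_utr_b[2], cds_valid = TRUE,
        cds = list(cds),
        utr5 = list(if (strand == "+") ivl(b_utr_a) else ivl(b_utr_b)),
        utr3 = list(if (strand == "+") ivl(b_utr_b) else ivl(b_utr_a)),
        exons = list(exons),
        introns = list(ivl(b_int))
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

# Random reference with stop-free sense codons written into every CDS.
build_reference <- function(cfg, genes) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, "reference"))
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  seqs <- purrr::map(chrom_names(cfg), function(ch) {
    bases <- sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
    for (i in which(genes$chrom == ch)) {
      cds <- genes$cds[[i]]
      pos <- unlist(lapply(seq_len(nrow(cds)),
                           function(k) cds$start[k]:cds$end[k]))
      n_codons <- length(pos) / 3L
      coding <- strsplit(paste(sample(sense, n_codons, replace = TRUE),
                               collapse = ""), "")[[1]]
      if (genes$strand[i] == "-") {
        coding <- chartr("ACGT", "TGCA", rev(coding))
      }
      bases[pos] <- coding
    }
    paste(bases, collapse = "")
  })
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  names(ref) <- chrom_names(cfg)
  ref
}

#' Simulate a complete cohort in memory
#'
#' Runs the full generator: reference genome with genic architecture,
#' Balding-Nichols group frequencies, implanted sweeps, (optionally
#' LD-structured) genotypes, plus a handful of indel/SV records for
#' annotation exercises. All randomness derives from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `gm` ([genotype_matrix()]), `grouping` (tibble), `genes`
#'   (gene-model tibble), `ref` (DNAStringSet), `chrom_lengths`, `freqs`
#'   (the drawn frequencies), `config`.
#' @export
simulate_cohort <- function(cfg) {
  genes <- gene_layout(cfg)
  ref <- build_reference(cfg, genes)
  freqs <- simulate_frequencies(cfg) |> implant_sweep(cfg)
  dosage <- simulate_genotypes(freqs, cfg)
  grouping <- attr(dosage, "grouping")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, "alleles"))
  ref_chars <- lapply(as.character(ref), function(s) strsplit(s, "")[[1]])
  ref_base <- vapply(seq_len(nrow(freqs$sites)), function(i) {
    ref_chars[[freqs$sites$chrom[i]]][freqs$sites$pos[i]]
  }, character(1))
  alt_base <- vapply(ref_base, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1), USE.NAMES = FALSE)
  sites <- dplyr::mutate(freqs$sites, ref = ref_base, alt = alt_base,
                         qual = 60)

  if (cfg$n_indels > 0) {
    idl <- simulate_indels(cfg, ref_chars, sites)
    sites <- dplyr::bind_rows(sites, idl$sites)
    dosage <- cbind(dosage, idl$dosage)
  }
  gm <- genotype_matrix(sites, dosage)
  list(gm = gm, grouping = grouping, genes = genes, ref = ref,
       chrom_lengths = setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                chrom_names(cfg)),
       freqs = freqs, config = cfg)
}

# Anchored insertion/deletion (and a few >5 bp SV) records at positions
# distinct from the SNPs; dosages are low-frequency binomials.
simulate_indels <- function(cfg, ref_chars, snp_sites) {
  set.seed(derive_seed(cfg$seed, "indels"))
  n <- cfg$n_indels
  chrom <- sample(chrom_names(cfg), n, replace = TRUE)
  pos <- sample.int(cfg$chrom_length - 20L, n)
  keys <- paste(chrom, pos)
  dup <- duplicated(keys) | keys %in% paste(snp_sites$chrom, snp_sites$pos)
  chrom <- chrom[!dup]; pos <- pos[!dup]
  n <- length(pos)
  len <- sample(c(1:5, 8L), n, replace = TRUE,
                prob = c(rep(0.18, 5), 0.1))
  is_ins <- runif(n) < 0.5
  ref_a <- character(n); alt_a <- character(n)
  for (i in seq_len(n)) {
    anchor <- ref_chars[[chrom[i]]][pos[i]]
    extra <- paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
                   collapse = "")
    if (is_ins[i]) {
      ref_a[i] <- anchor
      alt_a[i] <- paste0(anchor, extra)
    } else {
      following <- paste(ref_chars[[chrom[i]]][(pos[i] + 1):(pos[i] + len[i])],
                         collapse = "")
      ref_a[i] <- paste0(anchor, following)
      alt_a[i] <- anchor
    }
  }
  n_samples <- sum(cfg$groups$n)
  dosage <- matrix(rbinom(n_samples * n, 2, 0.2), nrow = n_samples)
  tibble_sites <- tibble::tibble(chrom = chrom, pos = pos, ref = ref_a,
                                 alt = alt_a, qual = 60)
  list(sites = tibble_sites, dosage = dosage)
}

#' Emit a complete synthetic dataset to disk
#'
#' Writes the reference FASTA, GFF3 gene models, a plain-text VCF and the
#' sample-to-group TSV for a simulated cohort, after self-checking that
#' every VCF reference allele matches the FASTA. Identical seeds give
#' byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Named list of file paths (`fasta`, `gff`, `vcf`, `groups`),
#'   invisibly; the cohort list is attached as attribute `cohort`.
#' @export
emit_dataset <- function(cfg, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  cohort <- simulate_cohort(cfg)
  ref_chars <- lapply(as.character(cohort$ref),
                      function(s) strsplit(s, "")[[1]])
  first_base <- vapply(seq_len(n_sites(cohort$gm)), function(i) {
    ref_chars[[cohort$gm$sites$chrom[i]]][cohort$gm$sites$pos[i]]
  }, character(1))
  if (!all(substr(cohort$gm$sites$ref, 1, 1) == first_base)) {
    abort("self-check failed: VCF reference alleles do not match the FASTA")
  }
  paths <- list(
    fasta = file.path(outdir, "reference.fa"),
    gff = file.path(outdir, "genes.gff3"),
    vcf = file.path(outdir, "variants.vcf"),
    groups = file.path(outdir, "groups.tsv")
  )
  Biostrings::writeXStringSet(cohort$ref, paths$fasta)
  write_gff(cohort$genes, paths$gff)
  write_vcf(cohort$gm, paths$vcf, contigs = cohort$chrom_lengths)
  readr::write_tsv(cohort$grouping, paths$groups, col_names = FALSE)
  attr(paths, "cohort") <- cohort
  invisible(paths)
}
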