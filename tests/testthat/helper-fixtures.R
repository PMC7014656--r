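# Shared fixture builders: everything is generated in code at test time.

# Minimal genotype matrix from a dosage matrix (samples x sites).
toy_gm <- function(dosage, chrom = "chr1", pos = NULL, ref = "A", alt = "G",
                   samples = NULL) {
  n_s <- ncol(dosage)
  pos <- pos %||% seq(10, by = 100, length.out = n_s)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- samples %||% paste0("s", seq_len(nrow(dosage)))
  }
  sites <- tibble::tibble(
    chrom = rep_len(chrom, n_s), pos = as.integer(pos),
    ref = rep_len(ref, n_s), alt = rep_len(alt, n_s)
  )
  genotype_matrix(sites, dosage)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Two-group grouping tibble for a gm whose samples are named "g1_*"/"g2_*",
# or an explicit assignment.
toy_grouping <- function(gm, split_at = NULL) {
  n <- length(gm$samples)
  split_at <- split_at %||% ceiling(n / 2)
  tibble::tibble(
    sample = gm$samples,
    group = rep(c("wild", "cult"), c(split_at, n - split_at))
  )
}

# One-row gene-model tibble in the read_gff() layout.
toy_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     utr5 = NULL, cds = NULL, utr3 = NULL) {
  ivl <- function(m) {
    if (is.null(m)) return(tibble::tibble(start = integer(), end = integer()))
    tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  }
  cds_t <- ivl(cds); utr5_t <- ivl(utr5); utr3_t <- ivl(utr3)
  exons <- dplyr::arrange(dplyr::bind_rows(cds_t, utr5_t, utr3_t), start)
  span <- range(c(exons$start, exons$end))
  introns <- lotuscan:::interval_gaps(exons)
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = span[1], end = span[2],
    cds_valid = nrow(cds_t) > 0 && sum(cds_t$end - cds_t$start + 1) %% 3 == 0,
    cds = list(cds_t), utr5 = list(utr5_t), utr3 = list(utr3_t),
    exons = list(exons),
    introns = list(introns)
  )
}

# Reference DNAStringSet from character chromosome sequences.
toy_ref <- function(...) {
  seqs <- c(...)
  ref <- Biostrings::DNAStringSet(unname(seqs))
  names(ref) <- names(seqs)
  ref
}

# Small simulated cohort shared across tests (memoised per session).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_chroms = 1, chrom_length = 2e5,
                        n_sites = 1500,
                        groups = tibble::tibble(
                          label = c("wild", "cult"),
                          n = c(12L, 10L), F = c(0.05, 0.05)),
                        sweeps = NULL, ld_correlation_length = 0,
                        missing_rate = 0.05, n_genes = 10, n_indels = 20)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
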