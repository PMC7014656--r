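#' Run the full comparative-population-genomics pipeline
#'
#' Orchestrates ingest -> filter -> annotation -> diversity -> sweep scans
#' (one per wild/cultivated contrast, with thresholds computed independently
#' per contrast) -> LD decay -> NJ tree and PCA, and writes a
#' publication-style report bundle to `outdir`:
#' `annotation_summary.tsv`, `venn_counts.tsv`, `diversity_by_group.tsv`,
#' `heterozygosity_by_sample.tsv`, per-contrast `window_stats_<group>.tsv`,
#' `selected_regions_<group>.bed` and `selected_genes_<group>.txt`,
#' `region_summary.tsv`, `ld_decay.tsv`, `ld_summary.tsv`, `tree.nwk`,
#' `pca_coords.tsv`, `pca_eigenvalues.tsv`, and `run_log.json` (parameters,
#' per-contrast thresholds, seeds).
#'
#' Any stage failure aborts with the stage name and removes partial outputs.
#' All randomness (LD pair subsampling, bootstrap) derives from `seed`, so
#' identical inputs and seed give a byte-identical bundle.
#'
#' @param vcf,gff,fasta,groups Paths to the input VCF, GFF3, FASTA and
#'   sample-to-group TSV.
#' @param wild Label of the wild reference group.
#' @param cultivated Character vector of cultivated group labels; one scan
#'   is run per `(wild, cultivated)` contrast.
#' @param outdir Output directory (created if needed).
#' @param min_qual,min_maf Ingest filters (defaults 20 and 0.1).
#' @param window_size,step,tail_quantile,min_snps Scan parameters (defaults
#'   10000 / 5000 / 0.05 / 10).
#' @param ld_max_dist,ld_bin_width LD curve settings (defaults 50000 / 100).
#' @param n_boot Bootstrap replicates for the NJ tree (default 100).
#' @param seed Master seed (default 1).
#' @return Invisibly, a list with all computed objects (`gm`, `grouping`,
#'   `annotation`, `ann_summary`, `diversity`, `scans`, `ld`, `tree`,
#'   `pca`, `table1`, `region_summary`) and `paths` of written files.
#' @export
run_full <- function(vcf, gff, fasta, groups, wild, cultivated, outdir,
                     min_qual = 20, min_maf = 0.1,
                     window_size = 10000, step = 5000,
                     tail_quantile = 0.05, min_snps = 10,
                     ld_max_dist = 50000, ld_bin_width = 100,
                     n_boot = 100, seed = 1) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character()
  stage <- "validate"
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    written <<- c(written, p)
    p
  }
  result <- tryCatch({
    stage <- "ingest"
    gm <- read_vcf(vcf, min_qual = min_qual)
    genes <- read_gff(gff)
    ref <- read_reference(fasta)
    grouping <- read_grouping(groups, gm)
    bad_groups <- setdiff(c(wild, cultivated), unique(grouping$group))
    if (length(bad_groups) > 0) {
      abort(paste0("unknown group(s): ", paste(bad_groups, collapse = ", ")))
    }
    chrom_lengths <- setNames(Biostrings::width(ref), names(ref))
    genome_length <- sum(chrom_lengths)

    stage <- "filter"
    gm_f <- filter_sites(gm, min_maf = min_maf)

    stage <- "annotation"
    ann <- annotate_variants(gm_f, genes, ref)
    ann_summary <- annotation_summary(gm_f, ann, grouping)
    venn <- venn_partition(group_site_sets(gm_f, grouping))

    stage <- "diversity"
    groups_all <- unique(grouping$group)
    div_groups <- groups_all[
      vapply(groups_all,
             function(g) length(group_samples(grouping, g)) >= 2, logical(1))]
    diversity <- purrr::map(div_groups, function(g) {
      group_theta_pi(gm_f, grouping, g, genome_length)
    }) |> dplyr::bind_rows()
    het <- heterozygosity_rate(gm_f, genome_length)

    stage <- "scan"
    scans <- purrr::map(cultivated, function(cg) {
      sweep_scan(gm_f, grouping, wild, cg, chrom_lengths, genes = genes,
                 window_size = window_size, step = step,
                 tail_quantile = tail_quantile, min_snps = min_snps)
    })
    names(scans) <- cultivated
    reg_summary <- purrr::map(scans, function(s) {
      region_summary(s, gm_f, grouping, ann)
    }) |> dplyr::bind_rows()

    stage <- "ld"
    ld_groups <- groups_all[
      vapply(groups_all,
             function(g) length(group_samples(grouping, g)) >= 4, logical(1))]
    ld_curves <- purrr::map(ld_groups, function(g) {
      ld_decay(gm_f, grouping, g, max_dist = ld_max_dist,
               bin_width = ld_bin_width, seed = derive_seed(seed, "ld")) |>
        dplyr::mutate(group = g, .before = 1)
    }) |> dplyr::bind_rows()
    ld_summary <- ld_curves |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(decay_distance_bp = suppressWarnings(
        ld_decay_distance(dplyr::pick(dplyr::everything()))),
        .groups = "drop")

    stage <- "structure"
    tree <- bootstrap_support(gm_f, n_replicates = n_boot,
                              seed = derive_seed(seed, "tree"))
    pca <- pca_genotypes(gm_f, n_components = min(10, n_samples(gm_f) - 1))

    stage <- "report"
    table1 <- format_table1(ann_summary, diversity)
    paths <- list(
      annotation_summary = emit("annotation_summary.tsv",
                                \(p) readr::write_tsv(table1, p)),
      venn_counts = emit("venn_counts.tsv", \(p) readr::write_tsv(venn, p)),
      diversity = emit("diversity_by_group.tsv",
                       \(p) readr::write_tsv(diversity, p)),
      heterozygosity = emit("heterozygosity_by_sample.tsv",
                            \(p) readr::write_tsv(het, p)),
      region_summary = emit("region_summary.tsv",
                            \(p) readr::write_tsv(reg_summary, p)),
      ld_decay = emit("ld_decay.tsv", \(p) readr::write_tsv(ld_curves, p)),
      ld_summary = emit("ld_summary.tsv",
                        \(p) readr::write_tsv(ld_summary, p)),
      tree = emit("tree.nwk", \(p) write_newick(tree, p)),
      pca_coords = emit("pca_coords.tsv",
                        \(p) readr::write_tsv(tidy(pca), p)),
      pca_eigenvalues = emit("pca_eigenvalues.tsv", \(p) readr::write_tsv(
        tibble::tibble(component = seq_along(pca$explained),
                       explained_fraction = pca$explained), p))
    )
    for (cg in cultivated) {
      s <- scans[[cg]]
      paths[[paste0("windows_", cg)]] <- emit(
        paste0("window_stats_", cg, ".tsv"),
        \(p) readr::write_tsv(tidy(s), p))
      bed <- s$regions |>
        dplyr::mutate(genes = vapply(.data$genes, paste, character(1),
                                     collapse = ",")) |>
        dplyr::select("chrom", "start", "end", "genes")
      paths[[paste0("regions_", cg)]] <- emit(
        paste0("selected_regions_", cg, ".bed"),
        \(p) readr::write_tsv(bed, p, col_names = FALSE))
      paths[[paste0("genes_", cg)]] <- emit(
        paste0("selected_genes_", cg, ".txt"),
        \(p) readr::write_lines(
          sort(unique(unlist(s$regions$genes, use.names = FALSE))), p))
    }
    log <- list(
      seed = seed,
      parameters = list(min_qual = min_qual, min_maf = min_maf,
                        window_size = window_size, step = step,
                        tail_quantile = tail_quantile, min_snps = min_snps,
                        ld_max_dist = ld_max_dist,
                        ld_bin_width = ld_bin_width, n_boot = n_boot),
      contrasts = purrr::map(scans, function(s) {
        list(wild = s$wild, cultivated = s$cultivated,
             threshold_log2_pi_ratio = s$thresholds$log2_pi_ratio,
             threshold_z_fst = s$thresholds$z_fst,
             n_flagged = sum(s$windows$flagged),
             n_regions = nrow(s$regions))
      })
    )
    paths$run_log <- emit("run_log.json", \(p) jsonlite::write_json(
      log, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))

    list(gm = gm_f, grouping = grouping, annotation = ann,
         ann_summary = ann_summary, venn = venn, diversity = diversity,
         heterozygosity = het, scans = scans,
         region_summary = reg_summary, ld = ld_curves,
         ld_summary = ld_summary, tree = tree, pca = pca, table1 = table1,
         paths = paths)
  }, error = function(e) {
    unlink(written)
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  invisible(result)
}

#' Format the per-group annotation summary as a publication table
#'
#' Fixed column order regardless of group insertion order: `group`, `n`,
#' `total`, `private`, `theta_pi_e3`, `utr3`, `utr5`, `utr5_utr3`,
#' `intergenic`, `intronic`, `cds_total`, `nonsynonymous`, `stopgain`,
#' `stoploss`, `synonymous`, `unknown`, `nonsyn_syn_ratio`, `total_genes`.
#'
#' @param ann_summary Tibble from [annotation_summary()].
#' @param diversity Optional tibble from [group_theta_pi()] rows; supplies
#'   `theta_pi_e3` (NA where absent).
#' @return The formatted tibble.
#' @export
format_table1 <- function(ann_summary, diversity = NULL) {
  out <- ann_summary
  if (!is.null(diversity)) {
    out <- dplyr::left_join(
      out, dplyr::select(diversity, "group", "theta_pi_e3"), by = "group")
  } else {
    out$theta_pi_e3 <- NA_real_
  }
  dplyr::select(out, "group", "n", "total", "private", "theta_pi_e3",
                "utr3", "utr5", "utr5_utr3", "intergenic", "intronic",
                "cds_total", "nonsynonymous", "stopgain", "stoploss",
                "synonymous", "unknown", "nonsyn_syn_ratio", "total_genes")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
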