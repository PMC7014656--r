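#' Classify variant sites by genomic region
#'
#' Assigns each site the "most genic" class across all overlapping genes with
#' precedence `cds > utr5/utr3 > intronic`; a site inside no gene span is
#' `intergenic`. A site falling in the 5'UTR of one gene and the 3'UTR of a
#' different, overlapping gene is classed `utr5_utr3`.
#'
#' @param sites Tibble with `chrom` and `pos` columns (1-based), sorted or
#'   not; typically `gm$sites`.
#' @param genes Gene-model tibble from [read_gff()].
#' @return Tibble with `region_class` (character) and `gene_ids` (list of
#'   character vectors of overlapping gene ids), one row per input site, in
#'   input order.
#' @export
classify_region <- function(sites, genes) {
  n <- nrow(sites)
  in_cds <- logical(n); in_u5 <- logical(n); in_u3 <- logical(n)
  in_gene <- logical(n)
  gene_hits <- vector("list", n)
  cds_gene <- rep(NA_character_, n)  # first CDS-overlapping gene per site

  if (nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      on_chrom <- which(sites$chrom == genes$chrom[i])
      if (length(on_chrom) == 0) next
      hit <- on_chrom[sites$pos[on_chrom] >= genes$start[i] &
                      sites$pos[on_chrom] <= genes$end[i]]
      if (length(hit) == 0) next
      in_gene[hit] <- TRUE
      for (j in hit) gene_hits[[j]] <- c(gene_hits[[j]], genes$gene_id[i])
      mark <- function(ivl) {
        if (nrow(ivl) == 0) return(integer())
        hit[vapply(sites$pos[hit],
                   function(p) any(p >= ivl$start & p <= ivl$end),
                   logical(1))]
      }
      h_cds <- mark(genes$cds[[i]])
      in_cds[h_cds] <- TRUE
      new_cds <- h_cds[is.na(cds_gene[h_cds])]
      cds_gene[new_cds] <- genes$gene_id[i]
      in_u5[mark(genes$utr5[[i]])] <- TRUE
      in_u3[mark(genes$utr3[[i]])] <- TRUE
    }
  }

  region <- dplyr::case_when(
    in_cds ~ "cds",
    in_u5 & in_u3 ~ "utr5_utr3",
    in_u5 ~ "utr5",
    in_u3 ~ "utr3",
    in_gene ~ "intronic",
    TRUE ~ "intergenic"
  )
  tibble::tibble(region_class = region,
                 gene_ids = purrr::map(gene_hits, ~ .x %||% character()),
                 cds_gene = cds_gene)
}

# CDS nucleotide sequence of a gene in translation order (reverse-complement
# for the minus strand). `ref` is a DNAStringSet; returns a character scalar
# plus the genomic positions in translation order.
cds_sequence <- function(gene, ref) {
  cds <- gene$cds[[1]]
  chrom_seq <- ref[[gene$chrom]]
  pos <- unlist(lapply(seq_len(nrow(cds)),
                       function(i) cds$start[i]:cds$end[i]))
  bases <- strsplit(as.character(chrom_seq), "")[[1]][pos]
  if (gene$strand == "-") {
    pos <- rev(pos)
    bases <- chartr("ACGT", "TGCA", rev(bases))
  }
  list(pos = pos, bases = bases)
}

#' Coding effect of a SNP inside a CDS
#'
#' Rebuilds the affected codon from the gene's CDS coordinates (reverse
#' -complemented on the minus strand), substitutes the alternate allele and
#' translates with the standard genetic code.
#'
#' @param chrom,pos,ref_allele,alt_allele The SNP (1-based position,
#'   single-base alleles on the forward strand).
#' @param gene One-row gene-model tibble (CDS valid).
#' @param ref Reference genome ([Biostrings::DNAStringSet]).
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stopgain"`,
#'   `"stoploss"`.
#' @export
coding_effect <- function(chrom, pos, ref_allele, alt_allele, gene, ref) {
  stopifnot(nrow(gene) == 1)
  if (!isTRUE(gene$cds_valid)) {
    abort(paste0("gene ", gene$gene_id, " has an invalid CDS"))
  }
  cs <- cds_sequence(gene, ref)
  idx <- match(pos, cs$pos)
  if (is.na(idx)) abort(sprintf("site %s:%d is not in the CDS of %s",
                                chrom, pos, gene$gene_id))
  genome_base <- if (gene$strand == "-") chartr("ACGT", "TGCA", ref_allele)
                 else ref_allele
  if (cs$bases[idx] != genome_base) {
    abort(sprintf("reference mismatch at %s:%d (FASTA has %s, VCF says %s)",
                  chrom, pos, cs$bases[idx], genome_base))
  }
  alt_base <- if (gene$strand == "-") chartr("ACGT", "TGCA", alt_allele)
              else alt_allele
  codon_i <- (idx - 1L) %/% 3L
  within <- (idx - 1L) %% 3L + 1L
  codon <- cs$bases[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  codon_alt <- codon
  codon_alt[within] <- alt_base
  aa_ref <- as.character(Biostrings::GENETIC_CODE[paste(codon, collapse = "")])
  aa_alt <- as.character(Biostrings::GENETIC_CODE[paste(codon_alt,
                                                        collapse = "")])
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "stopgain"
  else if (aa_ref == "*") "stoploss"
  else "nonsynonymous"
}

#' Coding effect of an indel
#'
#' @param ref_allele,alt_allele Indel alleles (VCF style, anchored).
#' @param in_cds Does the indel overlap a CDS interval?
#' @return `"frameshift"`, `"nonframeshift"`, or `"none"` outside CDS.
#' @export
indel_effect <- function(ref_allele, alt_allele, in_cds = TRUE) {
  if (!in_cds) return("none")
  d <- abs(nchar(ref_allele) - nchar(alt_allele))
  if (d %% 3L == 0L) "nonframeshift" else "frameshift"
}

#' Annotate every variant with region and coding-effect classes
#'
#' SNPs inside a valid CDS get a codon-level effect; CDS SNPs inside genes
#' with an invalid CDS (length not divisible by 3) or with a FASTA/VCF
#' reference mismatch are classed `unknown` (the residual class of summary
#' tables). CDS indels get frameshift/nonframeshift. Everything else is
#' `none`.
#'
#' @param gm A [genotype_matrix()].
#' @param genes Gene models from [read_gff()].
#' @param ref Reference genome from [read_reference()] (may be `NULL`, in
#'   which case coding effects of CDS SNPs are `unknown`).
#' @return Tibble, one row per site in `gm` order: `chrom`, `pos`, `ref`,
#'   `alt`, `variant_class`, `region_class`, `effect_class`, `gene_ids`.
#' @export
annotate_variants <- function(gm, genes, ref = NULL) {
  reg <- classify_region(gm$sites, genes)
  n <- n_sites(gm)
  effect <- rep("none", n)
  is_snp <- gm$sites$variant_class == "snp"
  is_indel <- gm$sites$variant_class %in% c("indel", "sv")

  cds_snp <- which(reg$region_class == "cds" & is_snp)
  for (i in cds_snp) {
    gid <- reg$cds_gene[i]
    gene <- genes[genes$gene_id == gid, ]
    if (is.null(ref) || !isTRUE(gene$cds_valid[1])) {
      effect[i] <- "unknown"
      next
    }
    effect[i] <- tryCatch(
      coding_effect(gm$sites$chrom[i], gm$sites$pos[i], gm$sites$ref[i],
                    gm$sites$alt[i], gene, ref),
      error = function(e) "unknown"
    )
  }
  cds_indel <- which(reg$region_class == "cds" & is_indel)
  effect[cds_indel] <- vapply(cds_indel, function(i) {
    indel_effect(gm$sites$ref[i], gm$sites$alt[i], in_cds = TRUE)
  }, character(1))

  tibble::tibble(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    ref = gm$sites$ref, alt = gm$sites$alt,
    variant_class = gm$sites$variant_class,
    region_class = reg$region_class,
    effect_class = effect,
    gene_ids = reg$gene_ids
  )
}

#' Per-group site sets (presence of the alternate allele)
#'
#' A site belongs to a group if any member of the group carries at least one
#' non-missing alternate allele.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Grouping tibble from [read_grouping()].
#' @param classes Variant classes to include (default `"snp"`).
#' @return Named list of character site keys (`chrom:pos:ref:alt`) per group.
#' @export
group_site_sets <- function(gm, grouping, classes = "snp") {
  gm <- subset_sites(gm, gm$sites$variant_class %in% classes)
  keys <- site_keys(gm$sites)
  groups <- unique(grouping$group)
  out <- lapply(groups, function(g) {
    rows <- group_samples(grouping, g)
    present <- colSums(gm$dosage[rows, , drop = FALSE] > 0, na.rm = TRUE) > 0
    keys[present]
  })
  setNames(out, groups)
}

site_keys <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Venn partition of per-group site sets
#'
#' Counts every non-empty intersection class over the groups' site sets:
#' for each site, the exact combination of groups containing it.
#'
#' @param site_sets Named list of character vectors (e.g. from
#'   [group_site_sets()]).
#' @return Tibble with `groups` (the `&`-joined combination label),
#'   `n_groups`, and `count`, sorted by descending `n_groups` then label.
#'   Private classes are single-group rows; the shared-by-all class has
#'   `n_groups == length(site_sets)`.
#' @export
venn_partition <- function(site_sets) {
  stopifnot(length(site_sets) >= 1, !is.null(names(site_sets)))
  universe <- unique(unlist(site_sets, use.names = FALSE))
  memb <- vapply(site_sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL,
                                                            names(site_sets)))
  labels <- apply(memb, 1, function(r) paste(names(site_sets)[r],
                                             collapse = "&"))
  tab <- table(labels)
  tibble::tibble(
    groups = names(tab),
    n_groups = stringr::str_count(names(tab), stringr::fixed("&")) + 1L,
    count = as.integer(tab)
  ) |>
    dplyr::arrange(dplyr::desc(.data$n_groups), .data$groups)
}

#' Nonsynonymous/synonymous ratio, presentation-rounded
#'
#' @param nonsyn,syn Counts.
#' @param digits Decimals (default 2, rounded half-up).
#' @return The ratio, or `NA` when `syn` is zero (undefined marker, not an
#'   error).
#' @export
#' @examples
#' nonsyn_syn_ratio(73500, 50018)  # 1.47
nonsyn_syn_ratio <- function(nonsyn, syn, digits = 2) {
  ifelse(syn > 0, round_half_up(nonsyn / syn, digits), NA_real_)
}

#' Percentage of a class count out of a total, presentation-rounded
#'
#' @param count,total Counts.
#' @param digits Decimals (default 2, rounded half-up).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' class_percent(19103583, 25475287)  # 74.99
class_percent <- function(count, total, digits = 2) {
  round_half_up(100 * count / total, digits)
}

#' Per-group annotation summary (publication-table layout)
#'
#' For each group: sample size, total SNPs present, private SNPs, region
#' -class counts, coding-effect counts, the nonsynonymous/synonymous ratio
#' (2 decimals, half-up) and the number of genes touched by CDS SNPs.
#'
#' @param gm A [genotype_matrix()].
#' @param ann Annotation tibble from [annotate_variants()].
#' @param grouping Grouping tibble from [read_grouping()].
#' @return Tibble, one row per group plus a `total` row, with columns
#'   `group`, `n`, `total`, `private`, `utr3`, `utr5`, `utr5_utr3`,
#'   `intergenic`, `intronic`, `cds_total`, `nonsynonymous`, `stopgain`,
#'   `stoploss`, `synonymous`, `unknown`, `nonsyn_syn_ratio`, `total_genes`.
#' @export
annotation_summary <- function(gm, ann, grouping) {
  snp <- gm$sites$variant_class == "snp"
  gm_s <- subset_sites(gm, snp)
  ann_s <- ann[snp, , drop = FALSE]
  groups <- unique(grouping$group)
  sets <- group_site_sets(gm, grouping)
  venn <- venn_partition(sets)

  presence <- vapply(groups, function(g) {
    rows <- group_samples(grouping, g)
    colSums(gm_s$dosage[rows, , drop = FALSE] > 0, na.rm = TRUE) > 0
  }, logical(n_sites(gm_s)))
  if (n_sites(gm_s) == 1) presence <- matrix(presence, nrow = 1,
                                             dimnames = list(NULL, groups))

  one_group <- function(g, present) {
    a <- ann_s[present, , drop = FALSE]
    reg <- table(factor(a$region_class,
                        levels = c("utr3", "utr5", "utr5_utr3", "intergenic",
                                   "intronic", "cds")))
    eff <- table(factor(a$effect_class,
                        levels = c("nonsynonymous", "stopgain", "stoploss",
                                   "synonymous", "unknown")))
    genes_touched <- length(unique(unlist(
      a$gene_ids[a$region_class == "cds"], use.names = FALSE)))
    tibble::tibble(
      group = g, n = NA_integer_, total = sum(present),
      private = NA_integer_,
      utr3 = as.integer(reg["utr3"]), utr5 = as.integer(reg["utr5"]),
      utr5_utr3 = as.integer(reg["utr5_utr3"]),
      intergenic = as.integer(reg["intergenic"]),
      intronic = as.integer(reg["intronic"]),
      cds_total = as.integer(reg["cds"]),
      nonsynonymous = as.integer(eff["nonsynonymous"]),
      stopgain = as.integer(eff["stopgain"]),
      stoploss = as.integer(eff["stoploss"]),
      synonymous = as.integer(eff["synonymous"]),
      unknown = as.integer(eff["unknown"]),
      nonsyn_syn_ratio = nonsyn_syn_ratio(as.integer(eff["nonsynonymous"]),
                                          as.integer(eff["synonymous"])),
      total_genes = genes_touched
    )
  }

  rows <- purrr::map(groups, function(g) {
    r <- one_group(g, presence[, g])
    r$n <- length(group_samples(grouping, g))
    priv <- venn$count[venn$groups == g]
    r$private <- if (length(priv) == 1) priv else 0L
    r
  })
  total_row <- one_group("total", rep(TRUE, n_sites(gm_s)))
  total_row$n <- nrow(grouping)
  total_row$private <- NA_integer_
  dplyr::bind_rows(rows, list(total_row))
}
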