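#' Read gene models from a GFF3 file
#'
#' Builds one gene model per `gene` feature from its mRNA's exon, CDS and UTR
#' children. Introns are derived as gaps between exons. Genes whose total CDS
#' length is not divisible by 3 are flagged (`cds_valid = FALSE`) and excluded
#' from coding-effect calls, but still contribute region classes.
#'
#' All coordinates are 1-based inclusive, as in GFF3.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon/CDS/five_prime_UTR/
#'   three_prime_UTR features.
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `cds_valid`, and list-columns `cds`, `utr5`, `utr3`,
#'   `exons`, `introns` (each a two-column `start`/`end` tibble sorted by
#'   start).
#' @export
read_gff <- function(path) {
  g <- ape::read.gff(path, GFF3 = TRUE)
  attr_field <- function(x, key) {
    has <- grepl(paste0("(^|;)", key, "="), x)
    val <- sub(paste0(".*(^|;)", key, "=([^;]+).*"), "\\2", x)
    ifelse(has, val, NA_character_)
  }
  empty_models <- tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), cds_valid = logical(),
    cds = list(), utr5 = list(), utr3 = list(), exons = list(),
    introns = list())
  if (nrow(g) == 0) return(empty_models)
  g$id <- attr_field(g$attributes, "ID")
  g$parent <- attr_field(g$attributes, "Parent")

  genes <- g[g$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) return(empty_models)
  mrna <- g[g$type == "mRNA", , drop = FALSE]
  # map any feature's Parent (an mRNA id) up to its gene id
  mrna_gene <- setNames(mrna$parent, mrna$id)
  feat <- g[g$type %in% c("exon", "CDS", "five_prime_UTR",
                          "three_prime_UTR"), , drop = FALSE]
  feat$gene_id <- ifelse(feat$parent %in% names(mrna_gene),
                         mrna_gene[feat$parent], feat$parent)

  ivl_tbl <- function(df) {
    if (nrow(df) == 0) {
      return(tibble::tibble(start = integer(), end = integer()))
    }
    tibble::tibble(start = as.integer(df$start), end = as.integer(df$end)) |>
      dplyr::arrange(.data$start)
  }

  models <- purrr::map(seq_len(nrow(genes)), function(i) {
    gid <- genes$id[i]
    f <- feat[feat$gene_id %in% gid, , drop = FALSE]
    cds <- ivl_tbl(f[f$type == "CDS", ])
    utr5 <- ivl_tbl(f[f$type == "five_prime_UTR", ])
    utr3 <- ivl_tbl(f[f$type == "three_prime_UTR", ])
    exons <- ivl_tbl(f[f$type == "exon", ])
    if (nrow(exons) == 0) {
      # no explicit exon features: exons = union of CDS and UTRs
      exons <- merge_intervals(dplyr::bind_rows(cds, utr5, utr3))
    }
    introns <- interval_gaps(exons)
    tibble::tibble(
      gene_id = gid,
      chrom = as.character(genes$seqid[i]),
      strand = as.character(genes$strand[i]),
      start = as.integer(genes$start[i]),
      end = as.integer(genes$end[i]),
      cds_valid = nrow(cds) > 0 && sum(cds$end - cds$start + 1L) %% 3L == 0L,
      cds = list(cds), utr5 = list(utr5), utr3 = list(utr3),
      exons = list(exons), introns = list(introns)
    )
  })
  dplyr::bind_rows(models) |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Merge overlapping/adjacent 1-based inclusive intervals.
merge_intervals <- function(ivl) {
  if (nrow(ivl) == 0) return(tibble::tibble(start = integer(), end = integer()))
  ivl <- dplyr::arrange(ivl, .data$start)
  out_s <- ivl$start[1]
  out_e <- ivl$end[1]
  k <- 1L
  if (nrow(ivl) > 1) {
    for (i in 2:nrow(ivl)) {
      if (ivl$start[i] <= out_e[k] + 1L) {
        out_e[k] <- max(out_e[k], ivl$end[i])
      } else {
        k <- k + 1L
        out_s[k] <- ivl$start[i]
        out_e[k] <- ivl$end[i]
      }
    }
  }
  tibble::tibble(start = out_s, end = out_e)
}

# Gaps between sorted disjoint intervals (introns from exons).
interval_gaps <- function(ivl) {
  if (nrow(ivl) < 2) return(tibble::tibble(start = integer(), end = integer()))
  ivl <- dplyr::arrange(ivl, .data$start)
  s <- ivl$end[-nrow(ivl)] + 1L
  e <- ivl$start[-1] - 1L
  keep <- s <= e
  tibble::tibble(start = s[keep], end = e[keep])
}

# point-in-intervals test (1-based inclusive)
pos_in_intervals <- function(pos, ivl) {
  if (nrow(ivl) == 0) return(FALSE)
  any(pos >= ivl$start & pos <= ivl$end)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff()] for simulator-emitted gene models; writing then
#' reading reproduces the models.
#'
#' @param genes Gene-model tibble as returned by [read_gff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    mid <- paste0(gid, ".t1")
    row9 <- function(type, s, e, attrs) {
      paste(genes$chrom[i], "lotuscan", type, s, e, ".", genes$strand[i],
            ".", attrs, sep = "\t")
    }
    lines <- c(lines,
      row9("gene", genes$start[i], genes$end[i], paste0("ID=", gid)),
      row9("mRNA", genes$start[i], genes$end[i],
           paste0("ID=", mid, ";Parent=", gid)))
    emit <- function(type, ivl) {
      if (nrow(ivl) == 0) return(character())
      vapply(seq_len(nrow(ivl)), function(j) {
        row9(type, ivl$start[j], ivl$end[j], paste0("Parent=", mid))
      }, character(1))
    }
    lines <- c(lines,
      emit("exon", genes$exons[[i]]),
      emit("five_prime_UTR", genes$utr5[[i]]),
      emit("CDS", genes$cds[[i]]),
      emit("three_prime_UTR", genes$utr3[[i]]))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a reference genome FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first token of each
#'   header line.
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
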