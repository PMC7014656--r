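test_that("region classification follows genic precedence", {
  gA <- toy_gene("gA", strand = "+", utr5 = cbind(101, 150),
                 cds = rbind(c(151, 250), c(351, 449)),
                 utr3 = cbind(450, 500))
  genes <- gA
  sites <- tibble::tibble(chrom = "chr1",
                          pos = c(200L, 300L, 120L, 470L, 50L, 600L))
  cls <- classify_region(sites, genes)
  expect_equal(cls$region_class,
               c("cds", "intronic", "utr5", "utr3", "intergenic",
                 "intergenic"))
  expect_equal(cls$gene_ids[[1]], "gA")
  expect_equal(cls$gene_ids[[5]], character())
})

test_that("a site in the 5'UTR of one gene and 3'UTR of another is utr5_utr3", {
  gA <- toy_gene("gA", strand = "+", utr5 = cbind(100, 220),
                 cds = cbind(221, 320))
  gB <- toy_gene("gB", strand = "+", cds = cbind(1, 99),
                 utr3 = cbind(100, 210))
  cls <- classify_region(tibble::tibble(chrom = "chr1", pos = 150L),
                         dplyr::bind_rows(gA, gB))
  expect_equal(cls$region_class, "utr5_utr3")
  expect_setequal(cls$gene_ids[[1]], c("gA", "gB"))
})

test_that("coding effects match the genetic code on simple codons", {
  # gene on +: CDS 11..19 codes GAA GAA TGG
  seq1 <- paste0(strrep("T", 10), "GAAGAATGG", strrep("T", 10))
  ref <- toy_ref(chr1 = seq1)
  gene <- toy_gene("g", strand = "+", cds = cbind(11, 19))
  # third-position A->G: GAA->GAG, Glu->Glu
  expect_equal(coding_effect("chr1", 13, "A", "G", gene, ref), "synonymous")
  # GAA->TAA: stopgain
  expect_equal(coding_effect("chr1", 14, "G", "T", gene, ref), "stopgain")
  # first-position G->C: GAA->CAA, Glu->Gln
  expect_equal(coding_effect("chr1", 11, "G", "C", gene, ref),
               "nonsynonymous")
  # reference mismatch is a data-integrity error naming the site
  expect_error(coding_effect("chr1", 13, "C", "G", gene, ref),
               "reference mismatch")
})

test_that("coding_effect agrees with full-CDS retranslation on random genes", {
  # randomized toy genome: 20 genes on both strands, SNPs at every CDS pos
  set.seed(101)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  chrom_len <- 20 * 400
  bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  genes <- list()
  for (i in 1:20) {
    s <- (i - 1) * 400 + 50
    # two CDS exons of 30 and 45 bp separated by a 20 bp intron
    cds <- rbind(c(s, s + 29), c(s + 50, s + 94))
    strand <- if (i %% 2 == 0) "+" else "-"
    g <- toy_gene(paste0("g", i), strand = strand, cds = cds)
    pos <- c(s:(s + 29), (s + 50):(s + 94))
    n_codons <- length(pos) / 3
    coding <- strsplit(paste(sample(sense, n_codons, TRUE), collapse = ""),
                       "")[[1]]
    if (strand == "-") coding <- chartr("ACGT", "TGCA", rev(coding))
    bases[pos] <- coding
    genes[[i]] <- g
  }
  genes <- dplyr::bind_rows(genes)
  ref <- toy_ref(chr1 = paste(bases, collapse = ""))

  # independent oracle: rebuild and translate the entire CDS with and
  # without the variant and compare protein strings
  oracle <- function(pos, alt, gene) {
    cds <- gene$cds[[1]]
    cds_pos <- unlist(lapply(seq_len(nrow(cds)),
                             function(k) cds$start[k]:cds$end[k]))
    translate_with <- function(b) {
      bb <- bases
      bb[pos] <- b
      s <- paste(bb[cds_pos], collapse = "")
      dna <- Biostrings::DNAString(s)
      if (gene$strand == "-") dna <- Biostrings::reverseComplement(dna)
      as.character(Biostrings::translate(dna, no.init.codon = TRUE))
    }
    p_ref <- translate_with(bases[pos])
    p_alt <- translate_with(alt)
    if (p_ref == p_alt) return("synonymous")
    i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
    aa_ref <- substr(p_ref, i, i); aa_alt <- substr(p_alt, i, i)
    if (aa_alt == "*") "stopgain" else if (aa_ref == "*") "stoploss"
    else "nonsynonymous"
  }

  set.seed(202)
  n_checked <- 0
  for (g_i in seq_len(nrow(genes))) {
    gene <- genes[g_i, ]
    cds <- gene$cds[[1]]
    cds_pos <- unlist(lapply(seq_len(nrow(cds)),
                             function(k) cds$start[k]:cds$end[k]))
    test_pos <- sample(cds_pos, 50)
    for (pos in test_pos) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), bases[pos]), 1)
      got <- coding_effect("chr1", pos, bases[pos], alt, gene, ref)
      expect_equal(got, oracle(pos, alt, gene),
                   label = sprintf("gene %s pos %d %s>%s", gene$gene_id,
                                   pos, bases[pos], alt))
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 1000)
})

test_that("indel effects depend on length mod 3 and CDS overlap", {
  expect_equal(indel_effect("ATT", "A", in_cds = TRUE), "frameshift")
  expect_equal(indel_effect("A", "ATTT", in_cds = TRUE), "nonframeshift")
  expect_equal(indel_effect("A", "AT", in_cds = FALSE), "none")
})

test_that("annotate_variants routes CDS indels and invalid genes correctly", {
  seq1 <- paste0(strrep("A", 10), "GAAGAATGG", strrep("A", 20))
  ref <- toy_ref(chr1 = seq1)
  good <- toy_gene("good", strand = "+", cds = cbind(11, 19))
  bad <- toy_gene("bad", strand = "+", cds = cbind(25, 32))  # 8 bp CDS
  genes <- dplyr::bind_rows(good, bad)
  d <- matrix(1L, nrow = 2, ncol = 3,
              dimnames = list(c("x", "y"), NULL))
  sites <- tibble::tibble(
    chrom = "chr1", pos = c(13L, 14L, 26L),
    ref = c("A", "GA", "A"), alt = c("G", "G", "C"))
  gm <- genotype_matrix(sites, d)
  ann <- annotate_variants(gm, genes, ref)
  expect_equal(ann$effect_class[ann$pos == 13], "synonymous")
  expect_equal(ann$effect_class[ann$pos == 14], "frameshift")
  expect_equal(ann$effect_class[ann$pos == 26], "unknown")
})

test_that("venn partition equals brute-force enumeration", {
  # simple three-set example
  v <- venn_partition(list(A = c("s1", "s2", "s3"), B = c("s2", "s3", "s4")))
  expect_equal(v$count[v$groups == "A"], 1L)
  expect_equal(v$count[v$groups == "B"], 1L)
  expect_equal(v$count[v$groups == "A&B"], 2L)

  # disjoint groups share nothing
  v2 <- venn_partition(list(A = "k1", B = "k2"))
  expect_false("A&B" %in% v2$groups)

  # 5 random sets vs exhaustive enumeration over all 31 classes
  set.seed(33)
  keys <- sprintf("k%04d", 1:1500)
  sets <- lapply(1:5, function(i) sample(keys, 1000))
  names(sets) <- LETTERS[1:5]
  got <- venn_partition(sets)
  universe <- unique(unlist(sets))
  brute <- integer()
  for (k in universe) {
    memb <- names(sets)[vapply(sets, function(s) k %in% s, logical(1))]
    lab <- paste(memb, collapse = "&")
    brute[lab] <- (if (lab %in% names(brute)) brute[[lab]] else 0L) + 1L
  }
  expect_equal(nrow(got), length(brute))
  for (lab in names(brute)) {
    expect_equal(got$count[got$groups == lab], unname(brute[lab]),
                 label = lab)
  }
  # counts sum to the union size
  expect_equal(sum(got$count), length(universe))
})

test_that("annotation summary conserves counts and handles single sites", {
  co <- shared_cohort()
  gm <- co$gm
  ann <- annotate_variants(gm, co$genes, co$ref)
  summ <- annotation_summary(gm, ann, co$grouping)
  region_cols <- c("utr3", "utr5", "utr5_utr3", "intergenic", "intronic",
                   "cds_total")
  for (i in seq_len(nrow(summ))) {
    expect_equal(sum(unlist(summ[i, region_cols])), summ$total[i],
                 label = paste("row", summ$group[i]))
  }
  # single annotated site: its class 1, all others 0
  one <- toy_gm(matrix(c(1L, 1L), nrow = 2))
  ann1 <- annotate_variants(one, toy_gene("g", cds = cbind(500, 502)), NULL)
  s1 <- annotation_summary(one, ann1,
                           tibble::tibble(sample = c("s1", "s2"),
                                          group = "only"))
  expect_equal(s1$total[1], 1)
  expect_equal(s1$intergenic[1], 1)
  expect_equal(sum(unlist(s1[1, setdiff(region_cols, "intergenic")])), 0)
})

test_that("ratio and percentage helpers round half-up to 2 decimals", {
  expect_equal(nonsyn_syn_ratio(3, 2), 1.5)
  expect_true(is.na(nonsyn_syn_ratio(5, 0)))
  expect_equal(round_half_up(2.345, 2), 2.35)  # would be 2.34 under banker's
  expect_equal(class_percent(1, 3), 33.33)
})
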