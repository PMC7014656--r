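#' Pairwise allele-sharing distance between samples
#'
#' `d(i, j)` is the mean over sites non-missing in both samples of
#' `|dosage_i - dosage_j| / 2` (half-Manhattan on dosages): 0 for identical
#' genotypes everywhere, 1 for opposite homozygotes everywhere.
#'
#' @param gm A [genotype_matrix()] (SNP sites are used).
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
genetic_distance <- function(gm) {
  gm_s <- snp_only(gm)
  d <- gm_s$dosage
  n <- nrow(d)
  if (n < 2) abort("need at least 2 samples")
  # |a-b| over dosages in {0,1,2}: (a-b)^2 minus 2 per opposite-homozygote
  # pair; all terms reduce to cross-products, with missing entries masked.
  M <- (!is.na(d)) * 1
  D0 <- d
  D0[is.na(D0)] <- 0L
  storage.mode(D0) <- "double"
  shared <- tcrossprod(M)
  sq <- tcrossprod(D0^2, M)
  cross <- tcrossprod(D0)
  opp <- tcrossprod((D0 == 0) * M, (D0 == 2) * M)
  abs_sum <- sq + t(sq) - 2 * cross - 2 * (opp + t(opp))
  off <- shared == 0 & row(shared) != col(shared)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    abort(sprintf("samples %s and %s share no non-missing sites",
                  rownames(d)[bad[1]], rownames(d)[bad[2]]))
  }
  D <- abs_sum / pmax(shared, 1) / 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(d), rownames(d))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero. Exact on additive distances.
#'
#' @param D Symmetric non-negative distance matrix (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) abort("need at least 3 taxa")
  if (any(D < 0) || any(abs(D - t(D)) > 1e-12)) {
    abort("distance matrix must be symmetric and non-negative")
  }
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Bootstrap support for the NJ tree of a genotype matrix
#'
#' Builds the full-data NJ tree, then resamples sites (columns) with
#' replacement `n_replicates` times, rebuilding distance and tree each time;
#' the support of each internal bipartition of the full tree is the fraction
#' of replicates containing it, stored in `node.label` (in `[0, 1]`).
#' Deterministic for a fixed seed.
#'
#' @param gm A [genotype_matrix()].
#' @param n_replicates Number of bootstrap replicates (conventionally 1000).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with bootstrap supports as node labels.
#' @export
bootstrap_support <- function(gm, n_replicates = 100, seed = 1) {
  stopifnot(n_replicates >= 1)
  gm_s <- snp_only(gm)
  full <- nj_tree(genetic_distance(gm_s))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "bootstrap"))
  m <- n_sites(gm_s)
  boots <- purrr::map(seq_len(n_replicates), function(b) {
    idx <- sample.int(m, m, replace = TRUE)
    g <- gm_s
    g$sites <- g$sites[idx, , drop = FALSE]
    g$dosage <- g$dosage[, idx, drop = FALSE]
    nj_tree(genetic_distance(g))
  })
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- counts / n_replicates
  full
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept and any node labels (e.g. bootstrap supports) are
#' written as internal-node labels. Tip labels containing Newick
#' metacharacters (parentheses, commas, colons, semicolons, brackets or
#' whitespace) are single-quoted.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  labs <- tree$tip.label
  needs_quote <- grepl("[][():;,'[:space:]]", labs)
  placeholder <- sprintf("lotuscanTIP%dPLH", seq_along(labs))
  tree$tip.label <- ifelse(needs_quote, placeholder, labs)
  txt <- ape::write.tree(tree)
  for (i in which(needs_quote)) {
    quoted <- paste0("'", gsub("'", "''", labs[i]), "'")
    txt <- sub(placeholder[i], quoted, txt, fixed = TRUE)
  }
  if (!is.null(path)) {
    readr::write_lines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Principal component analysis of a genotype matrix
#'
#' Patterson-normalized PCA: each SNP column is centered by twice its
#' estimated allele frequency and scaled by `sqrt(2 p (1 - p))`; missing
#' genotypes are mean-imputed (zero after centering); monomorphic sites are
#' dropped. Eigendecomposition of the sample-covariance (GRM) gives sample
#' coordinates scaled by the square root of the eigenvalues, with a
#' deterministic sign convention (the largest-magnitude coordinate of each
#' component is positive).
#'
#' @param gm A [genotype_matrix()] with >= 2 samples and >= 2 polymorphic
#'   SNPs.
#' @param n_components Number of components to return (default 10,
#'   truncated to the matrix rank with a warning).
#' @return Object of class `genotype_pca`: list with `scores` (tibble:
#'   `sample`, `PC1`, ...), `explained` (variance fractions, non-increasing,
#'   summing to <= 1), `n_sites_used`.
#' @export
pca_genotypes <- function(gm, n_components = 10) {
  gm_s <- snp_only(gm)
  d <- gm_s$dosage
  if (nrow(d) < 2) abort("need at least 2 samples")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) abort("need at least 2 polymorphic sites")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(d, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  grm <- tcrossprod(X) / ncol(X)
  eig <- eigen(grm, symmetric = TRUE)
  pos <- eig$values > 1e-12
  rank <- sum(pos)
  if (n_components > rank) {
    warn(sprintf("n_components truncated from %d to rank %d",
                 n_components, rank))
    n_components <- rank
  }
  vals <- eig$values[seq_len(n_components)]
  vecs <- eig$vectors[, seq_len(n_components), drop = FALSE]
  scores <- sweep(vecs, 2, sqrt(vals), "*")
  for (k in seq_len(ncol(scores))) {
    if (scores[which.max(abs(scores[, k])), k] < 0) {
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(
    list(
      scores = dplyr::bind_cols(tibble::tibble(sample = rownames(d)),
                                tibble::as_tibble(scores)),
      explained = vals / sum(eig$values[pos]),
      n_sites_used = ncol(X)
    ),
    class = "genotype_pca"
  )
}

#' @exportS3Method base::print
print.genotype_pca <- function(x, ...) {
  cat(sprintf("<genotype_pca> %d samples, %d sites, %d components\n",
              nrow(x$scores), x$n_sites_used, length(x$explained)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * head(x$explained, 5)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy PCA scores
#'
#' @param x A [pca_genotypes()] object.
#' @param ... Unused.
#' @return The scores tibble.
#' @export
tidy.genotype_pca <- function(x, ...) x$scores

#' One-row PCA summary
#'
#' @param x A [pca_genotypes()] object.
#' @param ... Unused.
#' @return One-row tibble with sample/site counts and the variance
#'   fractions of the first two components.
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_sites_used = x$n_sites_used,
    pc1_var = x$explained[1],
    pc2_var = if (length(x$explained) >= 2) x$explained[2] else NA_real_
  )
}
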