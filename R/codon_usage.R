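## Codon usage tables, subgenome usage ratios, and correlation-matrix PCA.
##
## Observations entering the PCA are per-mil codon frequencies (counts x
## 1000 / total codons) of a unit -- a chromosome copy, a chromosome
## segment, or a subgenome -- standardised column-wise; components come from
## the eigen-decomposition of the correlation matrix and factor loadings are
## eigenvector x sqrt(eigenvalue).  Stop codons stay among the 64 variables.

#' Codon counts of CDS sequences
#'
#' Counts complete in-frame codons (frame starts at position 1); codons
#' containing N are dropped with a warning, a trailing incomplete codon is
#' ignored.
#'
#' @param cds Named character vector of CDS sequences (length >= 3 each).
#' @return Integer matrix, one row per sequence, 64 codon columns in
#'   lexicographic order.
#' @export
codon_counts <- function(cds) {
  if (any(nchar(cds) < 3L)) stop("CDS shorter than one codon")
  x <- Biostrings::DNAStringSet(cds)
  m <- Biostrings::trinucleotideFrequency(x, step = 3L)
  n_complete <- nchar(cds) %/% 3L
  if (any(rowSums(m) < n_complete))
    warning("codons containing N dropped in ",
            sum(rowSums(m) < n_complete), " sequence(s)")
  rownames(m) <- names(cds)
  m
}

#' Per-mil codon frequencies
#'
#' @param counts Codon count vector or matrix (rows = units).
#' @return Same shape, each row scaled to sum to 1000.
#' @export
per_mil <- function(counts) {
  if (is.matrix(counts)) counts * 1000 / rowSums(counts)
  else counts * 1000 / sum(counts)
}

#' Aggregate codon counts over units
#'
#' Sums the per-gene counts of the members of each unit (chromosome copy,
#' segment, subgenome); a subgenome aggregate is therefore exactly the sum
#' of its chromosome aggregates.
#'
#' @param counts Gene-level codon count matrix ([codon_counts()]).
#' @param groups Named character/factor vector: `groups[gene_id]` = unit id,
#'   or a data.frame with columns `gene_id` and `unit`.
#' @return Codon count matrix with one row per unit.
#' @export
aggregate_usage <- function(counts, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$unit), groups$gene_id)
  miss <- setdiff(names(groups), rownames(counts))
  if (length(miss))
    stop("unknown gene id(s) in group map: ", miss[1])
  m <- counts[names(groups), , drop = FALSE]
  rowsum(m, group = as.character(groups), reorder = TRUE)
}

#' Per-codon usage ratio between two subgenomes
#'
#' Ratio of per-mil frequencies (Fso_h / Fso_l). Codons absent from both
#' tables get `NA` (flag `undefined`); zero denominator with nonzero
#' numerator gives `Inf` (flag `infinite`).
#'
#' @param table_h,table_l Codon count or per-mil vectors for the two
#'   subgenomes.
#' @return data.frame: codon, per_mil_h, per_mil_l, ratio, flag.
#' @export
usage_ratio <- function(table_h, table_l) {
  ph <- per_mil(table_h); pl <- per_mil(table_l)
  ratio <- ph / pl
  flag <- rep("ok", length(ratio))
  flag[ph == 0 & pl == 0] <- "undefined"
  ratio[ph == 0 & pl == 0] <- NA_real_
  flag[pl == 0 & ph > 0] <- "infinite"
  codon <- names(ph)
  if (is.null(codon)) codon <- codon_tables()$codons[seq_along(ph)]
  data.frame(codon = codon, per_mil_h = as.numeric(ph),
             per_mil_l = as.numeric(pl), ratio = as.numeric(ratio),
             flag = flag, stringsAsFactors = FALSE, row.names = NULL)
}

#' PCA on the correlation matrix of codon usage
#'
#' Columns (codons) are standardised to mean 0 / variance 1 after dropping
#' zero-variance columns; components come from the eigen-decomposition of
#' the correlation matrix. Loadings are eigenvector x sqrt(eigenvalue), so
#' their squared column sums equal the eigenvalues, and the eigenvalues sum
#' to the number of retained variables. Component signs are fixed for
#' reproducibility: PC1 is oriented so its mean loading is negative; PC2 so
#' that the mean score of Fso_h-labelled observations is at least that of
#' the rest (when `h_units` is given); remaining components so their
#' largest-magnitude loading is positive.
#'
#' @param mat Numeric matrix, units x codons (per-mil frequencies).
#' @param h_units Optional character vector of row names belonging to the
#'   Fso_h subgenome, used for the PC2 sign convention.
#' @return List of class `"allophase_pca"`: `scores`, `eigenvalues`,
#'   `loadings`, `explained`, `dropped` (zero-variance codons).
#' @export
pca_correlation <- function(mat, h_units = NULL) {
  if (nrow(mat) < 3L) stop("PCA needs at least 3 observations")
  sds <- apply(mat, 2L, stats::sd)
  dropped <- colnames(mat)[sds == 0]
  if (length(dropped))
    message("dropping ", length(dropped), " zero-variance codon column(s)")
  mat <- mat[, sds > 0, drop = FALSE]
  z <- scale(mat)
  e <- eigen(stats::cor(mat), symmetric = TRUE)
  val <- pmax(e$values, 0)
  vec <- e$vectors
  scores <- z %*% vec
  for (k in seq_len(ncol(vec))) {
    flip <- if (k == 1L) mean(vec[, 1L]) > 0
    else if (k == 2L && !is.null(h_units)) {
      h <- rownames(mat) %in% h_units
      mean(scores[h, 2L]) < mean(scores[!h, 2L])
    } else vec[which.max(abs(vec[, k])), k] < 0
    if (isTRUE(flip)) { vec[, k] <- -vec[, k]; scores[, k] <- -scores[, k] }
  }
  loadings <- sweep(vec, 2L, sqrt(val), `*`)
  dimnames(loadings) <- list(colnames(mat), paste0("PC", seq_along(val)))
  dimnames(scores) <- list(rownames(mat), paste0("PC", seq_along(val)))
  structure(list(scores = scores, eigenvalues = val, loadings = loadings,
                 eigenvectors = vec,
                 explained = val / sum(val), dropped = dropped),
            class = "allophase_pca")
}

#' Check subgenome separation along PC2
#'
#' Fraction of chromosome pairs whose Fso_h member scores higher on PC2
#' than its Fso_l partner, with per-pair deltas.
#'
#' @param pca [pca_correlation()] result whose observations are chromosome
#'   copies.
#' @param pairs_units data.frame with columns `unit_h` and `unit_l` (one
#'   row per chromosome pair).
#' @return List: `fraction`, `deltas` (data.frame with delta and tie/violn
#'   flags).
#' @export
separation_check <- function(pca, pairs_units) {
  sc <- pca$scores
  miss <- setdiff(c(pairs_units$unit_h, pairs_units$unit_l), rownames(sc))
  if (length(miss)) stop("observation missing for unit: ", miss[1])
  delta <- sc[pairs_units$unit_h, "PC2"] - sc[pairs_units$unit_l, "PC2"]
  data_out <- data.frame(unit_h = pairs_units$unit_h,
                         unit_l = pairs_units$unit_l,
                         delta = as.numeric(delta),
                         tie = delta == 0,
                         separated = delta > 0,
                         stringsAsFactors = FALSE)
  list(fraction = mean(delta > 0), deltas = data_out)
}

#' Codon usage matrix per chromosome copy
#'
#' Convenience builder for the chromosome-level PCA: aggregates per-gene
#' codon counts to each physical chromosome, using homoeologous (paired)
#' genes only by default.
#'
#' @param cds Named character vector of CDS.
#' @param pairs Pair table.
#' @param genes Gene record table.
#' @param include_singletons Also count non-homoeologous genes.
#' @return Per-mil matrix, one row per chromosome.
#' @export
chromosome_usage <- function(cds, pairs, genes, include_singletons = FALSE) {
  use <- genes
  if (!include_singletons) {
    paired <- c(pairs$gene_x, pairs$gene_x_prime)
    use <- genes[genes$gene_id %in% paired, , drop = FALSE]
  }
  counts <- codon_counts(cds[use$gene_id])
  per_mil(aggregate_usage(counts, stats::setNames(use$chrom, use$gene_id)))
}

#' PCA on chromosome segments
#'
#' Aggregates gene-level codon counts into user-defined segments (for
#' example the regions upstream/downstream of a dGC flip on each copy) and
#' runs the correlation-matrix PCA on the segment units. Segments with
#' fewer than `min_genes` genes are skipped with a warning.
#'
#' @param counts Gene-level codon count matrix.
#' @param segment_map data.frame with columns `gene_id` and `unit`.
#' @param min_genes Minimum genes per segment (default 5).
#' @param h_units Optional Fso_h unit ids for the PC2 sign convention.
#' @return [pca_correlation()] result on the retained segments.
#' @export
segment_pca <- function(counts, segment_map, min_genes = 5L, h_units = NULL) {
  sizes <- table(segment_map$unit)
  small <- names(sizes)[sizes < min_genes]
  if (length(small)) {
    warning("segment(s) with fewer than ", min_genes, " genes skipped: ",
            paste(small, collapse = ", "))
    segment_map <- segment_map[!segment_map$unit %in% small, , drop = FALSE]
  }
  agg <- aggregate_usage(counts, segment_map)
  pca_correlation(per_mil(agg), h_units = h_units)
}
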