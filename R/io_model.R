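## Shared domain containers, file readers and run configuration.
##
## Conventions used throughout the package:
##  * gene tables are plain data.frames with columns
##    gene_id, chrom, start, end, strand, order_index (1-based inclusive
##    coordinates, GFF3 dialect); CDS sequences travel separately as a named
##    character vector over {A,C,G,T,N}.
##  * a homoeologous pair table has columns pair_id, chrom_pair, gene_x,
##    gene_x_prime where gene_x lies on the member of the chromosome pair
##    with the higher global GC content (chromosome X).

#' Run configuration for the phasing / bias pipeline
#'
#' Bundles every tunable threshold in one validated list so that analysis
#' drivers, tests and output headers agree on the parameters in force.
#'
#' @param window Odd integer, width (in genes) of the simple moving average
#'   applied to dGC/dGC3 series before polarity calls. Default 11 genes.
#' @param expressed_threshold RPKM above which a gene counts as expressed.
#'   Default 1.
#' @param fold_threshold Fold change (inclusive) at which a homoeologous pair
#'   is called biased. Default 2.
#' @param min_flip_run Minimum number of consecutive genes of reversed dGC
#'   polarity for a flip-over (crossover) segment call. Default 20.
#' @param min_flip_effect Minimum mean |smoothed ratio - 1| inside a candidate
#'   flip segment. Default 0.01.
#' @param promoter_length Promoter length in bp upstream of the TSS.
#'   Default 500.
#' @param rpkm_strata RPKM cutoffs for stratified bias reports.
#' @param fdr_level Benjamini-Hochberg FDR level used when flagging
#'   significant terms/motifs. Default 0.05.
#' @param seed Optional integer seed recorded with the configuration.
#' @return A list of class `"allophase_config"`.
#' @export
run_config <- function(window = 11L, expressed_threshold = 1,
                       fold_threshold = 2, min_flip_run = 20L,
                       min_flip_effect = 0.01, promoter_length = 500L,
                       rpkm_strata = c(50, 100, 500), fdr_level = 0.05,
                       seed = NULL) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 1, got ", window)
  for (nm in c("expressed_threshold", "fold_threshold", "min_flip_effect",
               "promoter_length", "fdr_level")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive number")
  }
  if (as.integer(min_flip_run) < 1L) stop("`min_flip_run` must be >= 1")
  structure(list(window = window,
                 expressed_threshold = expressed_threshold,
                 fold_threshold = fold_threshold,
                 min_flip_run = as.integer(min_flip_run),
                 min_flip_effect = min_flip_effect,
                 promoter_length = as.integer(promoter_length),
                 rpkm_strata = as.numeric(rpkm_strata),
                 fdr_level = fdr_level,
                 seed = seed),
            class = "allophase_config")
}

#' Read a CDS FASTA into a named sequence vector
#'
#' Sequences are uppercased and U is converted to T; only A/C/G/T/N are
#' accepted after normalisation.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of CDS sequences (names are gene ids).
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA record id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- chartr("U", "T", toupper(as.character(set)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad][seq_len(min(3L, sum(bad)))], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Read a homoeologous gene-pair table
#'
#' Expects a TSV with header columns `pair_id`, `chrom_pair`, `gene_x`,
#' `gene_x_prime` where `gene_x` is the copy on chromosome X (the member of
#' the homoeologous chromosome pair with higher global GC). Row order is
#' preserved; pairs are grouped by `chrom_pair`.
#'
#' @param path Path to a TSV file.
#' @return A list with `pairs` (the validated table) and `pairings`
#'   (one row per chromosome pair, in order of first appearance).
#' @export
read_pair_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("pair_id", "chrom_pair", "gene_x", "gene_x_prime")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pair table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("pair table has no data rows: ", path)
    return(list(pairs = tab[, need], pairings = character(0)))
  }
  genes <- c(tab$gene_x, tab$gene_x_prime)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("gene(s) referenced in more than one pair: ",
         paste(dup[seq_len(min(3L, length(dup)))], collapse = ", "))
  if (anyDuplicated(tab$pair_id))
    stop("duplicate pair_id(s) in pair table")
  list(pairs = tab[, need], pairings = unique(tab$chrom_pair))
}

#' Read a chromosome pairing table
#'
#' TSV with columns `pair_name`, `chrom_x`, `chrom_x_prime`, `global_gc_x`,
#' `global_gc_x_prime`; by convention `chrom_x` is the member with the
#' higher global GC content.
#'
#' @param path Path to a TSV file.
#' @return Validated data.frame.
#' @export
read_chromosome_pairings <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("pair_name", "chrom_x", "chrom_x_prime",
            "global_gc_x", "global_gc_x_prime")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pairing table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$chrom_x == tab$chrom_x_prime))
    stop("a chromosome cannot be paired with itself")
  if (any(tab$global_gc_x < tab$global_gc_x_prime))
    stop("naming convention violated: global_gc_x must be >= global_gc_x_prime")
  tab[, need]
}

#' Read a per-gene RPKM expression table
#'
#' TSV whose first column is the gene id and whose remaining columns are
#' ordered time points. Values must be numeric and non-negative; missing
#' cells are rejected.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (genes x timepoints) with gene ids as rownames.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a gene column plus >= 1 timepoint")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene row(s): ",
         paste(unique(ids[duplicated(ids)])[1:1], collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v))
      stop("non-numeric or missing RPKM in column '", names(vals)[j], "'")
    if (any(v < 0))
      stop("negative RPKM in column '", names(vals)[j], "'")
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Read gene coordinates from a TSV or GFF3 file
#'
#' The TSV dialect has columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' and optionally `order_index`. Files ending in `.gff`/`.gff3` are parsed as
#' GFF3 gene features (the `ID` attribute becomes the gene id).
#'
#' @param path Path to the annotation file.
#' @return data.frame with gene_id, chrom, start, end, strand, order_index.
#' @export
read_gene_table <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(f, function(x) length(x) == 9L && x[3] == "gene", logical(1))
    f <- f[keep]
    if (!length(f)) stop("no gene features in GFF3 file: ", path)
    ids <- vapply(f, function(x) {
      m <- regmatches(x[9], regexpr("ID=[^;]+", x[9]))
      if (!length(m)) stop("GFF3 gene feature without ID attribute")
      sub("^ID=", "", m)
    }, character(1))
    tab <- data.frame(gene_id = ids,
                      chrom = vapply(f, `[[`, character(1), 1L),
                      start = as.integer(vapply(f, `[[`, character(1), 4L)),
                      end = as.integer(vapply(f, `[[`, character(1), 5L)),
                      strand = vapply(f, `[[`, character(1), 7L),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             comment.char = "#")
    need <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  }
  gene_records(tab)
}

#' Validate and order a gene record table
#'
#' Enforces the gene-record invariants (unique ids, start <= end, strand in
#' +/-) and fills `order_index` (rank along the chromosome from its 5'
#' terminus). When `order_index` is absent it is derived by sorting on
#' `start`, ties broken by lexicographic gene id.
#'
#' @param tab data.frame with at least gene_id, chrom, start, end, strand.
#' @return The validated table with a complete `order_index` column.
#' @export
gene_records <- function(tab) {
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id(s) in gene table")
  if (any(tab$start > tab$end)) stop("gene with start > end")
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(tab$order_index)) {
    tab$order_index <- NA_integer_
    for (ch in unique(tab$chrom)) {
      i <- which(tab$chrom == ch)
      tab$order_index[i][order(tab$start[i], tab$gene_id[i])] <- seq_along(i)
    }
  } else {
    for (ch in unique(tab$chrom)) {
      oi <- tab$order_index[tab$chrom == ch]
      if (anyDuplicated(oi))
        stop("order_index not unique within chromosome ", ch)
    }
  }
  tab
}

#' Write a result table as TSV with a provenance header
#'
#' Prepends a single `#` comment line carrying the package version and an
#' md5 hash of the run configuration, then writes plain TSV. Reading the
#' file back with any of the package readers (which skip `#` lines)
#' round-trips the values.
#'
#' @param tab data.frame to write.
#' @param path Output path.
#' @param config Optional `run_config()` object hashed into the header.
#' @return Invisibly, `path`.
#' @export
write_result_tsv <- function(tab, path, config = NULL) {
  ver <- as.character(utils::packageVersion("allophase"))
  hash <- if (is.null(config)) "none" else config_hash(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# allophase %s\tconfig=%s", ver, hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f, version = 2L)
  unname(tools::md5sum(f))
}
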