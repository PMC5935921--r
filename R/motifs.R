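## Promoter extraction, IUPAC motif scanning and motif statistics.
##
## Promoters are the `length` bp immediately upstream of the TSS on the
## gene's strand; motifs are degenerate IUPAC strings (e.g. TABASTA, where
## B = C/G/T and S = C/G) scanned on the promoter's sense sequence with
## overlapping matches allowed.

iupac_map <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' IUPAC nucleotide code expansions
#'
#' @return Named list mapping each IUPAC letter to its base set.
#' @export
iupac_codes <- function() {
  lapply(iupac_map, function(x) strsplit(x, "")[[1]])
}

#' Extract promoter sequences upstream of TSS positions
#'
#' Plus-strand genes get `[TSS - length, TSS - 1]`; minus-strand genes the
#' reverse complement of `[TSS + 1, TSS + length]`. Windows are clipped at
#' the chromosome bounds and flagged as truncated.
#'
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param tss data.frame with columns gene_id, chrom, pos (1-based TSS),
#'   strand.
#' @param length Promoter length in bp (default 500).
#' @return List of class `"allophase_promoters"`: `seq` (named character
#'   vector) and `intervals` (gene_id, chrom, start, end, strand,
#'   truncated).
#' @export
extract_promoters <- function(genome, tss, length = 500L) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  miss <- setdiff(tss$chrom, names(genome))
  if (base::length(miss)) stop("unknown chromosome: ", miss[1])
  if (any(tss$pos < 1L | tss$pos > chrlen[tss$chrom]))
    stop("TSS outside chromosome bounds")
  n <- nrow(tss)
  seqs <- character(n); start <- end <- integer(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    L <- chrlen[[tss$chrom[i]]]
    if (tss$strand[i] == "+") {
      s <- max(1L, tss$pos[i] - length); e <- tss$pos[i] - 1L
    } else {
      s <- tss$pos[i] + 1L; e <- min(L, tss$pos[i] + length)
    }
    trunc[i] <- (e - s + 1L) < length
    if (e < s) { seqs[i] <- ""; start[i] <- s; end[i] <- e; next }
    sub <- Biostrings::subseq(genome[[tss$chrom[i]]], s, e)
    if (tss$strand[i] == "-") sub <- Biostrings::reverseComplement(sub)
    seqs[i] <- as.character(sub)
    start[i] <- s; end[i] <- e
  }
  names(seqs) <- tss$gene_id
  structure(list(seq = seqs,
                 intervals = data.frame(gene_id = tss$gene_id,
                                        chrom = tss$chrom, start = start,
                                        end = end, strand = tss$strand,
                                        truncated = trunc,
                                        stringsAsFactors = FALSE)),
            class = "allophase_promoters")
}

#' Scan promoters for a degenerate IUPAC motif
#'
#' Reports every (overlapping) match position of `motif` on the sense
#' sequence of each promoter; with `both_strands = TRUE` the reverse
#' complement of the motif is scanned as well.
#'
#' @param promoters Named character vector of promoter sequences, or an
#'   [extract_promoters()] result.
#' @param motif IUPAC motif string.
#' @param both_strands Also scan the reverse-complement motif (default
#'   FALSE: MEME-style sense-strand scan is the package default).
#' @return data.frame: gene_id, n_matches, present, positions
#'   (comma-separated 1-based match starts).
#' @export
scan_iupac <- function(promoters, motif, both_strands = FALSE) {
  if (inherits(promoters, "allophase_promoters")) promoters <- promoters$seq
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], names(iupac_map))
  if (length(bad)) stop("invalid IUPAC letter(s) in motif: ",
                        paste(bad, collapse = ""))
  pats <- Biostrings::DNAString(motif)
  rc <- if (both_strands) Biostrings::reverseComplement(pats) else NULL
  res <- lapply(promoters, function(s) {
    if (nchar(s) < nchar(motif)) return(integer(0))
    subj <- Biostrings::DNAString(s)
    hits <- IRanges::start(Biostrings::matchPattern(pats, subj, fixed = FALSE))
    if (!is.null(rc) && as.character(rc) != motif)
      hits <- sort(unique(c(hits,
        IRanges::start(Biostrings::matchPattern(rc, subj, fixed = FALSE)))))
    hits
  })
  data.frame(gene_id = names(promoters),
             n_matches = lengths(res),
             present = lengths(res) > 0L,
             positions = vapply(res, paste, character(1), collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subgenome enrichment of motif occurrences
#'
#' For each motif, tests the 2x2 table (subgenome Fso_h/Fso_l) x (motif
#' present/absent) with Fisher's exact test and adjusts across motifs by
#' Benjamini-Hochberg. Motifs with zero occurrences are skipped with a
#' warning.
#'
#' @param occurrences Named list of [scan_iupac()] results (one per motif),
#'   or a single result (then named `"motif"`).
#' @param labels Named character vector gene_id -> `"Fso_h"`/`"Fso_l"`.
#' @return data.frame: motif, present_h, absent_h, present_l, absent_l,
#'   odds_ratio, p_value, q_value.
#' @export
motif_subgenome_enrichment <- function(occurrences, labels) {
  if (is.data.frame(occurrences)) occurrences <- list(motif = occurrences)
  rows <- list()
  for (m in names(occurrences)) {
    occ <- occurrences[[m]]
    lab <- labels[occ$gene_id]
    if (anyNA(lab)) stop("gene without subgenome label")
    if (!any(occ$present)) {
      warning("motif with zero occurrences skipped: ", m)
      next
    }
    tab <- matrix(c(sum(occ$present & lab == "Fso_h"),
                    sum(!occ$present & lab == "Fso_h"),
                    sum(occ$present & lab == "Fso_l"),
                    sum(!occ$present & lab == "Fso_l")), 2L)
    ft <- fisher_2x2(tab)
    rows[[m]] <- data.frame(motif = m,
                            present_h = tab[1, 1], absent_h = tab[2, 1],
                            present_l = tab[1, 2], absent_l = tab[2, 2],
                            odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Expression bias conditional on motif placement within a pair
#'
#' Splits pairs into three categories -- motif in both promoters, only in
#' the Fso_h copy, only in the Fso_l copy -- and, treating timepoints as
#' replicates, compares the per-timepoint counts of pairs biased toward the
#' motif-bearing side against those biased toward the other side with
#' Welch's t-test.
#'
#' @param occ Single-motif [scan_iupac()] result covering both copies of
#'   each pair.
#' @param calls [bias_calls()] output.
#' @param pairs Pair table (gene_x assumed to be the Fso_h side unless
#'   `h_gene`/`l_gene` columns are supplied).
#' @return data.frame, one row per category: mean/SD of counts toward each
#'   side over timepoints, Welch t, df, p (NA for the symmetric `both`
#'   category, where h is reported as the "motif side").
#' @export
motif_conditional_bias <- function(occ, calls, pairs) {
  tps <- unique(calls$timepoint)
  if (length(tps) < 2L) stop("Welch's test needs >= 2 timepoints")
  pres <- stats::setNames(occ$present, occ$gene_id)
  h_gene <- if (!is.null(pairs$h_gene)) pairs$h_gene else pairs$gene_x
  l_gene <- if (!is.null(pairs$l_gene)) pairs$l_gene else pairs$gene_x_prime
  ph <- pres[h_gene]; pl <- pres[l_gene]
  if (anyNA(ph) || anyNA(pl)) stop("pair gene missing from occurrence table")
  cat_of <- ifelse(ph & pl, "both", ifelse(ph, "h_only",
                                           ifelse(pl, "l_only", "none")))
  names(cat_of) <- pairs$pair_id
  out <- list()
  for (cat in c("both", "h_only", "l_only")) {
    ids <- pairs$pair_id[cat_of[pairs$pair_id] == cat]
    cnt_h <- cnt_l <- numeric(length(tps))
    for (j in seq_along(tps)) {
      s <- calls[calls$timepoint == tps[j] & calls$pair_id %in% ids, ]
      cnt_h[j] <- sum(s$direction == "toward_h")
      cnt_l[j] <- sum(s$direction == "toward_l")
    }
    motif_side <- if (cat == "l_only") cnt_l else cnt_h
    other_side <- if (cat == "l_only") cnt_h else cnt_l
    wt <- welch_t(motif_side, other_side)
    out[[cat]] <- data.frame(
      category = cat, n_pairs = length(ids),
      mean_toward_motif = mean(motif_side), sd_toward_motif = stats::sd(motif_side),
      mean_toward_other = mean(other_side), sd_toward_other = stats::sd(other_side),
      t = wt$t, df = wt$df, p_value = wt$p_value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
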