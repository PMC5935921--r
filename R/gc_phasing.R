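## dGC / dGC3 profiles, subgenome assignment, flip-over detection and
## chromosome summaries.
##
## The central statistic is the per-pair GC-content ratio
##   dGC_X  = GC_X  / ((GC_X + GC_X') / 2)
##   dGC_X' = GC_X' / ((GC_X + GC_X') / 2)
## so the two values of a homoeologous pair always sum to 2.  Profiles are
## ordered along chromosome X (the member of each pair with the higher
## global GC) and smoothed with a simple moving average before polarity
## calls.

#' GC content of nucleotide sequences
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T). N bases are excluded from both
#' numerator and denominator so assembly gaps cannot bias composition.
#'
#' @param seq Character vector of nucleotide sequences (A/C/G/T/N).
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(seq) {
  if (!length(seq) || any(!nzchar(seq))) stop("empty sequence")
  ss <- Biostrings::BStringSet(seq)
  f <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"), OR = 0)
  tot <- rowSums(f)
  if (any(tot == 0)) stop("sequence contains no unambiguous bases (only N?)")
  stats::setNames((f[, "G"] + f[, "C"]) / tot, names(seq))
}

#' GC content at third codon positions
#'
#' GC fraction over the third base of every complete codon (reading frame
#' starting at position 1). A trailing incomplete codon is ignored with a
#' warning; N third bases are excluded.
#'
#' @param cds Character vector of CDS sequences, each of length >= 3.
#' @return Numeric vector of GC3 fractions.
#' @export
gc3_content <- function(cds) {
  n <- nchar(cds)
  if (any(n < 3L)) stop("CDS shorter than one codon")
  if (any(n %% 3L != 0L))
    warning("trailing incomplete codon ignored in ",
            sum(n %% 3L != 0L), " sequence(s)")
  vapply(cds, function(s) {
    len <- nchar(s)
    pos <- seq.int(3L, len - len %% 3L, by = 3L)
    third <- substring(s, pos, pos)
    third <- third[third != "N"]
    if (!length(third)) stop("no unambiguous third positions")
    sum(third %in% c("G", "C")) / length(third)
  }, numeric(1), USE.NAMES = !is.null(names(cds)))
}

#' dGC ratio of a homoeologous pair
#'
#' @param gc_x,gc_x_prime GC fractions of the two copies (vectors).
#' @return A list with `dgc_x` and `dgc_x_prime`; the two sum to 2.
#' @export
dgc_pair <- function(gc_x, gc_x_prime) {
  if (any(gc_x + gc_x_prime == 0)) stop("both GC values are zero")
  m <- (gc_x + gc_x_prime) / 2
  list(dgc_x = gc_x / m, dgc_x_prime = gc_x_prime / m)
}

#' Simple moving average with truncated centred window
#'
#' Centred mean of the `window` nearest values; at the series edges the
#' window is truncated to the values that exist, so the output has the same
#' length and stays aligned with gene positions.
#'
#' @param values Numeric vector.
#' @param window Odd integer >= 1, at most `length(values)`.
#' @return Numeric vector of smoothed values.
#' @export
smooth_series <- function(values, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 1L) stop("window must be >= 1")
  n <- length(values)
  if (window > n) stop("window exceeds series length")
  if (window == 1L) return(values)
  h <- window %/% 2L
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' dGC and dGC3 profiles along homoeologous chromosome pairs
#'
#' Computes per-pair GC and GC3 of both copies, the dGC/dGC3 ratios, and
#' their moving averages, ordered by the position of the X-copy along
#' chromosome X (pairs displaced by transposition still enter the X-ordered
#' series).
#'
#' @param cds Named character vector of CDS sequences.
#' @param pairs Pair table (`pair_id`, `chrom_pair`, `gene_x`,
#'   `gene_x_prime`).
#' @param genes Gene record table (supplies `order_index` on chromosome X).
#' @param window Moving-average window (odd; default 11 genes).
#' @return A data.frame (class `"allophase_dgc"`) with one row per pair in
#'   plotting order: gc/gc3 and dgc/dgc3 of both copies plus smoothed
#'   `sm_dgc_x` and `sm_dgc3_x`.
#' @export
dgc_profiles <- function(cds, pairs, genes, window = 11L) {
  miss <- setdiff(c(pairs$gene_x, pairs$gene_x_prime), names(cds))
  if (length(miss))
    stop("pair gene(s) missing from CDS set: ", miss[1])
  ord <- stats::setNames(genes$order_index, genes$gene_id)
  out <- vector("list", 0L)
  for (cp in unique(pairs$chrom_pair)) {
    p <- pairs[pairs$chrom_pair == cp, , drop = FALSE]
    p <- p[order(ord[p$gene_x]), , drop = FALSE]
    gx <- gc_content(cds[p$gene_x])
    gxp <- gc_content(cds[p$gene_x_prime])
    g3x <- gc3_content(cds[p$gene_x])
    g3xp <- gc3_content(cds[p$gene_x_prime])
    d <- dgc_pair(gx, gxp)
    d3 <- dgc_pair(g3x, g3xp)
    w <- min(window, if (nrow(p) %% 2L == 0L) nrow(p) - 1L else nrow(p))
    out[[cp]] <- data.frame(
      chrom_pair = cp, pair_id = p$pair_id,
      gene_x = p$gene_x, gene_x_prime = p$gene_x_prime,
      order = seq_len(nrow(p)),
      gc_x = gx, gc_x_prime = gxp,
      dgc_x = d$dgc_x, dgc_x_prime = d$dgc_x_prime,
      gc3_x = g3x, gc3_x_prime = g3xp,
      dgc3_x = d3$dgc_x, dgc3_x_prime = d3$dgc_x_prime,
      sm_dgc_x = smooth_series(d$dgc_x, w),
      sm_dgc3_x = smooth_series(d3$dgc_x, w),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("allophase_dgc", class(res))
  res
}

# maximal runs of value TRUE in a logical vector -> data.frame(start, end)
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Assign pseudo-parental subgenomes and detect flip-over segments
#'
#' Per chromosome pair, the polarity of each position is the sign of the
#' smoothed ratio minus 1 (dGC3 by default, which carries roughly three
#' times the dGC amplitude when divergence is synonymous; `series = "dgc"`
#' uses the whole-CDS ratio). The majority polarity sets the default label
#' of chromosome X; maximal runs of opposite polarity (runs separated by
#' fewer than `merge_gap` positions are consolidated) become flip segments
#' when they cover at least `min_run` genes and their mean effect
#' |smoothed ratio - 1| is at least `min_effect`, and gene labels inside a
#' flip are swapped. Brief reciprocal reversals below these thresholds are
#' treated as noise.
#'
#' @param profiles [dgc_profiles()] output.
#' @param min_run Minimum flip length in genes (default 20).
#' @param min_effect Minimum mean |smoothed ratio - 1| of a flip (default
#'   0.01).
#' @param series `"dgc3"` (default) or `"dgc"`.
#' @param merge_gap Opposite-polarity runs separated by at most this many
#'   majority-polarity positions are consolidated before the length/effect
#'   test; default `min_run`, since interruptions shorter than an acceptable
#'   segment are themselves noise.
#' @return List of class `"allophase_assignment"` with `genes` (gene_id,
#'   chrom_pair, copy, subgenome), `chromosomes` (chrom_pair, x_label,
#'   low_confidence), and `flips` (chrom_pair, start_index, end_index,
#'   n_genes, mean_effect).
#' @export
assign_subgenomes <- function(profiles, min_run = 20L, min_effect = 0.01,
                              series = c("dgc3", "dgc"), merge_gap = min_run) {
  series <- match.arg(series)
  col <- if (series == "dgc3") "sm_dgc3_x" else "sm_dgc_x"
  genes_out <- list(); chrom_out <- list(); flips_out <- list()
  for (cp in unique(profiles$chrom_pair)) {
    pr <- profiles[profiles$chrom_pair == cp, , drop = FALSE]
    pr <- pr[order(pr$order), , drop = FALSE]
    s <- pr[[col]] - 1
    pol <- sign(s)
    n <- length(s)
    n_pos <- sum(pol > 0); n_neg <- sum(pol < 0)
    maj <- if (n_pos >= n_neg) 1 else -1
    x_label <- if (maj > 0) "Fso_h" else "Fso_l"
    low_conf <- FALSE
    flip_idx <- logical(n)
    if (n < min_run && n_pos > 0 && n_neg > 0) {
      # too short to ever host a flip call: label by mean ratio, flag it
      x_label <- if (mean(s) >= 0) "Fso_h" else "Fso_l"
      low_conf <- TRUE
    } else {
      opp <- pol == -maj               # ties (pol == 0) inherit majority
      rr <- runs_of(opp)
      if (nrow(rr) > 1L) {
        # consolidate runs across short gaps, but only when the merged span
        # still clears the effect threshold -- otherwise a distant noise
        # blip would dilute a genuine segment
        eff_span <- function(a, b) mean(-maj * s[a:b])
        keep <- rr[1, , drop = FALSE]
        for (k in 2:nrow(rr)) {
          last <- nrow(keep)
          if (rr$start[k] - keep$end[last] - 1L <= merge_gap &&
              eff_span(keep$start[last], rr$end[k]) >= min_effect)
            keep$end[last] <- rr$end[k]
          else keep <- rbind(keep, rr[k, ])
        }
        rr <- keep
      }
      if (nrow(rr)) {
        span_n <- rr$end - rr$start + 1L
        eff <- vapply(seq_len(nrow(rr)), function(k)
          mean(-maj * s[rr$start[k]:rr$end[k]]), numeric(1))
        ok <- span_n >= min_run & eff >= min_effect
        rr <- rr[ok, , drop = FALSE]
        if (nrow(rr)) {
          for (k in seq_len(nrow(rr))) flip_idx[rr$start[k]:rr$end[k]] <- TRUE
          flips_out[[cp]] <- data.frame(
            chrom_pair = cp, start_index = rr$start, end_index = rr$end,
            n_genes = rr$end - rr$start + 1L,
            mean_effect = eff[ok], stringsAsFactors = FALSE)
        }
      }
    }
    lab_x <- ifelse(flip_idx, setdiff(c("Fso_h", "Fso_l"), x_label), x_label)
    lab_xp <- ifelse(lab_x == "Fso_h", "Fso_l", "Fso_h")
    genes_out[[cp]] <- data.frame(
      gene_id = c(pr$gene_x, pr$gene_x_prime),
      chrom_pair = cp,
      copy = rep(c("x", "x_prime"), each = n),
      subgenome = c(lab_x, lab_xp),
      stringsAsFactors = FALSE)
    chrom_out[[cp]] <- data.frame(chrom_pair = cp, x_label = x_label,
                                  low_confidence = low_conf,
                                  stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, c(genes_out, make.row.names = FALSE)),
                 chromosomes = do.call(rbind, c(chrom_out, make.row.names = FALSE)),
                 flips = if (length(flips_out))
                   do.call(rbind, c(flips_out, make.row.names = FALSE))
                 else data.frame(chrom_pair = character(0),
                                 start_index = integer(0), end_index = integer(0),
                                 n_genes = integer(0), mean_effect = numeric(0))),
            class = "allophase_assignment")
}

# round half up to `digits` decimals (table formatting convention)
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Chromosome summary table (predicted / homoeologous / non-homoeologous)
#'
#' One row per chromosome pair with gene counts and percentages for the
#' H (Fso_h) and L (Fso_l) copy, keyed by the dGC-based subgenome
#' assignment, not by global GC. Chromosome pairs with flip segments get
#' additional `_A`/`_B` sub-rows (upstream / flip region), each re-keyed by
#' the dGC label inside the segment. Percentages are per cent of predicted
#' genes, rounded half-up to 2 decimals.
#'
#' @param assignment [assign_subgenomes()] result.
#' @param genes Gene record table.
#' @param pairs Pair table.
#' @param pairings Chromosome pairing table (supplies global GC per copy).
#' @param profiles [dgc_profiles()] output (needed to locate segment
#'   boundaries for the sub-rows).
#' @return data.frame with columns chrom_pair, segment, global_gc_h/l,
#'   predicted_h/l, hom_h/l, hom_pct_h/l, nonhom_h/l, nonhom_pct_h/l.
#' @export
chromosome_summary <- function(assignment, genes, pairs, pairings,
                               profiles = NULL) {
  paired_ids <- c(pairs$gene_x, pairs$gene_x_prime)
  lab <- stats::setNames(assignment$genes$subgenome, assignment$genes$gene_id)
  rows <- list()
  for (i in seq_len(nrow(pairings))) {
    cp <- pairings$pair_name[i]
    chx <- pairings$chrom_x[i]; chxp <- pairings$chrom_x_prime[i]
    x_label <- assignment$chromosomes$x_label[
      assignment$chromosomes$chrom_pair == cp]
    h_chrom <- if (x_label == "Fso_h") chx else chxp
    l_chrom <- if (x_label == "Fso_h") chxp else chx
    gh <- genes[genes$chrom == h_chrom, , drop = FALSE]
    gl <- genes[genes$chrom == l_chrom, , drop = FALSE]
    count_row <- function(segment, gh, gl, gch, gcl) {
      ph <- nrow(gh); pl <- nrow(gl)
      hh <- sum(gh$gene_id %in% paired_ids); hl <- sum(gl$gene_id %in% paired_ids)
      data.frame(chrom_pair = cp, segment = segment,
                 global_gc_h = gch, global_gc_l = gcl,
                 predicted_h = ph, predicted_l = pl,
                 hom_h = hh, hom_l = hl,
                 hom_pct_h = round_half_up(100 * hh / ph),
                 hom_pct_l = round_half_up(100 * hl / pl),
                 nonhom_h = ph - hh, nonhom_l = pl - hl,
                 nonhom_pct_h = round_half_up(100 * (ph - hh) / ph),
                 nonhom_pct_l = round_half_up(100 * (pl - hl) / pl),
                 stringsAsFactors = FALSE)
    }
    gc_h <- if (x_label == "Fso_h") pairings$global_gc_x[i] else pairings$global_gc_x_prime[i]
    gc_l <- if (x_label == "Fso_h") pairings$global_gc_x_prime[i] else pairings$global_gc_x[i]
    rows[[length(rows) + 1L]] <- count_row("all", gh, gl, gc_h, gc_l)

    fl <- assignment$flips[assignment$flips$chrom_pair == cp, , drop = FALSE]
    if (nrow(fl) && !is.null(profiles)) {
      pr <- profiles[profiles$chrom_pair == cp, , drop = FALSE]
      pr <- pr[order(pr$order), , drop = FALSE]
      ord <- stats::setNames(genes$order_index, genes$gene_id)
      # segment boundaries on each physical chromosome, via the boundary pairs
      cut_x <- ord[pr$gene_x[fl$start_index[1]]]
      cut_xp <- ord[pr$gene_x_prime[fl$start_index[1]]]
      gx_all <- genes[genes$chrom == chx, , drop = FALSE]
      gxp_all <- genes[genes$chrom == chxp, , drop = FALSE]
      seg_of <- function(g, cut) list(A = g[g$order_index < cut, , drop = FALSE],
                                      B = g[g$order_index >= cut, , drop = FALSE])
      sx <- seg_of(gx_all, cut_x); sxp <- seg_of(gxp_all, cut_xp)
      for (seg in c("A", "B")) {
        # inside the flip (B) the dGC keying swaps relative to the majority
        swap <- seg == "B"
        hx <- (x_label == "Fso_h") != swap
        gh_s <- if (hx) sx[[seg]] else sxp[[seg]]
        gl_s <- if (hx) sxp[[seg]] else sx[[seg]]
        rows[[length(rows) + 1L]] <- count_row(seg, gh_s, gl_s, NA_real_, NA_real_)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Fractionation bias across chromosome pairs
#'
#' Counts the chromosome pairs on which strictly more non-homoeologous
#' (singleton) genes sit on the Fso_h (high-dGC) side. For chromosome pairs
#' with flip segments the counts are summed over the dGC-keyed `_A`/`_B`
#' sub-rows rather than the whole-chromosome row. Ties count as neither and
#' are reported separately. The two-sided sign-test p-value is the exact
#' binomial test on non-tied pairs.
#'
#' @param summary [chromosome_summary()] output (or any data.frame with
#'   chrom_pair, segment, nonhom_h, nonhom_l).
#' @return List: `n_high` (pairs with more singletons on the Fso_h side),
#'   `n_total` (non-tied pairs), `n_ties`, `exceptions` (chrom_pair ids
#'   with more on the Fso_l side), `p_value`.
#' @export
fractionation_bias <- function(summary) {
  if (!nrow(summary)) stop("empty summary")
  cps <- unique(summary$chrom_pair)
  nh <- nl <- numeric(length(cps))
  for (k in seq_along(cps)) {
    rows <- summary[summary$chrom_pair == cps[k], , drop = FALSE]
    sub <- rows[rows$segment != "all", , drop = FALSE]
    use <- if (nrow(sub)) sub else rows
    nh[k] <- sum(use$nonhom_h); nl[k] <- sum(use$nonhom_l)
  }
  greater <- nh > nl; less <- nh < nl; tie <- nh == nl
  n_high <- sum(greater); n_nontied <- sum(!tie)
  p <- if (n_nontied > 0)
    stats::binom.test(n_high, n_nontied, p = 0.5,
                      alternative = "two.sided")$p.value else NA_real_
  list(n_high = n_high, n_total = n_nontied, n_ties = sum(tie),
       exceptions = cps[less], p_value = p)
}
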