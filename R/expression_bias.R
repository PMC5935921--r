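## Homoeolog expression bias classification and downstream statistics.
##
## A pair is biased at a timepoint when one copy's RPKM is two-fold or
## greater (inclusive) than its partner's, or when exactly one copy is
## expressed (RPKM >= threshold) -- the silencing route.  log2 fold changes
## are oriented so positive values point toward Fso_h throughout.

#' Remove pairs silent at every timepoint
#'
#' A pair is removed iff BOTH copies have RPKM below `threshold` at EVERY
#' timepoint.
#'
#' @param expr RPKM matrix (genes x timepoints).
#' @param pairs Pair table.
#' @param threshold Expressed threshold (RPKM, default 1).
#' @return List: `pairs` (retained table), `removed` (pair ids),
#'   `n_removed`.
#' @export
filter_expressed_pairs <- function(expr, pairs, threshold = 1) {
  miss <- setdiff(c(pairs$gene_x, pairs$gene_x_prime), rownames(expr))
  if (length(miss))
    stop("pair gene missing from expression matrix: ", miss[1])
  silent <- rowSums(expr[pairs$gene_x, , drop = FALSE] >= threshold) == 0 &
    rowSums(expr[pairs$gene_x_prime, , drop = FALSE] >= threshold) == 0
  list(pairs = pairs[!silent, , drop = FALSE],
       removed = pairs$pair_id[silent],
       n_removed = sum(silent))
}

#' Call expression bias between two homoeologous copies
#'
#' Vectorised single-timepoint rule: both copies below `threshold` gives
#' `not_expressed`; exactly one expressed copy gives a silencing call toward
#' that copy; both expressed gives a call toward the higher copy iff
#' max/min >= `fold` (inclusive), else `neutral`.
#'
#' @param rpkm_h,rpkm_l RPKM of the Fso_h-side and Fso_l-side copy.
#' @param threshold Expressed threshold (default 1).
#' @param fold Fold threshold, inclusive (default 2).
#' @return data.frame: direction (`toward_h`/`toward_l`/`neutral`/
#'   `not_expressed`), silenced, log2fc (log2(h/l), NA when either copy is
#'   zero).
#' @export
call_bias <- function(rpkm_h, rpkm_l, threshold = 1, fold = 2) {
  if (any(rpkm_h < 0) || any(rpkm_l < 0)) stop("negative RPKM")
  eh <- rpkm_h >= threshold; el <- rpkm_l >= threshold
  direction <- rep("neutral", length(rpkm_h))
  direction[!eh & !el] <- "not_expressed"
  silenced <- xor(eh, el)
  direction[silenced & eh] <- "toward_h"
  direction[silenced & el] <- "toward_l"
  both <- eh & el
  hi <- pmax(rpkm_h, rpkm_l); lo <- pmin(rpkm_h, rpkm_l)
  biased <- both & (hi >= fold * lo)
  direction[biased & (rpkm_h >= rpkm_l)] <- "toward_h"
  direction[biased & (rpkm_h < rpkm_l)] <- "toward_l"
  log2fc <- ifelse(rpkm_h > 0 & rpkm_l > 0, log2(rpkm_h / rpkm_l), NA_real_)
  data.frame(direction = direction, silenced = silenced, log2fc = log2fc,
             stringsAsFactors = FALSE)
}

#' Bias calls for every pair and timepoint
#'
#' Orients each pair by the subgenome assignment (positive log2FC toward
#' Fso_h) and applies [call_bias()] per timepoint.
#'
#' @param expr RPKM matrix.
#' @param pairs Pair table.
#' @param assignment Optional [assign_subgenomes()] result; without it the
#'   `gene_x` copy is taken as the Fso_h side.
#' @param threshold,fold Passed to [call_bias()].
#' @return Long data.frame: pair_id, timepoint, direction, silenced,
#'   log2fc.
#' @export
bias_calls <- function(expr, pairs, assignment = NULL, threshold = 1, fold = 2) {
  h_gene <- pairs$gene_x; l_gene <- pairs$gene_x_prime
  if (!is.null(assignment)) {
    lab <- stats::setNames(assignment$genes$subgenome, assignment$genes$gene_id)
    swap <- lab[pairs$gene_x] == "Fso_l"
    h_gene[swap] <- pairs$gene_x_prime[swap]
    l_gene[swap] <- pairs$gene_x[swap]
  }
  out <- lapply(colnames(expr), function(tp) {
    cb <- call_bias(expr[h_gene, tp], expr[l_gene, tp], threshold, fold)
    cbind(data.frame(pair_id = pairs$pair_id, timepoint = tp,
                     stringsAsFactors = FALSE), cb)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Consistency of bias direction across timepoints
#'
#' A pair is `consistent_h`/`consistent_l` when every evaluable timepoint
#' (calls other than `not_expressed`) points the same non-neutral way;
#' `neutral` when all evaluable calls are neutral; otherwise `mixed`. Pairs
#' with at least one `not_expressed` timepoint are evaluated on the
#' remaining timepoints and flagged `partial`.
#'
#' @param calls [bias_calls()] output.
#' @return data.frame: pair_id, class (`consistent_h`, `consistent_l`,
#'   `mixed`, `neutral`, `not_assessable`), n_evaluated, partial.
#' @export
consistency <- function(calls) {
  sp <- split(calls$direction, calls$pair_id)
  cls <- vapply(sp, function(d) {
    ev <- d[d != "not_expressed"]
    if (!length(ev)) return("not_assessable")
    if (all(ev == "toward_h")) "consistent_h"
    else if (all(ev == "toward_l")) "consistent_l"
    else if (all(ev == "neutral")) "neutral"
    else "mixed"
  }, character(1))
  data.frame(pair_id = names(sp), class = unname(cls),
             n_evaluated = vapply(sp, function(d)
               sum(d != "not_expressed"), integer(1)),
             partial = vapply(sp, function(d)
               any(d == "not_expressed"), logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression synchrony of homoeologous pairs
#'
#' Default `"sign-concordance"` method: a pair is synchronized iff the sign
#' of the RPKM change between consecutive timepoints matches for both
#' copies at every step, a zero change acting as a wildcard (such
#' degenerate profiles are flagged). Method `"pearson"` calls a pair
#' synchronized when the correlation of the two copies' profiles is at
#' least `r`. Pairs with a constant-zero profile or fewer than two
#' evaluable timepoints are `not_assessable`.
#'
#' @param expr RPKM matrix.
#' @param pairs Pair table.
#' @param method `"sign-concordance"` (default) or `"pearson"`.
#' @param r Correlation threshold for the pearson method (default 0.8).
#' @return data.frame: pair_id, class, method, degenerate.
#' @export
synchrony <- function(expr, pairs, method = c("sign-concordance", "pearson"),
                      r = 0.8) {
  method <- match.arg(method)
  if (ncol(expr) < 2L) stop("synchrony needs >= 2 timepoints")
  ex <- expr[pairs$gene_x, , drop = FALSE]
  exp_ <- expr[pairs$gene_x_prime, , drop = FALSE]
  n <- nrow(pairs)
  cls <- character(n); degen <- logical(n)
  for (i in seq_len(n)) {
    a <- ex[i, ]; b <- exp_[i, ]
    if (all(a == 0) || all(b == 0)) { cls[i] <- "not_assessable"; next }
    if (method == "sign-concordance") {
      da <- sign(diff(a)); db <- sign(diff(b))
      degen[i] <- any(da == 0) || any(db == 0)
      ok <- all(da == 0 | db == 0 | da == db)
      cls[i] <- if (ok) "synchronized" else "unsynchronized"
    } else {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        cls[i] <- "not_assessable"; degen[i] <- TRUE; next
      }
      cls[i] <- if (stats::cor(a, b) >= r) "synchronized" else "unsynchronized"
    }
  }
  data.frame(pair_id = pairs$pair_id, class = cls, method = method,
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson statistic against expected proportions.
#'
#' @param observed Non-negative integer counts.
#' @param expected Expected proportions (summing to 1).
#' @return List: statistic, df, p_value.
#' @export
chisq_gof <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected lengths differ")
  e <- sum(observed) * expected / sum(expected)
  if (any(e < 1)) stop("expected count below 1; test unreliable")
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one, with the customary relative tolerance for ties.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List: odds_ratio (sample OR, `Inf`/`NaN` possible on zero
#'   margins), p_value.
#' @export
fisher_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == 2L)) stop("need a 2x2 table")
  if (any(m < 0)) stop("negative counts")
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
       p_value = min(1, p))
}

#' Stratified bias report over RPKM cutoffs
#'
#' One report per timepoint x cutoff, restricted to pairs whose higher copy
#' exceeds the cutoff at that timepoint ([sim_params()]-style RPKM strata,
#' e.g. >50, >100, >500). Counts of fold-biased pairs toward each subgenome
#' are tested against a 50:50 split with [chisq_gof()]; silencing calls are
#' counted separately and excluded from the test, mirroring how silencing
#' pairs are kept out of bias histograms.
#'
#' @param calls [bias_calls()] output.
#' @param expr RPKM matrix.
#' @param pairs Pair table.
#' @param cutoffs RPKM cutoffs (default 50, 100, 500).
#' @param stratum_stat `"max"` (default) or `"mean"` of the two copies.
#' @return data.frame: timepoint, cutoff, n_pairs, toward_h, toward_l,
#'   neutral, silenced, p_value (NA for empty strata).
#' @export
strata_bias_report <- function(calls, expr, pairs, cutoffs = c(50, 100, 500),
                               stratum_stat = c("max", "mean")) {
  stratum_stat <- match.arg(stratum_stat)
  f <- if (stratum_stat == "max") pmax else function(a, b) (a + b) / 2
  out <- list()
  for (tp in unique(calls$timepoint)) {
    ct <- calls[calls$timepoint == tp, , drop = FALSE]
    ct <- ct[match(pairs$pair_id, ct$pair_id), , drop = FALSE]
    lev <- f(expr[pairs$gene_x, tp], expr[pairs$gene_x_prime, tp])
    for (co in cutoffs) {
      s <- ct[lev > co, , drop = FALSE]
      nh <- sum(s$direction == "toward_h" & !s$silenced)
      nl <- sum(s$direction == "toward_l" & !s$silenced)
      p <- if (nh + nl >= 2) chisq_gof(c(nh, nl), c(0.5, 0.5))$p_value
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        timepoint = tp, cutoff = co, n_pairs = nrow(s),
        toward_h = nh, toward_l = nl,
        neutral = sum(s$direction == "neutral"),
        silenced = sum(s$silenced),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-pathway homoeolog bias statistics
#'
#' Per term and timepoint: the log2FC distribution summary of member pairs,
#' counts biased toward each subgenome, and a 2x2 test of the member
#' toward_h:toward_l split against the genome background. Fisher's exact
#' test is used when any expected cell is below 5, the chi-squared test
#' otherwise. q-values are Benjamini-Hochberg within timepoint. Pairs whose
#' copies localise to different compartments are excluded when a
#' compartment table is supplied.
#'
#' @param calls [bias_calls()] output.
#' @param annotation data.frame: gene_id, term (and optionally term_label);
#'   pairs are mapped to a term via either copy.
#' @param pairs Pair table.
#' @param compartments Optional named vector gene_id -> compartment.
#' @return data.frame, one row per term x timepoint.
#' @export
pathway_bias <- function(calls, annotation, pairs, compartments = NULL) {
  pair_of <- stats::setNames(rep(pairs$pair_id, 2L),
                             c(pairs$gene_x, pairs$gene_x_prime))
  ann <- annotation[annotation$gene_id %in% names(pair_of), , drop = FALSE]
  if (!nrow(ann)) stop("annotation matches no pair gene")
  ann$pair_id <- pair_of[ann$gene_id]
  if (!is.null(compartments)) {
    cx <- compartments[pairs$gene_x]; cxp <- compartments[pairs$gene_x_prime]
    bad <- pairs$pair_id[!is.na(cx) & !is.na(cxp) & cx != cxp]
    ann <- ann[!ann$pair_id %in% bad, , drop = FALSE]
  }
  term_pairs <- lapply(split(ann$pair_id, ann$term), unique)
  out <- list()
  for (tp in unique(calls$timepoint)) {
    ct <- calls[calls$timepoint == tp, , drop = FALSE]
    bg_h <- sum(ct$direction == "toward_h")
    bg_l <- sum(ct$direction == "toward_l")
    for (term in names(term_pairs)) {
      s <- ct[ct$pair_id %in% term_pairs[[term]], , drop = FALSE]
      if (!nrow(s)) { warning("term with zero pairs skipped: ", term); next }
      nh <- sum(s$direction == "toward_h"); nl <- sum(s$direction == "toward_l")
      tab <- matrix(c(nh, nl, bg_h - nh, bg_l - nl), 2L)
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- any(e < 5) || any(!is.finite(e))
      p <- if (sum(tab) == 0 || any(tab < 0)) NA_real_
      else if (use_fisher) fisher_2x2(tab)$p_value
      else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      q <- stats::quantile(s$log2fc, c(0.25, 0.5, 0.75), na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        term = term, timepoint = tp, n_pairs = length(term_pairs[[term]]),
        toward_h = nh, toward_l = nl,
        log2fc_q1 = unname(q[1]), log2fc_median = unname(q[2]),
        log2fc_q3 = unname(q[3]),
        test = if (use_fisher) "fisher" else "chisq",
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$q_value <- NA_real_
  for (tp in unique(res$timepoint)) {
    i <- res$timepoint == tp
    res$q_value[i] <- stats::p.adjust(res$p_value[i], method = "BH")
  }
  res
}

#' Term frequency log-ratio between two gene groups
#'
#' Relative frequency of each annotation term inside two disjoint gene
#' groups (e.g. consistently Fso_h- vs Fso_l-biased genes) and the log2
#' ratio of those frequencies; terms present in only one group are flagged.
#'
#' @param group_a,group_b Character vectors of gene ids (disjoint,
#'   non-empty).
#' @param annotation data.frame: gene_id, term.
#' @return data.frame: term, freq_a, freq_b, log2_ratio, flag.
#' @export
term_frequency_logratio <- function(group_a, group_b, annotation) {
  if (!length(group_a) || !length(group_b)) stop("empty gene group")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  count <- function(g) {
    ann <- annotation[annotation$gene_id %in% g, , drop = FALSE]
    table(factor(ann$term, levels = sort(unique(annotation$term))))
  }
  ta <- count(group_a); tb <- count(group_b)
  fa <- as.numeric(ta) / length(group_a)
  fb <- as.numeric(tb) / length(group_b)
  lr <- log2(fa / fb)
  flag <- rep("ok", length(lr))
  flag[fa == 0 & fb == 0] <- "absent"
  flag[xor(fa == 0, fb == 0)] <- "infinite"
  data.frame(term = names(ta), freq_a = fa, freq_b = fb,
             log2_ratio = lr, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Welch's t statistic with a zero-variance guard: equal means with zero
# pooled variance give t = 0 / p = 1; unequal means give +-Inf / p = 0.
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("Welch's test needs >= 2 values per group")
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  dm <- mean(x) - mean(y)
  if (se2 == 0) {
    return(list(t = if (dm == 0) 0 else sign(dm) * Inf,
                df = nx + ny - 2, p_value = if (dm == 0) 1 else 0))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}
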