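test_that("bias calls implement the inclusive two-fold and silencing rules", {
  cb <- call_bias(c(10, 10, 10, 0.5, 1, 2),
                  c(5, 6, 0.4, 0.2, 2, 1))
  expect_equal(cb$direction, c("toward_h", "neutral", "toward_h",
                               "not_expressed", "toward_l", "toward_h"))
  expect_equal(cb$silenced, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cb$log2fc[1], 1)
  expect_error(call_bias(-1, 1), "negative")
  # symmetry: swapping the copies mirrors every call and negates log2fc
  set.seed(3)
  a <- rexp(500, 0.1); b <- rexp(500, 0.1)
  f <- call_bias(a, b); r <- call_bias(b, a)
  swap <- c(toward_h = "toward_l", toward_l = "toward_h",
            neutral = "neutral", not_expressed = "not_expressed")
  expect_equal(unname(swap[f$direction]), r$direction)
  expect_equal(f$log2fc, -r$log2fc)
  expect_equal(f$silenced, r$silenced)
})

test_that("all-silent pairs are filtered exactly", {
  expr <- rbind(x1 = c(0.5, 0.2, 0.4), y1 = c(0.3, 0.9, 0.1),
                x2 = c(0.5, 1.2, 0.4), y2 = c(0.3, 0.9, 0.1))
  colnames(expr) <- c("t1", "t2", "t3")
  pairs <- data.frame(pair_id = c("p1", "p2"), chrom_pair = "c1",
                      gene_x = c("x1", "x2"), gene_x_prime = c("y1", "y2"))
  fl <- filter_expressed_pairs(expr, pairs)
  expect_equal(fl$removed, "p1")
  expect_equal(fl$pairs$pair_id, "p2")
  expect_error(filter_expressed_pairs(expr, data.frame(
    pair_id = "p", chrom_pair = "c", gene_x = "zz", gene_x_prime = "y1")),
    "missing")
  # on simulated data the removed count equals the all-silent truth count
  fx <- default_fixture()
  expr_s <- fx$expr$expr
  silent <- rowSums(expr_s[fx$sim$pairs$gene_x, ] >= 1) == 0 &
    rowSums(expr_s[fx$sim$pairs$gene_x_prime, ] >= 1) == 0
  expect_equal(filter_expressed_pairs(expr_s, fx$sim$pairs)$n_removed,
               sum(silent))
})

test_that("consistency classes follow the strict direction rule", {
  calls <- data.frame(
    pair_id = rep(c("p1", "p2", "p3", "p4", "p5"), each = 3),
    timepoint = rep(c("t1", "t2", "t3"), 5),
    direction = c("toward_h", "toward_h", "toward_h",
                  "toward_h", "neutral", "toward_h",
                  "neutral", "neutral", "neutral",
                  "toward_l", "toward_l", "not_expressed",
                  "not_expressed", "not_expressed", "not_expressed"))
  cc <- consistency(calls)
  got <- setNames(cc$class, cc$pair_id)
  expect_equal(got[c("p1", "p2", "p3", "p4", "p5")],
               c(p1 = "consistent_h", p2 = "mixed", p3 = "neutral",
                 p4 = "consistent_l", p5 = "not_assessable"))
  expect_true(cc$partial[cc$pair_id == "p4"])
})

test_that("synchrony sign-concordance and pearson methods behave as stated", {
  expr <- rbind(a1 = c(1, 2, 3), b1 = c(10, 20, 30),
                a2 = c(1, 2, 3), b2 = c(3, 2, 1),
                a3 = c(1, 1, 1), b3 = c(5, 9, 2),
                a4 = c(0, 0, 0), b4 = c(1, 2, 3))
  colnames(expr) <- c("t1", "t2", "t3")
  pairs <- data.frame(pair_id = paste0("p", 1:4), chrom_pair = "c",
                      gene_x = paste0("a", 1:4), gene_x_prime = paste0("b", 1:4))
  sy <- synchrony(expr, pairs)
  expect_equal(sy$class, c("synchronized", "unsynchronized",
                           "synchronized", "not_assessable"))
  expect_true(sy$degenerate[3])   # wildcard zero-change profile flagged
  syp <- synchrony(expr, pairs, method = "pearson")
  expect_equal(syp$class[1:2], c("synchronized", "unsynchronized"))
  expect_equal(syp$class[3], "not_assessable")
})

test_that("chi-squared GOF matches the Pearson formula and is calibrated", {
  g <- chisq_gof(c(50, 50), c(0.5, 0.5))
  expect_equal(g$statistic, 0); expect_equal(g$p_value, 1)
  expect_equal(chisq_gof(c(10, 0), c(0.5, 0.5))$statistic, 10)
  expect_error(chisq_gof(c(1, 0), c(0.999, 0.001)), "below 1")
  # type-I error at alpha = 0.05 over 10,000 multinomial null replicates
  set.seed(17)
  reps <- 10000L; n <- 200L; k <- 4L
  draws <- rmultinom(reps, n, rep(1 / k, k))
  stat <- colSums((draws - n / k)^2 / (n / k))
  rej <- mean(pchisq(stat, k - 1, lower.tail = FALSE) < 0.05)
  expect_gte(rej, 0.04); expect_lte(rej, 0.06)
})

test_that("Fisher's exact test equals the hypergeometric enumeration", {
  expect_equal(fisher_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
  # spot-check random tables against the enumeration oracle and fisher.test
  set.seed(4)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6), 2)
    p <- fisher_2x2(m)$p_value
    expect_equal(p, oracle_fisher(m), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("noisy bias recovery meets the recall target", {
  fx <- default_fixture()
  sim <- fx$sim
  lab <- sim$truth$gene_subgenome
  calls <- bias_calls(fx$expr$expr, sim$pairs)
  m <- merge(calls, fx$expr$bias_truth, by = c("pair_id", "timepoint"))
  sub_x <- lab[sim$pairs$gene_x[match(m$pair_id, sim$pairs$pair_id)]]
  called <- called_subgenome(m$direction.x, sub_x)
  b <- m$class == "biased" & m$direction.x != "not_expressed"
  expect_gte(mean(called[b] == m$direction.y[b]), 0.90)
})

test_that("strata report counts and tests per cutoff", {
  pairs <- data.frame(pair_id = sprintf("p%03d", 1:120), chrom_pair = "c",
                      gene_x = sprintf("x%03d", 1:120),
                      gene_x_prime = sprintf("y%03d", 1:120))
  # high-expression pairs (>= 100) biased toward the h copy, the rest neutral
  hx <- c(rep(400, 40), rep(10, 80))
  lx <- c(rep(80, 40), rep(10, 80))
  expr <- rbind(matrix(hx, dimnames = list(pairs$gene_x, "t1")),
                matrix(lx, dimnames = list(pairs$gene_x_prime, "t1")))
  calls <- bias_calls(expr, pairs)
  rep1 <- strata_bias_report(calls, expr, pairs, cutoffs = c(50, 1000))
  r50 <- rep1[rep1$cutoff == 50, ]
  expect_equal(r50$toward_h, 40L); expect_equal(r50$toward_l, 0L)
  expect_lt(r50$p_value, 0.05)
  r1000 <- rep1[rep1$cutoff == 1000, ]
  expect_equal(r1000$n_pairs, 0L)
  expect_true(is.na(r1000$p_value))
  # balanced counts give p = 1
  expr2 <- expr
  expr2[pairs$gene_x_prime[1:20], 1] <- 400
  expr2[pairs$gene_x[1:20], 1] <- 80
  rep2 <- strata_bias_report(bias_calls(expr2, pairs), expr2, pairs,
                             cutoffs = 50)
  expect_equal(rep2$toward_h, rep2$toward_l)
  expect_equal(rep2$p_value, 1)
})

test_that("pathway bias flags enriched terms and picks the right test", {
  set.seed(8)
  n <- 600
  pairs <- data.frame(pair_id = sprintf("p%03d", 1:n), chrom_pair = "c",
                      gene_x = sprintf("x%03d", 1:n),
                      gene_x_prime = sprintf("y%03d", 1:n))
  # background: 50:50 direction split; term "lipid": 80% toward_l
  dir <- c(sample(rep(c("h", "l"), each = 30)),            # term members
           sample(c("h", "l"), n - 60, TRUE))
  dir[1:60] <- c(sample(c("h", "l"), 60, TRUE, prob = c(0.2, 0.8)))
  hx <- ifelse(dir == "h", 40, 10); lx <- ifelse(dir == "h", 10, 40)
  expr <- rbind(matrix(hx, dimnames = list(pairs$gene_x, "t1")),
                matrix(lx, dimnames = list(pairs$gene_x_prime, "t1")))
  calls <- bias_calls(expr, pairs)
  ann <- rbind(data.frame(gene_id = pairs$gene_x[1:60], term = "lipid"),
               data.frame(gene_id = pairs$gene_x[1:599], term = "background"),
               data.frame(gene_id = pairs$gene_x[5], term = "solo"))
  ann$term_label <- ann$term
  pb <- suppressWarnings(pathway_bias(calls, ann, pairs))
  lip <- pb[pb$term == "lipid", ]
  expect_lt(lip$p_value, 0.05)
  expect_lt(lip$log2fc_median, 0)
  expect_equal(pb$test[pb$term == "solo"], "fisher")
  expect_true(all(pb$q_value >= pb$p_value, na.rm = TRUE))
  # all-neutral calls give centred medians and nothing significant
  exprN <- expr; exprN[] <- 10
  pbN <- pathway_bias(bias_calls(exprN, pairs), ann, pairs)
  expect_true(all(abs(pbN$log2fc_median) < 1))
  expect_true(all(pbN$q_value > 0.05 | is.na(pbN$q_value)))
  # compartment mismatches are excluded
  comp <- setNames(rep("plastid", 2 * n), c(pairs$gene_x, pairs$gene_x_prime))
  comp[pairs$gene_x_prime[1:60]] <- "ER"
  pbC <- suppressWarnings(pathway_bias(calls, ann, pairs, compartments = comp))
  expect_false("lipid" %in% pbC$term)
})

test_that("BH q-values are monotone in p-value rank", {
  set.seed(12)
  p <- runif(40)^2
  q <- p.adjust(p, "BH")
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("term frequency log-ratios match an independent recount", {
  ann <- data.frame(gene_id = c("a1", "a2", "a3", "b1", "b2", "a1"),
                    term = c("T1", "T1", "T2", "T1", "T3", "T3"))
  ga <- c("a1", "a2", "a3"); gb <- c("b1", "b2")
  tf <- term_frequency_logratio(ga, gb, ann)
  expect_equal(tf$freq_a[tf$term == "T1"], 2 / 3)
  expect_equal(tf$freq_b[tf$term == "T1"], 1 / 2)
  expect_equal(tf$log2_ratio[tf$term == "T1"], log2((2 / 3) / (1 / 2)))
  expect_equal(tf$flag[tf$term == "T2"], "infinite")
  same <- term_frequency_logratio(ga, c("a9"),
                                  rbind(ann, data.frame(gene_id = "a9",
                                                        term = "T2")))
  expect_error(term_frequency_logratio(ga, character(0), ann), "empty")
  expect_error(term_frequency_logratio(ga, ga, ann), "disjoint")
  ident <- term_frequency_logratio(c("a1", "a2"), c("g1", "g2"),
    data.frame(gene_id = c("a1", "a2", "g1", "g2"), term = "T1"))
  expect_true(all(ident$log2_ratio[ident$flag == "ok"] == 0))
})

test_that("Welch helper matches the closed form and t.test", {
  w <- allophase:::welch_t(c(10, 10, 10), c(2, 2, 2))
  expect_equal(w$t, Inf); expect_equal(w$p_value, 0)
  w0 <- allophase:::welch_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(w0$t, 0); expect_equal(w0$p_value, 1)
  x <- c(12, 15, 9, 14); y <- c(8, 7, 11)
  w2 <- allophase:::welch_t(x, y)
  tt <- t.test(x, y)
  expect_equal(w2$t, unname(tt$statistic))
  expect_equal(w2$df, unname(tt$parameter))
  expect_equal(w2$p_value, tt$p.value)
})
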