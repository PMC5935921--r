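test_that("GC and GC3 contents follow the N-exclusion and frame rules", {
  expect_equal(gc_content(c("ATGC", "GGCC", "ANGC")), c(0.5, 1, 2 / 3))
  expect_error(gc_content("NNN"), "only N")
  expect_error(gc_content(""), "empty")

  expect_equal(gc3_content(c("ATGGCC", "ATAGCA")), c(1, 0))
  expect_warning(g <- gc3_content("ATGGC"), "incomplete codon")
  expect_equal(g, 1)
  expect_error(gc3_content("AT"), "shorter")
})

test_that("dGC ratios sum to 2 and are antisymmetric", {
  expect_equal(dgc_pair(0.5, 0.5), list(dgc_x = 1, dgc_x_prime = 1))
  expect_equal(dgc_pair(0.6, 0.4), list(dgc_x = 1.2, dgc_x_prime = 0.8))
  d <- dgc_pair(0.492, 0.479)   # the two subgenome GC3 means
  expect_equal(d$dgc_x, 2 * 0.492 / 0.971, tolerance = 1e-12)
  expect_equal(d$dgc_x + d$dgc_x_prime, 2, tolerance = 1e-12)
  expect_error(dgc_pair(0, 0), "zero")

  set.seed(42)
  a <- runif(10000, 0.01, 0.99); b <- runif(10000, 0.01, 0.99)
  d <- dgc_pair(a, b); ds <- dgc_pair(b, a)
  expect_true(all(abs(d$dgc_x + d$dgc_x_prime - 2) < 1e-12))
  expect_equal(d$dgc_x, ds$dgc_x_prime)
  expect_equal(d$dgc_x_prime, ds$dgc_x)
})

test_that("moving average matches a brute-force clipped-window mean", {
  expect_equal(smooth_series(c(1, 2, 3), 3), c(1.5, 2, 2.5))
  expect_equal(smooth_series(rep(7, 10), 5), rep(7, 10))
  x <- rnorm(30)
  expect_equal(smooth_series(x, 1), x)
  for (w in c(3, 7, 11)) {
    set.seed(w)
    x <- rnorm(50)
    expect_equal(smooth_series(x, w), oracle_smooth(x, w))
  }
  # window equal to the series length preserves the mean at the centre
  x <- rnorm(11)
  expect_equal(smooth_series(x, 11)[6], mean(x))
  expect_error(smooth_series(1:5, 4), "odd")
  expect_error(smooth_series(1:3, 5), "exceeds")
})

test_that("uniform polarity yields a whole-chromosome label and no flips", {
  # 60 pairs, X copy always GC3-higher: all Fso_h, no flip segments
  set.seed(1)
  n <- 60
  cds <- c(setNames(vapply(1:n, function(i) paste(
      sample(c("GAC", "GAG"), 90, TRUE, prob = c(.8, .2)), collapse = ""),
      character(1)), sprintf("x%02d", 1:n)),
    setNames(vapply(1:n, function(i) paste(
      sample(c("GAC", "GAT"), 90, TRUE, prob = c(.3, .7)), collapse = ""),
      character(1)), sprintf("y%02d", 1:n)))
  pairs <- data.frame(pair_id = sprintf("p%02d", 1:n), chrom_pair = "c1",
                      gene_x = sprintf("x%02d", 1:n),
                      gene_x_prime = sprintf("y%02d", 1:n))
  genes <- gene_records(data.frame(
    gene_id = names(cds), chrom = rep(c("c1a", "c1b"), each = n),
    start = rep(seq(1, by = 300, length.out = n), 2),
    end = rep(seq(270, by = 300, length.out = n), 2), strand = "+"))
  prof <- dgc_profiles(cds, pairs, genes, window = 11)
  asg <- assign_subgenomes(prof)
  expect_equal(nrow(asg$flips), 0L)
  expect_equal(asg$chromosomes$x_label, "Fso_h")
  expect_true(all(asg$genes$subgenome[asg$genes$copy == "x"] == "Fso_h"))
  # brief reciprocal reversals below min_run are noise, not flips:
  # flipping 3 consecutive pairs must not create a segment
  cds2 <- cds
  for (i in 30:32) {
    tmp <- cds2[sprintf("x%02d", i)]
    cds2[sprintf("x%02d", i)] <- cds2[sprintf("y%02d", i)]
    cds2[sprintf("y%02d", i)] <- tmp
  }
  asg2 <- assign_subgenomes(dgc_profiles(cds2, pairs, genes, window = 3))
  expect_equal(nrow(asg2$flips), 0L)
})

test_that("subgenome assignment recovers simulated truth", {
  fx <- default_fixture()
  lab <- fx$sim$truth$gene_subgenome
  pred <- setNames(fx$assignment$genes$subgenome, fx$assignment$genes$gene_id)
  common <- intersect(names(pred), names(lab))
  expect_gte(mean(pred[common] == lab[common]), 0.99)
  # every chromosome pair's majority label is right
  for (cp in unique(fx$sim$pairs$chrom_pair)) {
    pr <- fx$sim$pairs[fx$sim$pairs$chrom_pair == cp, ]
    maj_true <- names(which.max(table(lab[pr$gene_x])))
    expect_equal(
      fx$assignment$chromosomes$x_label[
        fx$assignment$chromosomes$chrom_pair == cp], maj_true)
  }
})

test_that("dGC and dGC3 polarity agree along the profiles", {
  fx <- default_fixture()
  agree <- sign(fx$profiles$sm_dgc_x - 1) == sign(fx$profiles$sm_dgc3_x - 1)
  expect_gte(mean(agree), 0.99)
})

test_that("chromosome summary arithmetic reproduces published-style cells", {
  build <- summary_for_counts
  s <- build(452, 422, 408)
  expect_equal(s$hom_pct_h, 90.27)
  expect_equal(s$hom_pct_l, 96.68)
  expect_equal(s$nonhom_h + s$hom_h, s$predicted_h)
  s2 <- build(165, 130, 118)
  expect_equal(s2$hom_pct_h, 71.52)
  s3 <- build(100, 100, 100)        # all homoeologous
  expect_equal(c(s3$hom_pct_h, s3$nonhom_pct_h), c(100, 0))
})

test_that("fractionation bias counts strict inequalities and ties", {
  t1 <- read.delim(system.file("extdata", "table1_fsolaris.tsv",
                               package = "allophase"))
  fb <- fractionation_bias(t1)
  expect_equal(fb$n_high, 38L)
  expect_equal(sort(fb$exceptions), c("Chr27", "Chr38", "Chr41", "Chr42"))
  # exact binomial sign test: p equals the two-sided enumeration
  d <- dbinom(0:42, 42, 0.5)
  expect_equal(fb$p_value, sum(d[d <= dbinom(38, 42, 0.5) * (1 + 1e-7)]),
               tolerance = 1e-12)

  ties <- data.frame(chrom_pair = sprintf("c%02d", 1:42), segment = "all",
                     nonhom_h = 5, nonhom_l = 5)
  fb2 <- fractionation_bias(ties)
  expect_equal(fb2$n_high, 0L)
  expect_equal(fb2$n_ties, 42L)
})

test_that("crossover breakpoints are localised from the flip segments", {
  fx <- default_fixture()
  bp <- Filter(length, fx$sim$truth$breakpoints)
  expect_length(bp, 1L)
  cp <- names(bp)[1]
  fl <- fx$assignment$flips[fx$assignment$flips$chrom_pair == cp, ]
  expect_equal(nrow(fl), 1L)
  # truth slot index -> pair-order position along chromosome X
  pr <- fx$sim$pairs[fx$sim$pairs$chrom_pair == cp, ]
  slots <- as.integer(sub(".*_p", "", pr$pair_id))
  true_pos <- sum(slots < bp[[1]]) + 1L
  # the flip is terminal: its inner boundary is the detected breakpoint
  detected <- if (fl$start_index == 1L) fl$end_index + 1L else fl$start_index
  expect_lte(abs(detected - true_pos), 11L)
})
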