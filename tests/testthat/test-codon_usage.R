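test_that("codon counting follows the frame and N rules", {
  expect_equal(unname(codon_counts("ATGATG")[1, "ATG"]), 2L)
  expect_equal(sum(codon_counts("ATGATG")), 2L)
  expect_warning(m <- codon_counts("ATGNNNGCC"), "N dropped")
  expect_equal(unname(m[1, c("ATG", "GCC")]), c(1L, 1L))
  expect_equal(sum(m), 2L)
  expect_equal(unname(per_mil(codon_counts("ATGATG"))[1, "ATG"]), 1000)
  expect_error(codon_counts("AT"), "shorter")
})

test_that("usage aggregation is an exact grouped sum", {
  cds <- c(a = "ATG", b = "ATG", c = "GACGAC")
  counts <- codon_counts(cds)
  agg <- aggregate_usage(counts, c(a = "u1", b = "u1", c = "u2"))
  expect_equal(unname(agg["u1", "ATG"]), 2L)
  expect_equal(unname(agg["u2", "GAC"]), 2L)
  # one unit per gene reproduces codon_counts
  solo <- aggregate_usage(counts, c(a = "a", b = "b", c = "c"))
  expect_equal(solo[rownames(counts), ], counts)
  # subgenome aggregate equals the sum of its chromosome aggregates
  two_lvl <- aggregate_usage(agg, c(u1 = "all", u2 = "all"))
  expect_equal(two_lvl["all", ], colSums(counts))
  expect_error(aggregate_usage(counts, c(zz = "u1")), "unknown gene")
})

test_that("usage ratios flag undefined and infinite codons", {
  h <- setNames(rep(0, 64), allophase:::codon_tables()$codons)
  l <- h
  h["GAC"] <- 20; h["ATG"] <- 980
  l["GAC"] <- 10; l["ATG"] <- 990
  ur <- usage_ratio(h, l)
  expect_equal(ur$ratio[ur$codon == "GAC"], 2)
  expect_equal(ur$flag[ur$codon == "AAA"], "undefined")
  expect_true(is.na(ur$ratio[ur$codon == "AAA"]))
  h2 <- h; h2["TTT"] <- 1
  ur2 <- usage_ratio(h2, l)
  expect_equal(ur2$flag[ur2$codon == "TTT"], "infinite")
  expect_true(is.infinite(ur2$ratio[ur2$codon == "TTT"]))
  same <- usage_ratio(h, h)
  expect_true(all(same$ratio[same$flag == "ok"] == 1))
})

test_that("correlation PCA matches a power-iteration oracle", {
  set.seed(9)
  mat <- matrix(rnorm(7 * 4), 7, 4) %*% diag(c(3, 2, 1.2, 0.4))
  rownames(mat) <- paste0("u", 1:7); colnames(mat) <- paste0("v", 1:4)
  pca <- pca_correlation(mat)
  oe <- oracle_eigen(cor(mat))
  expect_equal(pca$eigenvalues, oe$values, tolerance = 1e-10)
  z <- scale(mat)
  osc <- z %*% oe$vectors
  expect_equal(abs(unclass(pca$scores)), abs(osc), tolerance = 1e-10,
               ignore_attr = TRUE)
  # loadings identity: squared column sums equal the eigenvalues
  expect_equal(unname(colSums(pca$loadings^2)), pca$eigenvalues,
               tolerance = 1e-10)
  # eigenvalue sum equals number of retained variables
  expect_equal(sum(pca$eigenvalues), ncol(mat), tolerance = 1e-8)
  # full reconstruction of the standardised matrix
  recon <- pca$scores %*% t(pca$eigenvectors)
  expect_lt(sqrt(sum((unclass(z) - recon)^2)), 1e-8)
  # score vectors orthogonal
  g <- crossprod(pca$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # observation order only permutes scores (up to component sign)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  pca2 <- pca_correlation(mat[perm, ])
  expect_equal(pca2$eigenvalues, pca$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(unclass(pca2$scores)), abs(unclass(pca$scores))[perm, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("perfectly correlated variables collapse onto PC1", {
  x <- c(1, 3, 2, 5, 4)
  mat <- cbind(a = x, b = 2 * x + 1)
  rownames(mat) <- paste0("u", 1:5)
  pca <- pca_correlation(mat)
  expect_equal(pca$explained[1], 1, tolerance = 1e-12)
})

test_that("chromosome pairs separate along PC2 with the stated orientation", {
  fx <- default_fixture()
  sim <- fx$sim
  lab <- sim$truth$gene_subgenome
  chlab <- tapply(lab[sim$genes$gene_id], sim$genes$chrom,
                  function(x) names(which.max(table(x))))
  cu <- chromosome_usage(sim$cds, sim$pairs, sim$genes)
  pca <- pca_correlation(cu, h_units = names(chlab)[chlab == "Fso_h"])
  # PC1 sign convention: mean loading negative
  expect_lt(mean(pca$loadings[, 1]), 0)
  hx <- chlab[sim$pairings$chrom_x] == "Fso_h"
  pu <- data.frame(
    unit_h = ifelse(hx, sim$pairings$chrom_x, sim$pairings$chrom_x_prime),
    unit_l = ifelse(hx, sim$pairings$chrom_x_prime, sim$pairings$chrom_x))
  sep <- separation_check(pca, pu)
  expect_equal(sep$fraction, 1)
  expect_false(any(sep$deltas$tie))
  # PC2 loadings track the GC3 class of the codon (G/C-ending higher)
  third <- substr(rownames(pca$loadings), 3, 3)
  expect_gt(mean(pca$loadings[third %in% c("G", "C"), 2]),
            mean(pca$loadings[third %in% c("A", "T"), 2]))
  # and so does the subgenome usage ratio
  sub_counts <- aggregate_usage(codon_counts(sim$cds),
                                setNames(unname(lab), names(lab)))
  ur <- usage_ratio(sub_counts["Fso_h", ], sub_counts["Fso_l", ])
  t3 <- substr(ur$codon, 3, 3)
  expect_gt(mean(ur$ratio[t3 %in% c("G", "C")], na.rm = TRUE),
            mean(ur$ratio[t3 %in% c("A", "T")], na.rm = TRUE))
  expect_error(separation_check(pca, data.frame(unit_h = "nope",
                                                unit_l = pu$unit_l[1])),
               "missing")
})

test_that("identical profiles under equal GC3 give no systematic separation", {
  p <- sim_params(n_chrom_pairs = 10L, genes_per_chrom = 60L,
                  codons_per_gene = 120L, gc3_h = 0.485, gc3_l = 0.485,
                  codon_profile_divergence = 0, fractionation_rate = 0,
                  n_crossovers = 0L)
  s <- simulate_genome(p, seed = 21)
  lab <- s$truth$gene_subgenome
  chlab <- tapply(lab[s$genes$gene_id], s$genes$chrom,
                  function(x) names(which.max(table(x))))
  cu <- chromosome_usage(s$cds, s$pairs, s$genes)
  pca <- pca_correlation(cu, h_units = names(chlab)[chlab == "Fso_h"])
  hx <- chlab[s$pairings$chrom_x] == "Fso_h"
  pu <- data.frame(
    unit_h = ifelse(hx, s$pairings$chrom_x, s$pairings$chrom_x_prime),
    unit_l = ifelse(hx, s$pairings$chrom_x_prime, s$pairings$chrom_x))
  frac <- separation_check(pca, pu)$fraction
  # inside the 99% binomial band around 0.5 for 10 pairs
  expect_gte(frac, 0.1); expect_lte(frac, 0.9)
})

test_that("segment PCA places flip segments with the opposite subgenome", {
  fx <- default_fixture()
  sim <- fx$sim
  bp <- Filter(length, sim$truth$breakpoints)
  cp <- names(bp)[1]; cut <- bp[[1]]
  sl <- sim$truth$slots[sim$truth$slots$chrom_pair == cp, ]
  seg_unit <- function(side) {
    ids <- sprintf("%s_g%03d%s", cp, sl$slot, side)
    pres <- if (side == "a") sl$present_a else sl$present_b
    unit <- ifelse(sl$slot < cut, paste0("seg_", side, "_up"),
                   paste0("seg_", side, "_dn"))
    data.frame(gene_id = ids[pres], unit = unit[pres])
  }
  other <- sim$genes[sim$genes$chrom != paste0(cp, "a") &
                     sim$genes$chrom != paste0(cp, "b"), ]
  seg_map <- rbind(seg_unit("a"), seg_unit("b"),
                   data.frame(gene_id = other$gene_id, unit = other$chrom))
  counts <- codon_counts(sim$cds[seg_map$gene_id])
  lab <- sim$truth$gene_subgenome
  unit_lab <- tapply(lab[seg_map$gene_id], seg_map$unit,
                     function(x) names(which.max(table(x))))
  pca <- segment_pca(counts, seg_map,
                     h_units = names(unit_lab)[unit_lab == "Fso_h"])
  sc <- pca$scores[, "PC2"]
  # within each region the Fso_h-labelled segment scores higher, and the
  # upstream/downstream segments of one physical copy land on opposite sides
  for (reg in c("up", "dn")) {
    ua <- paste0("seg_a_", reg); ub <- paste0("seg_b_", reg)
    hseg <- if (unit_lab[ua] == "Fso_h") ua else ub
    lseg <- setdiff(c(ua, ub), hseg)
    expect_gt(sc[hseg], sc[lseg])
  }
  expect_true(unit_lab["seg_a_up"] != unit_lab["seg_a_dn"])
  # a tiny segment is skipped with a warning
  seg_map2 <- rbind(seg_map,
                    data.frame(gene_id = sim$genes$gene_id[1:4], unit = "tiny"))
  expect_warning(segment_pca(codon_counts(sim$cds[seg_map2$gene_id]), seg_map2),
                 "fewer than 5")
})

test_that("PCA refuses fewer than three observations", {
  expect_error(pca_correlation(matrix(1:4, 2, 2)), "at least 3")
})
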