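# Independent brute-force oracles used to check the package implementations,
# plus a lazily built, cached copy of the default synthetic dataset shared by
# the heavier tests.

.fixture_cache <- new.env(parent = emptyenv())

# default synthetic dataset: genome (seed 1), dGC profiles, assignment, and
# a default-noise expression draw (seed 2)
default_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  params <- sim_params()
  sim <- simulate_genome(params, seed = 1)
  profiles <- dgc_profiles(sim$cds, sim$pairs, sim$genes, window = 11L)
  assignment <- assign_subgenomes(profiles)
  expr <- simulate_expression(sim, params, seed = 2)
  .fixture_cache$fx <- list(params = params, sim = sim, profiles = profiles,
                            assignment = assignment, expr = expr)
  .fixture_cache$fx
}

# map a called direction (toward_h = toward the gene_x copy when no
# assignment is passed) to the subgenome label it points at
called_subgenome <- function(direction, sub_x) {
  ifelse(direction == "toward_h", as.character(sub_x),
         ifelse(direction == "toward_l",
                ifelse(sub_x == "Fso_h", "Fso_l", "Fso_h"), direction))
}

# one-chromosome-pair scaffold with given predicted/homoeologous counts,
# run through chromosome_summary() to exercise its percentage arithmetic
summary_for_counts <- function(pred_h, pred_l, hom) {
  gh <- sprintf("h%03d", seq_len(pred_h)); gl <- sprintf("l%03d", seq_len(pred_l))
  genes <- gene_records(data.frame(
    gene_id = c(gh, gl), chrom = rep(c("cXa", "cXb"), c(pred_h, pred_l)),
    start = c(seq_len(pred_h), seq_len(pred_l)) * 10 - 9,
    end = c(seq_len(pred_h), seq_len(pred_l)) * 10, strand = "+"))
  pairs <- data.frame(pair_id = sprintf("p%03d", seq_len(hom)),
                      chrom_pair = "cX", gene_x = gh[seq_len(hom)],
                      gene_x_prime = gl[seq_len(hom)])
  assignment <- structure(list(
    genes = data.frame(gene_id = c(gh, gl), chrom_pair = "cX",
                       copy = rep(c("x", "x_prime"), c(pred_h, pred_l)),
                       subgenome = rep(c("Fso_h", "Fso_l"), c(pred_h, pred_l))),
    chromosomes = data.frame(chrom_pair = "cX", x_label = "Fso_h",
                             low_confidence = FALSE),
    flips = data.frame(chrom_pair = character(0), start_index = integer(0),
                       end_index = integer(0), n_genes = integer(0),
                       mean_effect = numeric(0))), class = "allophase_assignment")
  pairings <- data.frame(pair_name = "cX", chrom_x = "cXa",
                         chrom_x_prime = "cXb",
                         global_gc_x = 0.46, global_gc_x_prime = 0.45)
  chromosome_summary(assignment, genes, pairs, pairings)
}

# brute-force moving average with clipped centred window
oracle_smooth <- function(x, w) {
  h <- w %/% 2
  vapply(seq_along(x), function(i)
    mean(x[max(1, i - h):min(length(x), i + h)]), numeric(1))
}

# brute-force Jacobi-rotation eigen-decomposition for symmetric matrices
oracle_eigen <- function(S, sweeps = 200) {
  n <- nrow(S); A <- S; V <- diag(n)
  for (sw in seq_len(sweeps)) {
    off <- 0
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      off <- off + A[p, q]^2
      if (abs(A[p, q]) < 1e-300) next
      theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
      t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      if (theta == 0) t <- 1
      cc <- 1 / sqrt(t^2 + 1); ss <- t * cc
      G <- diag(n); G[p, p] <- cc; G[q, q] <- cc
      G[p, q] <- ss; G[q, p] <- -ss
      A <- t(G) %*% A %*% G
      V <- V %*% G
    }
    if (off < 1e-30) break
  }
  o <- order(diag(A), decreasing = TRUE)
  list(values = diag(A)[o], vectors = V[, o, drop = FALSE])
}

# exhaustive two-sided Fisher p for a 2x2 table: enumerate every table with
# the observed margins, probabilities from binomial coefficients
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- choose(c1, xs) * choose(n - c1, r1 - xs) / choose(n, r1)
  p_obs <- pr[xs == m[1, 1]]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# position-by-position IUPAC scanner
oracle_scan <- function(seq, motif) {
  codes <- iupac_codes()
  s <- strsplit(seq, "")[[1]]
  mm <- strsplit(motif, "")[[1]]
  n <- length(s); k <- length(mm)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(s[i + j - 1] %in% codes[[mm[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# expected codon distribution of the generator for uniform amino-acid
# composition and zero codon-profile divergence, as a function of the
# GC-ending tilt p and gene length L (codons)
oracle_codon_expectation <- function(p, L) {
  tab <- allophase:::codon_tables()
  sf <- tab$subfam
  prob <- numeric(64); names(prob) <- tab$codons
  aa20 <- setdiff(unique(tab$aa), "*")
  site_prob <- function(aa_set, weight_per_aa) {
    pr <- numeric(64); names(pr) <- tab$codons
    for (a in aa_set) {
      rows <- which(sf$aa == a)
      wpre <- sf$n_codons[rows] / sum(sf$n_codons[rows])
      for (j in seq_along(rows)) {
        r <- rows[j]
        gcl <- sf$gc_letters[[r]]; atl <- sf$at_letters[[r]]
        pg <- if (length(gcl) && length(atl)) p else as.numeric(length(gcl) > 0)
        for (b in gcl)
          pr[paste0(sf$prefix[r], b)] <- pr[paste0(sf$prefix[r], b)] +
            weight_per_aa * wpre[j] * pg / length(gcl)
        for (b in atl)
          pr[paste0(sf$prefix[r], b)] <- pr[paste0(sf$prefix[r], b)] +
            weight_per_aa * wpre[j] * (1 - pg) / length(atl)
      }
    }
    pr
  }
  interior <- site_prob(aa20, 1 / 20)
  stop_site <- site_prob("*", 1)
  start <- numeric(64); names(start) <- tab$codons; start["ATG"] <- 1
  (start + (L - 2) * interior + stop_site) / L
}
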