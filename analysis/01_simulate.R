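#!/usr/bin/env Rscript
# Stage 1: generate the synthetic allopolyploid study dataset.
#
# Emits the same file formats the downstream stages read from disk -- CDS
# FASTA, gene/pair/pairing tables, the RPKM time course -- plus the truth
# sidecars (subgenome labels, crossover breakpoints, bias truth) that later
# stages use to score themselves.

suppressPackageStartupMessages(library(allophase))

seed <- as.integer(Sys.getenv("ALLOPHASE_SEED", "1"))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- sim_params(seed = seed)
cfg <- run_config(seed = seed)
message("simulating ", params$n_chrom_pairs, " chromosome pairs x ",
        params$genes_per_chrom, " gene slots (seed ", seed, ")")

sim <- simulate_genome(params, seed = seed)
ex <- simulate_expression(sim, params, seed = seed + 1L)

# CDS FASTA
Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds),
                            file.path(out, "cds.fasta"))
# tables in the package's TSV dialects
write_result_tsv(sim$genes, file.path(out, "genes.tsv"), cfg)
write_result_tsv(sim$pairs, file.path(out, "pairs.tsv"), cfg)
write_result_tsv(sim$pairings, file.path(out, "pairings.tsv"), cfg)
expr_tab <- data.frame(gene_id = rownames(ex$expr), ex$expr,
                       check.names = FALSE)
write_result_tsv(expr_tab, file.path(out, "expression.tsv"), cfg)
# truth sidecars
jsonlite::write_json(list(gene_subgenome = as.list(sim$truth$gene_subgenome),
                          chrom_base = as.list(sim$truth$chrom_base),
                          breakpoints = sim$truth$breakpoints),
                     file.path(out, "truth_labels.json"), auto_unbox = TRUE)
write_result_tsv(ex$bias_truth, file.path(out, "truth_bias.tsv"), cfg)

message("pairs: ", nrow(sim$pairs), ", singleton genes: ",
        length(sim$cds) - 2L * nrow(sim$pairs))
message("crossovers on: ",
        paste(names(Filter(length, sim$truth$breakpoints)), collapse = ", "))
message("wrote ", out, "/{cds.fasta,genes.tsv,pairs.tsv,pairings.tsv,",
        "expression.tsv,truth_labels.json,truth_bias.tsv}")
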