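#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Two datasets are produced: (a) a cryosection series of 3 replicate trees
# with 6 planted developmental clusters plus a noise pool, and (b) a
# two-species regulatory-module pair (5 seed hubs, 8 targets each, 1 seed
# rewired in species B) at expression-atlas depth. Everything downstream
# reads only the files written here.

suppressPackageStartupMessages(library(xylemnet))

seed <- 1
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(rng_seed = seed)
sim <- simulate_series(cfg)
write_expression_tsv(sim$matrix, "results/data/series_counts.tsv")

ann <- data.frame(gene_id = names(sim$truth$cluster_label),
                  is_tf = names(sim$truth$cluster_label) %in% sim$truth$tf_genes,
                  cluster = unname(sim$truth$cluster_label))
write_gene_annotation(ann, "results/data/gene_annotation.tsv")
write_gmt(gene_set_collection(sim$truth$gene_sets,
                              names(sim$truth$cluster_label)),
          "results/data/gene_sets.gmt")

pair_cfg <- simulation_config(n_genes = 300, n_trees = 5,
                              samples_per_tree = rep(18, 5),
                              peak_width = 0.10, amplitude = 600,
                              nb_dispersion = 0.05, rng_seed = seed)
sp <- simulate_species_pair(pair_cfg, n_seeds = 5, n_targets_per_seed = 8,
                            n_diverged = 1)
write_expression_tsv(sp$matrix_a, "results/data/species_a_counts.tsv")
write_expression_tsv(sp$matrix_b, "results/data/species_b_counts.tsv")
write_orthologs(sp$truth$orthologs, "results/data/orthologs.tsv")
write.table(sp$truth$seeds, "results/data/pair_seeds.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sp$truth$module_edges, "results/data/pair_module_edges.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("series: %d genes x %d samples (%d noise genes)\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            sum(sim$truth$cluster_label == "z")))
cat(sprintf("pair:   %d genes x %d samples per species, diverged seed: %s\n",
            nrow(sp$matrix_a$values), ncol(sp$matrix_a$values),
            sp$truth$seeds$seed_a[sp$truth$seeds$diverged]))
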