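#!/usr/bin/env Rscript
# Stage 4: network centralities over the largest sub-network.
#
# Degree, betweenness, farness/closeness and average neighbour degree per
# gene, with rank orders (rank 1 = most central) used to shortlist candidate
# regulators.

suppressPackageStartupMessages(library(xylemnet))

vf <- read_expression_tsv("results/vst_expressed.tsv", "vst")
net <- read_network("results/network_edges.tsv",
                    vertices = gene_ids(vf), threshold = 5)
sub <- largest_subnetwork(net)
tab <- centralities(sub)
write.table(tab, "results/centrality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top_deg <- rank_table(tab, "degree")[1:5]
top_btw <- rank_table(tab, "betweenness")[1:5]
cat("top degree genes:     ", paste(top_deg, collapse = ", "), "\n")
cat("top betweenness genes:", paste(top_btw, collapse = ", "), "\n")
cat(sprintf("degree sum = %d = 2 x %d edges\n", sum(tab$degree),
            igraph::ecount(sub)))
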