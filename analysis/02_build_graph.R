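#!/usr/bin/env Rscript
# Quantify the simulated panel assays, prune poor performers, build the
# cross-reactivity matrix G and the directed antibody graph.
# Input:  results/panel_spots/*.tsv (from 01_simulate_panel.R)
# Output: results/xreact_matrix.tsv, results/antibody_graph.{tsv,graphml}

library(fsmi)

config <- pipeline_config()
files <- list.files("results/panel_spots", full.names = TRUE)
stopifnot(length(files) > 0)

assays <- lapply(files, function(f) summarize_replicates(read_spot_table(f)))
names(assays) <- sub("\\.tsv$", "", basename(files))
assays <- assays[intersect(reference_antibodies(), names(assays))]

retained <- prune_antibodies(assays, multiplier = config$multiplier)
mat <- build_matrix(assays[retained], multiplier = config$multiplier,
                    weak_link_floor = config$weak_link_floor)
graph <- build_graph(mat)

write_matrix(mat, "results/xreact_matrix.tsv")
write_edge_list(graph, "results/antibody_graph.tsv")
write_graphml(graph, "results/antibody_graph.graphml")

cat(sprintf("retained %d of %d antibodies after pruning\n",
            length(retained), length(assays)))
cat(sprintf("antibody graph: %d nodes, %d links; %d type A, %d type B\n",
            nrow(graph$nodes), graph$l, sum(graph$nodes$type == "A"),
            sum(graph$nodes$type == "B")))
cat(sprintf("max |G - reference topology| = %.2e\n",
            max(abs(mat$G - reference_matrix()$G))))
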