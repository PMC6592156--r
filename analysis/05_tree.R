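#!/usr/bin/env Rscript
# Stage 5: minimum spanning tree of the AAindex properties.
#
# Builds the complete similarity graph over the 544 amino-acid indices
# (edge weight 1 - |Pearson r| between the 20-residue value vectors),
# extracts the Kruskal minimum spanning tree with deterministic
# tie-breaking, annotates each node with its six-group category and its
# dispersion-lessening result, and exports GraphML / DOT / TSV for
# visualisation.

# run from the repository root: Rscript analysis/05_tree.R
source("analysis/00_config.R")

indices <- study_indices()
graph <- build_mst(indices)
message(sprintf("property MST: %d nodes, %d edges, total weight %.2f",
                nrow(graph$nodes), nrow(graph$edges), graph$total_weight))

for (axis in c("temperature", "pH")) {
  out <- axis_dir(axis)
  scan <- data.table::fread(file.path(out, "enrichment.tsv"))
  g <- annotate_graph(graph, scan, q_threshold = Q_THRESHOLD)
  export_property_graph(g, file.path(out, "tree.graphml"), "graphml")
  export_property_graph(g, file.path(out, "tree.dot"), "dot")
  export_property_graph(g, file.path(out, "tree_edges.tsv"), "edgelist")
  n_dir <- table(g$nodes$direction)
  message(sprintf("[%s] node colouring: %s", axis,
                  paste(names(n_dir), as.integer(n_dir), sep = "=",
                        collapse = ", ")))
}
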