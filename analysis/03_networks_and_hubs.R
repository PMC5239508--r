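#!/usr/bin/env Rscript
# Disease network construction (median combined-score threshold over the
# DEG-restricted interactions) and first-stage hub selection, then the
# topological profile of the network.

library(herbnet)

edges <- read_edge_tsv("results/scenario/edges.tsv")
dm <- read_deg_tsv("results/deg/model_vs_control.tsv")
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

dnet <- build_network(deg_genes(dm), edges)
cat(sprintf("disease network: %d nodes, %d edges (score threshold %.1f)\n",
            length(dnet$nodes), nrow(dnet$edges),
            attr(dnet, "score_threshold")))
write_edge_tsv(dnet, "results/network/disease_network.tsv")

topo <- compute_topology(dnet)
write_topology_tsv(topo, "results/network/disease_topology.tsv")

hubs <- select_hubs(topo, multiplier = 2)
cat(sprintf("hub genes (degree > 2 x median %.1f): %d\n",
            hubs$criterion$median_degree, length(hubs$hub_ids)))
writeLines(hubs$hub_ids, "results/network/disease_hub_genes.txt")

# how much of the planted module did the degree rule keep?
truth <- read_ground_truth("results/scenario/ground_truth.json")
cat(sprintf("planted module genes among hubs: %d / %d\n",
            length(intersect(hubs$hub_ids, truth$planted_hub_genes)),
            length(truth$planted_hub_genes)))
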