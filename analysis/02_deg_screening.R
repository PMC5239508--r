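#!/usr/bin/env Rscript
# Differential-expression screening of the four study contrasts
# (disease vs control, treatment vs disease, and the two deleted-herb arms
# vs the full formula), plus the clustering / PCA quality checks on the
# disease-contrast DEGs.

library(herbnet)

expr <- read_expression_tsv("results/scenario/expression.tsv",
                            "results/scenario/arm_map.tsv")
dir.create("results/deg", showWarnings = FALSE, recursive = TRUE)

contrasts <- list(model_vs_control = c("model", "control"),
                  full_vs_model = c("full", "model"),
                  minus_a_vs_full = c("minus_a", "full"),
                  minus_b_vs_full = c("minus_b", "full"))
for (name in names(contrasts)) {
  ct <- contrasts[[name]]
  st <- screen_degs(compute_gene_stats(expr, ct[1], ct[2]),
                    lfc_threshold = 0.5, p_threshold = 0.05)
  write_deg_tsv(st, file.path("results/deg", paste0(name, ".tsv")))
  cat(sprintf("%-18s up %4d  down %4d\n", name,
              attr(st, "n_up"), attr(st, "n_down")))
}

# QC: do disease and control samples separate on the dysregulated genes?
dm <- read_deg_tsv("results/deg/model_vs_control.tsv")
degs <- deg_genes(dm)
keep <- names(expr$arms)[expr$arms %in% c("model", "control")]
sub <- expression_matrix(expr$values[, keep], expr$arms[keep])
hc <- cluster_samples(sub, degs)
cl <- cut_sample_clusters(hc, sub, k = 2)
write.table(cl, "results/deg/sample_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
pc <- pca_samples(sub, degs)
scores <- data.frame(sample_id = rownames(pc$scores), pc$scores,
                     arm = sub$arms[rownames(pc$scores)])
write.table(scores, "results/deg/sample_pca.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nclusters pure by arm at k=2: %s;  PC1 variance %.1f%%\n",
            all(tapply(cl$arm, cl$cluster,
                       function(a) length(unique(a)) == 1)),
            100 * pc$var_explained[1]))
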