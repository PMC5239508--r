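#!/usr/bin/env Rscript
# Chemical-similarity target transfer: compounds inherit the annotated
# targets of reference drugs whose fingerprints they match at Tanimoto >=
# 0.85, aggregated per herb and for the whole formula.

library(herbnet)

fps <- read_fingerprint_tsv("results/scenario/fingerprints.tsv")
ref <- read_reference_drug_tsv("results/scenario/reference_drugs.tsv")
dir.create("results/targets", showWarnings = FALSE, recursive = TRUE)

preds <- predict_compound_targets(fps, ref, threshold = 0.85)
write.table(preds, "results/targets/predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d predictions from %d compounds x %d reference drugs\n",
            nrow(preds), nrow(fps), nrow(ref)))

prof <- herb_target_profile(preds, setNames(fps$herb_id, fps$compound_id))
write.table(prof$counts, "results/targets/herb_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(prof$formula_targets, "results/targets/formula_targets.txt")
cat(sprintf("formula-level putative targets: %d\n",
            length(prof$formula_targets)))
print(prof$counts)
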