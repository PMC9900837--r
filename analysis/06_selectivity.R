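#!/usr/bin/env Rscript
## Baseline synapse distribution, shuffle-null Selectivity Index per
## interneuron, compartment-preference variant, and the motif-group
## selectivity matrix.
library(columncensus)

bundle <- read_bundle("results/column_bundle")
run_pipeline(bundle, "results/pipeline",
             config = list(seed = 1, apical = "truth", n_shuffles = 1000),
             stages = "selectivity")

si <- read.csv("results/pipeline/selectivity.csv")
cat("SI rows:", nrow(si), " significant:", sum(si$significant), "\n")
cat("SI distribution over (interneuron, M-type) pairs:\n")
print(summary(si$si[is.finite(si$si)]))

bud <- read.csv("results/pipeline/budgets.csv")
groups <- setNames(bud$motif_group, bud$cell_id)
gm <- group_selectivity_matrix(si, groups)
write.csv(gm$median_si, "results/pipeline/group_selectivity_matrix.csv")
cat("Motif-group median SI (non-significant entries set to 1):\n")
print(round(gm$median_si, 2))
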