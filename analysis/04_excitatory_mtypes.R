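#!/usr/bin/env Rscript
## 29-feature suite per excitatory cell, consensus Leiden clustering into
## M-types, naming by expert labels, and per-M-type feature importance.
library(columncensus)

bundle <- read_bundle("results/column_bundle")
run_pipeline(bundle, "results/pipeline",
             config = list(seed = 1, apical = "truth", n_consensus_runs = 100),
             stages = "mtypes")

mt <- read.csv("results/pipeline/mtypes.csv")
cat("Consensus clusters:", length(unique(mt$cluster)), "\n")
print(table(mtype = mt$mtype))
truth <- bundle$ground_truth$mtype[as.character(mt$cell_id)]
print(table(truth = truth, assigned = mt$mtype))

## feature importances per M-type (one-vs-rest forests with SMOTE balance)
proc <- process_column(bundle, apical = "truth")
fm <- feature_matrix(proc, mt$cell_id)
imp <- mtype_feature_importance(fm$features, mt$mtype, seed = 1)
write.csv(imp, "results/pipeline/mtype_feature_importance.csv")
top <- apply(imp, 1, function(r) colnames(imp)[order(-r)[1:3]])
cat("Top-3 features per M-type:\n")
print(t(top))
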