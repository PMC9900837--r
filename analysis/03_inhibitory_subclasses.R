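#!/usr/bin/env Rscript
## Six targeting features per interneuron, linear-discriminant subclass
## assignment, InhTC subtyping, and the subclass-level connectivity matrix.
library(columncensus)

bundle <- read_bundle("results/column_bundle")
run_pipeline(bundle, "results/pipeline",
             config = list(seed = 1, apical = "truth"),
             stages = "subclasses")

sc <- read.csv("results/pipeline/subclasses.csv")
truth <- bundle$ground_truth$subclass[as.character(sc$cell_id)]
cat("Subclass assignment vs planted truth:\n")
print(table(truth = truth, assigned = sc$assigned_subclass))
cat("InhTC subtypes:\n")
print(table(sc$inhtc_subtype, useNA = "ifany"))

## inhibition-of-inhibition matrix (mean synapses per postsynaptic cell)
ann <- read.csv("results/pipeline/synapse_annotations.csv")
subclass <- setNames(sc$assigned_subclass, sc$cell_id)
syn_ii <- ann[!is.na(ann$pre_cell) & ann$post_class == "inhibitory", ]
m <- subclass_connectivity_matrix(subclass, syn_ii)
write.csv(m, "results/pipeline/subclass_connectivity_matrix.csv")
cat("Subclass connectivity matrix (pre x post, mean synapses/target):\n")
print(round(m, 2))
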