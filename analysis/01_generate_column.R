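#!/usr/bin/env Rscript
## Build the default synthetic cortical column (8 excitatory M-types across
## layers 2-6, four inhibitory subclasses with planted targeting rules) and
## write it as a standard bundle with its planted ground truth.
library(columncensus)

spec <- column_spec(seed = 1)
bundle <- generate_column(spec)
write_bundle(bundle, "results/column_bundle")

cells <- bundle$cells
cat("Cells:", nrow(cells), "-",
    sum(cells$coarse_class == "excitatory"), "excitatory,",
    sum(cells$coarse_class == "inhibitory"), "inhibitory\n")
cat("Synapses:", nrow(bundle$synapses),
    "(", sum(!is.na(bundle$synapses$pre_cell)), "inhibitory outputs )\n")
cat("Planted M-types:", paste(names(table(bundle$ground_truth$mtype)), collapse = " "), "\n")
cat("Bundle written to results/column_bundle\n")
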