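#!/usr/bin/env Rscript
## Assemble one machine-readable connectivity card per interneuron from the
## stage artifacts: subclass, morphology summary, compartment histogram,
## output budget, selectivity and compartment preference.
library(columncensus)

bundle <- read_bundle("results/column_bundle")
run_pipeline(bundle, "results/pipeline",
             config = list(seed = 1, apical = "truth"),
             stages = "cards")
cards <- list.files("results/pipeline/cards", full.names = TRUE)
cat("Wrote", length(cards), "connectivity cards\n")
example <- jsonlite::read_json(cards[1], simplifyVector = TRUE)
cat("Example card (cell", example$cell_id, "):",
    example$subclass, "- motif group", example$motif_group, "\n")
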