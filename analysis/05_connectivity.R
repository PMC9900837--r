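#!/usr/bin/env Rscript
## Inhibition-onto-excitation summaries: net input by subclass x M-type,
## connection densities and their correlations, perisomatic/distal balance,
## output budgets and motif groups.
library(columncensus)

bundle <- read_bundle("results/column_bundle")
run_pipeline(bundle, "results/pipeline",
             config = list(seed = 1, apical = "truth", n_consensus_runs = 100),
             stages = "connectivity")

ann <- read.csv("results/pipeline/synapse_annotations.csv")
sc <- read.csv("results/pipeline/subclasses.csv")
mt <- read.csv("results/pipeline/mtypes.csv")
subclass <- setNames(sc$assigned_subclass, sc$cell_id)
mtype <- setNames(mt$mtype, mt$cell_id)
ann$target_class <- ifelse(ann$post_class == "inhibitory", "inhibitory",
                           mtype[as.character(ann$post_cell)])
syn_ie <- ann[!is.na(ann$pre_cell) & ann$post_class == "excitatory", ]

ns <- net_input_summary(syn_ie, subclass, mtype)
write.csv(ns$mean_net, "results/pipeline/net_input_matrix.csv")
cat("Mean net synapses per target cell (subclass x M-type):\n")
print(round(ns$mean_net, 1))

## connection-density correlations within the two dominant subclasses
for (scl in c("PeriTC", "DistTC")) {
  ids <- as.numeric(names(subclass)[subclass == scl])
  if (length(ids) < 3) next
  dens <- density_profile(ids, mtype, syn_ie)
  r <- density_correlation_matrix(dens)
  write.csv(r, sprintf("results/pipeline/density_correlation_%s.csv", scl))
  cat(scl, "mean |r| between M-types:",
      round(mean(abs(r[upper.tri(r)]), na.rm = TRUE), 2), "\n")
}

## perisomatic vs distal input balance per M-type
peri_ids <- names(subclass)[subclass == "PeriTC"]
dist_ids <- names(subclass)[subclass == "DistTC"]
exc_ids <- as.character(mt$cell_id)
count_from <- function(src) {
  s <- syn_ie[as.character(syn_ie$pre_cell) %in% src, ]
  tab <- table(factor(as.character(s$post_cell), levels = exc_ids))
  setNames(as.numeric(tab), exc_ids)
}
## restrict to M-types with enough cells for a stable correlation
big <- names(which(table(mtype) >= 5))
mt_big <- mtype[mtype %in% big]
pb <- peri_dist_balance(count_from(peri_ids)[names(mt_big)],
                        count_from(dist_ids)[names(mt_big)], mt_big)
write.csv(pb, "results/pipeline/peri_dist_balance.csv", row.names = FALSE)
cat("Spearman r of PeriTC vs DistTC input per M-type:\n")
print(pb[, c("mtype", "r", "ci_lower", "ci_upper", "significant")])

## laminar trend of synaptic input (inputs per excitatory cell vs depth)
bundle2 <- read_bundle("results/column_bundle")
exc_cells <- bundle2$cells[bundle2$cells$coarse_class == "excitatory", ]
inputs_per_cell <- table(factor(bundle2$synapses$post_cell,
                                levels = exc_cells$cell_id))
tr <- simple_stats(as.numeric(inputs_per_cell), exc_cells$soma_depth,
                   "spearman_depth")
cat("Spearman r of input count vs soma depth:", round(tr$statistic, 2),
    " p =", signif(tr$p, 2), "\n")

mg <- read.csv("results/pipeline/budgets.csv")
cat("Motif groups:", length(unique(mg$motif_group)), "\n")
print(table(group = mg$motif_group))
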