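## toy output table: one interneuron's synapses with known structure
toy_outputs <- function() {
  data.frame(
    post_cell = c(rep(101:110, each = 1),              # 10 inhibitory targets
                  rep(1:45, each = 2)),                 # 45 two-synapse connections
    post_class = c(rep("inhibitory", 10), rep("excitatory", 90)),
    post_compartment = c(rep("inhibitory", 10),
                         rep("soma", 45), rep("proximal", 18),
                         rep("apical", 9), rep("distal_basal", 18)),
    pre_vertex = 1, x = 0, y = 0, z = 0
  )
}

test_that("targeting feature fractions match hand arithmetic", {
  out <- toy_outputs()
  out$post_cell <- c(101:110, rep(1:90, each = 1)) # make all connections single
  f <- suppressWarnings(targeting_features(out, pre_skeleton = NULL))
  expect_equal(f$frac_inhibitory, 0.10)
  expect_equal(f$frac_soma, 0.50)
  expect_equal(f$frac_proximal, 0.20)
  expect_equal(f$frac_apical, 0.10)
  ## all single-synapse connections: no multisyn, no clumped
  expect_equal(f$frac_multisyn, 0)
  expect_equal(f$frac_clumped, 0)
  expect_error(targeting_features(out[0, ], NULL), "zero output")
})

test_that("clumped fraction uses presynaptic path distance within connections", {
  ## connection with synapses at axon path positions 0, 10, 40 um:
  ## the 0/10 pair is mutually within 15 um, the 40 um synapse is not -> 2/3
  sk <- chain_skeleton(5, spacing = 10) # path positions 0,10,20,30,40
  out <- data.frame(
    post_cell = rep(7, 3), post_class = "excitatory",
    post_compartment = "distal_basal",
    pre_vertex = c(1, 2, 5), x = 0, y = 0, z = 0)
  f <- targeting_features(out, sk)
  expect_equal(f$frac_multisyn, 1)
  expect_equal(f$frac_clumped, 2 / 3)
  ## threshold monotonicity on the same connection
  f5 <- targeting_features(out, sk, clump_threshold = 5)
  f40 <- targeting_features(out, sk, clump_threshold = 40)
  expect_lte(f5$frac_clumped, f$frac_clumped)
  expect_lte(f$frac_clumped, f40$frac_clumped)
})

test_that("LDA recovers planted subclasses and flags degenerate input", {
  ann <- small_annotated()
  b <- small_bundle()
  proc <- small_processed()
  inh <- b$cells$cell_id[b$cells$coarse_class == "inhibitory"]
  feats <- do.call(rbind, lapply(inh, function(id) {
    s <- ann[!is.na(ann$pre_cell) & ann$pre_cell == id, ]
    if (nrow(s) == 0) return(NULL)
    cbind(cell_id = id, targeting_features(s, proc$skeletons[[as.character(id)]]))
  }))
  expert <- stats::setNames(b$cells$expert_subclass, b$cells$cell_id)
  fit <- fit_and_assign_subclasses(feats, expert)
  truth <- b$ground_truth$subclass[as.character(fit$assignments$cell_id)]
  ## small column: 17 interneurons; the full-size recovery criterion is
  ## checked at acceptance scale
  expect_gte(mean(fit$assignments$assigned_subclass == truth), 0.9)
  ## duplicated feature rows predict the same class
  pred1 <- fit$assignments$assigned_subclass[1]
  dup <- feats[c(1, 1), ]
  dup$cell_id <- c(900, 901)
  lab2 <- expert
  fit2 <- fit_and_assign_subclasses(rbind(feats, dup), expert)
  p <- fit2$assignments
  expect_equal(p$assigned_subclass[p$cell_id == 900], p$assigned_subclass[p$cell_id == 901])
  ## constant features across classes -> informative error
  const <- feats
  const[c("frac_inhibitory", "frac_soma", "frac_proximal", "frac_apical",
          "frac_multisyn", "frac_clumped")] <- 0.5
  expect_error(fit_and_assign_subclasses(const, expert), "degenerate|constant")
})

test_that("subclass connectivity matrix equals a brute-force group-by", {
  subclass <- stats::setNames(c("PeriTC", "PeriTC", "DistTC", "DistTC", "InhTC"), 1:5)
  ## 2 PeriTCs send 3 and 5 synapses to the first of two DistTCs
  syn <- data.frame(pre_cell = c(rep(1, 3), rep(2, 5), rep(5, 4)),
                    post_cell = c(rep(3, 8), rep(4, 4)))
  m <- subclass_connectivity_matrix(subclass, syn)
  expect_equal(m["PeriTC", "DistTC"], (8 + 0) / 2)
  expect_equal(m["InhTC", "DistTC"], 4 / 2)
  expect_equal(m["DistTC", "PeriTC"], 0)
  ## no synapses -> zero matrix
  m0 <- subclass_connectivity_matrix(subclass, syn[0, ])
  expect_true(all(m0 == 0))
  ## brute-force oracle on a random toy table
  set.seed(8)
  syn2 <- data.frame(pre_cell = sample(1:5, 12, TRUE), post_cell = sample(1:5, 12, TRUE))
  m2 <- subclass_connectivity_matrix(subclass, syn2)
  for (pre in rownames(m2)) for (post in colnames(m2)) {
    cells_post <- names(subclass)[subclass == post]
    per_cell <- vapply(cells_post, function(cc) {
      sum(subclass[as.character(syn2$pre_cell)] == pre & syn2$post_cell == as.numeric(cc))
    }, numeric(1))
    expect_equal(unname(m2[pre, post]), mean(per_cell))
  }
  ## totals invariant: sum(entry * n_post) = total synapse count
  n_post <- table(subclass)[colnames(m2)]
  expect_equal(sum(sweep(m2, 2, as.numeric(n_post), "*")), nrow(syn2))
})

test_that("InhTC subtyping follows the dominant target share with tie rule", {
  subclass <- stats::setNames(c(rep("DistTC", 3), rep("PeriTC", 3), "InhTC", "InhTC", "InhTC"), 1:9)
  syn <- data.frame(
    pre_cell = c(rep(7, 10), rep(8, 10), rep(9, 4)),
    post_cell = c(sample(1:3, 10, TRUE)[1:7], 4, 4, 4,     # cell 7: mostly DistTC
                  rep(4:6, length.out = 9), 1,             # cell 8: mostly PeriTC
                  1, 2, 4, 5))                             # cell 9: 2/2 tie
  expect_warning(sp <- split_inhtc(c(7, 8, 9), syn, subclass), "tie")
  expect_equal(sp$subtype[sp$cell_id == 7], "InhTC_Dist")
  expect_equal(sp$subtype[sp$cell_id == 8], "InhTC_Peri")
  expect_equal(sp$subtype[sp$cell_id == 9], "InhTC_Dist")
  ## planted subtype recovery on the synthetic column
  b <- small_bundle()
  ann <- small_annotated()
  truth_sub <- b$ground_truth$subclass
  inhtc <- as.numeric(names(truth_sub)[!is.na(truth_sub) & truth_sub == "InhTC"])
  syn_ii <- ann[ann$post_class == "inhibitory" & !is.na(ann$pre_cell), ]
  sp2 <- split_inhtc(inhtc, syn_ii, truth_sub)
  expect_equal(stats::setNames(sp2$subtype, sp2$cell_id),
               b$ground_truth$inhtc_subtype[as.character(sp2$cell_id)])
})

test_that("connection property comparison reports medians, CIs and t-tests", {
  set.seed(11)
  ## identical groups: p ~ 1, CIs overlap
  g <- data.frame(size = rnorm(60, 100, 5), connection = rep(1:20, 3))
  same <- connection_property_comparison(g, g)
  expect_gt(same$size_test$p, 0.95)
  ## connections {4,4,4} vs {1,1,1}: means 4 vs 1, significant difference
  a <- data.frame(size = rnorm(12, 100, 1), connection = rep(1:3, each = 4))
  bb <- data.frame(size = rnorm(3, 100, 1), connection = 1:3)
  ## per-connection counts are constant in both groups (4,4,4 vs 1,1,1):
  ## zero pooled variance, so the count test is degenerate and omitted
  cmp <- connection_property_comparison(a, bb)
  expect_equal(cmp$group_a$mean_syn_per_conn, 4)
  expect_equal(cmp$group_b$mean_syn_per_conn, 1)
  ## jittered counts around 4 vs 1 give p < 0.01
  a2 <- data.frame(size = rnorm(17, 100, 1),
                   connection = rep(1:4, c(4, 4, 4, 5)))
  b2 <- data.frame(size = rnorm(5, 100, 1), connection = c(1, 1, 2, 3, 4))
  cmp2 <- connection_property_comparison(a2, b2)
  expect_lt(cmp2$count_test$p, 0.01)
  expect_error(connection_property_comparison(a[0, ], bb), "non-empty")
})
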