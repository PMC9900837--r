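test_that("soma collapse merges in-radius connected vertices into the root", {
  ## V = (4 pi / 3) 10^3 -> effective radius 10, padded to 12.5
  V <- 4 * pi / 3 * 1000
  sk <- chain_skeleton(6, spacing = 6.2) # vertices at 0, 6.2, 12.4, 18.6, ...
  res <- collapse_soma(sk, V)
  ## 6.2 and 12.4 are within 12.5 and connected through in-radius vertices
  expect_equal(unname(res$vertex_map[c("1", "2", "3")]), c(1, 1, 1))
  expect_equal(unname(res$vertex_map["4"]), 4) # 18.6 um: kept
  expect_equal(res$skeleton$n, 4)
  ## vertex Euclidean-close to the soma but connected only via a long
  ## out-of-radius path is NOT merged
  looped <- skeleton(data.frame(
    vertex_id = 1:5,
    x = c(0, 20, 40, 20, 5), y = c(0, 0, 10, 20, 2), z = 0, radius = 1,
    parent = c(NA, 1, 2, 3, 4), label = c("soma", rep("dendrite", 4))))
  res2 <- collapse_soma(looped, V) # vertex 5 is ~5.4 um from soma
  expect_equal(unname(res2$vertex_map["5"]), 5)
})

test_that("synapse flow centrality matches exhaustive pair-path enumeration", {
  ## chain with 2 inputs left of middle, 3 outputs right: middle sees all 6 pairs
  sk <- chain_skeleton(5)
  cent <- synapse_flow_centrality(sk, c(1, 2), c(4, 5, 5))
  expect_equal(cent[3], 6)
  ## vertex distal to all synapses has zero centrality
  sk2 <- chain_skeleton(6)
  expect_equal(synapse_flow_centrality(sk2, 2, 4)[6], 0)
  expect_error(synapse_flow_centrality(sk, integer(0), 1), "cannot split")
  ## oracle equivalence on random trees
  for (seed in 1:8) {
    n <- sample(20:200, 1)
    sk <- random_tree_skeleton(n, seed + 100)
    inputs <- sample(n, 8, replace = TRUE)
    outputs <- sample(n, 7, replace = TRUE)
    expect_equal(synapse_flow_centrality(sk, inputs, outputs),
                 brute_force_flow_centrality(sk, inputs, outputs))
  }
})

test_that("segregation index hits its limits and the hand-computed case", {
  sk <- y_skeleton(5, 5)
  up <- 7:11; down <- 12:16 # the two branch arms
  ## perfect segregation
  seg1 <- segregation_index(sk, 7, rep(up, 2), rep(down, 2))
  expect_equal(seg1$index, 1)
  ## both parts 50/50 -> 0
  seg0 <- segregation_index(sk, 7, c(up, down), c(up, down))
  expect_equal(seg0$index, 0)
  ## 9/1 vs 1/9 (N = 20): 1 - H(0.1)/H(0.5)
  inputs <- c(rep(up[1], 9), down[1])
  outputs <- c(up[1], rep(down[1], 9))
  seg <- segregation_index(sk, 7, inputs, outputs)
  H <- function(p) -p * log(p) - (1 - p) * log(1 - p)
  expect_equal(seg$index, 1 - H(0.1) / H(0.5), tolerance = 1e-12)
  expect_error(segregation_index(sk, 7, integer(0), integer(0)), "no synapses")
})

test_that("axon detection recovers the planted subtree and applies the fallback", {
  ## perfectly segregated mixed neuron: recovered set equals planted set
  mx <- generate_mixed_neuron(100, 100, epsilon = 0, seed = 2)
  ax <- detect_axon(mx$skeleton, mx$input_vertices, mx$output_vertices, "inhibitory")
  expect_setequal(ax$axon_vertex_ids, mx$axon_vertex_ids)
  expect_equal(ax$method, "flow_centrality")
  ## slightly mixed excitatory neuron above the segregation gate keeps the split
  mx2 <- generate_mixed_neuron(150, 150, epsilon = 0.02, seed = 3)
  ax2 <- detect_axon(mx2$skeleton, mx2$input_vertices, mx2$output_vertices, "excitatory")
  expect_gte(ax2$segregation, 0.7)
  expect_equal(ax2$method, "flow_centrality")
  ## density fallback: the branch downstream of the 30 um perisomatic region
  ## with ~0.05 inputs/um is axonal; its densely innervated mirror is kept
  sk <- y_skeleton(2, 5, spacing = 5) # diagonal arms, ~21 um beyond 30 um region
  up <- 4:8; down <- 9:13
  ax3 <- detect_axon(sk, input_vertices = c(up[3], down),
                     output_vertices = integer(0), coarse_class = "excitatory")
  expect_equal(ax3$method, "density_fallback")
  expect_true(all(6:8 %in% ax3$axon_vertex_ids))     # bare branch: 1 input
  expect_false(any(down %in% ax3$axon_vertex_ids))   # dense branch kept
  ## inhibitory cell without outputs is flagged with an empty axon
  ax4 <- detect_axon(sk, up, integer(0), "inhibitory")
  expect_true(ax4$flagged)
  expect_length(ax4$axon_vertex_ids, 0)
})

test_that("false-merge pruning iterates to a fixed point", {
  ## terminal 30 um segment with no inputs is pruned; with 10 inputs kept
  sk <- y_skeleton(5, 3, spacing = 10)
  up <- 7:9; down <- 10:12
  inputs <- c(rep(2:6, 2), rep(down, 4)) # trunk and lower arm dense, upper arm bare
  pruned <- prune_false_merges(sk, inputs)
  expect_setequal(pruned, up)
  ## pruning a bare terminal segment exposes a bare parent segment,
  ## which is pruned on the next iteration
  verts <- data.frame(
    vertex_id = 1:16,
    x = c(0, 10, 20, 30,           # trunk to branch point 4
          rep(30, 5),              # dense arm 5:9 (along +y)
          40, 50, 60,              # bare interior segment 10:12
          70, 80, 90,              # bare terminal chain 13:15
          60),                     # bare terminal stub 16
    y = c(rep(0, 4), 10 * (1:5), rep(0, 6), 10),
    z = 0, radius = 1,
    parent = c(NA, 1, 2, 3, 4, 5, 6, 7, 8, 4, 10, 11, 12, 13, 14, 12),
    label = c("soma", rep("dendrite", 15)))
  sk2 <- skeleton(verts)
  inputs2 <- rep(c(2:4, 5:9), 3) # trunk and arm dense; 10:16 bare
  pruned2 <- prune_false_merges(sk2, inputs2)
  expect_setequal(pruned2, 10:16)
  ## idempotent at the fixed point
  sk2$vertices$label[match(pruned2, sk2$vertices$vertex_id)] <- "pruned"
  expect_length(prune_false_merges(sk2, inputs2), 0)
})

test_that("apical vertex features follow the stated conventions", {
  g <- column_geometry()
  ## straight vertical ascending branch: tortuosity 1, angle 0
  sk <- skeleton(data.frame(vertex_id = 1:5, x = 0, y = seq(500, 420, by = -20),
                            z = 0, radius = 1, parent = c(NA, 1:4),
                            label = c("soma", rep("dendrite", 4))))
  f <- vertex_apical_features(sk, g)
  expect_equal(f$tortuosity, rep(1, 5), tolerance = 1e-9)
  expect_equal(f$angle_to_vertical, rep(0, 5), tolerance = 1e-9)
  ## root conventions
  expect_equal(f$path_dist_to_soma[1], 0)
  ## 30 um lateral, 40 um above the soma: Euclidean 50, radial 30, angle 36.87
  sk2 <- skeleton(data.frame(vertex_id = 1:2, x = c(0, 30), y = c(500, 460),
                             z = 0, radius = 1, parent = c(NA, 1),
                             label = c("soma", "dendrite")))
  f2 <- vertex_apical_features(sk2, g)
  expect_equal(f2$euclidean_dist[2], 50)
  expect_equal(f2$radial_dist[2], 30)
  expect_equal(f2$angle_to_vertical[2], atan2(30, 40) * 180 / pi, tolerance = 1e-9)
  expect_equal(f2$depth_diff[2], -40)
})

test_that("apical branch scoring aggregates log-odds with clipping and soft-max", {
  ## two 120 um branches off the root with per-vertex probabilities that
  ## aggregate to R = 50 and R = -10
  two_branch <- function() {
    skeleton(data.frame(
      vertex_id = 1:25,
      x = c(0, 10 * (1:12), -10 * (1:12)),
      y = 0, z = 0, radius = 1,
      parent = c(NA, 1, 2:12, 1, 14:24),
      label = c("soma", rep("dendrite", 24))))
  }
  sk <- two_branch()
  p <- rep(0.5, 25)
  p[2:13] <- stats::plogis(50 / 12)
  p[14:25] <- stats::plogis(-10 / 12)
  sc <- score_apical_branches(sk, p)
  expect_equal(sort(sc$R), c(-10, 50), tolerance = 1e-6)
  s1 <- exp(1) / (exp(1) + exp(-0.2))
  expect_equal(max(sc$S), s1, tolerance = 1e-6)
  expect_equal(sc$qualifies, sc$R > 0)
  ## saturation at +/- 200: raw sum 300 clips
  p2 <- p; p2[2:13] <- stats::plogis(300 / 12)
  sc2 <- score_apical_branches(sk, p2)
  expect_equal(max(sc2$R), 200)
  ## four equal branches: S = 0.25 each, strict inequality -> no apicals
  sk4 <- skeleton(data.frame(
    vertex_id = 1:41,
    x = c(0, as.vector(vapply(1:4, function(k) cos(k) * seq(10, 100, 10), numeric(10)))),
    y = c(0, as.vector(vapply(1:4, function(k) sin(k) * seq(10, 100, 10), numeric(10)))),
    z = 0, radius = 1,
    parent = c(NA, as.vector(vapply(0:3, function(k) c(1, 10 * k + 2:10), numeric(10)))),
    label = c("soma", rep("dendrite", 40))))
  p4 <- rep(stats::plogis(100 / 10), 41)
  sc4 <- score_apical_branches(sk4, p4)
  expect_equal(sc4$S, rep(0.25, 4), tolerance = 1e-9)
  expect_false(any(sc4$qualifies))
  ## branches shorter than 50 um are excluded entirely
  sc5 <- score_apical_branches(chain_skeleton(4, spacing = 10), rep(0.9, 4))
  expect_false(any(sc5$qualifies))
})

test_that("compartment assignment partitions dendritic vertices at 50 um", {
  sk <- chain_skeleton(13, spacing = 10) # path distances 0..120
  sk2 <- assign_compartments(sk, apical_branch_roots = integer(0))
  comp <- sk2$vertices$compartment
  expect_equal(comp[1], "soma")
  expect_true(all(comp[2:6] == "proximal"))   # 10..50 um inclusive
  expect_true(all(comp[7:13] == "distal_basal"))
  ## with an apical branch: beyond-proximal vertices on it become apical
  sk3 <- assign_compartments(sk, apical_branch_roots = 2)
  expect_true(all(sk3$vertices$compartment[7:13] == "apical"))
  expect_true(all(sk3$vertices$compartment[2:6] == "proximal"))
  ## synapses inherit their vertex compartment; boundary at exactly 50 um
  expect_equal(synapse_compartments(sk3, c(1, 6, 7)),
               c("soma", "proximal", "apical"))
})

test_that("planted apical branches are recovered by the trained vertex model", {
  b <- small_bundle()
  model <- train_apical_model_on_bundle(b, training_cells = 24, seed = 2)
  gt <- b$ground_truth
  exc <- b$cells$cell_id[b$cells$coarse_class == "excitatory"]
  test_ids <- exc[vapply(as.character(exc),
                         function(k) length(gt$apical_roots[[k]]) > 0, logical(1))]
  hits <- 0; total <- 0
  syn <- b$synapses
  for (id in test_ids) {
    key <- as.character(id)
    res <- process_cell(
      b$skeletons[[key]],
      b$cells$nucleus_volume[match(id, b$cells$cell_id)],
      input_vertices = syn$post_vertex[syn$post_cell == id],
      output_vertices = integer(0),
      coarse_class = "excitatory", geometry = b$geometry,
      apical_model = model)
    sc <- res$apical_scores
    found <- sc$branch_root[sc$qualifies]
    ## planted root maps through the soma collapse; compare via subtree overlap
    planted <- gt$apical_roots[[key]]
    sk0 <- b$skeletons[[key]]
    planted_set <- subtree_ids(sk0, planted)
    ok <- length(found) == 1 && found %in% planted_set
    hits <- hits + ok; total <- total + 1
  }
  expect_gte(hits / total, 0.9)
})
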