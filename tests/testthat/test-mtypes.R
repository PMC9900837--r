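test_that("morphology scalars match hand-built dendrites", {
  g <- column_geometry()
  ## straight 100 um vertical dendrite, 50 uniform synapses
  n <- 21
  sk <- skeleton(data.frame(vertex_id = 1:n, x = 0, y = seq(300, 400, by = 5),
                            z = 0, radius = 1, parent = c(NA, 1:(n - 1)),
                            label = c("soma", rep("dendrite", n - 1))))
  syn <- data.frame(post_vertex = rep(2:n, length.out = 50), size = 100,
                    depth = rep(seq(305, 400, by = 5), length.out = 50))
  f <- morphology_feature_suite(sk, syn, g)
  expect_equal(f$total_cable, 100)
  expect_equal(f$tip_dist_median, 100)
  expect_equal(f$tip_tortuosity_median, 1)
  expect_equal(f$linear_density_median, 0.5, tolerance = 0.1)
  expect_equal(f$n_dendritic_inputs, 50)
  ## all synapses the same size: dynamic range 0, medians equal the size
  expect_equal(f$syn_size_dynamic_range, 0)
  expect_equal(f$dend_syn_size_median, 100)
  ## L-shaped branch: 60 um up then 80 um lateral -> tip path 140,
  ## Euclidean 100, tortuosity 1.4
  m <- 12 + 16
  skL <- skeleton(data.frame(
    vertex_id = 1:(1 + m),
    x = c(rep(0, 13), seq(5, 80, by = 5)),
    y = c(seq(300, 240, by = -5), rep(240, 16)),
    z = 0, radius = 1, parent = c(NA, 1:m),
    label = c("soma", rep("dendrite", m))))
  synL <- data.frame(post_vertex = 2:(1 + m), size = 1,
                     depth = depth_of(0, 270, g) + numeric(m))
  fL <- morphology_feature_suite(skL, synL, g)
  expect_equal(fL$tip_dist_median, 140)
  expect_equal(fL$tip_tortuosity_median, 1.4)
  expect_error(morphology_feature_suite(sk, syn[0, ], g), "no input synapses")
})

test_that("depth histogram components have the right shape and invariances", {
  g <- column_geometry()
  set.seed(2)
  ## two planted depth archetypes: shallow vs deep
  depths <- c(lapply(1:12, function(i) runif(200, 100, 200)),
              lapply(1:12, function(i) runif(200, 600, 700)))
  dh <- depth_histogram_components(depths, g)
  expect_equal(dim(dh$scores), c(24, 6))
  expect_equal(rowMeans(dh$histograms), rep(0, 24), tolerance = 1e-10)
  ## the dominant component separates the archetypes perfectly
  s1 <- dh$scores[, 1]
  expect_true(all(s1[1:12] > 0) == all(s1[13:24] > 0) ||
              xor(all(s1[1:12] > 0), all(s1[13:24] > 0)))
  expect_true(max(s1[1:12]) < min(s1[13:24]) || min(s1[1:12]) > max(s1[13:24]))
  expect_error(depth_histogram_components(depths[1:3], g), "at least k")
})

test_that("soma-adjusted components are invariant to depth translation", {
  set.seed(3)
  base <- runif(300, -80, 80)
  depths <- list(400 + base, 650 + base, 400 + runif(300, -80, 0),
                 650 + runif(300, -80, 0), 500 + base, 300 + base)
  soma <- c(400, 650, 400, 650, 500, 300)
  sh <- soma_adjusted_components(depths, soma)
  expect_equal(dim(sh$scores), c(6, 5))
  ## depth-translated copies (same relative profile) get identical histograms
  expect_equal(sh$histograms[1, ], sh$histograms[2, ], tolerance = 1e-10)
  ## above-soma vs below-soma profiles load with opposite signs
  expect_lt(sh$scores[1, 1] * sh$scores[3, 1], 0)
})

test_that("branch-count profile counts connected components per shell", {
  ## unbranched 300 um dendrite -> all 1s
  sk <- chain_skeleton(61, spacing = 5)
  expect_equal(branch_count_profile(sk), rep(1, 10))
  ## bifurcation at 45 um: 1 component at d = 30, 2 from 60 on
  sk2 <- y_skeleton(9, 60, spacing = 5) # trunk 45 um, arms ~424 um
  p2 <- branch_count_profile(sk2)
  expect_equal(p2[1], 1)
  expect_true(all(p2[2:10] == 2))
  ## arbor shorter than 20 um -> all 0s
  sk3 <- chain_skeleton(4, spacing = 5)
  expect_equal(branch_count_profile(sk3), rep(0, 10))
})

test_that("consensus clustering recovers separated blobs deterministically", {
  set.seed(5)
  x <- rbind(matrix(rnorm(20 * 3), 20, 3), matrix(rnorm(20 * 3, 10), 20, 3))
  cc <- consensus_cluster(x, n_runs = 30, seed = 7)
  expect_equal(cc$k, 2)
  expect_equal(mclust::adjustedRandIndex(cc$labels, rep(1:2, each = 20)), 1)
  ## identical cells co-cluster with probability 1
  xd <- x[c(1:20, 1:4, 21:40), ]
  ccd <- consensus_cluster(xd, n_runs = 30, seed = 7)
  expect_true(all(ccd$coclust[1:4, 21:24][cbind(1:4, 1:4)] == 1))
  ## determinism under the same seed
  cc2 <- consensus_cluster(x, n_runs = 30, seed = 7)
  expect_identical(cc$labels, cc2$labels)
  expect_error(consensus_cluster(x, n_runs = 1), "n_runs")
  ## co-clustering matrix is symmetric with unit diagonal
  expect_equal(cc$coclust, t(cc$coclust))
  expect_equal(diag(cc$coclust), rep(1, 40))
})

test_that("cluster naming uses modal expert labels ordered by depth", {
  labels <- rep(1:3, each = 10)
  expert <- c(rep("L4", 7), rep("L5", 3), rep("L4", 6), rep(NA, 4), rep(NA, 10))
  depth <- c(rep(430, 10), rep(380, 10), rep(800, 10))
  nm <- name_and_order_clusters(labels, expert, depth)
  ## two L4 clusters: suffixes by ascending median depth
  expect_equal(unique(nm[labels == 2]), "L4a") # depth 380
  expect_equal(unique(nm[labels == 1]), "L4b") # depth 430
  expect_equal(unique(nm[labels == 3]), "unlabeled_3")
  ## modal tie resolves alphabetically with a warning
  expert2 <- c(rep(c("L4", "L5"), 5), rep("L2", 10), rep("L6", 10))
  expect_warning(nm2 <- name_and_order_clusters(labels, expert2, depth), "tie")
  expect_equal(unique(nm2[labels == 1]), "L4")
})

test_that("feature importances are normalized and identify the informative axis", {
  set.seed(9)
  n <- 60
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  labels <- rep(c("A", "B", "C"), each = n / 3)
  x[labels == "A", 3] <- x[labels == "A", 3] + 8 # only f3 separates A
  imp <- mtype_feature_importance(x, labels, seed = 4)
  expect_equal(unname(rowSums(imp)), rep(1, 3), tolerance = 1e-9)
  expect_equal(names(which.max(imp["A", ])), "f3")
  ## permuted labels: near-uniform importances
  ratios <- vapply(1:5, function(s) {
    set.seed(s + 50)
    impP <- mtype_feature_importance(x, sample(labels), seed = s)
    max(impP["A", ]) / mean(impP["A", ])
  }, numeric(1))
  expect_lt(mean(ratios), 2)
})

test_that("full feature pipeline is invariant to lateral translation", {
  b <- small_bundle()
  proc <- small_processed()
  exc <- utils::head(b$cells$cell_id[b$cells$coarse_class == "excitatory"], 12)
  fm1 <- feature_matrix(proc, exc)
  shifted <- proc
  for (id in as.character(exc)) {
    shifted$skeletons[[id]]$vertices$x <- shifted$skeletons[[id]]$vertices$x + 40
    shifted$skeletons[[id]]$vertices$z <- shifted$skeletons[[id]]$vertices$z - 25
  }
  rows <- shifted$synapses$post_cell %in% exc
  shifted$synapses$x[rows] <- shifted$synapses$x[rows] + 40
  shifted$synapses$z[rows] <- shifted$synapses$z[rows] - 25
  shifted$cells$soma_x <- shifted$cells$soma_x + 40
  fm2 <- feature_matrix(shifted, exc)
  expect_equal(fm1$features, fm2$features, tolerance = 1e-8)
})
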