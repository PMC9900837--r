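test_that("net input summary equals a brute-force group-by and is linear", {
  subclass <- stats::setNames(c("PeriTC", "DistTC"), 101:102)
  mtype <- stats::setNames(c("L2a", "L2a", "L4a"), 1:3)
  syn <- data.frame(pre_cell = c(101, 101, 101, 102, 102, 101, 102, 101, 101, 102),
                    post_cell = c(1, 1, 2, 2, 3, 3, 3, 1, 2, 1))
  ns <- net_input_summary(syn, subclass, mtype)
  for (sc in rownames(ns$mean_net)) for (mt in colnames(ns$mean_net)) {
    cells_mt <- as.numeric(names(mtype)[mtype == mt])
    per_cell <- vapply(cells_mt, function(cc)
      sum(subclass[as.character(syn$pre_cell)] == sc & syn$post_cell == cc), numeric(1))
    expect_equal(unname(ns$mean_net[sc, mt]), mean(per_cell))
  }
  ## totals invariant
  n_tgt <- table(mtype)[colnames(ns$mean_net)]
  expect_equal(sum(sweep(ns$mean_net, 2, as.numeric(n_tgt), "*")), nrow(syn))
  ## doubling every connection doubles all entries
  ns2 <- net_input_summary(rbind(syn, syn), subclass, mtype)
  expect_equal(ns2$mean_net, ns$mean_net * 2)
  ## no synapses -> zeros
  ns0 <- net_input_summary(syn[0, ], subclass, mtype)
  expect_true(all(ns0$mean_net == 0))
})

test_that("connection density counts contacted cells once", {
  syn <- data.frame(pre_cell = rep(9, 7), post_cell = c(1, 1, 1, 1, 1, 2, 3))
  expect_equal(connection_density(9, 1:10, syn), 0.3)
  expect_equal(connection_density(9, 1, syn), 1.0)
  syn2 <- data.frame(pre_cell = rep(9, 5), post_cell = rep(4, 5))
  expect_equal(connection_density(9, 1:10, syn2), 0.1)
  expect_error(connection_density(9, integer(0), syn), "empty M-type")
})

test_that("density correlations flag zero variance and find planted structure", {
  set.seed(12)
  d <- matrix(runif(200 * 4), 200, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  d[, "B"] <- d[, "A"]                  # duplicated column -> r = 1
  d[, "D"] <- 0.9 - 0.8 * d[, "C"] + rnorm(200, 0, 0.02) # anti-correlated
  r <- density_correlation_matrix(d)
  expect_equal(r["A", "B"], 1)
  expect_lt(r["C", "D"], -0.9)
  ## independent random densities: |r| < 0.2 for at least 95 percent of pairs
  d2 <- matrix(runif(200 * 8), 200, 8)
  r2 <- density_correlation_matrix(d2)
  off <- r2[upper.tri(r2)]
  expect_gte(mean(abs(off) < 0.2), 0.95)
  ## zero-variance column reported missing, not propagated
  d3 <- cbind(d[, 1:2], flat = 1)
  r3 <- density_correlation_matrix(d3)
  expect_true(all(is.na(r3[, "flat"])))
  expect_false(anyNA(r3[1:2, 1:2]))
  expect_error(density_correlation_matrix(d[1:2, ]), ">= 3 interneurons")
})

test_that("perisomatic/distal balance detects monotone coupling", {
  mtype <- stats::setNames(rep(c("L2a", "L4a"), each = 10), 1:20)
  peri <- stats::setNames(c(1:10, sample(10)), 1:20)
  dist <- 2 * peri   # perfectly monotone
  pb <- peri_dist_balance(peri, dist, mtype, n_boot = 200)
  expect_equal(pb$r, c(1, 1))
  expect_true(all(pb$significant))
  ## independent counts: CI covers zero most of the time
  set.seed(13)
  cover <- vapply(1:20, function(i) {
    p2 <- stats::setNames(rpois(10, 20), 1:10)
    d2 <- stats::setNames(rpois(10, 20), 1:10)
    row <- peri_dist_balance(p2, d2, stats::setNames(rep("X", 10), 1:10), n_boot = 200)
    row$ci_lower <= 0 && row$ci_upper >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  expect_error(peri_dist_balance(peri[1:4], dist[1:4],
                                 stats::setNames(rep("X", 4), 1:4)),
               "too few cells")
})

test_that("output budgets normalize over excitatory targets only", {
  mtype <- stats::setNames(c(rep("L2a", 3), rep("L3a", 2)), 1:5)
  syn <- data.frame(pre_cell = rep(9, 10),
                    post_cell = c(rep(1, 6), rep(2, 2), 4, 5))
  ## cells 1,2 are L2a (8 synapses), 4,5 are L3a (2 synapses)
  bud <- output_budget(9, syn, mtype)
  expect_equal(unname(bud["L2a"]), 0.8)
  expect_equal(unname(bud["L3a"]), 0.2)
  expect_equal(sum(bud), 1)
  ## adding synapses onto non-excitatory targets leaves the budget unchanged
  syn2 <- rbind(syn, data.frame(pre_cell = 9, post_cell = c(99, 99, 99)))
  expect_equal(output_budget(9, syn2, mtype), bud)
  expect_warning(output_budget(8, syn, mtype), "no excitatory-target")
})

test_that("motif groups recover planted archetypes and reconcile matrices", {
  set.seed(14)
  ## 24 interneurons, two planted targeting archetypes over 4 M-types
  mtype <- stats::setNames(rep(c("L2a", "L3a", "L4a", "L5a"), each = 5), 1:20)
  mtype_depth <- c(L2a = 150, L3a = 250, L4a = 400, L5a = 600)
  rows <- list()
  for (j in 1:24) {
    pre <- 100 + j
    targets <- if (j <= 12) c(rep(1:5, 8), sample(6:10, 5, TRUE))
               else c(rep(16:20, 8), sample(11:15, 5, TRUE))
    rows[[j]] <- data.frame(pre_cell = pre, post_cell = targets)
  }
  syn <- do.call(rbind, rows)
  bud <- output_budget_matrix(101:124, syn, mtype)
  mg <- motif_groups(bud, syn, mtype, mtype_depth, n_runs = 40, knn = 6, seed = 3)
  expect_equal(length(unique(mg$groups)), 2)
  expect_equal(mclust::adjustedRandIndex(mg$groups, rep(1:2, each = 12)), 1)
  ## groups ordered superficial-first by synapse-weighted target depth
  expect_lt(sum(mg$output_fraction["Group1", ] * mtype_depth[colnames(bud)]),
            sum(mg$output_fraction["Group2", ] * mtype_depth[colnames(bud)]))
  ## input-fraction columns sum to 1 over groups for targeted M-types
  hit <- colSums(mg$input_fraction) > 0
  expect_true(all(abs(colSums(mg$input_fraction)[hit] - 1) < 1e-9))
  ## group mean output fractions equal the member means
  for (g in 1:2) {
    members <- names(mg$groups)[mg$groups == g]
    expect_equal(unname(mg$output_fraction[paste0("Group", g), ]),
                 unname(colMeans(bud[members, , drop = FALSE])))
  }
  expect_error(motif_groups(bud[1, , drop = FALSE], syn, mtype, mtype_depth),
               ">= 2 interneurons")
})
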