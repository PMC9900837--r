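## tiny hand-made baseline: 2 depth bins x 1 compartment x 2 classes
toy_baseline <- function(counts) {
  g <- column_geometry()
  syn <- data.frame(
    depth = rep(c(5, 25), times = c(sum(counts[1, ]), sum(counts[2, ]))),
    post_compartment = "distal_basal",
    target_class = c(rep(colnames(counts), counts[1, ]),
                     rep(colnames(counts), counts[2, ])),
    pre_cell = NA)
  build_baseline(syn, g)
}

test_that("baseline binning conserves totals and matches a group-by oracle", {
  g <- column_geometry()
  syn <- data.frame(
    depth = c(5, 15, 25, 35),
    post_compartment = c("soma", "soma", "distal_basal", "distal_basal"),
    target_class = c("L2a", "L2a", "L2a", "inhibitory"),
    pre_cell = NA)
  b <- build_baseline(syn, g)
  expect_equal(sum(b), 4)
  expect_equal(unname(b["1", "soma", "L2a"]), 2)
  expect_equal(unname(b["2", "distal_basal", "L2a"]), 1)
  expect_equal(unname(b["2", "distal_basal", "inhibitory"]), 1)
  ## 3-way group-by oracle on a random toy table
  set.seed(15)
  syn2 <- data.frame(
    depth = runif(200, 0, 1000),
    post_compartment = sample(c("soma", "proximal", "distal_basal"), 200, TRUE),
    target_class = sample(c("L2a", "L4a"), 200, TRUE), pre_cell = NA)
  b2 <- build_baseline(syn2, g)
  expect_equal(sum(b2), 200)
  oracle <- table(depth_bin(syn2$depth, g), syn2$post_compartment, syn2$target_class)
  for (bn in dimnames(oracle)[[1]]) for (cp in dimnames(oracle)[[2]])
    for (cl in dimnames(oracle)[[3]]) {
      expect_equal(unname(b2[bn, cp, cl]), unname(oracle[bn, cp, cl]))
    }
  ## exclusion of designated presynaptic cells
  syn2$pre_cell <- rep(c(NA, 7), 100)
  b3 <- build_baseline(syn2, g, exclude_pre = 7)
  expect_equal(sum(b3), 100)
  syn_bad <- syn; syn_bad$post_compartment[1] <- NA
  expect_error(build_baseline(syn_bad, g), "no compartment")
})

test_that("conditional shuffles are binomial, conserve totals, and are seeded", {
  counts <- matrix(c(500, 500, 300, 100), 2, 2, byrow = TRUE,
                   dimnames = list(NULL, c("A", "B")))
  base <- toy_baseline(counts)
  ## 10 observed synapses in bin 1 (50/50 stratum): counts ~ Binomial(10, .5)
  obs <- data.frame(depth_bin = rep(1, 10), compartment = "distal_basal")
  sh <- shuffle_outputs(obs, base, n_shuffles = 4000, seed = 2)
  expect_equal(stats::median(sh$shuffled["A", ]), 5)
  expect_equal(mean(sh$shuffled["A", ]), 5, tolerance = 0.1)
  expect_equal(stats::sd(sh$shuffled["A", ]), sqrt(10 * 0.25), tolerance = 0.1)
  ## every shuffle redistributes exactly the observed count
  expect_true(all(colSums(sh$shuffled) == 10))
  ## single-class stratum: zero variance
  single <- toy_baseline(matrix(c(100, 0, 100, 0), 2, 2, byrow = TRUE,
                                dimnames = list(NULL, c("A", "B"))))
  sh1 <- shuffle_outputs(obs, single, n_shuffles = 100, seed = 2)
  expect_true(all(sh1$shuffled["A", ] == 10))
  ## determinism
  sh2 <- shuffle_outputs(obs, base, n_shuffles = 50, seed = 9)
  sh3 <- shuffle_outputs(obs, base, n_shuffles = 50, seed = 9)
  expect_identical(sh2$shuffled, sh3$shuffled)
  ## empty stratum is a hard error naming the stratum
  obs_bad <- data.frame(depth_bin = 40, compartment = "distal_basal")
  expect_error(shuffle_outputs(obs_bad, base, 10, 1), "empty baseline stratum")
})

test_that("selectivity index arithmetic, sentinels and p-values", {
  sh <- list(shuffled = matrix(rep(c(15, 0), each = 100), 2, 100, byrow = TRUE,
                               dimnames = list(c("A", "B"), NULL)),
             potential = c(A = TRUE, B = TRUE))
  si <- selectivity_index(c(A = 30, B = 2), sh)
  expect_equal(si$si[si$target_class == "A"], 2)
  ## zero shuffle median with positive observation: infinite sentinel
  expect_true(is.infinite(si$si[si$target_class == "B"]))
  expect_true(all(si$p_adj >= si$p))
  ## single-class baseline, all observed onto it: SI 1, p 1
  shA <- list(shuffled = matrix(10, 1, 200, dimnames = list("A", NULL)),
              potential = c(A = TRUE))
  siA <- selectivity_index(c(A = 10), shA)
  expect_equal(siA$si, 1)
  expect_equal(siA$p, 1)
})

test_that("compartment preference detects planted somatic targeting", {
  g <- column_geometry()
  set.seed(16)
  ## uniform compartment baseline within one class and bin
  syn <- data.frame(
    depth = runif(4000, 0, 40),
    post_compartment = rep(c("soma", "proximal", "distal_basal", "apical"), 1000),
    target_class = "L2a", pre_cell = NA)
  base <- build_baseline(syn, g)
  obs <- data.frame(depth_bin = depth_bin(runif(80, 0, 40), g),
                    compartment = "soma", target_class = "L2a")
  cp <- compartment_preference(obs, base, n_shuffles = 500, seed = 3)
  soma_row <- cp[cp$target_class == "soma", ]
  expect_gt(soma_row$si, 1)
  expect_true(soma_row$significant)
  ## observations matching baseline proportions: all SIs near 1
  obs2 <- data.frame(depth_bin = depth_bin(runif(400, 0, 40), g),
                     compartment = sample(c("soma", "proximal", "distal_basal",
                                            "apical"), 400, TRUE),
                     target_class = "L2a")
  cp2 <- compartment_preference(obs2, base, n_shuffles = 500, seed = 3)
  expect_true(all(abs(cp2$si - 1) < 0.35))
  ## deterministic under a fixed seed
  cp3 <- compartment_preference(obs, base, n_shuffles = 100, seed = 8)
  cp4 <- compartment_preference(obs, base, n_shuffles = 100, seed = 8)
  expect_identical(cp3, cp4)
})

test_that("group selectivity matrix medians with non-significant set to 1", {
  si_tab <- data.frame(
    pre_cell = c(1, 2, 3),
    target_class = "L2a",
    si = c(2.0, 1.8, 0.9),
    significant = c(TRUE, TRUE, FALSE))
  groups <- stats::setNames(c(1, 1, 1), 1:3)
  gm <- group_selectivity_matrix(si_tab, groups)
  expect_equal(unname(gm$median_si["Group1", "L2a"]), 1.8)
  expect_false(gm$nonsignificant["Group1", "L2a"])
  ## all non-significant: median 1, flagged
  si_tab$significant <- FALSE
  gm2 <- group_selectivity_matrix(si_tab, groups)
  expect_equal(unname(gm2$median_si["Group1", "L2a"]), 1)
  expect_true(gm2$nonsignificant["Group1", "L2a"])
  ## infinite sentinels are excluded from the median
  si_tab2 <- data.frame(pre_cell = 1:3, target_class = "L2a",
                        si = c(Inf, 2, 2), significant = TRUE)
  gm3 <- group_selectivity_matrix(si_tab2, groups)
  expect_equal(unname(gm3$median_si["Group1", "L2a"]), 2)
})
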