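## Shared fixtures, built in code. Heavy objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

## simple chain skeleton along +x with unit radius, spacing um apart
chain_skeleton <- function(n, spacing = 10) {
  skeleton(data.frame(
    vertex_id = seq_len(n),
    x = (seq_len(n) - 1) * spacing, y = 0, z = 0, radius = 1,
    parent = c(NA, seq_len(n - 1)),
    label = c("soma", rep("dendrite", n - 1))
  ))
}

## random tree: each vertex's parent drawn among earlier vertices
random_tree_skeleton <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
  skeleton(data.frame(
    vertex_id = seq_len(n),
    x = stats::runif(n, 0, 100), y = stats::runif(n, 0, 100),
    z = stats::runif(n, 0, 100), radius = 1, parent = parent,
    label = c("soma", rep("dendrite", n - 1))
  ))
}

## Y-shaped skeleton: root -> trunk of n1, then two branches of n2 each
y_skeleton <- function(n1 = 5, n2 = 5, spacing = 10) {
  ids <- seq_len(1 + n1 + 2 * n2)
  x <- c(0, seq_len(n1) * spacing,
         n1 * spacing + seq_len(n2) * spacing,
         n1 * spacing + seq_len(n2) * spacing)
  y <- c(rep(0, 1 + n1), seq_len(n2) * spacing, -seq_len(n2) * spacing)
  parent <- c(NA, 1, if (n1 > 1) 1 + seq_len(n1 - 1),
              1 + n1, if (n2 > 1) 1 + n1 + seq_len(n2 - 1),
              1 + n1, if (n2 > 1) 1 + n1 + n2 + seq_len(n2 - 1))
  skeleton(data.frame(vertex_id = ids, x = x, y = y, z = 0, radius = 1,
                      parent = parent,
                      label = c("soma", rep("dendrite", length(ids) - 1))))
}

## vertex ids of the subtree rooted at a given vertex id
subtree_ids <- function(sk, root_id) {
  sk$vertices$vertex_id[columncensus:::subtree_index(
    sk, columncensus:::vertex_index(sk, root_id))]
}

## brute-force flow centrality by explicit pair-path enumeration (igraph)
brute_force_flow_centrality <- function(skel, inputs, outputs) {
  g <- igraph::graph_from_edgelist(
    cbind(which(!is.na(skel$parent_idx)),
          skel$parent_idx[!is.na(skel$parent_idx)]), directed = FALSE)
  g <- igraph::add_vertices(g, skel$n - igraph::vcount(g))
  cent <- numeric(skel$n)
  iin <- match(inputs, skel$vertices$vertex_id)
  iout <- match(outputs, skel$vertices$vertex_id)
  for (a in iin) for (b in iout) {
    p <- as.integer(igraph::shortest_paths(g, a, b)$vpath[[1]])
    cent[p] <- cent[p] + 1
  }
  cent
}

## small default column + processed version, cached (used by several files)
small_spec <- function(seed = 5) {
  column_spec(seed = seed, mtypes = default_mtype_params(8),
              inhibitory = default_inhibitory_params(5, 5, 3, 4))
}

small_bundle <- function() cached("small_bundle", function() generate_column(small_spec()))

small_processed <- function() cached("small_processed", function() {
  process_column(small_bundle(), apical = "truth")
})

small_annotated <- function() cached("small_annotated", function() {
  b <- small_bundle()
  mt <- b$ground_truth$mtype
  annotate_synapses(small_processed(), mtype = mt[!is.na(mt)])
})
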