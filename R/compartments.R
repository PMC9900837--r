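#' Skeleton processing: soma collapse, axon split, pruning, compartments
#'
#' The processing pipeline for each neuron: (1) collapse the soma region
#' into the root vertex, (2) identify the axon with synapse flow
#' centrality (with a density fallback for poorly segregated excitatory
#' cells), (3) prune falsely merged axon fragments from the dendrite,
#' (4) score candidate apical branches, and (5) assign each vertex and
#' synapse to a compartment.
#'
#' @name compartments
NULL

#' Collapse the soma region of a skeleton into the root vertex
#'
#' All vertices within Euclidean radius \code{1.25 * (3 V / 4 pi)^(1/3)}
#' of the soma centroid (the effective nucleus radius padded by a factor
#' 1.25 for lopsided cell bodies) AND connected to the root through
#' in-radius vertices are merged into the root. Children of merged
#' vertices are re-parented to the root.
#'
#' @param skel a \code{skeleton} rooted at the soma centroid
#' @param nucleus_volume nucleus volume in um^3 (> 0)
#' @return list with the collapsed \code{skeleton} and \code{vertex_map},
#'   a named map old vertex_id -> new vertex_id (merged vertices map to
#'   the root id) for re-assigning synapses.
#' @export
collapse_soma <- function(skel, nucleus_volume) {
  stopifnot(nucleus_volume > 0)
  r <- 1.25 * (3 * nucleus_volume / (4 * pi))^(1 / 3)
  v <- skel$vertices
  root <- skel$root
  d <- sqrt((v$x - v$x[root])^2 + (v$y - v$y[root])^2 + (v$z - v$z[root])^2)
  in_radius <- d <= r
  ## flood fill from root through in-radius vertices (topological order works
  ## because parents precede children)
  merged <- logical(skel$n)
  merged[root] <- TRUE
  for (u in skel$topo_order[-1]) {
    p <- skel$parent_idx[u]
    if (in_radius[u] && merged[p]) merged[u] <- TRUE
  }
  vertex_map <- v$vertex_id
  vertex_map[merged] <- v$vertex_id[root]
  names(vertex_map) <- as.character(v$vertex_id)

  keep <- !merged | seq_len(skel$n) == root
  new_v <- v[keep, , drop = FALSE]
  ## re-parent children of merged vertices to root
  pidx <- skel$parent_idx
  new_parent <- v$vertex_id[pidx]
  new_parent[merged[pidx]] <- v$vertex_id[root]
  new_v$parent <- new_parent[keep]
  new_v$parent[new_v$vertex_id == v$vertex_id[root]] <- NA
  new_v$label[new_v$vertex_id == v$vertex_id[root]] <- "soma"
  list(skeleton = skeleton(new_v), vertex_map = vertex_map)
}

#' Synapse flow centrality
#'
#' For each vertex, the number of (input, output) synapse pairs whose
#' tree path passes through it. The maximum marks the axon split point.
#' Computed in O(n) with subtree counts: a pair's path avoids v only if
#' both synapses lie in the same component of the tree minus v.
#'
#' @param skel a \code{skeleton}
#' @param input_vertices,output_vertices vertex ids of input/output
#'   synapses (one entry per synapse; repeats allowed)
#' @return integer vector of centrality per vertex (in vertex table order)
#' @export
synapse_flow_centrality <- function(skel, input_vertices, output_vertices) {
  if (length(input_vertices) == 0 || length(output_vertices) == 0) {
    stop("cannot split: need at least one input and one output synapse")
  }
  n <- skel$n
  in_at <- tabulate(vertex_index(skel, input_vertices), nbins = n)
  out_at <- tabulate(vertex_index(skel, output_vertices), nbins = n)
  I <- sum(in_at); O <- sum(out_at)
  ## subtree sums (children before parents in reverse topological order)
  in_sub <- in_at; out_sub <- out_at
  for (u in rev(skel$topo_order)) {
    p <- skel$parent_idx[u]
    if (!is.na(p)) {
      in_sub[p] <- in_sub[p] + in_sub[u]
      out_sub[p] <- out_sub[p] + out_sub[u]
    }
  }
  cent <- numeric(n)
  for (v in seq_len(n)) {
    ## components of tree \ v: each child subtree, plus the complement above v
    same <- 0
    for (u in skel$children[[v]]) same <- same + in_sub[u] * out_sub[u]
    up_in <- I - in_sub[v]; up_out <- O - out_sub[v]
    same <- same + up_in * up_out
    cent[v] <- I * O - same
  }
  cent
}

#' Entropy-based input/output segregation index at a split vertex
#'
#' The split partitions the arbor into the subtree rooted at
#' \code{split_vertex} (inclusive) and the remainder. For each part with
#' \code{n_i} synapses and input fraction \code{p_i}, the binary entropy
#' \code{H_i = -p ln p - (1-p) ln(1-p)} (with 0 ln 0 = 0) is computed;
#' the index is \code{1 - sum(n_i H_i) / (N H_total)}, clipped to [0, 1].
#' 1 means perfect segregation of inputs and outputs; 0 means both parts
#' mirror the overall input/output mix.
#'
#' @param skel a \code{skeleton}
#' @param split_vertex vertex id of the split
#' @param input_vertices,output_vertices synapse vertex ids
#' @return list: \code{index}, \code{split_vertex}, per-part counts and
#'   entropies.
#' @export
segregation_index <- function(skel, split_vertex, input_vertices, output_vertices) {
  N <- length(input_vertices) + length(output_vertices)
  if (N == 0) stop("no synapses: segregation index undefined")
  sub <- subtree_index(skel, vertex_index(skel, split_vertex))
  inset <- logical(skel$n); inset[sub] <- TRUE
  iin <- inset[vertex_index(skel, input_vertices)]
  iout <- inset[vertex_index(skel, output_vertices)]
  counts <- rbind(
    part_a = c(inputs = sum(iin), outputs = sum(iout)),
    part_b = c(inputs = sum(!iin), outputs = sum(!iout))
  )
  H <- function(in_n, out_n) {
    n <- in_n + out_n
    if (n == 0) return(0)
    p <- in_n / n
    h <- 0
    if (p > 0) h <- h - p * log(p)
    if (p < 1) h <- h - (1 - p) * log(1 - p)
    h
  }
  h_parts <- c(H(counts[1, 1], counts[1, 2]), H(counts[2, 1], counts[2, 2]))
  n_parts <- rowSums(counts)
  h_total <- H(length(input_vertices), length(output_vertices))
  idx <- if (h_total == 0) 0 else 1 - sum(n_parts * h_parts) / (N * h_total)
  list(index = min(max(idx, 0), 1), split_vertex = split_vertex,
       counts = counts, entropy = h_parts, entropy_total = h_total)
}

#' Identify the axon of a processed skeleton
#'
#' Inhibitory cells: split at the maximum synapse flow centrality (ties
#' broken toward the soma) and take the output-rich side as the axon.
#' Excitatory cells: the same split is used only if its segregation
#' index is at least 0.7; otherwise every branch downstream of the
#' 30 um (path distance) perisomatic region with path length > 20 um and
#' input density < 0.1 synapses/um is labeled axonal.
#'
#' @param skel a collapsed \code{skeleton}
#' @param input_vertices,output_vertices synapse vertex ids
#' @param coarse_class "excitatory" or "inhibitory"
#' @param segregation_threshold minimum segregation index to accept the
#'   flow-centrality split on excitatory cells (default 0.7)
#' @param n_axons number of axons to extract for inhibitory cells
#'   (default 1; rerun with the previous axon masked if 2)
#' @return list: \code{axon_vertex_ids}, \code{split_vertex} (NA for the
#'   density fallback), \code{segregation}, \code{method}, \code{flagged}
#'   (TRUE when an inhibitory cell had no outputs and no axon could be
#'   found).
#' @export
detect_axon <- function(skel, input_vertices, output_vertices, coarse_class,
                        segregation_threshold = 0.7, n_axons = 1) {
  if (coarse_class == "inhibitory") {
    if (length(output_vertices) == 0) {
      return(list(axon_vertex_ids = integer(0), split_vertex = NA,
                  segregation = NA, method = "none", flagged = TRUE))
    }
    res <- flow_split(skel, input_vertices, output_vertices)
    axon_ids <- res$axon_vertex_ids
    if (n_axons > 1) {
      keep <- !(skel$vertices$vertex_id %in% axon_ids) | seq_len(skel$n) == skel$root
      sub_v <- skel$vertices[keep, , drop = FALSE]
      ## re-root orphaned parents onto root is not needed: the axon is a
      ## full subtree, so the remainder is still a tree
      skel2 <- skeleton(sub_v)
      in2 <- intersect(input_vertices, sub_v$vertex_id)
      out2 <- setdiff(intersect(output_vertices, sub_v$vertex_id), axon_ids)
      if (length(out2) > 0 && length(in2) > 0) {
        res2 <- flow_split(skel2, in2, out2)
        axon_ids <- union(axon_ids, res2$axon_vertex_ids)
      }
    }
    return(list(axon_vertex_ids = axon_ids, split_vertex = res$split_vertex,
                segregation = res$segregation, method = "flow_centrality",
                flagged = FALSE))
  }
  ## excitatory
  if (length(output_vertices) > 0 && length(input_vertices) > 0) {
    res <- flow_split(skel, input_vertices, output_vertices)
    if (res$segregation >= segregation_threshold) {
      return(list(axon_vertex_ids = res$axon_vertex_ids,
                  split_vertex = res$split_vertex,
                  segregation = res$segregation,
                  method = "flow_centrality", flagged = FALSE))
    }
    seg_val <- res$segregation
  } else {
    seg_val <- NA
  }
  ## density fallback: branches downstream of the 30 um perisomatic region
  axon_idx <- integer(0)
  near <- skel$dist_root <= 30
  starts <- which(!near & near[skel$parent_idx])
  in_count <- tabulate(vertex_index(skel, input_vertices), nbins = skel$n)
  for (s in starts) {
    sub <- subtree_index(skel, s)
    len <- sum(skel$edge_len[sub]) # edge above s included: s's parent is in-region
    n_in <- sum(in_count[sub])
    if (len > 20 && n_in / len < 0.1) axon_idx <- c(axon_idx, sub)
  }
  list(axon_vertex_ids = skel$vertices$vertex_id[unique(axon_idx)],
       split_vertex = NA, segregation = seg_val,
       method = "density_fallback", flagged = FALSE)
}

## split at max flow centrality; axon = output-rich side. The root is not
## an admissible split (its subtree is the whole arbor), so ties among
## maximal vertices are broken toward the soma among non-root vertices.
flow_split <- function(skel, input_vertices, output_vertices) {
  cent <- synapse_flow_centrality(skel, input_vertices, output_vertices)
  cent[skel$root] <- -1
  best <- which(cent == max(cent))
  if (length(best) > 1) best <- best[which.min(skel$dist_root[best])]
  sub <- subtree_index(skel, best)
  inset <- logical(skel$n); inset[sub] <- TRUE
  out_idx <- vertex_index(skel, output_vertices)
  in_idx <- vertex_index(skel, input_vertices)
  n_out <- length(out_idx); n_in <- length(in_idx)
  ## axon = the side where outputs are enriched relative to inputs
  axon_in_subtree <- sum(inset[out_idx]) / n_out >= sum(inset[in_idx]) / n_in
  axon_idx <- if (axon_in_subtree) sub else setdiff(seq_len(skel$n), sub)
  axon_idx <- setdiff(axon_idx, skel$root)
  seg <- segregation_index(skel, skel$vertices$vertex_id[best],
                           input_vertices, output_vertices)
  list(axon_vertex_ids = skel$vertices$vertex_id[axon_idx],
       split_vertex = skel$vertices$vertex_id[best],
       segregation = seg$index)
}

#' Prune falsely merged axon fragments from a dendritic arbor
#'
#' Iteratively removes terminal dendritic segments whose input density is
#' below \code{min_density} synapses/um until every terminal segment
#' meets the density; removal can expose new bare terminals, which are
#' pruned on subsequent iterations. Idempotent at the fixed point.
#'
#' @param skel a \code{skeleton} with axon already masked (labels)
#' @param input_vertices vertex ids of input synapses
#' @param min_density minimum input density (default 0.1 synapses/um)
#' @return vertex ids to prune (label \code{pruned})
#' @export
prune_false_merges <- function(skel, input_vertices, min_density = 0.1) {
  n <- skel$n
  active <- skel$vertices$label %in% c("dendrite", "soma") |
    is.na(skel$vertices$label)
  active[skel$root] <- TRUE
  in_count <- tabulate(vertex_index(skel, input_vertices), nbins = n)
  pruned <- logical(n)
  repeat {
    mask <- active & !pruned
    segs <- decompose_segments(skel, vertex_mask = mask)
    removed_any <- FALSE
    for (s in segs) {
      if (!s$is_terminal) next
      ## synapses on the boundary (top) vertex belong to the neighboring
      ## segment; count only strictly-interior + bottom vertices
      own <- s$vertex_idx[-1]
      if (length(own) == 0) next
      dens <- sum(in_count[own]) / s$path_length
      if (s$path_length > 0 && dens < min_density) {
        pruned[own] <- TRUE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skel$vertices$vertex_id[pruned]
}

#' Per-vertex features for the apical-branch vertex model
#'
#' Eleven geometric features per vertex describing orientation, location
#' in cortical space, location relative to the soma, and path complexity.
#' Conventions at the root: tortuosity 1, angle 0.
#'
#' @param skel a collapsed \code{skeleton} (axon/pruned vertices get
#'   features too; filter downstream)
#' @param geometry a \code{column_geometry}
#' @return data.frame, one row per vertex: \code{vertex_depth},
#'   \code{soma_depth}, \code{depth_diff}, \code{path_dist_to_soma},
#'   \code{dist_to_farthest_tip}, \code{norm_tip_dist},
#'   \code{tortuosity}, \code{branch_points_to_root},
#'   \code{radial_dist}, \code{euclidean_dist}, \code{angle_to_vertical}
#'   (degrees).
#' @export
vertex_apical_features <- function(skel, geometry) {
  v <- skel$vertices
  n <- skel$n
  root <- skel$root
  depth <- depth_of(v$x, v$y, geometry)
  soma_depth <- depth[root]
  d_root <- skel$dist_root

  ## farthest downstream tip distance per vertex (max over subtree leaves)
  far <- d_root
  for (u in rev(skel$topo_order)) {
    p <- skel$parent_idx[u]
    if (!is.na(p) && far[u] > far[p]) far[p] <- far[u]
  }
  dist_to_tip <- far - d_root
  total_span <- d_root + dist_to_tip
  norm_tip <- ifelse(total_span > 0, d_root / total_span, 0)

  dxe <- v$x - v$x[root]; dye <- v$y - v$y[root]; dze <- v$z - v$z[root]
  eucl <- sqrt(dxe^2 + dye^2 + dze^2)
  radial <- sqrt(dxe^2 + dze^2)
  tort <- ifelse(eucl > 0, d_root / eucl, 1)
  ## angle between soma->vertex vector and the vertical (depth) axis
  ang <- ifelse(eucl > 0, atan2(radial, abs(dye)) * 180 / pi, 0)

  nchild <- vapply(skel$children, length, integer(1))
  is_branch <- nchild > 1
  bp <- integer(n)
  for (u in skel$topo_order[-1]) {
    p <- skel$parent_idx[u]
    bp[u] <- bp[p] + as.integer(is_branch[p] && p != root)
  }

  data.frame(
    vertex_id = v$vertex_id,
    vertex_depth = depth,
    soma_depth = soma_depth,
    depth_diff = depth - soma_depth,
    path_dist_to_soma = d_root,
    dist_to_farthest_tip = dist_to_tip,
    norm_tip_dist = norm_tip,
    tortuosity = tort,
    branch_points_to_root = bp,
    radial_dist = radial,
    euclidean_dist = eucl,
    angle_to_vertical = ang
  )
}

apical_feature_names <- c(
  "vertex_depth", "soma_depth", "depth_diff", "path_dist_to_soma",
  "dist_to_farthest_tip", "norm_tip_dist", "tortuosity",
  "branch_points_to_root", "radial_dist", "euclidean_dist",
  "angle_to_vertical")

#' Train the random-forest vertex model for apical-branch detection
#'
#' The model predicts per-vertex apical membership probability from the
#' eleven \code{\link{vertex_apical_features}}. Weights are retrainable;
#' any external per-vertex probability can be supplied to
#' \code{\link{score_apical_branches}} instead.
#'
#' @param features data.frame from \code{vertex_apical_features} (rows
#'   pooled over training cells)
#' @param labels logical vector, TRUE when the vertex lies on an apical branch
#' @param ntree number of trees (default 100)
#' @param seed RNG seed
#' @return a \code{randomForest} object
#' @export
train_apical_vertex_model <- function(features, labels, ntree = 200, seed = 1) {
  set.seed(seed)
  x <- features[, apical_feature_names, drop = FALSE]
  y <- factor(labels, levels = c(FALSE, TRUE))
  ## balanced per-tree sampling: apical vertices are a small minority and an
  ## unbalanced forest biases probabilities (hence aggregated log-odds) low
  n_min <- min(table(y))
  randomForest::randomForest(x, y, ntree = ntree,
                             sampsize = c(n_min, n_min), strata = y)
}

#' Predict per-vertex apical probability (clipped away from 0 and 1)
#' @param model model from \code{\link{train_apical_vertex_model}}
#' @param features data.frame from \code{\link{vertex_apical_features}}
#' @param eps probability clip (default 1e-3) so log-odds stay finite
#' @export
predict_apical_probability <- function(model, features, eps = 1e-3) {
  p <- stats::predict(model, features[, apical_feature_names, drop = FALSE],
                      type = "prob")[, "TRUE"]
  pmin(pmax(p, eps), 1 - eps)
}

#' Score soma-child branches as apical dendrites
#'
#' Per branch (subtree of each root child), the per-vertex apical
#' log-odds are summed into \code{R}, clipped to [-200, 200]. Branches
#' whose farthest tip is under \code{min_tip_length} (50 um) are too
#' short to be apical and are excluded from the soft-max denominator.
#' Soft-max shares are \code{S_i = exp(R_i/50) / sum_j exp(R_j/50)};
#' a branch qualifies as apical when its tip length is >= 50 um,
#' \code{R > 0} and \code{S > 0.25} (strict), allowing 0-3 apicals.
#'
#' @param skel a collapsed \code{skeleton}
#' @param vertex_probability per-vertex apical probability in (0,1),
#'   aligned with the vertex table
#' @param min_tip_length minimum branch tip length in um (default 50)
#' @param clip saturation of the aggregated log-odds (default 200)
#' @param temperature soft-max scale (default 50)
#' @return data.frame per root-child branch: \code{branch_root}
#'   (vertex id), \code{max_tip_length}, \code{R}, \code{S},
#'   \code{qualifies}.
#' @export
score_apical_branches <- function(skel, vertex_probability,
                                  min_tip_length = 50, clip = 200,
                                  temperature = 50) {
  stopifnot(length(vertex_probability) == skel$n)
  logodds <- log(vertex_probability) - log1p(-vertex_probability)
  kids <- skel$children[[skel$root]]
  if (length(kids) == 0) {
    return(data.frame(branch_root = integer(0), max_tip_length = numeric(0),
                      R = numeric(0), S = numeric(0), qualifies = logical(0)))
  }
  rows <- lapply(kids, function(k) {
    sub <- subtree_index(skel, k)
    dendritic <- sub[!(skel$vertices$label[sub] %in% c("axon", "pruned"))]
    tip <- if (length(dendritic) > 0) max(skel$dist_root[dendritic]) else 0
    R <- if (length(dendritic) > 0) sum(logodds[dendritic]) else -Inf
    data.frame(branch_root = skel$vertices$vertex_id[k],
               max_tip_length = tip,
               R = min(max(R, -clip), clip))
  })
  out <- do.call(rbind, rows)
  eligible <- out$max_tip_length >= min_tip_length
  out$S <- 0
  if (any(eligible)) {
    e <- exp(out$R[eligible] / temperature)
    out$S[eligible] <- e / sum(e)
  }
  out$qualifies <- eligible & out$R > 0 & out$S > 0.25
  out
}

#' Assign compartments to vertices and synapses
#'
#' Soma = root; proximal = dendritic vertices within 50 um path distance
#' of the root (boundary tie at exactly 50 um is proximal); apical =
#' beyond-proximal vertices on qualifying apical branches; distal basal =
#' all remaining dendritic vertices. Axon and pruned vertices get no
#' compartment. Synapses inherit their postsynaptic vertex's compartment;
#' synapses onto inhibitory cells are treated downstream as a fifth
#' target compartment ("inhibitory").
#'
#' @param skel a collapsed \code{skeleton} with labels set
#' @param apical_branch_roots vertex ids of qualifying apical branch roots
#' @param proximal_radius path-distance threshold in um (default 50)
#' @return the skeleton with \code{compartment} filled on non-axon,
#'   non-pruned vertices
#' @export
assign_compartments <- function(skel, apical_branch_roots, proximal_radius = 50) {
  comp <- rep(NA_character_, skel$n)
  dendritic <- !(skel$vertices$label %in% c("axon", "pruned"))
  comp[skel$root] <- "soma"
  on_apical <- logical(skel$n)
  for (b in apical_branch_roots) {
    on_apical[subtree_index(skel, vertex_index(skel, b))] <- TRUE
  }
  idx <- which(dendritic & seq_len(skel$n) != skel$root)
  comp[idx] <- ifelse(skel$dist_root[idx] <= proximal_radius, "proximal",
                      ifelse(on_apical[idx], "apical", "distal_basal"))
  if (any(dendritic & is.na(comp))) stop("internal error: unlabeled dendritic vertex")
  skel$vertices$compartment <- comp
  skel
}

#' Compartment of synapses given a labeled skeleton
#' @param skel labeled skeleton (after \code{\link{assign_compartments}})
#' @param post_vertices postsynaptic vertex ids
#' @return character vector of compartments (NA for axon/pruned targets)
#' @export
synapse_compartments <- function(skel, post_vertices) {
  skel$vertices$compartment[vertex_index(skel, post_vertices)]
}

#' Run the full skeleton-processing pipeline on one cell
#'
#' Soma collapse, axon detection, false-merge pruning, apical scoring
#' (optional, excitatory only) and compartment assignment. Synapse
#' vertex references are remapped through the soma collapse.
#'
#' @param skel raw \code{skeleton}
#' @param nucleus_volume um^3
#' @param input_vertices,output_vertices synapse vertex ids (inputs =
#'   postsynaptic on this cell; outputs = presynaptic)
#' @param coarse_class "excitatory" or "inhibitory"
#' @param geometry a \code{column_geometry} (needed for apical features)
#' @param apical_model optional vertex model (see
#'   \code{\link{train_apical_vertex_model}}); if NULL, no apical
#'   compartment is assigned
#' @param vertex_probability optional externally supplied per-vertex
#'   apical probability (overrides \code{apical_model}): either a numeric
#'   vector aligned with the collapsed skeleton or a function of the
#'   collapsed skeleton returning one
#' @return list: \code{skeleton} (labeled), \code{vertex_map},
#'   \code{axon}, \code{pruned_vertex_ids}, \code{apical_scores}.
#' @export
process_cell <- function(skel, nucleus_volume, input_vertices, output_vertices,
                         coarse_class, geometry, apical_model = NULL,
                         vertex_probability = NULL) {
  col <- collapse_soma(skel, nucleus_volume)
  sk <- col$skeleton
  map_v <- function(ids) unname(col$vertex_map[as.character(ids)])
  inputs <- map_v(input_vertices)
  outputs <- map_v(output_vertices)

  ax <- detect_axon(sk, inputs, outputs, coarse_class)
  sk$vertices$label[sk$vertices$vertex_id %in% ax$axon_vertex_ids] <- "axon"

  dend_inputs <- inputs[!(inputs %in% ax$axon_vertex_ids)]
  pr <- prune_false_merges(sk, dend_inputs)
  sk$vertices$label[sk$vertices$vertex_id %in% pr] <- "pruned"

  apical <- NULL
  apical_roots <- integer(0)
  if (coarse_class == "excitatory" && (!is.null(apical_model) || !is.null(vertex_probability))) {
    if (is.function(vertex_probability)) {
      vertex_probability <- vertex_probability(sk)
    } else if (is.null(vertex_probability)) {
      feats <- vertex_apical_features(sk, geometry)
      vertex_probability <- predict_apical_probability(apical_model, feats)
    }
    apical <- score_apical_branches(sk, vertex_probability)
    apical_roots <- apical$branch_root[apical$qualifies]
  }
  sk <- assign_compartments(sk, apical_roots)
  list(skeleton = sk, vertex_map = col$vertex_map, axon = ax,
       pruned_vertex_ids = pr, apical_scores = apical)
}
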