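#' Excitatory M-types: feature suite and consensus clustering
#'
#' Each excitatory cell is described by 29 features: 15 morphology and
#' synapse scalars, 6 sparse-component loadings of its 50-bin absolute
#' depth synapse histogram, 5 sparse-component loadings of a 13-bin
#' soma-centered histogram, and 3 singular-vector loadings of its
#' branch-count-vs-distance profile. Features are z-scored per column and
#' clustered by repeated Leiden community detection on subsampled
#' k-nearest-neighbour graphs, consolidated by complete-linkage
#' agglomeration of the co-clustering matrix.
#'
#' @name excitatory_mtypes
NULL

#' Fifteen morphology and synapse scalars for one cell
#'
#' Computed on the dendritic arbor (axon and pruned vertices masked).
#' The linear density is the median over nonzero-cable depth bins of
#' synapse count / cable length per bin.
#'
#' @param skel labeled \code{skeleton} (post-processing)
#' @param syn_in this cell's input synapses (data.frame with
#'   \code{post_vertex}, \code{size}, \code{depth}); axon/pruned targets
#'   already excluded
#' @param geometry a \code{column_geometry}
#' @return one-row data.frame of 15 named scalars (vertex radius beyond
#'   30 um is NA when no such vertex exists; imputed at matrix assembly)
#' @export
morphology_feature_suite <- function(skel, syn_in, geometry) {
  dendritic <- !(skel$vertices$label %in% c("axon", "pruned"))
  dend_idx <- which(dendritic)
  if (nrow(syn_in) == 0) stop("cell has no input synapses")
  v <- skel$vertices
  root <- skel$root

  ## tips = dendritic leaves
  nchild_d <- integer(skel$n)
  for (u in seq_len(skel$n)) {
    p <- skel$parent_idx[u]
    if (!is.na(p) && dendritic[u] && dendritic[p]) nchild_d[p] <- nchild_d[p] + 1L
  }
  tips <- which(dendritic & nchild_d == 0L & seq_len(skel$n) != root)
  tip_dists <- skel$dist_root[tips]
  eucl <- sqrt((v$x[tips] - v$x[root])^2 + (v$y[tips] - v$y[root])^2 +
                 (v$z[tips] - v$z[root])^2)
  tip_tort <- ifelse(eucl > 0, tip_dists / eucl, 1)

  syn_idx <- vertex_index(skel, syn_in$post_vertex)
  on_soma <- syn_idx == root
  dend_syn <- syn_in[!on_soma, , drop = FALSE]
  soma_syn <- syn_in[on_soma, , drop = FALSE]

  radial <- sqrt((v$x[dend_idx] - v$x[root])^2 + (v$z[dend_idx] - v$z[root])^2)

  ## per-depth-bin linear density over the dendritic cable
  vdepth <- depth_of(v$x, v$y, geometry)
  vb <- depth_bin(vdepth[dend_idx], geometry)
  cable_by_bin <- tapply(skel$edge_len[dend_idx], vb, sum)
  syn_bins <- depth_bin(dend_syn$depth, geometry)
  syn_by_bin <- table(factor(syn_bins, levels = names(cable_by_bin)))
  dens <- as.numeric(syn_by_bin) / as.numeric(cable_by_bin)
  dens <- dens[as.numeric(cable_by_bin) > 0]

  far30 <- dend_idx[skel$dist_root[dend_idx] >= 30 & dend_idx != root]

  data.frame(
    tip_dist_median = stats::median(tip_dists),
    tip_tortuosity_median = stats::median(tip_tort),
    n_dendritic_inputs = nrow(dend_syn),
    n_somatic_inputs = nrow(soma_syn),
    total_cable = sum(skel$edge_len[dend_idx]),
    radial_extent = stats::quantile(radial, 0.97, names = FALSE),
    syn_dist_median = stats::median(skel$dist_root[syn_idx]),
    soma_syn_size_median = if (nrow(soma_syn) > 0) stats::median(soma_syn$size) else NA_real_,
    dend_syn_size_median = if (nrow(dend_syn) > 0) stats::median(dend_syn$size) else NA_real_,
    syn_size_dynamic_range = if (nrow(dend_syn) > 0)
      diff(stats::quantile(dend_syn$size, c(0.05, 0.95), names = FALSE)) else NA_real_,
    syn_depth_shallow = stats::quantile(syn_in$depth, 0.05, names = FALSE),
    syn_depth_deep = stats::quantile(syn_in$depth, 0.95, names = FALSE),
    syn_depth_extent = diff(stats::quantile(syn_in$depth, c(0.05, 0.95), names = FALSE)),
    linear_density_median = if (length(dens) > 0) stats::median(dens) else NA_real_,
    vertex_radius_median = if (length(far30) > 0) stats::median(v$radius[far30]) else NA_real_
  )
}

## row z-score with zero-variance guard
row_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  sd[sd == 0] <- 1
  (m - mu) / sd
}

## sign-fix sparse components so the largest-magnitude loading is positive
fix_signs <- function(scores, loadings) {
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Sparse components of per-cell absolute-depth synapse histograms
#'
#' Each cell's input synapses are binned into \code{n_bins} depth bins
#' spanning pia to white matter; counts are z-scored per cell and the top
#' \code{k} sparse principal components are extracted. Per-cell component
#' scores are appended to the feature matrix; the component (loading)
#' matrix is returned for reproducibility.
#'
#' @param syn_depth_by_cell list of per-cell synapse depth vectors
#' @param geometry a \code{column_geometry}
#' @param n_bins depth bins (default 50)
#' @param k components (default 6)
#' @param keepX nonzero loadings per component (default 10)
#' @return list: \code{scores} (cells x k), \code{components}
#'   (n_bins x k), \code{histograms}
#' @export
depth_histogram_components <- function(syn_depth_by_cell, geometry,
                                       n_bins = 50, k = 6, keepX = 10) {
  n <- length(syn_depth_by_cell)
  if (n < k) stop("need at least k = ", k, " cells")
  span <- geometry$wm_depth - geometry$pia_depth
  edges <- seq(0, span, length.out = n_bins + 1)
  h <- t(vapply(syn_depth_by_cell, function(d) {
    b <- pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1L), n_bins)
    tabulate(b, nbins = n_bins)
  }, numeric(n_bins)))
  hz <- row_zscore(h)
  fit <- mixOmics::spca(hz, ncomp = k, keepX = rep(keepX, k), scale = FALSE)
  fx <- fix_signs(unclass(fit$variates$X), unclass(fit$loadings$X))
  colnames(fx$scores) <- paste0("depth_pc", seq_len(k))
  list(scores = fx$scores, components = fx$loadings, histograms = hz)
}

#' Sparse components of soma-centered synapse histograms
#'
#' As \code{\link{depth_histogram_components}} but with \code{n_bins}
#' bins spanning soma depth - 100 um to soma depth + 100 um, making the
#' decomposition invariant to depth translation of the cell.
#'
#' @param syn_depth_by_cell list of per-cell synapse depth vectors
#' @param soma_depths per-cell soma depths (same order)
#' @param n_bins bins (default 13)
#' @param k components (default 5)
#' @param keepX nonzero loadings per component (default 5)
#' @param half_span um above/below the soma (default 100)
#' @export
soma_adjusted_components <- function(syn_depth_by_cell, soma_depths,
                                     n_bins = 13, k = 5, keepX = 5,
                                     half_span = 100) {
  n <- length(syn_depth_by_cell)
  if (n < k) stop("need at least k = ", k, " cells")
  h <- t(vapply(seq_len(n), function(i) {
    rel <- syn_depth_by_cell[[i]] - soma_depths[i]
    edges <- seq(-half_span, half_span, length.out = n_bins + 1)
    b <- findInterval(rel, edges, rightmost.closed = TRUE)
    b <- b[b >= 1 & b <= n_bins]
    tabulate(b, nbins = n_bins)
  }, numeric(n_bins)))
  hz <- row_zscore(h)
  fit <- mixOmics::spca(hz, ncomp = k, keepX = rep(keepX, k), scale = FALSE)
  fx <- fix_signs(unclass(fit$variates$X), unclass(fit$loadings$X))
  colnames(fx$scores) <- paste0("soma_pc", seq_len(k))
  list(scores = fx$scores, components = fx$loadings, histograms = hz)
}

#' Branch count as a function of distance from the soma
#'
#' At each distance d in 30, 60, ..., 300 um, the number of distinct
#' connected components of the dendritic skeleton restricted to vertices
#' with path distance in [d - 10, d].
#'
#' @param skel labeled \code{skeleton}
#' @return numeric 10-vector
#' @export
branch_count_profile <- function(skel) {
  dendritic <- !(skel$vertices$label %in% c("axon", "pruned"))
  vapply(seq(30, 300, by = 30), function(d) {
    inset <- dendritic & skel$dist_root >= d - 10 & skel$dist_root <= d
    nv <- sum(inset)
    if (nv == 0) return(0)
    p <- skel$parent_idx
    ne <- sum(inset & !is.na(p) & inset[ifelse(is.na(p), 1L, p)])
    nv - ne
  }, numeric(1))
}

#' Singular-vector loadings of stacked branch-count profiles
#' @param profiles matrix (cells x 10) of \code{\link{branch_count_profile}} rows
#' @param k components (default 3)
#' @return list: \code{scores} (cells x k), \code{v} (right singular vectors)
#' @export
branch_profile_svd <- function(profiles, k = 3) {
  s <- svd(profiles, nu = k, nv = k)
  fx <- fix_signs(s$u %*% diag(s$d[seq_len(k)], k), s$v)
  colnames(fx$scores) <- paste0("branch_sv", seq_len(k))
  list(scores = fx$scores, v = fx$loadings)
}

#' Assemble the 29-column z-scored feature matrix for excitatory cells
#'
#' @param bundle a processed \code{column_bundle} (labeled skeletons,
#'   remapped synapses)
#' @param cell_ids excitatory cell ids to include
#' @return list: \code{features} (z-scored matrix, cells x 29, NAs
#'   median-imputed before scaling), \code{raw}, \code{components}
#'   (persisted decomposition matrices)
#' @export
feature_matrix <- function(bundle, cell_ids) {
  syn <- connectivity_synapses(bundle)
  geometry <- bundle$geometry
  scal <- list(); depth_list <- list(); profiles <- list()
  soma_depths <- numeric(length(cell_ids))
  for (i in seq_along(cell_ids)) {
    id <- cell_ids[i]
    sk <- bundle$skeletons[[as.character(id)]]
    s <- syn[syn$post_cell == id, , drop = FALSE]
    scal[[i]] <- morphology_feature_suite(sk, s, geometry)
    depth_list[[i]] <- s$depth
    profiles[[i]] <- branch_count_profile(sk)
    soma_depths[i] <- bundle$cells$soma_depth[match(id, bundle$cells$cell_id)]
  }
  scalars <- do.call(rbind, scal)
  dh <- depth_histogram_components(depth_list, geometry)
  sh <- soma_adjusted_components(depth_list, soma_depths)
  bp <- branch_profile_svd(do.call(rbind, profiles))
  raw <- cbind(as.matrix(scalars), dh$scores, sh$scores, bp$scores)
  rownames(raw) <- as.character(cell_ids)
  ## median imputation then column z-score
  x <- raw
  for (jj in seq_len(ncol(x))) {
    col <- x[, jj]
    if (anyNA(col)) {
      col[is.na(col)] <- stats::median(col, na.rm = TRUE)
      x[, jj] <- col
    }
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  list(features = z, raw = raw,
       components = list(depth = dh$components, soma = sh$components,
                         branch = bp$v))
}

#' Subsampled consensus Leiden clustering
#'
#' Runs Leiden community detection (modularity objective at the given
#' resolution) on k-nearest-neighbour graphs of repeated random
#' subsamples, accumulates a co-clustering matrix normalized by the
#' number of times each pair was co-sampled, then cuts a complete-linkage
#' dendrogram of (1 - co-clustering). The cluster number is scanned over
#' \code{k_range} and chosen by minimum Davies-Bouldin score on the
#' feature matrix, with the maximum Silhouette breaking near-ties (within
#' 1 percent of the optimum). Deterministic given \code{seed}.
#'
#' @param x numeric matrix (cells x features, z-scored)
#' @param n_runs subsampled runs (default 500)
#' @param subsample fraction of cells per run (default 0.95)
#' @param knn neighbours for the graph (default 10)
#' @param resolution Leiden resolution parameter (default 1.3)
#' @param seed RNG seed
#' @param k_range candidate cluster numbers (default 2:30, clipped)
#' @return list of class \code{consensus_result}: \code{labels},
#'   \code{k}, \code{coclust} (normalized co-clustering), \code{db_trace},
#'   \code{sil_trace}
#' @export
consensus_cluster <- function(x, n_runs = 500, subsample = 0.95, knn = 10,
                              resolution = 1.3, seed = 1, k_range = 2:30) {
  n <- nrow(x)
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (n < 2 * knn) stop("need at least 2 * knn cells")
  set.seed(seed)
  co <- matrix(0, n, n)
  cs <- matrix(0, n, n)
  m <- max(2L, as.integer(round(subsample * n)))
  for (r in seq_len(n_runs)) {
    idx <- sort(sample.int(n, m))
    memb <- leiden_knn(x[idx, , drop = FALSE], knn, resolution)
    cs[idx, idx] <- cs[idx, idx] + 1
    for (cl in unique(memb)) {
      members <- idx[memb == cl]
      co[members, members] <- co[members, members] + 1
    }
  }
  p <- co / pmax(cs, 1)
  diag(p) <- 1
  ## co-clustering distance with an infinitesimal feature-distance term:
  ## pairs that are never co-clustered (distance 1) would otherwise merge
  ## in arbitrary order; the tie-break keeps feature-space neighbours
  ## together without affecting non-tied merges
  dfeat <- as.matrix(stats::dist(x))
  d <- stats::as.dist((1 - p) + 1e-3 * dfeat / max(dfeat))
  hc <- stats::hclust(d, method = "complete")
  ks <- k_range[k_range >= 2 & k_range <= n - 1]
  db <- sil <- rep(NA_real_, length(ks))
  consistent <- rep(FALSE, length(ks))
  labs <- vector("list", length(ks))
  dx <- stats::dist(x)
  for (i in seq_along(ks)) {
    l <- stats::cutree(hc, k = ks[i])
    labs[[i]] <- l
    ## singleton clusters have zero within-scatter and would trivially
    ## minimize Davies-Bouldin; such cuts are not admissible
    if (length(unique(l)) < 2 || min(table(l)) < 2) next
    db[i] <- davies_bouldin(x, l)
    sil[i] <- mean(cluster::silhouette(l, dx)[, "sil_width"])
    ## consensus consistency: every cluster's members must co-cluster in a
    ## substantial share of runs, otherwise a cut can look compact in
    ## feature space while lumping cells the base clusterer always separates
    consistent[i] <- all(vapply(unique(l), function(cl) {
      idx <- which(l == cl)
      mean(p[idx, idx][upper.tri(p[idx, idx])]) >= 0.4
    }, logical(1)))
  }
  ok <- which(!is.na(db) & consistent)
  if (length(ok) == 0) ok <- which(!is.na(db))
  ## among consistent cuts: maximum Silhouette, Davies-Bouldin breaking
  ## near-ties (within 1 percent)
  best_sil <- max(sil[ok])
  near <- ok[sil[ok] >= best_sil - 0.01 * abs(best_sil)]
  best <- near[which.min(db[near])]
  structure(list(labels = labs[[best]], k = ks[best], coclust = p,
                 db_trace = stats::setNames(db, ks),
                 sil_trace = stats::setNames(sil, ks)),
            class = "consensus_result")
}

## one Leiden run on a Jaccard-weighted knn graph (Euclidean metric;
## the phenograph convention: edge weight = Jaccard overlap of the two
## endpoints' neighbour sets, which suppresses spurious bridge edges)
leiden_knn <- function(x, knn, resolution) {
  n <- nrow(x)
  knn <- min(knn, n - 1)
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  nbmat <- matrix(0L, n, knn)
  for (i in seq_len(n)) nbmat[i, ] <- order(dm[i, ])[seq_len(knn)]
  ## neighbour indicator including self, for Jaccard overlap
  ind <- matrix(FALSE, n, n)
  ind[cbind(rep(seq_len(n), knn), as.vector(nbmat))] <- TRUE
  diag(ind) <- TRUE
  pairs <- unique(t(apply(cbind(rep(seq_len(n), knn), as.vector(nbmat)), 1, sort)))
  w <- vapply(seq_len(nrow(pairs)), function(e) {
    a <- ind[pairs[e, 1], ]; b <- ind[pairs[e, 2], ]
    sum(a & b) / sum(a | b)
  }, numeric(1))
  keep <- w > 0
  g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity", weights = w[keep],
    resolution = resolution, n_iterations = 3))
}

#' Name clusters from expert labels and order by soma depth
#'
#' Each cluster takes the modal expert label of its members; clusters
#' sharing a name get letter suffixes (a, b, ...) by ascending median
#' soma depth. Clusters with no labeled member are named
#' \code{unlabeled_<k>}; modal ties resolve alphabetically with a warning.
#'
#' @param labels integer cluster labels
#' @param expert_labels character vector (NA = unlabeled), same order
#' @param soma_depths numeric, same order
#' @return character vector of M-type names per cell, plus attribute
#'   \code{cluster_names} (named by cluster id)
#' @export
name_and_order_clusters <- function(labels, expert_labels, soma_depths) {
  ks <- sort(unique(labels))
  base <- character(length(ks)); med <- numeric(length(ks))
  for (i in seq_along(ks)) {
    members <- labels == ks[i]
    lab <- expert_labels[members]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) {
      base[i] <- paste0("unlabeled_", ks[i])
    } else {
      tab <- sort(table(lab), decreasing = TRUE)
      if (sum(tab == max(tab)) > 1) {
        warning("modal expert-label tie in cluster ", ks[i], "; using alphabetical first")
        base[i] <- sort(names(tab)[tab == max(tab)])[1]
      } else {
        base[i] <- names(tab)[1]
      }
    }
    med[i] <- stats::median(soma_depths[members])
  }
  final <- base
  for (nm in unique(base)) {
    same <- which(base == nm)
    if (length(same) > 1) {
      ord <- same[order(med[same])]
      final[ord] <- paste0(nm, letters[seq_along(ord)])
    }
  }
  out <- final[match(labels, ks)]
  attr(out, "cluster_names") <- stats::setNames(final, ks)
  out
}

#' Per-M-type feature importance via one-vs-rest random forests
#'
#' For each M-type, a random forest predicts membership after SMOTE
#' balancing of the minority class; Mean-Decrease-in-Impurity importances
#' are normalized to sum 1. Single-member classes are skipped with a
#' warning.
#'
#' @param x feature matrix (cells x features)
#' @param labels M-type labels per cell
#' @param ntree trees per forest (default 200)
#' @param seed RNG seed
#' @return matrix (M-types x features) of normalized importances
#' @export
mtype_feature_importance <- function(x, labels, ntree = 200, seed = 1) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  set.seed(seed)
  out <- matrix(NA_real_, length(classes), ncol(x),
                dimnames = list(classes, colnames(x)))
  for (cl in classes) {
    y <- labels == cl
    if (sum(y) < 2) {
      warning("class ", cl, " has a single member; skipped")
      next
    }
    bal <- smote_balance(x, y)
    rf <- randomForest::randomForest(bal$x, factor(bal$y), ntree = ntree)
    imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
    out[cl, ] <- imp / sum(imp)
  }
  out
}
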