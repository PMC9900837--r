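#' Inhibition-onto-excitation connectivity summaries
#'
#' Net input matrices, connection densities and their correlations,
#' perisomatic/distal input balance, per-interneuron output budgets over
#' M-types, and motif-group discovery from the budgets.
#'
#' @name connectivity_stats
NULL

#' Mean net synaptic input per target cell, by subclass and M-type
#'
#' @param syn inhibitory-to-excitatory synapses: \code{pre_cell},
#'   \code{post_cell}
#' @param subclass named subclass vector (names = inhibitory cell ids)
#' @param mtype named M-type vector (names = excitatory cell ids)
#' @return list: \code{mean_net} (subclass x M-type matrix of mean
#'   synapses per target cell, zero-input cells included),
#'   \code{per_target} (named totals per postsynaptic cell),
#'   \code{per_presyn} (named totals per presynaptic cell)
#' @export
net_input_summary <- function(syn, subclass, mtype) {
  subclasses <- sort(unique(subclass))
  mtypes <- sort(unique(mtype))
  n_tgt <- table(factor(mtype, levels = mtypes))
  m <- matrix(0, length(subclasses), length(mtypes),
              dimnames = list(subclass = subclasses, mtype = mtypes))
  if (nrow(syn) > 0) {
    pre_sc <- subclass[as.character(syn$pre_cell)]
    post_mt <- mtype[as.character(syn$post_cell)]
    counts <- table(factor(pre_sc, levels = subclasses),
                    factor(post_mt, levels = mtypes))
    m <- sweep(unclass(counts), 2, as.numeric(n_tgt), "/")
  }
  per_target <- table(factor(as.character(syn$post_cell), levels = names(mtype)))
  per_presyn <- table(factor(as.character(syn$pre_cell), levels = names(subclass)))
  list(mean_net = m,
       per_target = stats::setNames(as.numeric(per_target), names(per_target)),
       per_presyn = stats::setNames(as.numeric(per_presyn), names(per_presyn)))
}

#' Connection density of one interneuron onto an M-type
#'
#' The fraction of cells of the M-type receiving at least one synapse
#' from the interneuron (a multisynaptic connection counts once).
#'
#' @param interneuron presynaptic cell id
#' @param mtype_cells cell ids of the target M-type (>= 1)
#' @param syn synapse table (\code{pre_cell}, \code{post_cell})
#' @export
connection_density <- function(interneuron, mtype_cells, syn) {
  if (length(mtype_cells) == 0) stop("empty M-type: density undefined")
  hit <- unique(syn$post_cell[!is.na(syn$pre_cell) & syn$pre_cell == interneuron])
  mean(mtype_cells %in% hit)
}

#' Connection-density matrix (interneurons x M-types)
#' @param interneurons presynaptic cell ids
#' @param mtype named M-type vector (names = excitatory cell ids)
#' @param syn synapse table
#' @export
density_profile <- function(interneurons, mtype, syn) {
  mtypes <- sort(unique(mtype))
  out <- matrix(0, length(interneurons), length(mtypes),
                dimnames = list(as.character(interneurons), mtypes))
  for (mt in mtypes) {
    cells_mt <- as.numeric(names(mtype)[mtype == mt])
    for (i in seq_along(interneurons)) {
      out[i, mt] <- connection_density(interneurons[i], cells_mt, syn)
    }
  }
  out
}

#' Pearson correlation of connection density between M-types
#'
#' Computed across interneurons of one presynaptic subclass. Pairs
#' involving a zero-variance column are reported as NA (missing), not
#' propagated.
#'
#' @param densities matrix (interneurons x M-types) from
#'   \code{\link{density_profile}}, already restricted to one subclass
#' @return M-type x M-type correlation matrix
#' @export
density_correlation_matrix <- function(densities) {
  if (nrow(densities) < 3) stop("need >= 3 interneurons of the subclass")
  sds <- apply(densities, 2, stats::sd)
  r <- suppressWarnings(stats::cor(densities))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  r
}

#' Balance of perisomatic and distal inhibition per M-type
#'
#' Per M-type, the Spearman correlation of per-cell PeriTC vs DistTC
#' synapse counts, with a percentile bootstrap CI over cell resamples and
#' a bootstrap two-sided p-value, Holm-Sidak corrected across M-types.
#'
#' @param peri_counts,dist_counts named per-cell synapse counts (names =
#'   excitatory cell ids)
#' @param mtype named M-type vector
#' @param n_boot bootstrap resamples (default 2000)
#' @param min_cells minimum cells per M-type (default 5)
#' @return data.frame per M-type: r, ci_lower, ci_upper, p, p_adj,
#'   significant (NA rows where r is undefined)
#' @export
peri_dist_balance <- function(peri_counts, dist_counts, mtype,
                              n_boot = 2000, min_cells = 5) {
  mtypes <- sort(unique(mtype))
  rows <- lapply(mtypes, function(mt) {
    ids <- names(mtype)[mtype == mt]
    if (length(ids) < min_cells) stop("too few cells in M-type ", mt)
    x <- peri_counts[ids]; y <- dist_counts[ids]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(mtype = mt, r = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_, flagged = TRUE))
    }
    r <- stats::cor(x, y, method = "spearman")
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- sample(length(ids), replace = TRUE)
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
      stats::cor(x[i], y[i], method = "spearman")
    }, numeric(1))
    bs <- bs[!is.na(bs)]
    q <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    p <- 2 * min((sum(bs <= 0) + 1) / (length(bs) + 1),
                 (sum(bs >= 0) + 1) / (length(bs) + 1))
    data.frame(mtype = mt, r = r, ci_lower = q[1], ci_upper = q[2],
               p = min(p, 1), flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- holm_sidak(out$p[ok])
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' Normalized synaptic output budget of an interneuron over M-types
#'
#' Only synapses onto excitatory column cells enter the normalization.
#'
#' @param interneuron presynaptic cell id
#' @param syn synapse table
#' @param mtype named M-type vector (names = excitatory cell ids)
#' @return named numeric vector over M-types summing to 1, or NULL (with
#'   a warning) when the cell has no excitatory-target synapses
#' @export
output_budget <- function(interneuron, syn, mtype) {
  s <- syn[!is.na(syn$pre_cell) & syn$pre_cell == interneuron, , drop = FALSE]
  tgt <- mtype[as.character(s$post_cell)]
  tgt <- tgt[!is.na(tgt)]
  if (length(tgt) == 0) {
    warning("interneuron ", interneuron, " has no excitatory-target synapses; excluded")
    return(NULL)
  }
  mtypes <- sort(unique(mtype))
  counts <- table(factor(tgt, levels = mtypes))
  as.numeric(counts) / length(tgt) -> v
  stats::setNames(v, mtypes)
}

#' Output-budget matrix for a set of interneurons
#' @param interneurons presynaptic cell ids
#' @param syn synapse table
#' @param mtype named M-type vector
#' @return matrix (interneurons x M-types); rows for budget-less cells dropped
#' @export
output_budget_matrix <- function(interneurons, syn, mtype) {
  rows <- lapply(interneurons, function(id) output_budget(id, syn, mtype))
  keep <- !vapply(rows, is.null, logical(1))
  m <- do.call(rbind, rows[keep])
  rownames(m) <- as.character(interneurons[keep])
  m
}

#' Discover motif groups from output budgets
#'
#' Applies the consensus-clustering engine to the budget vectors, then
#' orders groups by synapse-weighted mean target depth (superficial
#' first). Also returns the group-level mean output-fraction matrix and
#' the input-fraction matrix (each group's share of all within-column
#' inhibitory synapses received by each M-type).
#'
#' @param budgets matrix from \code{\link{output_budget_matrix}}
#' @param syn inhibitory-to-excitatory synapse table
#' @param mtype named M-type vector
#' @param mtype_depth named median soma depth per M-type
#' @param n_runs,knn,resolution,seed consensus parameters (defaults 500,
#'   10, 1.3)
#' @param k_range candidate group numbers
#' @return list: \code{groups} (named by interneuron),
#'   \code{output_fraction} (group x M-type), \code{input_fraction}
#'   (group x M-type, columns sum to 1), \code{consensus}
#' @export
motif_groups <- function(budgets, syn, mtype, mtype_depth,
                         n_runs = 500, knn = 10, resolution = 1.3,
                         seed = 1, k_range = 2:30) {
  if (nrow(budgets) < 2) stop("need >= 2 interneurons")
  cc <- consensus_cluster(budgets, n_runs = n_runs, knn = knn,
                          resolution = resolution, seed = seed,
                          k_range = k_range)
  raw <- cc$labels
  ## order groups by synapse-weighted mean target depth
  depth_score <- vapply(sort(unique(raw)), function(g) {
    b <- budgets[raw == g, , drop = FALSE]
    w <- colSums(b)
    sum(w * mtype_depth[colnames(budgets)]) / sum(w)
  }, numeric(1))
  remap <- match(raw, sort(unique(raw))[order(depth_score)])
  groups <- stats::setNames(remap, rownames(budgets))

  gs <- sort(unique(remap))
  out_frac <- t(vapply(gs, function(g)
    colMeans(budgets[remap == g, , drop = FALSE]), numeric(ncol(budgets))))
  rownames(out_frac) <- paste0("Group", gs)

  ## input fraction: synapse counts (pre in group) onto each M-type
  s <- syn[!is.na(syn$pre_cell) & as.character(syn$pre_cell) %in% names(groups), , drop = FALSE]
  tgt <- mtype[as.character(s$post_cell)]
  keep <- !is.na(tgt)
  g_of <- groups[as.character(s$pre_cell[keep])]
  counts <- table(factor(g_of, levels = gs),
                  factor(tgt[keep], levels = colnames(budgets)))
  tot <- colSums(counts)
  in_frac <- sweep(unclass(counts), 2, pmax(tot, 1), "/")
  rownames(in_frac) <- paste0("Group", gs)
  list(groups = groups, output_fraction = out_frac,
       input_fraction = in_frac, consensus = cc)
}
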