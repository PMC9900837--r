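#' Inhibitory targeting features and cardinal subclasses
#'
#' Six features describe how an interneuron distributes its output:
#' the fraction of synapses onto inhibitory neurons; the fractions of
#' excitatory-target synapses onto soma, proximal dendrite and apical
#' dendrite (distal basal is the complement and is not a feature); the
#' fraction of synapses in multisynaptic connections (>= 2 synapses onto
#' one target); and the fraction of multisynaptic-connection synapses
#' within a path-distance threshold of another synapse of the same
#' connection along the presynaptic axon ("clumped").
#'
#' @name inhibitory_subclasses
NULL

targeting_feature_names <- c("frac_inhibitory", "frac_soma", "frac_proximal",
                             "frac_apical", "frac_multisyn", "frac_clumped")

#' Compute the six targeting features for one interneuron
#'
#' @param syn_out this cell's output synapses (autapses excluded):
#'   data.frame with \code{post_cell}, \code{post_class} ("excitatory" or
#'   "inhibitory"), \code{post_compartment}, \code{pre_vertex}
#' @param pre_skeleton the presynaptic \code{skeleton} (for axonal path
#'   distances); if NULL, Euclidean distance between synapse positions is
#'   used with a warning (columns \code{x,y,z} then required)
#' @param clump_threshold path-distance threshold in um (default 15)
#' @return one-row data.frame of the six features
#' @export
targeting_features <- function(syn_out, pre_skeleton, clump_threshold = 15) {
  n <- nrow(syn_out)
  if (n == 0) stop("cell has zero output synapses")
  frac_inh <- mean(syn_out$post_class == "inhibitory")
  exc <- syn_out[syn_out$post_class == "excitatory", , drop = FALSE]
  if (nrow(exc) > 0) {
    frac_soma <- mean(exc$post_compartment == "soma")
    frac_prox <- mean(exc$post_compartment == "proximal")
    frac_apic <- mean(exc$post_compartment == "apical")
  } else {
    frac_soma <- frac_prox <- frac_apic <- 0
  }
  conn_sizes <- table(syn_out$post_cell)
  multi_cells <- names(conn_sizes)[conn_sizes >= 2]
  is_multi <- as.character(syn_out$post_cell) %in% multi_cells
  frac_multi <- mean(is_multi)
  frac_clumped <- 0
  if (any(is_multi)) {
    clumped <- logical(sum(is_multi))
    ms <- syn_out[is_multi, , drop = FALSE]
    pos <- 0L
    for (tc in multi_cells) {
      rows <- which(as.character(ms$post_cell) == tc)
      d <- presyn_pair_distances(ms[rows, , drop = FALSE], pre_skeleton)
      diag(d) <- Inf
      clumped[rows] <- apply(d, 1, min) <= clump_threshold
    }
    frac_clumped <- mean(clumped)
  }
  data.frame(frac_inhibitory = frac_inh, frac_soma = frac_soma,
             frac_proximal = frac_prox, frac_apical = frac_apic,
             frac_multisyn = frac_multi, frac_clumped = frac_clumped)
}

## pairwise presynaptic distances for synapses of one connection
presyn_pair_distances <- function(syn_rows, pre_skeleton) {
  k <- nrow(syn_rows)
  if (is.null(pre_skeleton)) {
    warning("presynaptic skeleton absent; falling back to Euclidean distance")
    return(as.matrix(stats::dist(syn_rows[, c("x", "y", "z")])))
  }
  idx <- vertex_index(pre_skeleton, syn_rows$pre_vertex)
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (jj in (i + 1):k) {
      il <- lca_index(pre_skeleton, idx[i], idx[jj])
      d[i, jj] <- d[jj, i] <- pre_skeleton$dist_root[idx[i]] +
        pre_skeleton$dist_root[idx[jj]] - 2 * pre_skeleton$dist_root[il]
    }
  }
  d
}

#' Fit a linear discriminant on expert-labeled cells and assign all cells
#'
#' The model is trained on the labeled subset only and applied to every
#' inhibitory cell; disagreements with the expert labels are retained as
#' the data-driven view.
#'
#' @param features data.frame: \code{cell_id} plus the six targeting
#'   features
#' @param expert_labels named character vector (names = cell ids); NA =
#'   unlabeled
#' @return list: \code{model} (MASS::lda fit), \code{assignments}
#'   (data.frame cell_id, assigned_subclass), \code{classes}
#' @export
fit_and_assign_subclasses <- function(features, expert_labels) {
  lab <- expert_labels[as.character(features$cell_id)]
  train <- !is.na(lab)
  classes <- sort(unique(lab[train]))
  tab <- table(lab[train])
  if (any(tab < 2)) {
    stop("need >= 2 labeled cells per class; short: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  x <- as.matrix(features[, targeting_feature_names])
  fit <- tryCatch(
    MASS::lda(x[train, , drop = FALSE], grouping = factor(lab[train])),
    error = function(e) stop("degenerate feature input for LDA: ", conditionMessage(e))
  )
  pred <- stats::predict(fit, x)$class
  list(model = fit,
       assignments = data.frame(cell_id = features$cell_id,
                                assigned_subclass = as.character(pred),
                                stringsAsFactors = FALSE),
       classes = classes)
}

#' Subclass-to-subclass connectivity matrix
#'
#' Entry (pre, post) is the total number of synapses from all cells of
#' the presynaptic subclass onto each postsynaptic-subclass cell,
#' averaged over postsynaptic cells (cells with zero input included).
#'
#' @param subclass named character vector of subclasses (names = cell ids)
#' @param syn synapses between inhibitory cells: \code{pre_cell},
#'   \code{post_cell}
#' @return matrix (pre subclass x post subclass); empty-subclass entries NA
#' @export
subclass_connectivity_matrix <- function(subclass, syn) {
  classes <- sort(unique(subclass))
  n_post <- table(factor(subclass, levels = classes))
  m <- matrix(0, length(classes), length(classes),
              dimnames = list(pre = classes, post = classes))
  if (nrow(syn) > 0) {
    pre_sc <- subclass[as.character(syn$pre_cell)]
    post_sc <- subclass[as.character(syn$post_cell)]
    counts <- table(factor(pre_sc, levels = classes), factor(post_sc, levels = classes))
    m <- sweep(unclass(counts), 2, as.numeric(n_post), "/")
  }
  m[, n_post == 0] <- NA
  m
}

#' Split InhTCs into DistTC-targeting and PeriTC-targeting subtypes
#'
#' Per InhTC, the output fraction over the four target subclasses (among
#' synapses onto inhibitory cells) is computed; cells are assigned to
#' InhTC_Dist or InhTC_Peri by the larger of the DistTC vs PeriTC share
#' (ties go to InhTC_Dist with a warning).
#'
#' @param inhtc_ids cell ids of InhTCs
#' @param syn inhibitory-to-inhibitory synapses (\code{pre_cell},
#'   \code{post_cell})
#' @param subclass named subclass vector for target lookup
#' @return data.frame: cell_id, subtype (NA and flagged when a cell has
#'   no inhibitory-target synapses), plus the four target-share columns
#' @export
split_inhtc <- function(inhtc_ids, syn, subclass) {
  classes <- c("PeriTC", "DistTC", "SparTC", "InhTC")
  rows <- lapply(inhtc_ids, function(id) {
    s <- syn[!is.na(syn$pre_cell) & syn$pre_cell == id, , drop = FALSE]
    tgt <- subclass[as.character(s$post_cell)]
    shares <- as.numeric(table(factor(tgt, levels = classes))) / max(nrow(s), 1)
    if (nrow(s) == 0) {
      subtype <- NA_character_
    } else if (shares[classes == "DistTC"] == shares[classes == "PeriTC"]) {
      warning("InhTC ", id, ": DistTC/PeriTC tie; assigned InhTC_Dist")
      subtype <- "InhTC_Dist"
    } else {
      subtype <- if (shares[classes == "DistTC"] > shares[classes == "PeriTC"])
        "InhTC_Dist" else "InhTC_Peri"
    }
    out <- data.frame(cell_id = id, subtype = subtype, stringsAsFactors = FALSE)
    out[classes] <- as.list(shares)
    out
  })
  do.call(rbind, rows)
}

#' Compare synapse sizes and synapses-per-connection between two groups
#'
#' Medians with percentile-bootstrap 95 percent CIs (n = 1000), a
#' two-sample t-test on synapse sizes, and a t-test on per-connection
#' synapse counts, with Holm-Sidak adjustment across the two tests.
#' Welch's unequal-variance t is the default; classical Student's t by
#' flag.
#'
#' @param group_a,group_b data.frames with \code{size} and
#'   \code{connection} (an id shared by synapses of one connection)
#' @param n_boot bootstrap resamples (default 1000)
#' @param welch use Welch's t (default TRUE)
#' @return nested list of estimates and tests
#' @export
connection_property_comparison <- function(group_a, group_b, n_boot = 1000,
                                           welch = TRUE) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) stop("both groups must be non-empty")
  summarize <- function(g) {
    cs <- as.numeric(table(g$connection))
    list(median_size = bootstrap_ci(g$size, stats::median, n_boot),
         mean_syn_per_conn = mean(cs), conn_counts = cs)
  }
  a <- summarize(group_a); b <- summarize(group_b)
  size_t <- stats::t.test(group_a$size, group_b$size, var.equal = !welch)
  count_t <- if (length(a$conn_counts) >= 2 && length(b$conn_counts) >= 2 &&
                 (stats::var(a$conn_counts) + stats::var(b$conn_counts)) > 0) {
    stats::t.test(a$conn_counts, b$conn_counts, var.equal = !welch)
  } else NULL
  p_raw <- c(size = size_t$p.value,
             count = if (is.null(count_t)) NA else count_t$p.value)
  p_adj <- rep(NA_real_, 2); names(p_adj) <- names(p_raw)
  ok <- !is.na(p_raw)
  p_adj[ok] <- holm_sidak(p_raw[ok])
  list(group_a = a, group_b = b,
       size_test = list(statistic = unname(size_t$statistic), p = size_t$p.value),
       count_test = if (is.null(count_t)) NULL else
         list(statistic = unname(count_t$statistic), p = count_t$p.value),
       p_adjusted = p_adj)
}
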