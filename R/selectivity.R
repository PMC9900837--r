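#' Selectivity Index: baseline, conditional shuffles, SI and p-values
#'
#' The null model redistributes each of an interneuron's output synapses
#' to a target class drawn from the baseline distribution of all column
#' synaptic inputs, conditioned on the synapse's (depth bin, target
#' compartment) stratum. The Selectivity Index for a target class is the
#' observed synapse count divided by the median shuffled count;
#' significance is a two-sided permutation p-value with add-one
#' smoothing, Holm-Sidak corrected within each interneuron over classes
#' with nonzero potential connectivity.
#'
#' @name selectivity
NULL

#' Build the baseline synapse distribution
#'
#' Bins every somatic/dendritic input synapse of every column cell by
#' (depth bin, target compartment, target class), where target class is
#' the postsynaptic cell's M-type, with synapses onto inhibitory cells
#' pooled as class (and compartment) "inhibitory".
#'
#' @param syn annotated input synapses: \code{depth},
#'   \code{post_compartment} (with "inhibitory" for inhibitory targets),
#'   \code{target_class}, and \code{pre_cell}
#' @param geometry a \code{column_geometry}
#' @param exclude_pre optional cell ids whose outputs are left out of the
#'   baseline (leave-self-out correction for small synthetic columns
#'   where assayed interneurons would otherwise contaminate their own
#'   null; immaterial at biological scale)
#' @return 3-d array (depth bin x compartment x class) of counts, class
#'   \code{baseline_distribution}
#' @export
build_baseline <- function(syn, geometry, exclude_pre = NULL) {
  if (any(is.na(syn$post_compartment))) stop("synapse with no compartment")
  if (!is.null(exclude_pre)) {
    syn <- syn[is.na(syn$pre_cell) | !(syn$pre_cell %in% exclude_pre), , drop = FALSE]
  }
  comps <- c("soma", "proximal", "distal_basal", "apical", "inhibitory")
  classes <- sort(unique(syn$target_class))
  b <- table(
    bin = factor(depth_bin(syn$depth, geometry), levels = seq_len(geometry$n_depth_bins)),
    compartment = factor(syn$post_compartment, levels = comps),
    class = factor(syn$target_class, levels = classes)
  )
  structure(unclass(b), class = "baseline_distribution")
}

#' Conditional shuffle of an interneuron's outputs over target classes
#'
#' Each observed synapse independently redraws its target class from the
#' baseline conditional distribution of its (depth bin, compartment)
#' stratum (multinomial, i.e. with replacement). Deterministic given
#' \code{seed}.
#'
#' @param obs observed output synapses: \code{depth_bin},
#'   \code{compartment}
#' @param baseline a \code{baseline_distribution}
#' @param n_shuffles shuffle count (default 1000)
#' @param seed RNG seed
#' @return list: \code{shuffled} (classes x n_shuffles count matrix),
#'   \code{potential} (classes with nonzero baseline mass in at least one
#'   observed stratum)
#' @export
shuffle_outputs <- function(obs, baseline, n_shuffles = 1000, seed = 1) {
  set.seed(seed)
  classes <- dimnames(baseline)[[3]]
  strata <- table(obs$depth_bin, obs$compartment)
  nz <- which(strata > 0, arr.ind = TRUE)
  shuffled <- matrix(0L, length(classes), n_shuffles,
                     dimnames = list(classes, NULL))
  potential <- rep(FALSE, length(classes))
  for (r in seq_len(nrow(nz))) {
    bin <- rownames(strata)[nz[r, 1]]
    comp <- colnames(strata)[nz[r, 2]]
    n_s <- strata[nz[r, 1], nz[r, 2]]
    mass <- baseline[bin, comp, ]
    tot <- sum(mass)
    if (tot == 0) stop("empty baseline stratum: depth bin ", bin, ", compartment ", comp)
    potential <- potential | mass > 0
    draws <- stats::rmultinom(n_shuffles, n_s, mass / tot)
    shuffled <- shuffled + draws
  }
  list(shuffled = shuffled, potential = stats::setNames(potential, classes))
}

#' Selectivity Index with permutation p-values
#'
#' SI = observed / median(shuffled); two-sided p =
#' 2 min(P(X <= obs), P(X >= obs)) with add-one smoothing, capped at 1;
#' Holm-Sidak within the interneuron over classes with nonzero potential
#' connectivity. A zero shuffle median with positive observation yields
#' an infinite SI sentinel (finite p).
#'
#' @param observed named counts per target class
#' @param shuffle result of \code{\link{shuffle_outputs}}
#' @param alpha significance level after correction (default 0.05)
#' @return data.frame per potential class: observed, shuffle_median, si,
#'   p, p_adj, significant, n_shuffles
#' @export
selectivity_index <- function(observed, shuffle, alpha = 0.05) {
  classes <- rownames(shuffle$shuffled)
  n_sh <- ncol(shuffle$shuffled)
  obs <- stats::setNames(rep(0, length(classes)), classes)
  obs[names(observed)] <- observed
  pot <- names(shuffle$potential)[shuffle$potential]
  rows <- lapply(pot, function(cl) {
    x <- shuffle$shuffled[cl, ]
    med <- stats::median(x)
    si <- if (med > 0) obs[cl] / med else if (obs[cl] > 0) Inf else NA_real_
    p_lo <- (sum(x <= obs[cl]) + 1) / (n_sh + 1)
    p_hi <- (sum(x >= obs[cl]) + 1) / (n_sh + 1)
    data.frame(target_class = cl, observed = unname(obs[cl]),
               shuffle_median = med, si = unname(si),
               p = min(1, 2 * min(p_lo, p_hi)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_sidak(out$p)
  out$significant <- out$p_adj < alpha
  out$n_shuffles <- n_sh
  out
}

#' Compartment-preference index (shuffle over compartments)
#'
#' Mirror of \code{\link{shuffle_outputs}} +
#' \code{\link{selectivity_index}} with the roles of compartment and
#' target class swapped: the shuffle preserves the observed depth and
#' target-class distributions and redraws the compartment from the
#' baseline conditional on (depth bin, target class).
#'
#' @param obs observed output synapses: \code{depth_bin},
#'   \code{compartment}, \code{target_class}
#' @param baseline a \code{baseline_distribution}
#' @param n_shuffles shuffle count (default 1000)
#' @param seed RNG seed
#' @param alpha significance level (default 0.05)
#' @return data.frame per potential compartment (as
#'   \code{\link{selectivity_index}})
#' @export
compartment_preference <- function(obs, baseline, n_shuffles = 1000, seed = 1,
                                   alpha = 0.05) {
  ## swap axes: strata = (bin, class), redraw compartment
  swapped <- aperm(baseline, c(1, 3, 2))
  obs2 <- data.frame(depth_bin = obs$depth_bin, compartment = obs$target_class)
  sh <- shuffle_outputs(obs2, swapped, n_shuffles, seed)
  observed <- table(obs$compartment)
  selectivity_index(stats::setNames(as.numeric(observed), names(observed)), sh, alpha)
}

#' Per-interneuron selectivity over M-types from a labeled bundle
#'
#' Convenience wrapper: computes observed per-class counts and runs the
#' shuffle + SI machinery for each interneuron.
#'
#' @param syn_out annotated output synapses of all interneurons:
#'   \code{pre_cell}, \code{depth}, \code{post_compartment},
#'   \code{target_class}
#' @param baseline a \code{baseline_distribution}
#' @param geometry a \code{column_geometry}
#' @param interneurons cell ids to assay
#' @param n_shuffles per-interneuron shuffles (default 1000)
#' @param seed master seed (per-cell substreams derived from it)
#' @return data.frame stacking \code{\link{selectivity_index}} rows with
#'   a \code{pre_cell} column
#' @export
selectivity_table <- function(syn_out, baseline, geometry, interneurons,
                              n_shuffles = 1000, seed = 1) {
  rows <- lapply(interneurons, function(id) {
    s <- syn_out[syn_out$pre_cell == id, , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    obs <- data.frame(depth_bin = depth_bin(s$depth, geometry),
                      compartment = s$post_compartment)
    sh <- shuffle_outputs(obs, baseline, n_shuffles,
                          seed = substream_seed(seed, id))
    observed <- table(s$target_class)
    si <- selectivity_index(stats::setNames(as.numeric(observed), names(observed)), sh)
    cbind(pre_cell = id, si)
  })
  do.call(rbind, rows)
}

#' Motif-group selectivity matrix
#'
#' Median SI per (group, M-type) with non-significant entries set to 1
#' before taking the median; infinite SI sentinels are excluded from the
#' median. An entry is annotated non-significant when fewer than half of
#' the group's member entries for that class are significant.
#'
#' @param si_table output of \code{\link{selectivity_table}} (with
#'   \code{pre_cell})
#' @param groups named group labels (names = interneuron ids)
#' @return list: \code{median_si} (group x class),
#'   \code{nonsignificant} (logical matrix, dotted in displays)
#' @export
group_selectivity_matrix <- function(si_table, groups) {
  gs <- sort(unique(groups))
  classes <- sort(unique(si_table$target_class))
  med <- matrix(NA_real_, length(gs), length(classes),
                dimnames = list(paste0("Group", gs), classes))
  nonsig <- matrix(TRUE, length(gs), length(classes),
                   dimnames = dimnames(med))
  for (i in seq_along(gs)) {
    members <- as.numeric(names(groups)[groups == gs[i]])
    sub <- si_table[si_table$pre_cell %in% members, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (jj in seq_along(classes)) {
      rows <- sub[sub$target_class == classes[jj], , drop = FALSE]
      if (nrow(rows) == 0) next
      v <- ifelse(rows$significant, rows$si, 1)
      v <- v[is.finite(v)]
      if (length(v) == 0) next
      med[i, jj] <- stats::median(v)
      nonsig[i, jj] <- mean(rows$significant) < 0.5
    }
  }
  list(median_si = med, nonsignificant = nonsig)
}
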