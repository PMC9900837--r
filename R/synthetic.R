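#' Synthetic cortical column with planted ground truth
#'
#' Generates a column of excitatory neurons (layered somata, branching
#' dendritic trees with type-specific synapse densities and log-normal
#' synapse sizes, optional apical trunk + tuft) and inhibitory neurons
#' (multipolar dendrites plus an output axon placing multisynaptic,
#' spatially clumped synapses with configurable compartment preferences
#' and per-M-type selectivity multipliers). Every downstream stage of the
#' pipeline can be validated against the planted truth.
#'
#' @name synthetic_column
NULL

#' Default excitatory M-type parameter table
#'
#' Eight M-types spanning layers 2-6 with well-separated morphology and
#' synapse statistics: per-type dendritic cable, branch count, segment
#' length, apical presence/trunk length/tuft breadth, tortuosity jitter,
#' linear input density (syn/um), somatic input count, log-normal synapse
#' size (median, sigma) and vertex radius.
#' @param n_per_type cells per M-type (default 28)
#' @return data.frame, one row per M-type
#' @export
default_mtype_params <- function(n_per_type = 28) {
  data.frame(
    mtype        = c("L2a", "L2b", "L3a", "L4a", "L4b", "L5a", "L5b", "L6a"),
    expert_label = c("L2", "L2", "L3", "L4", "L4", "L5ET", "L5IT", "L6"),
    n_cells      = rep(n_per_type, 8),
    depth_lo     = c(130, 135, 230, 370, 375, 550, 555, 760),
    depth_hi     = c(140, 145, 240, 380, 385, 560, 565, 770),
    n_basal      = c(5, 3, 4, 6, 3, 5, 4, 4),
    cable        = c(1000, 450, 750, 950, 500, 1300, 650, 900),
    seg_len      = c(60, 45, 55, 50, 45, 70, 55, 50),
    apical       = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    apical_trunk = c(70, 60, 150, 0, 120, 420, 220, 0),
    tuft_n       = c(3, 2, 3, 0, 2, 4, 2, 0),
    tuft_len     = c(120, 70, 100, 0, 60, 200, 80, 0),
    jitter       = c(0.15, 0.3, 0.18, 0.2, 0.35, 0.12, 0.2, 0.25),
    density      = c(0.90, 0.30, 0.60, 0.85, 0.30, 0.65, 0.25, 0.50),
    soma_inputs  = c(80, 20, 50, 70, 25, 90, 25, 45),
    size_median  = c(500, 250, 380, 460, 260, 550, 220, 340),
    size_sigma   = c(0.45, 0.30, 0.40, 0.35, 0.30, 0.50, 0.30, 0.35),
    radius       = c(0.55, 0.30, 0.45, 0.60, 0.25, 0.85, 0.30, 0.45),
    stringsAsFactors = FALSE
  )
}

#' Default inhibitory parameter table
#'
#' Four connectivity subclasses with disjoint compartment-preference
#' vectors over (soma, proximal, distal_basal, apical, inhibitory),
#' per-cell output budget, synapses-per-connection distribution
#' (k = 1 + Poisson(lambda)), presynaptic clump spatial scale and axial
#' span. InhTC cells alternate between DistTC-biased and PeriTC-biased
#' inhibitory targeting so both InhTC subtypes are planted.
#' @param n_peri,n_dist,n_spar,n_inh cells per subclass
#' @return data.frame, one row per subclass
#' @export
default_inhibitory_params <- function(n_peri = 12, n_dist = 14, n_spar = 8, n_inh = 6) {
  data.frame(
    subclass = c("PeriTC", "DistTC", "SparTC", "InhTC"),
    n_cells  = c(n_peri, n_dist, n_spar, n_inh),
    budget   = c(350, 350, 120, 150),
    pref_soma = c(0.55, 0.02, 0.10, 0.02),
    pref_proximal = c(0.30, 0.08, 0.20, 0.04),
    pref_distal_basal = c(0.08, 0.55, 0.45, 0.08),
    pref_apical = c(0.02, 0.30, 0.15, 0.01),
    pref_inhibitory = c(0.05, 0.05, 0.10, 0.85),
    syn_per_conn_lambda = c(2.5, 1.5, 0.05, 2.0),
    clump_scale = c(5, 8, 10, 6),
    span = c(250, 350, 300, 300),
    depth_lo = c(120, 120, 120, 120),
    depth_hi = c(900, 900, 900, 900),
    dend_cable = c(500, 500, 400, 350),
    dend_density = c(0.45, 0.40, 0.35, 0.40),
    stringsAsFactors = FALSE
  )
}

#' Column specification for the synthetic generator
#'
#' @param seed master seed; identical seed gives byte-identical output
#' @param geometry a \code{column_geometry}
#' @param mtypes excitatory M-type table (see
#'   \code{\link{default_mtype_params}})
#' @param inhibitory inhibitory subclass table (see
#'   \code{\link{default_inhibitory_params}})
#' @param multipliers named per-M-type selectivity multipliers applied to
#'   every interneuron's target choice (default all 1); can also be a
#'   function(subclass) returning a named vector, for per-cell control
#' @param expert_label_fraction fraction of inhibitory cells carrying an
#'   expert subclass label (default 0.6)
#' @param column_width lateral extent (um) for soma placement
#' @export
column_spec <- function(seed = 1,
                        geometry = column_geometry(
                          pia_depth = 0, wm_depth = 1000,
                          layer_boundaries = c(100, 200, 320, 500, 700)),
                        mtypes = default_mtype_params(),
                        inhibitory = default_inhibitory_params(),
                        multipliers = NULL,
                        expert_label_fraction = 0.6,
                        column_width = 100) {
  if (is.null(multipliers)) {
    multipliers <- stats::setNames(rep(1, nrow(mtypes)), mtypes$mtype)
  }
  if (is.numeric(multipliers)) {
    stopifnot(all(multipliers > 0))
  }
  stopifnot(all(mtypes$density > 0), all(mtypes$n_cells > 0))
  pref <- as.matrix(inhibitory[, c("pref_soma", "pref_proximal", "pref_distal_basal",
                                   "pref_apical", "pref_inhibitory")])
  if (any(abs(rowSums(pref) - 1) > 1e-9)) stop("compartment-preference vectors must sum to 1")
  structure(list(seed = seed, geometry = geometry, mtypes = mtypes,
                 inhibitory = inhibitory, multipliers = multipliers,
                 expert_label_fraction = expert_label_fraction,
                 column_width = column_width),
            class = "column_spec")
}

## ---- low-level tree growth -------------------------------------------------

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 1, 0) else v / n
}

## grow a branching dendritic tree; returns updated vertex store
## store: env with mat (list of rows), count
new_vertex_store <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- vector("list", 256)
  env$count <- 0L
  env
}

add_vertex <- function(store, parent, x, y, z, radius, label) {
  store$count <- store$count + 1L
  if (store$count > length(store$rows)) {
    store$rows <- c(store$rows, vector("list", length(store$rows)))
  }
  store$rows[[store$count]] <- c(parent, x, y, z, radius, match(label, c("soma", "axon", "dendrite")))
  store$count
}

store_to_vertices <- function(store) {
  m <- do.call(rbind, store$rows[seq_len(store$count)])
  data.frame(
    vertex_id = seq_len(store$count),
    x = m[, 2], y = m[, 3], z = m[, 4], radius = m[, 5],
    parent = ifelse(is.na(m[, 1]) | m[, 1] <= 0, NA_integer_, as.integer(m[, 1])),
    label = c("soma", "axon", "dendrite")[m[, 6]],
    stringsAsFactors = FALSE
  )
}

## recursive branch growth with direction jitter and depth reflection
grow_branch <- function(store, parent, pos, dir, cable, seg_len, jitter,
                        radius, depth_range, step = 5, level = 1) {
  if (cable < step) return(invisible(NULL))
  L <- max(stats::rnorm(1, seg_len, 0.25 * seg_len), 2 * step)
  L <- min(L, cable)
  nstep <- max(1L, as.integer(round(L / step)))
  for (i in seq_len(nstep)) {
    dir <- normalize3(dir + stats::rnorm(3, 0, jitter))
    newpos <- pos + dir * step
    if (newpos[2] < depth_range[1] + 2 || newpos[2] > depth_range[2] - 2) {
      dir[2] <- -dir[2]
      newpos <- pos + dir * step
    }
    parent <- add_vertex(store, parent, newpos[1], newpos[2], newpos[3], radius, "dendrite")
    pos <- newpos
  }
  rem <- cable - nstep * step
  if (rem >= 2 * step && level < 6) {
    for (k in 1:2) {
      child_dir <- normalize3(dir + stats::rnorm(3, 0, 0.6))
      grow_branch(store, parent, pos, child_dir, rem / 2, seg_len, jitter,
                  radius * 0.85, depth_range, step, level + 1)
    }
  }
  invisible(NULL)
}

## generate one excitatory neuron; returns list(skeleton, apical_root, inputs)
gen_excitatory_cell <- function(soma, mt, geometry, step = 5) {
  depth_range <- c(0, geometry$wm_depth - geometry$pia_depth)
  store <- new_vertex_store()
  root <- add_vertex(store, NA, soma[1], soma[2], soma[3], 6, "soma")
  for (b in seq_len(mt$n_basal)) {
    dir <- normalize3(c(stats::rnorm(1), stats::runif(1, -0.3, 0.9), stats::rnorm(1)))
    grow_branch(store, root, soma, dir, mt$cable / mt$n_basal, mt$seg_len,
                mt$jitter, mt$radius, depth_range, step)
  }
  apical_root <- NA_integer_
  if (isTRUE(mt$apical) && mt$apical_trunk > 0) {
    trunk_len <- min(mt$apical_trunk, soma[2] - 15)
    if (trunk_len > 2 * step) {
      pos <- soma; parent <- root
      dir <- c(0, -1, 0)
      nstep <- max(2L, as.integer(round(trunk_len / step)))
      for (i in seq_len(nstep)) {
        dir <- normalize3(dir + stats::rnorm(3, 0, mt$jitter / 2))
        if (dir[2] > -0.3) dir <- normalize3(c(dir[1], -0.7, dir[3]))
        pos <- pos + dir * step
        if (pos[2] < 12) { pos[2] <- 12 + stats::runif(1, 0, 1); pos[1] <- pos[1] + 0.5 }
        parent <- add_vertex(store, parent, pos[1], pos[2], pos[3], mt$radius * 2.2, "dendrite")
        if (i == 1) apical_root <- parent
      }
      for (t in seq_len(mt$tuft_n)) {
        tdir <- normalize3(c(stats::rnorm(1, 0, 1), stats::runif(1, -0.8, -0.1), stats::rnorm(1, 0, 1)))
        grow_branch(store, parent, pos, tdir, mt$tuft_len, mt$seg_len * 0.7,
                    mt$jitter * 1.5, mt$radius * 0.7, depth_range, step)
      }
    }
  }
  sk <- skeleton(store_to_vertices(store))
  if (cable_length(sk) <= 0 && mt$density > 0) {
    stop("infeasible spec: demanded input density on zero-length arbor")
  }
  list(skeleton = sk, apical_root = apical_root)
}

## place background input synapses on a cell; returns data.frame
place_inputs <- function(sk, density, soma_inputs, size_median, size_sigma) {
  v <- sk$vertices
  non_root <- which(seq_len(sk$n) != sk$root & v$label != "axon")
  counts <- stats::rpois(length(non_root), density * sk$edge_len[non_root])
  idx <- rep(non_root, counts)
  n_soma <- stats::rpois(1, soma_inputs)
  idx <- c(idx, rep(sk$root, n_soma))
  if (length(idx) == 0) return(NULL)
  data.frame(
    post_vertex = v$vertex_id[idx],
    x = v$x[idx], y = v$y[idx], z = v$z[idx],
    size = stats::rlnorm(length(idx), log(size_median), size_sigma)
  )
}

## ground-truth compartments used by the generator's targeting step
truth_compartments <- function(sk, apical_root, proximal_radius = 50) {
  comp <- rep("distal_basal", sk$n)
  comp[sk$dist_root <= proximal_radius] <- "proximal"
  comp[sk$root] <- "soma"
  if (!is.na(apical_root)) {
    api <- subtree_index(sk, apical_root)
    comp[api][sk$dist_root[api] > proximal_radius] <- "apical"
  }
  comp
}

#' Generate a synthetic cortical column
#'
#' @param spec a \code{\link{column_spec}}
#' @return a \code{column_bundle} (cells, skeletons, synapses, geometry)
#'   whose \code{ground_truth} holds planted M-types, subclasses, apical
#'   branch roots, axon vertex sets and selectivity multipliers.
#' @export
generate_column <- function(spec) {
  geometry <- spec$geometry
  mts <- spec$mtypes
  inh <- spec$inhibitory
  w <- spec$column_width

  cells <- list(); skels <- list(); syn_parts <- list()
  truth_mtype <- character(0); truth_subclass <- character(0)
  truth_apical <- list(); truth_axon <- list()
  cell_id <- 0L

  ## --- excitatory population -------------------------------------------
  for (m in seq_len(nrow(mts))) {
    mt <- mts[m, ]
    even <- isTRUE(mt$even_depth)
    for (i in seq_len(mt$n_cells)) {
      cell_id <- cell_id + 1L
      set.seed(substream_seed(spec$seed, cell_id))
      soma_depth <- if (even) {
        ## deterministic even spacing over the band (smooth depth coverage
        ## for sparse reference populations)
        mt$depth_lo + (i - 0.5) / mt$n_cells * (mt$depth_hi - mt$depth_lo)
      } else stats::runif(1, mt$depth_lo, mt$depth_hi)
      soma <- c(stats::runif(1, -w / 2, w / 2), soma_depth,
                stats::runif(1, -w / 2, w / 2))
      g <- gen_excitatory_cell(soma, mt, geometry)
      inp <- place_inputs(g$skeleton, mt$density, mt$soma_inputs,
                          mt$size_median, mt$size_sigma)
      if (!is.null(inp)) {
        inp$pre_cell <- NA_integer_; inp$post_cell <- cell_id
        inp$pre_vertex <- NA_integer_
        syn_parts[[length(syn_parts) + 1L]] <- inp
      }
      cells[[cell_id]] <- data.frame(
        cell_id = cell_id, soma_x = soma[1], soma_y = soma[2], soma_z = soma[3],
        nucleus_volume = 500, coarse_class = "excitatory",
        expert_subclass = mt$expert_label, stringsAsFactors = FALSE)
      skels[[cell_id]] <- g$skeleton
      truth_mtype[cell_id] <- mt$mtype
      truth_subclass[cell_id] <- NA_character_
      truth_apical[[cell_id]] <- if (is.na(g$apical_root)) integer(0) else g$apical_root
      truth_axon[[cell_id]] <- integer(0)
    }
  }
  n_exc <- cell_id

  ## --- inhibitory dendrites --------------------------------------------
  inh_rows <- inh[rep(seq_len(nrow(inh)), inh$n_cells), ]
  inh_target_bias <- vector("list", nrow(inh_rows))
  inhtc_counter <- 0L
  truth_inhtc <- character(0)
  for (j in seq_len(nrow(inh_rows))) {
    cell_id <- cell_id + 1L
    set.seed(substream_seed(spec$seed, cell_id))
    row <- inh_rows[j, ]
    soma <- c(stats::runif(1, -w / 2, w / 2),
              stats::runif(1, row$depth_lo, row$depth_hi),
              stats::runif(1, -w / 2, w / 2))
    store <- new_vertex_store()
    root <- add_vertex(store, NA, soma[1], soma[2], soma[3], 5, "soma")
    for (b in 1:4) {
      dir <- normalize3(stats::rnorm(3))
      grow_branch(store, root, soma, dir, row$dend_cable / 4, 50, 0.2, 0.4,
                  c(0, geometry$wm_depth - geometry$pia_depth))
    }
    sk <- skeleton(store_to_vertices(store))
    inp <- place_inputs(sk, row$dend_density, 30, 300, 0.35)
    if (!is.null(inp)) {
      inp$pre_cell <- NA_integer_; inp$post_cell <- cell_id
      inp$pre_vertex <- NA_integer_
      syn_parts[[length(syn_parts) + 1L]] <- inp
    }
    cells[[cell_id]] <- data.frame(
      cell_id = cell_id, soma_x = soma[1], soma_y = soma[2], soma_z = soma[3],
      nucleus_volume = 400, coarse_class = "inhibitory",
      expert_subclass = NA_character_, stringsAsFactors = FALSE)
    skels[[cell_id]] <- sk
    truth_mtype[cell_id] <- NA_character_
    truth_subclass[cell_id] <- row$subclass
    truth_apical[[cell_id]] <- integer(0)
    ## inhibitory-target bias: InhTCs alternate Dist- and Peri-specialists
    if (row$subclass == "InhTC") {
      inhtc_counter <- inhtc_counter + 1L
      if (inhtc_counter %% 2 == 1) {
        inh_target_bias[[j]] <- c(PeriTC = 0.08, DistTC = 0.80, SparTC = 0.08, InhTC = 0.04)
        truth_inhtc[as.character(cell_id)] <- "InhTC_Dist"
      } else {
        inh_target_bias[[j]] <- c(PeriTC = 0.80, DistTC = 0.08, SparTC = 0.08, InhTC = 0.04)
        truth_inhtc[as.character(cell_id)] <- "InhTC_Peri"
      }
    } else {
      inh_target_bias[[j]] <- c(PeriTC = 0.25, DistTC = 0.25, SparTC = 0.25, InhTC = 0.25)
    }
  }
  n_cells <- cell_id
  cells <- do.call(rbind, cells)

  ## --- background synapse frame for targeting ---------------------------
  bg <- do.call(rbind, syn_parts)
  bg_comp <- character(nrow(bg))
  bg_class <- character(nrow(bg))
  for (id in unique(bg$post_cell)) {
    rows <- which(bg$post_cell == id)
    sk <- skels[[id]]
    if (cells$coarse_class[id] == "inhibitory") {
      bg_comp[rows] <- "inhibitory"
      bg_class[rows] <- "inhibitory"
    } else {
      comp <- truth_compartments(sk, if (length(truth_apical[[id]]) > 0) truth_apical[[id]] else NA)
      bg_comp[rows] <- comp[match(bg$post_vertex[rows], sk$vertices$vertex_id)]
      bg_class[rows] <- truth_mtype[id]
    }
  }
  bg_depth <- depth_of(bg$x, bg$y, geometry)

  ## --- inhibitory outputs ------------------------------------------------
  comp_names <- c("soma", "proximal", "distal_basal", "apical", "inhibitory")
  out_parts <- list()
  for (j in seq_len(nrow(inh_rows))) {
    id <- n_exc + j
    set.seed(substream_seed(spec$seed, 100000 + id))
    row <- inh_rows[j, ]
    soma <- c(cells$soma_x[id], cells$soma_y[id], cells$soma_z[id])
    soma_d <- depth_of(soma[1], soma[2], geometry)
    dlo <- soma_d - row$span / 2
    dhi <- soma_d + row$span / 2
    elig <- which(bg_depth >= dlo & bg_depth <= dhi & bg$post_cell != id)
    if (length(elig) == 0) next
    pref <- as.numeric(row[c("pref_soma", "pref_proximal", "pref_distal_basal",
                             "pref_apical", "pref_inhibitory")])
    mult <- if (is.function(spec$multipliers)) spec$multipliers(row$subclass) else spec$multipliers
    wts <- numeric(length(elig))
    exc_rows <- bg_class[elig] != "inhibitory"
    wts[exc_rows] <- mult[bg_class[elig][exc_rows]]
    wts[!exc_rows] <- 1
    by_comp <- split(seq_along(elig), factor(bg_comp[elig], levels = comp_names))
    elig_bin <- depth_bin(bg_depth[elig], geometry)
    ## inhibitory-target draws pick the target subclass first (so planted
    ## inhibition-of-inhibition shares are realized exactly), then a cell
    ## within the subclass in proportion to its baseline synapses
    all_sc <- unique(truth_subclass[!is.na(truth_subclass)])
    bias <- stats::setNames(rep(1, length(all_sc)), all_sc)
    known <- intersect(names(inh_target_bias[[j]]), all_sc)
    bias[known] <- inh_target_bias[[j]][known]
    inh_cand <- by_comp[["inhibitory"]]
    inh_by_subclass <- split(inh_cand,
                             factor(truth_subclass[bg$post_cell[elig[inh_cand]]],
                                    levels = names(bias)))

    v0 <- skels[[id]]$vertices
    root_vid <- v0$vertex_id[skels[[id]]$root]
    next_vid <- max(v0$vertex_id)
    pos <- soma + c(2, 0, 0)
    prev_parent <- root_vid
    adir <- normalize3(stats::rnorm(3))
    placed <- 0L
    guard <- 0L
    ## preallocated per-cell accumulators, assembled into frames once
    cap <- as.integer(row$budget + 8)
    ax <- list(vid = integer(cap), x = numeric(cap), y = numeric(cap),
               z = numeric(cap), parent = integer(cap))
    sy <- list(post_cell = integer(cap), x = numeric(cap), y = numeric(cap),
               z = numeric(cap), size = numeric(cap), pre_vertex = integer(cap),
               post_vertex = integer(cap))
    n_ax <- 0L
    max_depth <- geometry$wm_depth - geometry$pia_depth
    while (placed < row$budget && guard < row$budget * 20) {
      guard <- guard + 1L
      ci <- sample.int(5, 1, prob = pref)
      if (comp_names[ci] == "inhibitory") {
        avail <- vapply(inh_by_subclass, length, integer(1)) > 0
        if (!any(avail)) next
        bsub <- bias[avail] / sum(bias[avail])
        sc_pick <- sample(names(bsub), 1, prob = bsub)
        cand <- inh_by_subclass[[sc_pick]]
        pick <- cand[sample.int(length(cand), 1)]
      } else {
        cand <- by_comp[[comp_names[ci]]]
        if (length(cand) == 0) next
        ## two-stage draw: the (depth bin, compartment) stratum follows the
        ## unweighted baseline (where the axon is); the multiplier acts on
        ## the target-class choice *within* the stratum
        r0 <- cand[sample.int(length(cand), 1)]
        stratum <- cand[elig_bin[cand] == elig_bin[r0]]
        wc <- wts[stratum]
        if (sum(wc) <= 0) next
        pick <- stratum[sample.int(length(stratum), 1, prob = wc)]
      }
      anchor <- elig[pick]
      target <- bg$post_cell[anchor]
      k <- 1L + stats::rpois(1, row$syn_per_conn_lambda)
      k <- min(k, row$budget - placed)
      ## postsynaptic rows: anchor plus other rows of same target & compartment
      same_target <- cand[bg$post_cell[elig[cand]] == target]
      tgt_rows <- elig[same_target]
      extra <- if (k > 1) tgt_rows[sample.int(length(tgt_rows), k - 1, replace = TRUE)] else integer(0)
      post_pick <- c(anchor, extra)
      ## presynaptic axon: waypoint gap then clumped spacings
      spacings <- c(20 + stats::rexp(1, 1 / 50),
                    if (k > 1) 0.5 + stats::rexp(k - 1, 1 / row$clump_scale))
      for (s in seq_len(k)) {
        adir <- normalize3(adir + stats::rnorm(3, 0, 0.3))
        newpos <- pos + adir * spacings[s]
        dcur <- depth_of(newpos[1], newpos[2], geometry)
        if (dcur < 5 || dcur > max_depth - 5) {
          adir[2] <- -adir[2]
          newpos <- pos + adir * spacings[s]
        }
        pos <- newpos
        next_vid <- next_vid + 1L
        n_ax <- n_ax + 1L
        ax$vid[n_ax] <- next_vid
        ax$x[n_ax] <- pos[1]; ax$y[n_ax] <- pos[2]; ax$z[n_ax] <- pos[3]
        ax$parent[n_ax] <- prev_parent
        prev_parent <- next_vid
        sy$post_cell[n_ax] <- target
        sy$x[n_ax] <- bg$x[post_pick[s]]
        sy$y[n_ax] <- bg$y[post_pick[s]]
        sy$z[n_ax] <- bg$z[post_pick[s]]
        sy$size[n_ax] <- stats::rlnorm(1, log(350), 0.4)
        sy$pre_vertex[n_ax] <- next_vid
        sy$post_vertex[n_ax] <- bg$post_vertex[post_pick[s]]
      }
      placed <- placed + k
    }
    if (n_ax > 0) {
      ax <- lapply(ax, function(v) v[seq_len(n_ax)])
      sy <- lapply(sy, function(v) v[seq_len(n_ax)])
      av <- data.frame(vertex_id = ax$vid, x = ax$x, y = ax$y, z = ax$z,
                       radius = 0.3, parent = ax$parent, label = "axon",
                       stringsAsFactors = FALSE)
      skels[[id]] <- skeleton(rbind(
        v0[, c("vertex_id", "x", "y", "z", "radius", "parent", "label")], av))
      truth_axon[[id]] <- av$vertex_id
      out_parts[[length(out_parts) + 1L]] <- data.frame(
        pre_cell = id, post_cell = sy$post_cell, x = sy$x, y = sy$y, z = sy$z,
        size = sy$size, pre_vertex = sy$pre_vertex, post_vertex = sy$post_vertex)
    }
  }

  ## --- assemble tables ---------------------------------------------------
  bg$pre_cell <- NA_integer_
  bg_tab <- data.frame(pre_cell = NA_integer_, post_cell = bg$post_cell,
                       x = bg$x, y = bg$y, z = bg$z, size = bg$size,
                       pre_vertex = NA_integer_, post_vertex = bg$post_vertex)
  out_tab <- if (length(out_parts) > 0) do.call(rbind, out_parts) else NULL
  syn <- rbind(bg_tab, out_tab[, names(bg_tab)])
  syn <- cbind(synapse_id = seq_len(nrow(syn)), syn)

  ## expert labels on a deterministic subset of inhibitory cells
  set.seed(substream_seed(spec$seed, 999983))
  inh_ids <- which(cells$coarse_class == "inhibitory")
  n_lab <- max(8L, as.integer(round(spec$expert_label_fraction * length(inh_ids))))
  lab_ids <- sort(sample(inh_ids, min(n_lab, length(inh_ids))))
  ## guarantee >= 2 labels per subclass
  for (sc in unique(truth_subclass[inh_ids])) {
    have <- sum(truth_subclass[lab_ids] == sc, na.rm = TRUE)
    if (have < 2) {
      extra <- setdiff(inh_ids[truth_subclass[inh_ids] == sc], lab_ids)
      lab_ids <- sort(c(lab_ids, utils::head(extra, 2 - have)))
    }
  }
  cells$expert_subclass[inh_ids] <- NA_character_
  cells$expert_subclass[lab_ids] <- truth_subclass[lab_ids]

  mult_record <- if (is.function(spec$multipliers)) {
    lapply(stats::setNames(inh$subclass, inh$subclass), spec$multipliers)
  } else {
    as.list(spec$multipliers)
  }
  gt <- list(
    mtype = stats::setNames(truth_mtype, cells$cell_id),
    subclass = stats::setNames(truth_subclass, cells$cell_id),
    inhtc_subtype = truth_inhtc,
    apical_roots = stats::setNames(truth_apical, cells$cell_id),
    axon_vertices = stats::setNames(truth_axon, cells$cell_id),
    multipliers = mult_record
  )
  names(skels) <- as.character(cells$cell_id)
  bundle <- structure(list(cells = cells, skeletons = skels, synapses = syn,
                           geometry = geometry, ground_truth = gt),
                      class = "column_bundle")
  validate_bundle(bundle)
}

#' Generate a mixed input/output neuron for axon-split tests
#'
#' Two designated subtrees hang off the root: a dendrite-designated and
#' an axon-designated subtree. A fraction \code{1 - epsilon} of output
#' synapses land on the axon subtree (and of inputs on the dendrite
#' subtree); \code{epsilon = 0} gives perfect segregation,
#' \code{epsilon = 0.5} uniform mixing.
#'
#' @param n_inputs,n_outputs synapse counts
#' @param epsilon mixing fraction in [0, 0.5]
#' @param seed RNG seed
#' @param n_vertices_per_subtree chain length per subtree (default 50)
#' @return list: \code{skeleton}, \code{input_vertices},
#'   \code{output_vertices}, \code{axon_vertex_ids} (planted truth)
#' @export
generate_mixed_neuron <- function(n_inputs, n_outputs, epsilon, seed = 1,
                                  n_vertices_per_subtree = 50) {
  set.seed(seed)
  nv <- n_vertices_per_subtree
  ## root at origin; subtree A along +x (dendrite), subtree B along -x (axon)
  mk_chain <- function(start_id, sign) {
    data.frame(vertex_id = start_id + seq_len(nv) - 1L,
               x = sign * 5 * seq_len(nv),
               y = stats::rnorm(nv, 0, 0.5), z = stats::rnorm(nv, 0, 0.5),
               radius = 0.5,
               parent = c(1L, start_id + seq_len(nv - 1) - 1L),
               label = "dendrite", stringsAsFactors = FALSE)
  }
  root <- data.frame(vertex_id = 1L, x = 0, y = 0, z = 0, radius = 5,
                     parent = NA_integer_, label = "soma", stringsAsFactors = FALSE)
  A <- mk_chain(2L, +1)
  B <- mk_chain(2L + nv, -1)
  sk <- skeleton(rbind(root, A, B))
  on_dend <- stats::runif(n_inputs) < (1 - epsilon)
  input_vertices <- ifelse(on_dend, sample(A$vertex_id, n_inputs, replace = TRUE),
                           sample(B$vertex_id, n_inputs, replace = TRUE))
  on_axon <- stats::runif(n_outputs) < (1 - epsilon)
  output_vertices <- ifelse(on_axon, sample(B$vertex_id, n_outputs, replace = TRUE),
                            sample(A$vertex_id, n_outputs, replace = TRUE))
  list(skeleton = sk, input_vertices = input_vertices,
       output_vertices = output_vertices, axon_vertex_ids = B$vertex_id)
}

## ---- study-condition scenario specs ---------------------------------------

#' Calibration column: selectivity-free, single-synapse connections
#'
#' Study conditions for checking the Selectivity Index null calibration:
#' all multipliers 1 and synapses-per-connection fixed at 1, so each
#' output synapse is an independent draw from the baseline conditional —
#' the permutation null's own generative model.
#' @param seed master seed
#' @param n_interneurons number of interneurons (default 200)
#' @param n_per_type excitatory cells per M-type (default 16)
#' @param budget output synapses per interneuron (default 200)
#' @export
calibration_spec <- function(seed = 1, n_interneurons = 200, n_per_type = 16,
                             budget = 200) {
  inh <- data.frame(
    subclass = "DistTC", n_cells = n_interneurons, budget = budget,
    pref_soma = 0.15, pref_proximal = 0.20, pref_distal_basal = 0.40,
    pref_apical = 0.15, pref_inhibitory = 0.10,
    syn_per_conn_lambda = 0, clump_scale = 8, span = 500,
    depth_lo = 120, depth_hi = 900,
    dend_cable = 300, dend_density = 0.4, stringsAsFactors = FALSE)
  column_spec(seed = seed, mtypes = default_mtype_params(n_per_type), inhibitory = inh)
}

#' Recovery column: planted selectivity multiplier on a rare M-type
#'
#' Adds a sparse cross-layer M-type ("Lsp", ~3 percent of baseline
#' synapses) and interneurons carrying the planted multiplier for it.
#' The rare target keeps the finite-budget SI compression negligible
#' (SI ~ m / (1 + (m - 1) b) for baseline share b).
#' @param seed master seed
#' @param multiplier planted selectivity multiplier for "Lsp"
#' @param n_interneurons interneurons carrying the multiplier (default 10)
#' @param budget output synapses per interneuron (default 400)
#' @export
recovery_spec <- function(seed = 1, multiplier = 2, n_interneurons = 24,
                          budget = 2400) {
  mts <- default_mtype_params(16)
  ## broad contiguous depth bands: the baseline must cover every depth bin
  ## smoothly so the rare type's share is well-defined in all strata
  mts$depth_lo <- c(100, 100, 200, 320, 320, 500, 500, 700)
  mts$depth_hi <- c(200, 200, 320, 500, 500, 700, 700, 950)
  ## the rare reference type is spread evenly over depth with modest
  ## arbors: SI compresses by 1/(1 + (m-1) b_local), so the type's LOCAL
  ## per-stratum share must stay small and smooth, and its input density
  ## must stay well above the false-merge pruning threshold
  lsp <- data.frame(
    mtype = "Lsp", expert_label = "Lsp", n_cells = 12,
    depth_lo = 150, depth_hi = 850, n_basal = 2, cable = 400, seg_len = 60,
    apical = FALSE, apical_trunk = 0, tuft_n = 0, tuft_len = 0,
    jitter = 0.2, density = 0.30, soma_inputs = 5,
    size_median = 300, size_sigma = 0.35, radius = 0.35,
    stringsAsFactors = FALSE)
  mts$even_depth <- FALSE
  lsp$even_depth <- TRUE
  mts <- rbind(mts, lsp)
  inh <- data.frame(
    subclass = "DistTC", n_cells = n_interneurons, budget = budget,
    pref_soma = 0, pref_proximal = 0, pref_distal_basal = 0.9,
    pref_apical = 0, pref_inhibitory = 0.10,
    syn_per_conn_lambda = 0, clump_scale = 8, span = 900,
    depth_lo = 150, depth_hi = 850,
    dend_cable = 300, dend_density = 0.4, stringsAsFactors = FALSE)
  mult <- stats::setNames(rep(1, nrow(mts)), mts$mtype)
  mult["Lsp"] <- multiplier
  column_spec(seed = seed, mtypes = mts, inhibitory = inh, multipliers = mult)
}

#' Motif-archetype column: four planted targeting archetypes
#'
#' Forty interneurons in four groups of ten; each group carries a strong
#' multiplier for a disjoint pair of M-types, planting four distinct
#' output-budget archetypes for motif-group recovery.
#' @param seed master seed
#' @param n_per_type excitatory cells per M-type (default 16)
#' @param boost archetype multiplier (default 8)
#' @export
motif_spec <- function(seed = 1, n_per_type = 16, boost = 15) {
  arch <- list(c("L2a", "L2b"), c("L3a", "L4a"), c("L4b", "L5a"), c("L5b", "L6a"))
  inh <- data.frame(
    subclass = paste0("Arch", 1:4), n_cells = 10, budget = 350,
    pref_soma = 0.15, pref_proximal = 0.20, pref_distal_basal = 0.50,
    pref_apical = 0.10, pref_inhibitory = 0.05,
    syn_per_conn_lambda = 1, clump_scale = 8, span = 200,
    depth_lo = c(160, 300, 470, 720), depth_hi = c(190, 330, 500, 750),
    dend_cable = 300, dend_density = 0.4, stringsAsFactors = FALSE)
  mts <- default_mtype_params(n_per_type)
  mult_fun <- function(subclass) {
    m <- stats::setNames(rep(1, nrow(mts)), mts$mtype)
    k <- as.integer(sub("Arch", "", subclass))
    m[arch[[k]]] <- boost
    m
  }
  column_spec(seed = seed, mtypes = mts, inhibitory = inh, multipliers = mult_fun)
}
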