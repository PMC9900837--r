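#' Pipeline orchestration and connectivity cards
#'
#' Stages run in dependency order: compartments -> subclasses -> mtypes
#' -> connectivity -> selectivity -> cards. Each stage writes plain-text
#' artifacts (CSV/JSON) into the output directory plus a manifest with
#' the configuration and per-file checksums; identical configuration and
#' seed give byte-identical artifacts.
#'
#' @name cli_reports
NULL

#' Process every cell of a bundle (collapse, axon, prune, compartments)
#'
#' @param bundle a \code{column_bundle}
#' @param apical apical-branch source for excitatory cells:
#'   \code{"truth"} (planted ground-truth branch roots; synthetic bundles
#'   only), \code{"model"} (random-forest vertex model trained on the
#'   bundle's planted labels), or \code{"none"}
#' @param apical_model optional pre-trained vertex model used when
#'   \code{apical = "model"}; if NULL one is trained on the bundle
#' @param training_cells number of cells used to train the vertex model
#'   (default 40)
#' @param seed RNG seed for model training
#' @return the bundle with labeled skeletons, synapse vertex references
#'   remapped through the soma collapse, and a \code{processing} element
#'   (per-cell axon/prune/apical records)
#' @export
process_column <- function(bundle, apical = c("truth", "model", "none"),
                           apical_model = NULL, training_cells = 40, seed = 1) {
  apical <- match.arg(apical)
  cells <- bundle$cells
  syn <- bundle$synapses
  gt <- bundle$ground_truth
  if (apical == "truth" && is.null(gt)) stop("apical = 'truth' needs a ground truth")
  if (apical == "model" && is.null(apical_model)) {
    apical_model <- train_apical_model_on_bundle(bundle, training_cells, seed)
  }
  ## planted apical membership in original vertex ids, per cell
  apical_members <- function(id) {
    sk <- bundle$skeletons[[as.character(id)]]
    roots <- gt$apical_roots[[as.character(id)]]
    if (length(roots) == 0) return(integer(0))
    unlist(lapply(roots, function(r) sk$vertices$vertex_id[subtree_index(sk, vertex_index(sk, r))]))
  }
  processing <- list()
  for (i in seq_len(nrow(cells))) {
    id <- cells$cell_id[i]
    key <- as.character(id)
    sk <- bundle$skeletons[[key]]
    in_rows <- which(syn$post_cell == id)
    out_rows <- which(!is.na(syn$pre_cell) & syn$pre_cell == id)
    vp <- NULL; model <- NULL
    if (cells$coarse_class[i] == "excitatory") {
      if (apical == "truth") {
        members <- apical_members(id)
        vp <- function(csk) ifelse(csk$vertices$vertex_id %in% members, 0.999, 0.001)
      } else if (apical == "model") {
        model <- apical_model
      }
    }
    res <- process_cell(sk, cells$nucleus_volume[i],
                        input_vertices = syn$post_vertex[in_rows],
                        output_vertices = syn$pre_vertex[out_rows],
                        coarse_class = cells$coarse_class[i],
                        geometry = bundle$geometry,
                        apical_model = model, vertex_probability = vp)
    bundle$skeletons[[key]] <- res$skeleton
    syn$post_vertex[in_rows] <- unname(res$vertex_map[as.character(syn$post_vertex[in_rows])])
    syn$pre_vertex[out_rows] <- unname(res$vertex_map[as.character(syn$pre_vertex[out_rows])])
    processing[[key]] <- list(axon = res$axon, pruned = res$pruned_vertex_ids,
                              apical = res$apical_scores)
  }
  bundle$synapses <- syn
  bundle$processing <- processing
  bundle
}

#' Train the apical vertex model on a bundle's planted labels
#' @param bundle synthetic \code{column_bundle} with ground truth
#' @param training_cells excitatory cells to pool (default 40)
#' @param seed RNG seed
#' @return a \code{randomForest} vertex model
#' @export
train_apical_model_on_bundle <- function(bundle, training_cells = 40, seed = 1) {
  gt <- bundle$ground_truth
  if (is.null(gt)) stop("training requires planted apical labels")
  exc <- bundle$cells$cell_id[bundle$cells$coarse_class == "excitatory"]
  set.seed(substream_seed(seed, 424243))
  train_ids <- sort(sample(exc, min(training_cells, length(exc))))
  feats <- list(); labs <- list()
  for (id in train_ids) {
    sk <- bundle$skeletons[[as.character(id)]]
    f <- vertex_apical_features(sk, bundle$geometry)
    roots <- gt$apical_roots[[as.character(id)]]
    members <- if (length(roots) == 0) integer(0) else
      unlist(lapply(roots, function(r) sk$vertices$vertex_id[subtree_index(sk, vertex_index(sk, r))]))
    feats[[as.character(id)]] <- f
    labs[[as.character(id)]] <- f$vertex_id %in% members
  }
  train_apical_vertex_model(do.call(rbind, feats), unlist(labs), seed = seed)
}

#' Annotate connectivity synapses with compartments and target classes
#'
#' @param bundle a processed \code{column_bundle}
#' @param mtype optional named M-type vector (names = excitatory cell
#'   ids); when supplied, \code{target_class} is the M-type for
#'   excitatory targets and "inhibitory" for inhibitory targets
#' @return synapse data.frame with \code{post_class},
#'   \code{post_compartment} ("inhibitory" for inhibitory targets) and
#'   \code{target_class}
#' @export
annotate_synapses <- function(bundle, mtype = NULL) {
  syn <- connectivity_synapses(bundle)
  cls <- bundle$cells$coarse_class[match(syn$post_cell, bundle$cells$cell_id)]
  syn$post_class <- cls
  comp <- rep(NA_character_, nrow(syn))
  for (id in unique(syn$post_cell)) {
    rows <- which(syn$post_cell == id)
    sk <- bundle$skeletons[[as.character(id)]]
    comp[rows] <- synapse_compartments(sk, syn$post_vertex[rows])
  }
  comp[cls == "inhibitory"] <- "inhibitory"
  syn$post_compartment <- comp
  syn$target_class <- ifelse(cls == "inhibitory", "inhibitory",
                             if (is.null(mtype)) NA_character_ else
                               mtype[as.character(syn$post_cell)])
  syn
}

#' Run the full analysis pipeline and write versioned artifacts
#'
#' @param bundle a \code{column_bundle} (typically from
#'   \code{\link{generate_column}} or \code{\link{read_bundle}})
#' @param out_dir artifact directory (created)
#' @param config list of stage parameters: \code{seed},
#'   \code{apical} ("truth"/"model"/"none"), \code{n_consensus_runs},
#'   \code{knn}, \code{resolution}, \code{n_shuffles},
#'   \code{clump_threshold}; missing entries take defaults
#' @param stages stages to run (default all); earlier-stage artifacts
#'   must already exist in \code{out_dir} when skipped
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(bundle, out_dir,
                         config = list(),
                         stages = c("compartments", "subclasses", "mtypes",
                                    "connectivity", "selectivity", "cards")) {
  defaults <- list(seed = 1, apical = "truth", n_consensus_runs = 100,
                   knn = 10, resolution = 1.3, n_shuffles = 500,
                   clump_threshold = 15)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifact <- function(name) file.path(out_dir, name)
  cells <- bundle$cells
  inh_ids <- cells$cell_id[cells$coarse_class == "inhibitory"]
  exc_ids <- cells$cell_id[cells$coarse_class == "excitatory"]

  ## ---- compartments stage ------------------------------------------------
  if ("compartments" %in% stages) {
    message("[compartments] processing ", nrow(cells), " cells")
    proc <- process_column(bundle, apical = config$apical, seed = config$seed)
    ann <- annotate_synapses(proc)
    utils::write.csv(ann, artifact("synapse_annotations.csv"), row.names = FALSE)
    saveRDS_plain_labels(proc, artifact("vertex_labels.csv"))
  } else {
    proc <- process_column(bundle, apical = config$apical, seed = config$seed)
    if (!file.exists(artifact("synapse_annotations.csv"))) {
      stop("stage 'compartments' must run first: missing synapse_annotations.csv")
    }
    ann <- utils::read.csv(artifact("synapse_annotations.csv"), stringsAsFactors = FALSE)
  }

  ## ---- subclasses stage ----------------------------------------------------
  if ("subclasses" %in% stages) {
    message("[subclasses] targeting features for ", length(inh_ids), " interneurons")
    feats <- list()
    for (id in inh_ids) {
      s <- ann[!is.na(ann$pre_cell) & ann$pre_cell == id, , drop = FALSE]
      if (nrow(s) == 0) next
      feats[[as.character(id)]] <- cbind(
        cell_id = id,
        targeting_features(s, proc$skeletons[[as.character(id)]],
                           clump_threshold = config$clump_threshold))
    }
    features <- do.call(rbind, feats)
    expert <- stats::setNames(cells$expert_subclass, cells$cell_id)
    fit <- fit_and_assign_subclasses(features, expert)
    sc_tab <- merge(features, fit$assignments, by = "cell_id")
    subclass <- stats::setNames(sc_tab$assigned_subclass, sc_tab$cell_id)
    inhtc <- split_inhtc(sc_tab$cell_id[sc_tab$assigned_subclass == "InhTC"],
                         ann[ann$post_class == "inhibitory", , drop = FALSE],
                         subclass)
    sc_tab$inhtc_subtype <- inhtc$subtype[match(sc_tab$cell_id, inhtc$cell_id)]
    utils::write.csv(sc_tab, artifact("subclasses.csv"), row.names = FALSE)
  }

  ## ---- mtypes stage --------------------------------------------------------
  if ("mtypes" %in% stages) {
    message("[mtypes] 29-feature suite + consensus clustering for ",
            length(exc_ids), " cells")
    fm <- feature_matrix(proc, exc_ids)
    cc <- consensus_cluster(fm$features, n_runs = config$n_consensus_runs,
                            knn = config$knn, resolution = config$resolution,
                            seed = config$seed)
    expert_exc <- cells$expert_subclass[match(exc_ids, cells$cell_id)]
    depths <- cells$soma_depth[match(exc_ids, cells$cell_id)]
    names_mt <- name_and_order_clusters(cc$labels, expert_exc, depths)
    mt_tab <- data.frame(cell_id = exc_ids, cluster = cc$labels,
                         mtype = as.character(names_mt), soma_depth = depths)
    utils::write.csv(mt_tab, artifact("mtypes.csv"), row.names = FALSE)
    jsonlite::write_json(list(depth = fm$components$depth,
                              soma = fm$components$soma,
                              branch = fm$components$branch,
                              db_trace = as.list(cc$db_trace),
                              sil_trace = as.list(cc$sil_trace)),
                         artifact("components.json"), digits = NA)
  } else if (any(c("connectivity", "selectivity") %in% stages)) {
    if (!file.exists(artifact("mtypes.csv"))) {
      stop("stage 'mtypes' must run first: missing mtypes.csv")
    }
    mt_tab <- utils::read.csv(artifact("mtypes.csv"), stringsAsFactors = FALSE)
  } else {
    mt_tab <- NULL
  }
  if (!is.null(mt_tab)) {
    mtype <- stats::setNames(mt_tab$mtype, mt_tab$cell_id)
    ann$target_class <- ifelse(ann$post_class == "inhibitory", "inhibitory",
                               mtype[as.character(ann$post_cell)])
  }

  ## ---- connectivity stage --------------------------------------------------
  if ("connectivity" %in% stages) {
    message("[connectivity] output budgets and motif groups")
    syn_ie <- ann[!is.na(ann$pre_cell) & ann$post_class == "excitatory", , drop = FALSE]
    budgets <- output_budget_matrix(inh_ids, ann, mtype)
    mtype_depth <- tapply(mt_tab$soma_depth, mt_tab$mtype, stats::median)
    ## small interneuron populations need a smaller neighbourhood
    knn_budget <- max(3, min(config$knn, nrow(budgets) %/% 2 - 1))
    mg <- motif_groups(budgets, syn_ie, mtype, mtype_depth,
                       n_runs = config$n_consensus_runs, knn = knn_budget,
                       resolution = config$resolution, seed = config$seed)
    bud_tab <- data.frame(cell_id = as.numeric(rownames(budgets)),
                          motif_group = mg$groups[rownames(budgets)], budgets)
    utils::write.csv(bud_tab, artifact("budgets.csv"), row.names = FALSE)
    utils::write.csv(data.frame(group = rownames(mg$output_fraction),
                                mg$output_fraction),
                     artifact("motif_output_fraction.csv"), row.names = FALSE)
    utils::write.csv(data.frame(group = rownames(mg$input_fraction),
                                mg$input_fraction),
                     artifact("motif_input_fraction.csv"), row.names = FALSE)
  }

  ## ---- selectivity stage -----------------------------------------------------
  if ("selectivity" %in% stages) {
    message("[selectivity] ", config$n_shuffles, " shuffles per interneuron")
    baseline <- build_baseline(ann, bundle$geometry)
    si <- selectivity_table(ann[!is.na(ann$pre_cell), , drop = FALSE],
                            baseline, bundle$geometry, inh_ids,
                            n_shuffles = config$n_shuffles, seed = config$seed)
    utils::write.csv(si, artifact("selectivity.csv"), row.names = FALSE)
    cp <- list()
    for (id in inh_ids) {
      s <- ann[!is.na(ann$pre_cell) & ann$pre_cell == id, , drop = FALSE]
      if (nrow(s) == 0) next
      obs <- data.frame(depth_bin = depth_bin(s$depth, bundle$geometry),
                        compartment = s$post_compartment,
                        target_class = s$target_class)
      cp[[as.character(id)]] <- cbind(pre_cell = id,
        compartment_preference(obs, baseline, n_shuffles = config$n_shuffles,
                               seed = substream_seed(config$seed, id + 7)))
    }
    utils::write.csv(do.call(rbind, cp), artifact("compartment_preference.csv"),
                     row.names = FALSE)
  }

  ## ---- cards stage -------------------------------------------------------------
  if ("cards" %in% stages) {
    message("[cards] writing connectivity cards")
    dir.create(artifact("cards"), showWarnings = FALSE)
    for (id in inh_ids) {
      card <- connectivity_card(id, out_dir, proc)
      if (!is.null(card)) {
        jsonlite::write_json(card, artifact(file.path("cards", paste0(id, ".json"))),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
    }
  }

  ## manifest with checksums
  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config = config,
                   artifacts = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, artifact("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## per-vertex label table as CSV (cell, vertex, label, compartment)
saveRDS_plain_labels <- function(proc, path) {
  rows <- lapply(names(proc$skeletons), function(key) {
    v <- proc$skeletons[[key]]$vertices
    data.frame(cell_id = as.numeric(key), vertex_id = v$vertex_id,
               label = v$label, compartment = v$compartment,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Assemble a connectivity card for one interneuron from stage artifacts
#'
#' Cards summarize a cell's morphology, compartment-output histogram,
#' per-M-type output fractions, selectivity (with significance) and
#' compartment preference — every number traceable to a stage artifact.
#'
#' @param cell_id interneuron id
#' @param artifact_dir pipeline output directory
#' @param proc optional processed bundle (for the morphology summary)
#' @return list (JSON-ready) or NULL when the cell has no outputs
#' @export
connectivity_card <- function(cell_id, artifact_dir, proc = NULL) {
  rd <- function(name) {
    p <- file.path(artifact_dir, name)
    if (!file.exists(p)) stop("missing prerequisite artifact: ", name)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  sc <- rd("subclasses.csv")
  bud <- rd("budgets.csv")
  si <- rd("selectivity.csv")
  cp <- rd("compartment_preference.csv")
  ann <- rd("synapse_annotations.csv")
  row <- sc[sc$cell_id == cell_id, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  s <- ann[!is.na(ann$pre_cell) & ann$pre_cell == cell_id, , drop = FALSE]
  comp_hist <- table(s$post_compartment)
  comp_hist <- as.list(as.numeric(comp_hist) / sum(comp_hist)) |>
    stats::setNames(names(comp_hist))
  morph <- NULL
  if (!is.null(proc)) {
    sk <- proc$skeletons[[as.character(cell_id)]]
    dend <- !(sk$vertices$label %in% c("axon", "pruned"))
    morph <- list(cable_length = sum(sk$edge_len[dend]),
                  depth_extent = diff(range(sk$vertices$depth[dend])),
                  soma_depth = sk$vertices$depth[sk$root])
  }
  bud_row <- bud[bud$cell_id == cell_id, , drop = FALSE]
  mt_cols <- setdiff(names(bud_row), c("cell_id", "motif_group"))
  si_rows <- si[si$pre_cell == cell_id, , drop = FALSE]
  cp_rows <- cp[cp$pre_cell == cell_id, , drop = FALSE]
  list(cell_id = cell_id,
       subclass = row$assigned_subclass,
       inhtc_subtype = row$inhtc_subtype,
       morphology = morph,
       compartment_output = comp_hist,
       motif_group = if (nrow(bud_row) > 0) bud_row$motif_group else NA,
       output_budget = if (nrow(bud_row) > 0)
         as.list(bud_row[1, mt_cols]) else NULL,
       selectivity = si_rows[, c("target_class", "observed", "shuffle_median",
                                 "si", "p_adj", "significant")],
       compartment_preference = cp_rows[, c("target_class", "si", "p_adj",
                                            "significant")])
}
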