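#' Read and write column data bundles
#'
#' A bundle directory holds one SWC skeleton per cell
#' (\code{skeletons/<cell_id>.swc}), a synapse table
#' (\code{synapses.csv}), a cell table (\code{cells.csv}), a geometry
#' config (\code{geometry.json}) and, for synthetic columns, a planted
#' ground truth (\code{ground_truth.json}).
#'
#' @name bundle
NULL

#' @describeIn bundle read a column geometry from JSON
#' @param path file or directory path
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  column_geometry(pia_depth = g$pia_depth, wm_depth = g$wm_depth,
                  layer_boundaries = g$layer_boundaries,
                  rotation_angle = g$rotation_angle %||% 0,
                  depth_bin_width = g$depth_bin_width %||% 20)
}

#' @describeIn bundle write a column geometry to JSON
#' @param geometry a \code{column_geometry}
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry)[c("pia_depth", "wm_depth", "layer_boundaries",
                                           "rotation_angle", "depth_bin_width")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

synapse_columns <- c("synapse_id", "pre_cell", "post_cell", "x", "y", "z",
                     "size", "pre_vertex", "post_vertex")
cell_columns <- c("cell_id", "soma_x", "soma_y", "soma_z", "nucleus_volume",
                  "coarse_class", "expert_subclass")

#' Read a full bundle into a cross-linked in-memory model
#'
#' Validates that every skeleton is a rooted tree, that every neuronal
#' cell referenced by a synapse exists in the cell table and has a
#' skeleton, and that synapse vertex references resolve. Computes the
#' depth coordinate (after applying the geometry's rotation) for every
#' vertex and synapse. Synapses with \code{pre_cell = NA} are background
#' inputs from unidentified partners outside the modeled population.
#'
#' @param dir bundle directory
#' @return list of class \code{column_bundle}: \code{cells},
#'   \code{skeletons} (named by cell id), \code{synapses},
#'   \code{geometry}, and \code{ground_truth} if present.
#' @export
read_bundle <- function(dir) {
  geometry <- read_geometry(file.path(dir, "geometry.json"))
  cells <- utils::read.csv(file.path(dir, "cells.csv"), stringsAsFactors = FALSE)
  synapses <- utils::read.csv(file.path(dir, "synapses.csv"), stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = FALSE)
    named_chr <- function(l) {
      out <- vapply(l, function(e) if (is.null(e)) NA_character_ else as.character(e),
                    character(1))
      stats::setNames(out, names(l))
    }
    list(mtype = named_chr(gt$mtype),
         subclass = named_chr(gt$subclass),
         inhtc_subtype = named_chr(gt$inhtc_subtype),
         apical_roots = lapply(gt$apical_roots, function(e) as.numeric(unlist(e))),
         axon_vertices = lapply(gt$axon_vertices, function(e) as.numeric(unlist(e))),
         multipliers = lapply(gt$multipliers, function(e) unlist(e)))
  } else NULL
  skels <- lapply(cells$cell_id, function(id) {
    p <- file.path(dir, "skeletons", paste0(id, ".swc"))
    if (!file.exists(p)) stop("missing skeleton for cell ", id)
    read_swc(p)
  })
  names(skels) <- as.character(cells$cell_id)
  bundle <- structure(list(cells = cells, skeletons = skels, synapses = synapses,
                           geometry = geometry, ground_truth = ground_truth),
                      class = "column_bundle")
  validate_bundle(bundle)
}

#' Validate and cross-link a bundle (depth columns, reference checks)
#' @param bundle a \code{column_bundle}
#' @export
validate_bundle <- function(bundle) {
  cells <- bundle$cells; syn <- bundle$synapses; geometry <- bundle$geometry
  ref <- unique(c(syn$pre_cell[!is.na(syn$pre_cell)], syn$post_cell))
  missing_cells <- setdiff(ref, cells$cell_id)
  if (length(missing_cells) > 0) {
    stop("synapse references cells absent from cell table: ",
         paste(utils::head(missing_cells, 5), collapse = ", "))
  }
  for (id in ref) {
    if (is.null(bundle$skeletons[[as.character(id)]])) stop("missing skeleton for cell ", id)
  }
  ## vertex references must resolve
  check_vertex <- function(cell, vertex, what) {
    ok <- which(!is.na(cell))
    for (id in unique(cell[ok])) {
      rows <- ok[cell[ok] == id]
      sk <- bundle$skeletons[[as.character(id)]]
      bad <- is.na(match(vertex[rows], sk$vertices$vertex_id))
      if (any(bad)) stop("dangling ", what, " reference for cell ", id,
                         " vertex ", vertex[rows][which(bad)[1]])
    }
  }
  check_vertex(syn$post_cell, syn$post_vertex, "post_vertex")
  check_vertex(syn$pre_cell, syn$pre_vertex, "pre_vertex")

  bundle$synapses$depth <- depth_of(syn$x, syn$y, geometry)
  bundle$cells$soma_depth <- depth_of(cells$soma_x, cells$soma_y, geometry)
  bundle$skeletons <- lapply(bundle$skeletons, function(sk) {
    sk$vertices$depth <- depth_of(sk$vertices$x, sk$vertices$y, geometry)
    sk
  })
  n_autapse <- sum(!is.na(syn$pre_cell) & syn$pre_cell == syn$post_cell)
  if (n_autapse > 0) message(n_autapse, " autapse(s) retained in table; excluded from connectivity statistics")
  bundle
}

#' Write a bundle directory
#' @param bundle a \code{column_bundle}
#' @param dir output directory (created if needed)
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "skeletons"), recursive = TRUE, showWarnings = FALSE)
  cells <- bundle$cells; cells$soma_depth <- NULL
  syn <- bundle$synapses; syn$depth <- NULL
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(syn, file.path(dir, "synapses.csv"), row.names = FALSE)
  write_geometry(bundle$geometry, file.path(dir, "geometry.json"))
  if (!is.null(bundle$ground_truth)) {
    gt <- bundle$ground_truth
    ## named vectors as JSON objects (lists) so names survive the round trip
    gt_json <- list(mtype = as.list(gt$mtype), subclass = as.list(gt$subclass),
                    inhtc_subtype = as.list(gt$inhtc_subtype),
                    apical_roots = gt$apical_roots,
                    axon_vertices = gt$axon_vertices,
                    multipliers = gt$multipliers)
    jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  for (id in names(bundle$skeletons)) {
    write_swc(bundle$skeletons[[id]], file.path(dir, "skeletons", paste0(id, ".swc")))
  }
  invisible(dir)
}

#' Synapses usable for connectivity statistics
#'
#' Drops autapses and synapses whose postsynaptic vertex was pruned or
#' lies on the target's axon (when skeleton labels are available).
#' @param bundle a \code{column_bundle} (skeletons must carry labels)
#' @param drop_autapses drop pre == post synapses (default TRUE)
#' @return filtered synapse table
#' @export
connectivity_synapses <- function(bundle, drop_autapses = TRUE) {
  syn <- bundle$synapses
  if (drop_autapses) {
    syn <- syn[is.na(syn$pre_cell) | syn$pre_cell != syn$post_cell, , drop = FALSE]
  }
  keep <- rep(TRUE, nrow(syn))
  for (id in unique(syn$post_cell)) {
    rows <- which(syn$post_cell == id)
    sk <- bundle$skeletons[[as.character(id)]]
    lab <- sk$vertices$label[match(syn$post_vertex[rows], sk$vertices$vertex_id)]
    keep[rows] <- !(lab %in% c("pruned", "axon"))
  }
  syn[keep, , drop = FALSE]
}
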