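#' Neuron skeletons as rooted trees
#'
#' A skeleton is a rooted tree of 3-D vertices with per-vertex radius,
#' a processing label (\code{soma}, \code{dendrite}, \code{axon},
#' \code{pruned}) and, after compartment labeling, a compartment
#' (\code{soma}, \code{proximal}, \code{distal_basal}, \code{apical}).
#' Coordinates are in micrometers; the root vertex is the soma.
#'
#' @param vertices data.frame with columns \code{vertex_id}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent} (\code{NA} for the
#'   root), and optionally \code{label} and \code{compartment}.
#' @param validate check tree invariants (single root, acyclic,
#'   positive edge lengths).
#' @return An object of class \code{skeleton}: the vertex table plus
#'   precomputed parent indices, edge lengths, path distance to root,
#'   children lists and a topological (root-first) order.
#' @export
skeleton <- function(vertices, validate = TRUE) {
  req <- c("vertex_id", "x", "y", "z", "radius", "parent")
  miss <- setdiff(req, names(vertices))
  if (length(miss) > 0) stop("skeleton vertices missing columns: ", paste(miss, collapse = ", "))
  vertices <- as.data.frame(vertices, stringsAsFactors = FALSE)
  if (is.null(vertices$label)) vertices$label <- "dendrite"
  if (is.null(vertices$compartment)) vertices$compartment <- NA_character_
  n <- nrow(vertices)
  if (n == 0) stop("skeleton has no vertices")
  if (anyDuplicated(vertices$vertex_id)) stop("duplicate vertex ids")

  pidx <- match(vertices$parent, vertices$vertex_id)
  is_root <- is.na(vertices$parent)
  if (validate) {
    if (sum(is_root) != 1) stop("multiple roots (or none): skeleton must have exactly one root")
    if (any(is.na(pidx) & !is_root)) stop("dangling parent reference in skeleton")
  }
  root <- which(is_root)[1]

  ## topological order by BFS from root; also detects cycles/disconnection
  children <- split(seq_len(n), factor(pidx, levels = seq_len(n)))
  order <- integer(n); order[1] <- root
  head <- 1L; tail <- 1L
  while (head <= tail && tail < n) {
    ch <- children[[order[head]]]
    if (length(ch) > 0) {
      order[(tail + 1L):(tail + length(ch))] <- ch
      tail <- tail + length(ch)
    }
    head <- head + 1L
  }
  if (validate && tail != n) stop("skeleton is not a tree (cycle or disconnected component)")

  dx <- vertices$x - vertices$x[pidx]
  dy <- vertices$y - vertices$y[pidx]
  dz <- vertices$z - vertices$z[pidx]
  edge_len <- sqrt(dx^2 + dy^2 + dz^2)
  edge_len[root] <- 0
  if (validate && any(edge_len[-root][!is.na(edge_len[-root])] <= 0)) {
    stop("all edge lengths must be > 0")
  }

  dist_root <- numeric(n)
  for (v in order[-1]) dist_root[v] <- dist_root[pidx[v]] + edge_len[v]

  structure(list(
    vertices = vertices,
    n = n,
    root = root,
    parent_idx = pidx,
    children = children,
    edge_len = edge_len,
    dist_root = dist_root,
    topo_order = order
  ), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d vertices, cable %.1f um, root vertex_id %s\n",
              x$n, cable_length(x), x$vertices$vertex_id[x$root]))
  invisible(x)
}

#' Total cable length of a skeleton (sum of edge lengths), in micrometers.
#' @param skel a \code{skeleton}
#' @param vertex_subset optional logical/integer index: only edges whose
#'   child vertex is in the subset are summed.
#' @export
cable_length <- function(skel, vertex_subset = NULL) {
  if (is.null(vertex_subset)) return(sum(skel$edge_len))
  sum(skel$edge_len[vertex_subset])
}

vertex_index <- function(skel, vertex_id) {
  i <- match(vertex_id, skel$vertices$vertex_id)
  if (anyNA(i)) stop("vertex not in skeleton: ", paste(vertex_id[is.na(i)], collapse = ", "))
  i
}

#' Path distance between two vertices along the tree, in micrometers
#'
#' Uses the unique tree path: d(a,b) = d(a,root) + d(b,root) - 2 d(lca,root).
#' @param skel a \code{skeleton}
#' @param a,b vertex ids
#' @return nonnegative distance; symmetric; zero iff \code{a == b}.
#' @export
path_distance <- function(skel, a, b) {
  ia <- vertex_index(skel, a); ib <- vertex_index(skel, b)
  il <- lca_index(skel, ia, ib)
  skel$dist_root[ia] + skel$dist_root[ib] - 2 * skel$dist_root[il]
}

## lowest common ancestor by climbing parent pointers (vector indices)
lca_index <- function(skel, ia, ib) {
  anc <- logical(skel$n)
  v <- ia
  while (!is.na(v)) { anc[v] <- TRUE; v <- skel$parent_idx[v] }
  v <- ib
  while (!anc[v]) v <- skel$parent_idx[v]
  v
}

#' Ancestor trail (vertex indices root-ward, inclusive of start and root)
#' @noRd
ancestors_index <- function(skel, i) {
  out <- integer(0); v <- i
  while (!is.na(v)) { out <- c(out, v); v <- skel$parent_idx[v] }
  out
}

#' All vertices in the subtree rooted at a vertex (indices, inclusive)
#' @noRd
subtree_index <- function(skel, i) {
  n <- skel$n
  inset <- logical(n)
  inset[i] <- TRUE
  for (v in skel$topo_order) {
    p <- skel$parent_idx[v]
    if (!is.na(p) && inset[p]) inset[v] <- TRUE
  }
  which(inset)
}

#' Decompose a skeleton into unbranched segments
#'
#' A segment is a maximal path between consecutive topological events
#' (branch point, end point, or root); interior vertices have exactly one
#' child. Segments partition the edge set.
#'
#' @param skel a \code{skeleton}
#' @param vertex_mask optional logical vector (TRUE = vertex participates);
#'   segments are computed on the induced subforest.
#' @return list of segments, each a list with \code{vertex_idx} (ordered
#'   rootward to tipward, including the boundary vertex at the top),
#'   \code{path_length}, and \code{is_terminal}.
#' @export
decompose_segments <- function(skel, vertex_mask = NULL) {
  n <- skel$n
  if (is.null(vertex_mask)) vertex_mask <- rep(TRUE, n)
  ## child counts within mask
  nchild <- integer(n)
  for (v in seq_len(n)) {
    p <- skel$parent_idx[v]
    if (!is.na(p) && vertex_mask[v] && vertex_mask[p]) nchild[p] <- nchild[p] + 1L
  }
  is_root_like <- vapply(seq_len(n), function(v) {
    vertex_mask[v] && (is.na(skel$parent_idx[v]) || !vertex_mask[skel$parent_idx[v]])
  }, logical(1))
  ## segment bottoms: masked vertices that are leaves or branch points (within mask), excluding root-likes with no parent edge
  bottoms <- which(vertex_mask & nchild != 1L & !is_root_like)
  ## root-like vertices that are themselves isolated or have != 1 child produce no upward segment
  segs <- vector("list", length(bottoms))
  for (k in seq_along(bottoms)) {
    v <- bottoms[k]
    path <- v
    p <- skel$parent_idx[v]
    while (!is.na(p) && vertex_mask[p] && nchild[p] == 1L && !is_root_like[p]) {
      path <- c(p, path)
      v <- p
      p <- skel$parent_idx[v]
    }
    top <- if (!is.na(p) && vertex_mask[p]) p else v
    vertex_idx <- unique(c(top, path))
    segs[[k]] <- list(
      vertex_idx = vertex_idx,
      path_length = skel$dist_root[bottoms[k]] - skel$dist_root[top],
      is_terminal = nchild[bottoms[k]] == 0L
    )
  }
  segs
}

#' Column geometry
#'
#' Depth is measured from the pia (depth 0) toward white matter, after a
#' rigid rotation about the z axis that flattens the pial surface.
#' Depth bins are half-open \code{[lo, hi)} of width
#' \code{depth_bin_width} micrometers.
#'
#' @param pia_depth y coordinate of the pia in raw coordinates (um)
#' @param wm_depth y coordinate of the white-matter boundary (um)
#' @param layer_boundaries ordered depths (um, relative to pia) of layer
#'   transitions; strictly increasing, within \code{[0, wm_depth - pia_depth]}
#' @param rotation_angle degrees of rotation about the z axis
#' @param depth_bin_width bin width in um (default 20)
#' @export
column_geometry <- function(pia_depth = 0, wm_depth = 1000,
                            layer_boundaries = c(100, 270, 450, 650, 850),
                            rotation_angle = 0, depth_bin_width = 20) {
  if (wm_depth <= pia_depth) stop("wm_depth must exceed pia_depth")
  span <- wm_depth - pia_depth
  if (is.unsorted(layer_boundaries, strictly = TRUE) ||
      any(layer_boundaries <= 0) || any(layer_boundaries >= span)) {
    stop("layer_boundaries must be strictly increasing within (0, wm_depth - pia_depth)")
  }
  structure(list(
    pia_depth = pia_depth, wm_depth = wm_depth,
    layer_boundaries = layer_boundaries,
    rotation_angle = rotation_angle,
    depth_bin_width = depth_bin_width,
    n_depth_bins = as.integer(ceiling(span / depth_bin_width))
  ), class = "column_geometry")
}

#' Depth (um from pia) of points after applying the flattening rotation
#' @param x,y numeric coordinates (um); \code{y} is the raw depth axis
#' @param geometry a \code{column_geometry}
#' @export
depth_of <- function(x, y, geometry) {
  a <- geometry$rotation_angle * pi / 180
  (sin(a) * x + cos(a) * y) - geometry$pia_depth
}

#' Depth bin index (1..n_depth_bins), half-open [lo, hi), clamped to range
#' @param depth depths in um from pia
#' @param geometry a \code{column_geometry}
#' @export
depth_bin <- function(depth, geometry) {
  b <- 1L + as.integer(floor(depth / geometry$depth_bin_width))
  pmin(pmax(b, 1L), geometry$n_depth_bins)
}

#' Cortical layer of a depth (1-based index into layer bands)
#' @param depth depths in um from pia
#' @param geometry a \code{column_geometry}
#' @export
layer_of <- function(depth, geometry) {
  findInterval(depth, c(-Inf, geometry$layer_boundaries)) # 1..(k+1)
}

## ---- SWC I/O -------------------------------------------------------------

swc_label_codes <- c(soma = 1L, axon = 2L, dendrite = 3L, pruned = 7L)

#' Read a skeleton from an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; parent -1 for
#' the root). Type codes: 1 soma, 2 axon, 3 dendrite, 7 pruned.
#' @param path file path
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, col.names = c("vertex_id", "type", "x", "y", "z", "radius", "parent"))
  lab <- names(swc_label_codes)[match(tab$type, swc_label_codes)]
  lab[is.na(lab)] <- "dendrite"
  skeleton(data.frame(
    vertex_id = as.integer(tab$vertex_id),
    x = tab$x, y = tab$y, z = tab$z, radius = tab$radius,
    parent = ifelse(tab$parent < 0, NA_integer_, as.integer(tab$parent)),
    label = lab, stringsAsFactors = FALSE
  ))
}

#' Write a skeleton to an SWC file
#' @param skel a \code{skeleton}
#' @param path file path
#' @export
write_swc <- function(skel, path) {
  v <- skel$vertices
  type <- unname(swc_label_codes[v$label])
  type[is.na(type)] <- 3L
  tab <- data.frame(v$vertex_id, type, v$x, v$y, v$z, v$radius,
                    ifelse(is.na(v$parent), -1L, v$parent))
  utils::write.table(format(tab, digits = 12, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
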