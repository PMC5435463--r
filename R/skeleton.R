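#' Rooted-tree neuron skeletons
#'
#' A `skeleton` is a data frame of SWC-style nodes: `node_id`, `parent_id`
#' (-1 for the root), `x`, `y`, `z` in micrometres, and `radius`. Exactly one
#' root is required and every node must be reachable from it (no cycles).
#' For T4 cells the root is placed at the axon's main trunk, the reference
#' point from which dendrites spread; SWC files read from disk must already
#' be rooted there.
#'
#' @param nodes Data frame with columns `node_id`, `parent_id`, `x`, `y`,
#'   `z`, and optionally `radius` (default 0.1 um).
#' @return A validated `skeleton`.
#' @export
skeleton <- function(nodes) {
  need <- c("node_id", "parent_id", "x", "y", "z")
  if (!all(need %in% names(nodes))) {
    stop("skeleton: nodes need columns ", paste(need, collapse = ", "))
  }
  if (is.null(nodes$radius)) nodes$radius <- 0.1
  nodes <- nodes[, c("node_id", "parent_id", "x", "y", "z", "radius")]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  validate_skeleton(nodes)
  class(nodes) <- c("skeleton", "data.frame")
  nodes
}

validate_skeleton <- function(nodes) {
  if (nrow(nodes) == 0L) stop("skeleton: empty node table")
  if (anyDuplicated(nodes$node_id)) stop("skeleton: duplicated node ids")
  roots <- which(nodes$parent_id == -1L)
  if (length(roots) != 1L) {
    stop("skeleton: structure error, found ", length(roots),
         " roots (need exactly 1)")
  }
  idx <- match(nodes$parent_id, nodes$node_id)
  bad <- which(nodes$parent_id != -1L & is.na(idx))
  if (length(bad)) {
    stop("skeleton: structure error, parent of node ",
         nodes$node_id[bad[1L]], " not in table")
  }
  # reachability from root == acyclic for n nodes with n-1 parent edges
  depth <- node_depths(nodes)
  if (anyNA(depth)) {
    stop("skeleton: structure error, cycle or unreachable nodes detected")
  }
  invisible(TRUE)
}

# integer depth of each node from the root; NA marks unreachable/cyclic nodes
node_depths <- function(nodes) {
  n <- nrow(nodes)
  pidx <- match(nodes$parent_id, nodes$node_id)
  depth <- rep(NA_integer_, n)
  depth[nodes$parent_id == -1L] <- 0L
  for (i in seq_len(n)) {
    changed <- is.na(depth) & !is.na(pidx) & !is.na(depth[pidx])
    if (!any(changed)) break
    depth[changed] <- depth[pidx[changed]] + 1L
  }
  depth
}

#' Root and node path distances along the tree
#'
#' Cumulative Euclidean path length in micrometres from the root to every
#' node, following parent edges.
#'
#' @param skel A `skeleton`.
#' @return Numeric vector aligned with `skel$node_id`.
#' @export
skeleton_path_dist <- function(skel) {
  pidx <- match(skel$parent_id, skel$node_id)
  edge <- rep(0, nrow(skel))
  has_parent <- skel$parent_id != -1L
  edge[has_parent] <- sqrt(
    (skel$x[has_parent] - skel$x[pidx[has_parent]])^2 +
    (skel$y[has_parent] - skel$y[pidx[has_parent]])^2 +
    (skel$z[has_parent] - skel$z[pidx[has_parent]])^2
  )
  depth <- node_depths(skel)
  dist <- rep(NA_real_, nrow(skel))
  for (d in sort(unique(depth))) {
    at <- depth == d
    if (d == 0L) dist[at] <- 0 else dist[at] <- dist[pidx[at]] + edge[at]
  }
  dist
}

#' Total cable length of a skeleton in micrometres
#' @param skel A `skeleton`.
#' @export
skeleton_cable_length <- function(skel) {
  pidx <- match(skel$parent_id, skel$node_id)
  has_parent <- skel$parent_id != -1L
  sum(sqrt(
    (skel$x[has_parent] - skel$x[pidx[has_parent]])^2 +
    (skel$y[has_parent] - skel$y[pidx[has_parent]])^2 +
    (skel$z[has_parent] - skel$z[pidx[has_parent]])^2
  ))
}

skeleton_root <- function(skel) {
  skel[skel$parent_id == -1L, , drop = FALSE]
}

#' Read a neuron skeleton from an SWC file
#'
#' Standard 7-column SWC: id, structure type, x, y, z (micrometres), radius,
#' parent (-1 for the root). The rooted-tree invariant is enforced on read.
#'
#' @param path Path to an SWC file.
#' @return A `skeleton`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("read_swc: no data rows in ", path)
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    stop("read_swc: malformed SWC row(s) at line(s) ",
         paste(which(nf != 7L)[1:min(5, sum(nf != 7))], collapse = ", "),
         " (need 7 whitespace-separated fields)")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) stop("read_swc: non-numeric field in ", path)
  skeleton(data.frame(
    node_id = as.integer(m[, 1L]), parent_id = as.integer(m[, 7L]),
    x = m[, 3L], y = m[, 4L], z = m[, 5L], radius = m[, 6L]
  ))
}

#' Write a neuron skeleton to an SWC file
#'
#' @param skel A `skeleton`.
#' @param path Output path.
#' @param header Optional provenance comment lines (without leading `#`).
#' @export
write_swc <- function(skel, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("# SWC: id type x y z radius parent (um)", con)
  writeLines(sprintf("%d 0 %.17g %.17g %.17g %.17g %d",
                     skel$node_id, skel$x, skel$y, skel$z, skel$radius,
                     skel$parent_id), con)
  invisible(path)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes, cable %.1f um, root #%d at (%.1f, %.1f, %.1f)\n",
              nrow(x), skeleton_cable_length(x), skeleton_root(x)$node_id,
              skeleton_root(x)$x, skeleton_root(x)$y, skeleton_root(x)$z))
  invisible(x)
}

#' Plot a skeleton in the x-y plane
#' @param x A `skeleton`.
#' @param add Add to an existing plot.
#' @param ... Passed to [graphics::segments()].
#' @export
plot.skeleton <- function(x, add = FALSE, ...) {
  pidx <- match(x$parent_id, x$node_id)
  has <- x$parent_id != -1L
  if (!add) {
    graphics::plot(x$x, x$y, type = "n", asp = 1,
                   xlab = "x (um)", ylab = "y (um)")
  }
  graphics::segments(x$x[has], x$y[has], x$x[pidx[has]], x$y[pidx[has]], ...)
  root <- skeleton_root(x)
  graphics::points(root$x, root$y, pch = 19, col = "goldenrod", cex = 1.2)
  invisible(x)
}
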