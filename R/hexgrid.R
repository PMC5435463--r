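#' Hexagonal retinotopic lattice geometry
#'
#' The medulla repeats one column per ommatidium on a hexagonal lattice. The
#' package represents columns by integer axial coordinates `(q, r)` with the
#' central "Home" column at `(0, 0)`, and converts to Cartesian ommatidial
#' units, where 1.0 is the centre-to-centre distance between two adjacent
#' columns. The basis is "pointy-top": `(1, 0)` maps to `(1, 0)` on the +x
#' axis and `(0, 1)` to `(0.5, sqrt(3)/2)`, 60 degrees counter-clockwise.
#' Orientation relative to the fly's body axes is a labelling convention, not
#' a result, and can be chosen freely by the caller.
#'
#' @name hexgrid
NULL

#' Convert axial hex coordinates to Cartesian ommatidial units
#'
#' @param q,r Integer axial coordinates (vectorized).
#' @return A two-column numeric matrix with columns `x`, `y`.
#' @examples
#' axial_to_cart(1, 0)   # (1, 0)
#' axial_to_cart(0, 1)   # (0.5, 0.866...)
#' @export
axial_to_cart <- function(q, r) {
  stopifnot(length(q) == length(r))
  cbind(x = q + r / 2, y = r * sqrt(3) / 2)
}

#' Six lattice neighbours of an axial coordinate
#'
#' @param q,r A single axial coordinate.
#' @return A 6-row data frame of axial coordinates, each at Cartesian
#'   distance 1 from `(q, r)`.
#' @export
hex_neighbours <- function(q, r) {
  stopifnot(length(q) == 1L, length(r) == 1L)
  dq <- c(1L, -1L, 0L, 0L, 1L, -1L)
  dr <- c(0L, 0L, 1L, -1L, -1L, 1L)
  data.frame(q = q + dq, r = r + dr)
}

#' Hex ring distance from the origin
#'
#' Number of lattice steps from `(0, 0)`; ring 1 is the six immediate
#' neighbours of Home.
#' @param q,r Integer axial coordinates (vectorized).
#' @return Integer vector of ring numbers.
#' @export
hex_ring <- function(q, r) {
  (abs(q) + abs(r) + abs(q + r)) %/% 2L
}

#' Synapse-count-weighted centre of mass on the lattice
#'
#' Centre of mass of column positions in an ideal hexagonal array, weighted
#' by the synapse count associated with each column. This is the primitive
#' behind every anatomical subfield centre in the package.
#'
#' @param q,r Integer axial coordinates of the contributing columns.
#' @param w Non-negative weights (synapse counts), at least one strictly
#'   positive.
#' @return Named numeric vector `c(x, y)` in ommatidial units. Lies in the
#'   convex hull of the contributing columns.
#' @export
weighted_centroid <- function(q, r, w) {
  stopifnot(length(q) == length(r), length(q) == length(w))
  if (length(w) == 0L) stop("weighted_centroid: no columns supplied")
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weighted_centroid: weights must be finite and non-negative")
  }
  tot <- sum(w)
  if (tot <= 0) {
    stop("weighted_centroid: degenerate input, all weights are zero")
  }
  xy <- axial_to_cart(q, r)
  c(x = sum(xy[, "x"] * w) / tot, y = sum(xy[, "y"] * w) / tot)
}

#' Construct a hexagonal disc lattice of reconstructed columns
#'
#' A disc of `1 + 3 * radius * (radius + 1)` columns. `radius = 1` gives the
#' seven-column geometry (Home plus its six immediate neighbours A-F) of the
#' reconstructed medulla volume. Ring-1 columns are labelled A-F
#' counter-clockwise starting from `(1, 0)`; labels are cosmetic and all
#' algorithms work on the axial coordinates.
#'
#' @param radius Integer >= 1, number of rings around Home.
#' @return A `hex_lattice`: data frame with columns `q`, `r`, `label`.
#' @export
make_lattice <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1 ||
      radius != round(radius)) {
    stop("make_lattice: radius must be a single integer >= 1")
  }
  radius <- as.integer(radius)
  grid <- expand.grid(q = -radius:radius, r = -radius:radius)
  grid <- grid[hex_ring(grid$q, grid$r) <= radius, , drop = FALSE]
  # order by ring, then counter-clockwise angle from +x
  xy <- axial_to_cart(grid$q, grid$r)
  ang <- atan2(xy[, "y"], xy[, "x"]) %% (2 * pi)
  ord <- order(hex_ring(grid$q, grid$r), ang)
  grid <- grid[ord, , drop = FALSE]
  label <- rep(NA_character_, nrow(grid))
  label[1L] <- "Home"
  ring1 <- which(hex_ring(grid$q, grid$r) == 1L)
  label[ring1] <- LETTERS[seq_along(ring1)]
  out <- data.frame(q = as.integer(grid$q), r = as.integer(grid$r),
                    label = label, row.names = NULL)
  class(out) <- c("hex_lattice", "data.frame")
  out
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("<hex_lattice> %d columns, rings 0-%d\n",
              nrow(x), max(hex_ring(x$q, x$r))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a column lattice in ommatidial units
#' @param x A `hex_lattice`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hex_lattice <- function(x, ...) {
  xy <- axial_to_cart(x$q, x$r)
  graphics::plot(xy, asp = 1, pch = 21, bg = "grey85", cex = 3,
                 xlab = "x (ommatidia)", ylab = "y (ommatidia)", ...)
  graphics::text(xy, labels = ifelse(is.na(x$label), "", x$label), cex = 0.7)
  invisible(x)
}

lattice_has <- function(lattice, q, r) {
  paste(q, r) %in% paste(lattice$q, lattice$r)
}

#' Read / write a column lattice as TSV
#'
#' Plain TSV with columns `q`, `r`, `label`.
#' @param path File path.
#' @rdname lattice_io
#' @export
read_lattice <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("q", "r")
  if (!all(need %in% names(df))) {
    stop("read_lattice: file must have columns q, r")
  }
  if (is.null(df$label)) df$label <- NA_character_
  out <- data.frame(q = as.integer(df$q), r = as.integer(df$r),
                    label = as.character(df$label))
  class(out) <- c("hex_lattice", "data.frame")
  out
}

#' @param lattice A `hex_lattice`.
#' @param header Optional provenance comment lines (without leading `#`).
#' @rdname lattice_io
#' @export
write_lattice <- function(lattice, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(lattice), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
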