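#' Cell types of the T4 input circuit
#'
#' The recognised cell types: the eight types presynaptic to T4 (Mi1, Tm3,
#' Mi4, Mi9, C3, CT1, TmY15 and T4 itself, the latter split into the four
#' directional subtypes a-d), the upstream lamina/photoreceptor types that
#' appear in the pathway connectivity matrix (R8, L1, L3, L5), the minor
#' input Mi10, and `"unknown"` for unidentified profiles.
#'
#' @format Character vector of valid `cell_type` values.
#' @export
CELL_TYPES <- c("Mi1", "Tm3", "Mi4", "Mi9", "C3", "CT1", "TmY15", "Mi10",
                "T4a", "T4b", "T4c", "T4d", "L1", "L3", "L5", "R8", "unknown")

#' @rdname CELL_TYPES
#' @format NULL
#' @export
T4_SUBTYPES <- c("T4a", "T4b", "T4c", "T4d")

# Types whose arbours span several columns without columnar subdivision and
# therefore cannot be assigned a home column (Tm3/TmY15 per the EM data;
# unidentified profiles are treated the same way). CT1 is wide-field but its
# per-column terminal units are modelled as separate column-assignable units.
MULTICOLUMNAR_TYPES <- c("Tm3", "TmY15", "unknown")

#' Is a cell type assignable to a single medulla column?
#'
#' Mi1, Mi4, Mi9, C3, per-column CT1 terminals, lamina cells and T4s can be
#' unambiguously assigned to specific columns; Tm3 and TmY15 are
#' multicolumnar and cannot.
#' @param cell_type Character vector of cell types.
#' @return Logical vector.
#' @export
is_column_assignable <- function(cell_type) {
  !(cell_type %in% MULTICOLUMNAR_TYPES)
}

#' Construct a neuron metadata table
#'
#' @param id Character cell ids (unique, opaque).
#' @param cell_type One of [CELL_TYPES] per cell.
#' @param home_q,home_r Optional axial home-column coordinates (NA where a
#'   cell has none). Multicolumnar types must not carry a home column.
#' @param completeness Optional reconstruction completeness in (0, 1]: the
#'   fraction of the cell's synapses captured inside the imaged volume.
#' @param unit_of Optional parent cell id for per-column terminal units
#'   (used for CT1, whose single wide-field neuron is counted as one arbour
#'   unit per column).
#' @return A `neuron_table` data frame.
#' @export
neuron_table <- function(id, cell_type,
                         home_q = NA_integer_, home_r = NA_integer_,
                         completeness = NA_real_, unit_of = NA_character_) {
  df <- data.frame(id = as.character(id), cell_type = as.character(cell_type),
                   home_q = as.integer(home_q), home_r = as.integer(home_r),
                   completeness = as.numeric(completeness),
                   unit_of = as.character(unit_of),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("neuron_table: duplicated cell ids")
  bad <- !(df$cell_type %in% CELL_TYPES)
  if (any(bad)) {
    stop("neuron_table: unknown cell_type ",
         paste(unique(df$cell_type[bad]), collapse = ", "))
  }
  class(df) <- c("neuron_table", "data.frame")
  df
}

#' Construct a synapse (postsynaptic-site) table
#'
#' One row is one postsynaptic density (PSD), the unit in which synaptic
#' inputs are counted throughout the package. Fly synapses are polyadic: one
#' presynaptic T-bar contacts several postsynaptic sites, so a `tbar_id` may
#' recur across rows.
#'
#' @param pre_id,post_id Presynaptic / postsynaptic cell ids.
#' @param tbar_id Presynaptic T-bar id.
#' @param x,y,z Synapse location in micrometres.
#' @param allow_autapse Keep rows with `pre_id == post_id`? Default `FALSE`
#'   (autapses are treated as annotation errors).
#' @return A `synapse_table` data frame.
#' @export
synapse_table <- function(pre_id, post_id, tbar_id, x, y, z,
                          allow_autapse = FALSE) {
  df <- data.frame(pre_id = as.character(pre_id),
                   post_id = as.character(post_id),
                   tbar_id = as.character(tbar_id),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  auto <- df$pre_id == df$post_id
  if (any(auto) && !allow_autapse) {
    stop("synapse_table: ", sum(auto), " autaptic row(s) (pre_id == post_id); ",
         "set allow_autapse = TRUE to keep them")
  }
  class(df) <- c("synapse_table", "data.frame")
  df
}

empty_synapse_table <- function() {
  synapse_table(character(), character(), character(),
                numeric(), numeric(), numeric())
}

#' Read / write a synapse table as TSV
#'
#' The file must carry a header row with columns `pre_id`, `post_id`,
#' `tbar_id`, `x`, `y`, `z`; lines starting with `#` are ignored. Malformed
#' rows are reported with their line numbers. Round-trip through
#' [write_synapse_table()] preserves numeric fields exactly for finite
#' decimal inputs.
#'
#' @param path File path.
#' @param allow_autapse Passed to [synapse_table()].
#' @return A `synapse_table`.
#' @rdname synapse_io
#' @export
read_synapse_table <- function(path, allow_autapse = FALSE) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pre_id", "post_id", "tbar_id", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("read_synapse_table: format error, missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_synapse_table())
  coords <- suppressWarnings(
    cbind(as.numeric(df$x), as.numeric(df$y), as.numeric(df$z)))
  bad <- which(rowSums(is.na(coords)) > 0)
  if (length(bad)) {
    stop("read_synapse_table: non-numeric coordinate at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  synapse_table(df$pre_id, df$post_id, df$tbar_id,
                coords[, 1L], coords[, 2L], coords[, 3L],
                allow_autapse = allow_autapse)
}

#' @param syn A `synapse_table`.
#' @param header Optional provenance comment lines (without leading `#`).
#' @rdname synapse_io
#' @export
write_synapse_table <- function(syn, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  out <- as.data.frame(syn)
  for (col in c("x", "y", "z")) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a neuron table as TSV
#'
#' Columns `id`, `cell_type`, and optionally `home_q`, `home_r`,
#' `completeness`, `unit_of`.
#' @param path File path.
#' @rdname neuron_io
#' @export
read_neuron_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("id", "cell_type") %in% names(df))) {
    stop("read_neuron_table: format error, need columns id, cell_type")
  }
  opt <- function(col, default) if (is.null(df[[col]])) default else df[[col]]
  neuron_table(df$id, df$cell_type,
               home_q = opt("home_q", NA), home_r = opt("home_r", NA),
               completeness = opt("completeness", NA),
               unit_of = opt("unit_of", NA))
}

#' @param neurons A `neuron_table`.
#' @param header Optional provenance comment lines.
#' @rdname neuron_io
#' @export
write_neuron_table <- function(neurons, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(neurons), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a connectome dataset
#'
#' The universal pipeline input: neurons, synapses, the column lattice,
#' axis-aligned volume bounds in micrometres, per-cell skeletons, and (for
#' synthetic data only) generator ground truth.
#'
#' @param neurons A [neuron_table()].
#' @param synapses A [synapse_table()].
#' @param lattice A [make_lattice()] column lattice.
#' @param volume_bounds Named numeric vector `xmin, xmax, ymin, ymax, zmin,
#'   zmax` in micrometres.
#' @param skeletons Named list of [skeleton()] objects, keyed by cell id.
#' @param ground_truth Optional list of generator ground truth.
#' @param column_spacing_um Physical centre-to-centre column spacing used to
#'   relate micrometre coordinates to ommatidial units.
#' @return A `connectome` object.
#' @export
connectome <- function(neurons, synapses, lattice, volume_bounds,
                       skeletons = list(), ground_truth = NULL,
                       column_spacing_um = 8) {
  stopifnot(inherits(neurons, "neuron_table"),
            inherits(synapses, "synapse_table"),
            inherits(lattice, "hex_lattice"))
  need <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  if (!all(need %in% names(volume_bounds))) {
    stop("connectome: volume_bounds needs ", paste(need, collapse = ", "))
  }
  obj <- structure(list(
    neurons = neurons, synapses = synapses, lattice = lattice,
    volume_bounds = volume_bounds[need], skeletons = skeletons,
    ground_truth = ground_truth, column_spacing_um = column_spacing_um
  ), class = "connectome")
  obj
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(paste0(
    "<connectome> %d neurons (%d types), %d postsynaptic sites, ",
    "%d T-bars, %d columns, %d skeletons%s\n"),
    nrow(x$neurons), length(unique(x$neurons$cell_type)),
    nrow(x$synapses), length(unique(x$synapses$tbar_id)),
    nrow(x$lattice), length(x$skeletons),
    if (is.null(x$ground_truth)) "" else " [synthetic, with ground truth]"))
  invisible(x)
}

in_bounds <- function(x, y, z, b) {
  x >= b["xmin"] & x <= b["xmax"] &
  y >= b["ymin"] & y <= b["ymax"] &
  z >= b["zmin"] & z <= b["zmax"]
}

#' Validate a connectome dataset
#'
#' Checks referential integrity and the data-model invariants and returns a
#' findings report rather than raising: dangling synapse cell references,
#' synapse locations outside the volume bounds, home columns absent from the
#' lattice, multicolumnar cells carrying a home column, completeness values
#' outside (0, 1], and autaptic rows.
#'
#' @param dataset A [connectome()].
#' @return Data frame with columns `finding`, `id`, `detail`; zero rows for
#'   a well-formed dataset.
#' @export
validate_connectome <- function(dataset) {
  stopifnot(inherits(dataset, "connectome"))
  nr <- dataset$neurons
  sy <- dataset$synapses
  findings <- list()
  add <- function(finding, id, detail) {
    findings[[length(findings) + 1L]] <<-
      data.frame(finding = finding, id = id, detail = detail)
  }

  dang <- setdiff(unique(c(sy$pre_id, sy$post_id)), nr$id)
  for (id in dang) add("dangling_reference", id,
                       "synapse references a cell absent from the neuron table")

  if (nrow(sy)) {
    out <- !in_bounds(sy$x, sy$y, sy$z, dataset$volume_bounds)
    if (any(out)) {
      for (i in which(out)) {
        add("out_of_bounds", sy$tbar_id[i],
            sprintf("synapse row %d at (%.2f, %.2f, %.2f) outside volume bounds",
                    i, sy$x[i], sy$y[i], sy$z[i]))
      }
    }
    auto <- sy$pre_id == sy$post_id
    for (i in which(auto)) add("autapse", sy$pre_id[i],
                               sprintf("row %d has pre_id == post_id", i))
  }

  has_home <- !is.na(nr$home_q) & !is.na(nr$home_r)
  bad_multi <- has_home & !is_column_assignable(nr$cell_type)
  for (i in which(bad_multi)) {
    add("multicolumnar_home_column", nr$id[i],
        sprintf("%s is multicolumnar and must not carry a home column",
                nr$cell_type[i]))
  }
  off_lat <- has_home & !lattice_has(dataset$lattice, nr$home_q, nr$home_r)
  for (i in which(off_lat)) {
    add("home_column_off_lattice", nr$id[i],
        sprintf("home column (%d, %d) not in lattice", nr$home_q[i], nr$home_r[i]))
  }
  bad_comp <- !is.na(nr$completeness) &
    (nr$completeness <= 0 | nr$completeness > 1)
  for (i in which(bad_comp)) {
    add("completeness_out_of_range", nr$id[i],
        sprintf("completeness %.3f outside (0, 1]", nr$completeness[i]))
  }

  if (!length(findings)) {
    return(data.frame(finding = character(), id = character(),
                      detail = character()))
  }
  do.call(rbind, findings)
}
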