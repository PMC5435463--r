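#' Anatomical subfield centre of one input type onto a T4
#'
#' The centre of mass of the presynaptic cells' home columns in an ideal
#' hexagonal array, weighted by the synapse count each cell makes onto the
#' target T4. Only column-assignable types (Mi1, Mi4, Mi9, C3, CT1
#' terminals, T4) are admissible; Tm3 and TmY15 are multicolumnar and have
#' no per-column subfield (see [tm3_mi1_offset()] for the L1-based Tm3
#' analysis).
#'
#' @param dataset A [connectome()].
#' @param t4_id Target T4 cell id.
#' @param pre_type Column-assignable presynaptic cell type.
#' @param min_synapses Per-connection threshold applied before weighting
#'   (use 2 to drop single-synapse connections).
#' @return A `subfield_result` list: `t4_id`, `pre_type`, `centre` (x, y in
#'   ommatidial units), `weights` (per-column counts), `n_synapses`.
#' @export
subfield_centre <- function(dataset, t4_id, pre_type, min_synapses = 1L) {
  counts <- per_column_counts(dataset, t4_id, pre_type,
                              min_synapses = min_synapses)
  if (!nrow(counts)) {
    stop("subfield_centre: ", t4_id, " has no inputs of type ", pre_type)
  }
  centre <- weighted_centroid(counts$q, counts$r, counts$count)
  structure(list(t4_id = t4_id, pre_type = pre_type, centre = centre,
                 weights = counts, n_synapses = sum(counts$count)),
            class = "subfield_result")
}

#' @export
print.subfield_result <- function(x, ...) {
  cat(sprintf("<subfield> %s <- %s: centre (%.3f, %.3f) om. units, n = %d over %d columns\n",
              x$t4_id, x$pre_type, x$centre["x"], x$centre["y"],
              x$n_synapses, nrow(x$weights)))
  invisible(x)
}

#' Subfield offset of an input type referenced to Mi1
#'
#' Displacement of `pre_type`'s anatomical subfield centre from the Mi1
#' subfield centre of the same T4, in ommatidial units.
#'
#' @inheritParams subfield_centre
#' @return An `offset_vector`: list with `dx`, `dy`, `mode = "raw"` and the
#'   two subfield results.
#' @export
offset_from_mi1 <- function(dataset, t4_id, pre_type, min_synapses = 1L) {
  ref <- subfield_centre(dataset, t4_id, "Mi1", min_synapses = min_synapses)
  sf <- if (pre_type == "Mi1") ref else {
    subfield_centre(dataset, t4_id, pre_type, min_synapses = min_synapses)
  }
  structure(list(t4_id = t4_id, pre_type = pre_type,
                 dx = unname(sf$centre["x"] - ref$centre["x"]),
                 dy = unname(sf$centre["y"] - ref$centre["y"]),
                 mode = "raw", subfield = sf, reference = ref),
            class = "offset_vector")
}

#' @export
print.offset_vector <- function(x, ...) {
  cat(sprintf("<offset> %s: %s - Mi1 = (%+.3f, %+.3f) om. units [%s]\n",
              x$t4_id, x$pre_type, x$dx, x$dy, x$mode))
  invisible(x)
}

#' L1-based field centre of a medulla cell
#'
#' The field centre of a cell's L1 connections, assumed to originate from
#' within a regular hexagonal grid, weighted by their respective synapse
#' counts. This assigns a retinotopic position even to multicolumnar cells
#' such as Tm3, which receive L1 input across several columns.
#'
#' @param dataset A [connectome()].
#' @param cell_id Postsynaptic cell id (must receive L1 input; every
#'   presynaptic L1 must carry a home column).
#' @return Named numeric `c(x, y)` in ommatidial units.
#' @export
l1_field_centre <- function(dataset, cell_id) {
  counts <- per_column_counts(dataset, cell_id, "L1")
  if (!nrow(counts)) {
    stop("l1_field_centre: ", cell_id, " receives no L1 input")
  }
  weighted_centroid(counts$q, counts$r, counts$count)
}

#' Tm3-to-Mi1 field-centre offset of a T4, raw or completeness-adjusted
#'
#' For each Mi1 and Tm3 presynaptic to the T4, an L1-based field centre is
#' computed ([l1_field_centre()]); the Tm3 and Mi1 population centres are
#' then the synapse-count-weighted means of those per-cell centres, and the
#' offset is their difference (Mi1 at the origin). Because most Tm3 cells
#' leave the imaged volume and are only partially reconstructed, their
#' synapse counts under-represent them; in `"adjusted"` mode each Tm3's
#' weight is its PSD count divided by its reconstruction completeness
#' (inverse-completeness reweighting -- unbiased when a partial cell's
#' synapses are missed uniformly at random).
#'
#' @param dataset A [connectome()].
#' @param t4_id Target T4 id (needs both Mi1 and Tm3 inputs with computable
#'   L1 field centres).
#' @param mode `"raw"` or `"adjusted"`.
#' @return An `offset_vector` with `dx`, `dy`, `mode`, and per-cell detail
#'   tables `tm3` and `mi1`.
#' @export
tm3_mi1_offset <- function(dataset, t4_id, mode = c("raw", "adjusted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "connectome"))
  sy <- dataset$synapses[dataset$synapses$post_id == t4_id, , drop = FALSE]
  ty <- cell_type_of(dataset, sy$pre_id)

  side <- function(type) {
    ids <- unique(sy$pre_id[!is.na(ty) & ty == type])
    if (!length(ids)) {
      stop("tm3_mi1_offset: ", t4_id, " has no ", type, " inputs")
    }
    w <- vapply(ids, function(id) sum(sy$pre_id == id), numeric(1L))
    centres <- t(vapply(ids, function(id) l1_field_centre(dataset, id),
                        numeric(2L)))
    data.frame(id = ids, n_psd = w, cx = centres[, 1L], cy = centres[, 2L],
               row.names = NULL)
  }

  tm3 <- side("Tm3")
  mi1 <- side("Mi1")
  tm3$weight <- tm3$n_psd
  if (mode == "adjusted") {
    comp <- dataset$neurons$completeness[match(tm3$id, dataset$neurons$id)]
    if (anyNA(comp)) {
      stop("tm3_mi1_offset: adjusted mode needs a completeness estimate ",
           "for every Tm3; missing for ",
           paste(tm3$id[is.na(comp)], collapse = ", "))
    }
    tm3$completeness <- comp
    tm3$weight <- tm3$n_psd / comp
  }
  mi1$weight <- mi1$n_psd

  tm3_centre <- c(sum(tm3$cx * tm3$weight), sum(tm3$cy * tm3$weight)) /
    sum(tm3$weight)
  mi1_centre <- c(sum(mi1$cx * mi1$weight), sum(mi1$cy * mi1$weight)) /
    sum(mi1$weight)

  structure(list(t4_id = t4_id, pre_type = "Tm3",
                 dx = tm3_centre[1L] - mi1_centre[1L],
                 dy = tm3_centre[2L] - mi1_centre[2L],
                 mode = mode, tm3 = tm3, mi1 = mi1),
            class = "offset_vector")
}

#' Alignment of a subfield offset with a preferred direction
#'
#' Cosine of the angle between an offset vector and a T4's preferred
#' direction: +1 for an offset along the PD, -1 opposite, 0 orthogonal,
#' `NaN` (undefined) for a zero offset.
#'
#' @param offset An `offset_vector` (or any list with `dx`, `dy`).
#' @param preferred_direction Angle in radians.
#' @return Signed scalar in `[-1, 1]`, or `NaN`.
#' @export
offset_alignment <- function(offset, preferred_direction) {
  v <- c(offset$dx, offset$dy)
  len <- sqrt(sum(v^2))
  if (len == 0) return(NaN)
  pd <- unit_vec(preferred_direction)
  sum(v * pd) / len
}

#' Tabulate subfield offsets of all column-assignable inputs to the Home T4s
#'
#' Convenience report across T4s and input types, one row per (T4, type):
#' subfield centre, offset from Mi1 and synapse count.
#'
#' @param dataset A [connectome()].
#' @param t4_ids T4 cell ids (default: all T4s with synaptic input).
#' @param pre_types Input types to include.
#' @param min_synapses Per-connection threshold (2 drops single-synapse
#'   connections, the convention used for per-column input maps).
#' @return Data frame `t4_id`, `pre_type`, `cx`, `cy`, `dx`, `dy`, `mode`,
#'   `n_synapses`.
#' @export
subfield_report <- function(dataset, t4_ids = NULL,
                            pre_types = c("Mi1", "Mi9", "Mi4", "C3", "CT1"),
                            min_synapses = 2L) {
  stopifnot(inherits(dataset, "connectome"))
  if (is.null(t4_ids)) {
    is_t4 <- cell_type_of(dataset, dataset$synapses$post_id) %in% T4_SUBTYPES
    t4_ids <- sort(unique(dataset$synapses$post_id[is_t4]))
  }
  rows <- list()
  for (t4 in t4_ids) {
    for (ty in pre_types) {
      res <- tryCatch(offset_from_mi1(dataset, t4, ty, min_synapses),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[paste(t4, ty)]] <- data.frame(
        t4_id = t4, pre_type = ty,
        cx = unname(res$subfield$centre["x"]),
        cy = unname(res$subfield$centre["y"]),
        dx = res$dx, dy = res$dy, mode = res$mode,
        n_synapses = res$subfield$n_synapses)
    }
  }
  if (!length(rows)) {
    return(data.frame(t4_id = character(), pre_type = character(),
                      cx = numeric(), cy = numeric(), dx = numeric(),
                      dy = numeric(), mode = character(),
                      n_synapses = integer()))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
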