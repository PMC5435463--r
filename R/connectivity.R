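#' Count the synapses of one connection
#'
#' Number of postsynaptic-site rows from `pre_id` onto `post_id`.
#'
#' @param dataset A [connectome()].
#' @param pre_id,post_id Cell ids (must exist in the neuron table).
#' @return Integer PSD count.
#' @export
count_connection <- function(dataset, pre_id, post_id) {
  stopifnot(inherits(dataset, "connectome"))
  for (id in c(pre_id, post_id)) {
    if (!id %in% dataset$neurons$id) stop("unknown cell id: ", id)
  }
  sum(dataset$synapses$pre_id == pre_id & dataset$synapses$post_id == post_id)
}

cell_type_of <- function(dataset, ids) {
  dataset$neurons$cell_type[match(ids, dataset$neurons$id)]
}

#' Remove weak connections from a dataset
#'
#' Drops every (pre, post) cell pair connected by fewer than `min_synapses`
#' postsynaptic sites, mirroring the convention that connections with only a
#' single synapse are excluded from per-column input maps.
#'
#' @param dataset A [connectome()].
#' @param min_synapses Minimum PSD count per connection to retain
#'   (default 2, i.e. single-synapse connections removed).
#' @return A `connectome` view with the weak rows removed.
#' @export
exclude_weak <- function(dataset, min_synapses = 2L) {
  stopifnot(inherits(dataset, "connectome"), min_synapses >= 1L)
  sy <- dataset$synapses
  key <- paste(sy$pre_id, sy$post_id, sep = "\r")
  n <- ave(rep(1L, nrow(sy)), key, FUN = sum)
  out <- dataset
  kept <- sy[n >= min_synapses, , drop = FALSE]
  class(kept) <- class(sy)
  out$synapses <- kept
  out
}

#' Input fractions by presynaptic cell type
#'
#' Fraction of a postsynaptic cell's synaptic inputs (PSD counts)
#' contributed by each presynaptic cell type, optionally after removing
#' connections below a per-connection synapse threshold.
#'
#' @param dataset A [connectome()].
#' @param post_id Postsynaptic cell id.
#' @param min_synapses Per-connection threshold applied before computing
#'   fractions (1 = keep everything).
#' @return Named numeric vector of fractions summing to 1 over the included
#'   synapses, sorted decreasing.
#' @export
input_fractions <- function(dataset, post_id, min_synapses = 1L) {
  stopifnot(inherits(dataset, "connectome"))
  if (!post_id %in% dataset$neurons$id) stop("unknown cell id: ", post_id)
  if (min_synapses > 1L) dataset <- exclude_weak(dataset, min_synapses)
  sy <- dataset$synapses[dataset$synapses$post_id == post_id, , drop = FALSE]
  if (nrow(sy) == 0L) {
    stop("input_fractions: ", post_id, " has no synaptic inputs",
         if (min_synapses > 1L) " above the threshold" else "")
  }
  ty <- cell_type_of(dataset, sy$pre_id)
  ty[is.na(ty)] <- "unknown"
  ty[ty %in% T4_SUBTYPES] <- "T4"
  tab <- sort(table(ty), decreasing = TRUE)
  as.vector(tab) / nrow(sy) -> fr
  stats::setNames(fr, names(tab))
}

#' Per-column input counts for a column-assignable cell type
#'
#' Counts of synaptic inputs onto one cell from each column's cell of the
#' given presynaptic type, keyed by the presynaptic home column on the
#' hexagonal array. Multicolumnar types (Tm3, TmY15) cannot be assigned to
#' columns and are rejected.
#'
#' @param dataset A [connectome()].
#' @param post_id Postsynaptic cell id.
#' @param pre_type Column-assignable presynaptic cell type. `"T4"` counts
#'   all four subtypes together.
#' @param min_synapses Per-connection threshold applied first.
#' @return Data frame `q`, `r`, `count`; counts sum to the total input from
#'   that type.
#' @export
per_column_counts <- function(dataset, post_id, pre_type, min_synapses = 1L) {
  stopifnot(inherits(dataset, "connectome"))
  if (!is_column_assignable(pre_type)) {
    stop("per_column_counts: ", pre_type, " cells cannot be assigned to a ",
         "particular column (multicolumnar type)")
  }
  if (min_synapses > 1L) dataset <- exclude_weak(dataset, min_synapses)
  sy <- dataset$synapses[dataset$synapses$post_id == post_id, , drop = FALSE]
  ty <- cell_type_of(dataset, sy$pre_id)
  if (pre_type == "T4") ty[ty %in% T4_SUBTYPES] <- "T4"
  sy <- sy[!is.na(ty) & ty == pre_type, , drop = FALSE]
  nr <- dataset$neurons[match(sy$pre_id, dataset$neurons$id), , drop = FALSE]
  if (nrow(sy) && anyNA(nr$home_q)) {
    stop("per_column_counts: presynaptic ", pre_type,
         " cell(s) without a home column: ",
         paste(unique(nr$id[is.na(nr$home_q)]), collapse = ", "))
  }
  if (!nrow(sy)) {
    return(data.frame(q = integer(), r = integer(), count = integer()))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(sy))),
                          by = list(q = nr$home_q, r = nr$home_r), FUN = sum)
  agg[order(-agg$count), , drop = FALSE]
}

#' Type-by-type (or cell-by-cell) connectivity matrix
#'
#' Integer PSD counts between ordered presynaptic rows and postsynaptic
#' columns, in the spirit of a pathway connection matrix over R8, L1, L3,
#' L5, C3, Mi1, Mi4, Mi9, Tm3, TmY15, CT1 and T4.
#'
#' @param dataset A [connectome()].
#' @param by `"type"` (default) aggregates cells into types, with the four
#'   T4 subtypes merged into `"T4"`; `"cell"` keeps individual cells.
#' @param min_synapses Per-connection threshold applied first.
#' @return Integer matrix with `threshold` attribute.
#' @export
connectivity_matrix <- function(dataset, by = c("type", "cell"),
                                min_synapses = 1L) {
  by <- match.arg(by)
  stopifnot(inherits(dataset, "connectome"))
  if (min_synapses > 1L) dataset <- exclude_weak(dataset, min_synapses)
  sy <- dataset$synapses
  if (by == "type") {
    pre <- cell_type_of(dataset, sy$pre_id)
    post <- cell_type_of(dataset, sy$post_id)
    pre[pre %in% T4_SUBTYPES] <- "T4"
    post[post %in% T4_SUBTYPES] <- "T4"
    lev <- c("R8", "L1", "L3", "L5", "C3", "Mi1", "Mi4", "Mi9", "Mi10",
             "Tm3", "TmY15", "CT1", "T4", "unknown")
    lev <- lev[lev %in% unique(c(pre, post))]
    m <- table(factor(pre, lev), factor(post, lev))
  } else {
    ids <- sort(unique(c(sy$pre_id, sy$post_id)))
    m <- table(factor(sy$pre_id, ids), factor(sy$post_id, ids))
  }
  m <- unclass(as.matrix(m))
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("pre", "post")
  attr(m, "threshold") <- as.integer(min_synapses)
  m
}

#' Bin a connection count into strength classes
#'
#' The pathway-matrix colour convention: fewer than 10 synapses is `weak`,
#' 10-20 inclusive is `medium`, more than 20 is `strong`.
#'
#' @param count Non-negative integer vector of PSD counts.
#' @return Factor with levels `weak < medium < strong`.
#' @export
bin_strength <- function(count) {
  if (any(count < 0)) stop("bin_strength: negative count")
  cut(count, breaks = c(-Inf, 9.5, 20.5, Inf),
      labels = c("weak", "medium", "strong"), ordered_result = TRUE)
}

#' Percent increase between two sets of counts
#'
#' `100 * (sum(new) / sum(old) - 1)`, rounded to the nearest integer
#' percent -- the arithmetic used to compare total synaptic input counts
#' between reconstructions.
#'
#' @param new_counts,old_counts Numeric vectors; `sum(old_counts)` must be
#'   positive.
#' @return Integer percent.
#' @export
percent_increase <- function(new_counts, old_counts) {
  if (sum(old_counts) <= 0) stop("percent_increase: old counts sum to zero")
  round(100 * (sum(new_counts) / sum(old_counts) - 1))
}

#' Export a connectivity matrix as TSV
#'
#' Presynaptic types as rows, postsynaptic as columns.
#' @param m Matrix from [connectivity_matrix()].
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @export
write_connectivity_matrix <- function(m, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(pre = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
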