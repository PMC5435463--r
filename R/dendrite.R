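#' Map synapses onto a skeleton
#'
#' Attaches each synapse to its nearest skeleton node (Euclidean distance)
#' and records the path distance along the tree from the root (the axon's
#' main trunk for T4 cells), the normalized dendritic position (path
#' distance divided by the arbor's maximum path distance) and the
#' tip/shaft/base region. Synapses farther than `snap_radius_um` from every
#' node are flagged `mapped = FALSE` and excluded from positional summaries,
#' never silently dropped.
#'
#' @param skel A [skeleton()].
#' @param x,y,z Synapse coordinates in micrometres (vectorized).
#' @param snap_radius_um Maximum attachment distance (default 2).
#' @param region_breaks Two ascending numbers in (0, 1) splitting the
#'   normalized position into base / shaft / tip (default tertiles).
#' @return Data frame: `node_id`, `snap_dist_um`, `path_um`, `norm_pos`,
#'   `region`, `mapped`.
#' @export
map_synapses <- function(skel, x, y, z, snap_radius_um = 2,
                         region_breaks = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(skel, "skeleton"), length(x) == length(y),
            length(x) == length(z))
  pd <- skeleton_path_dist(skel)
  maxd <- max(pd)
  n <- length(x)
  if (n == 0L) {
    return(data.frame(node_id = integer(), snap_dist_um = numeric(),
                      path_um = numeric(), norm_pos = numeric(),
                      region = character(), mapped = logical()))
  }
  # nearest node per synapse
  d2 <- outer(x, skel$x, "-")^2 + outer(y, skel$y, "-")^2 +
    outer(z, skel$z, "-")^2
  idx <- max.col(-d2, ties.method = "first")
  snap <- sqrt(d2[cbind(seq_len(n), idx)])
  mapped <- snap <= snap_radius_um
  norm_pos <- ifelse(mapped, if (maxd > 0) pd[idx] / maxd else 0, NA_real_)
  data.frame(node_id = ifelse(mapped, skel$node_id[idx], NA_integer_),
             snap_dist_um = snap,
             path_um = ifelse(mapped, pd[idx], NA_real_),
             norm_pos = norm_pos,
             region = ifelse(mapped,
                             as.character(region_of(ifelse(is.na(norm_pos), 0,
                                                           norm_pos),
                                                    region_breaks)),
                             NA_character_),
             mapped = mapped)
}

#' Dendritic region of a normalized position
#'
#' Partition of `[0, 1]` into `base` (nearest the trunk), `shaft` and `tip`.
#' The default tertile boundaries realise the qualitative base/shaft/tip
#' vocabulary; boundaries are half-open `[0, b1)`, `[b1, b2)`, `[b2, 1]` so
#' the three regions tile the interval exactly.
#'
#' @param norm_pos Numeric vector in `[0, 1]`.
#' @param breaks Two ascending interior break points.
#' @return Factor with levels `base < shaft < tip`.
#' @export
region_of <- function(norm_pos, breaks = c(1 / 3, 2 / 3)) {
  if (any(norm_pos < 0 | norm_pos > 1, na.rm = TRUE)) {
    stop("region_of: normalized position outside [0, 1]")
  }
  stopifnot(length(breaks) == 2L, breaks[1L] < breaks[2L])
  cut(norm_pos, breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c("base", "shaft", "tip"), ordered_result = TRUE)
}

#' Map all synapses onto one T4's dendrites, by presynaptic type
#'
#' @param dataset A [connectome()] whose `skeletons` include `t4_id`.
#' @param t4_id Target T4 id.
#' @param snap_radius_um,region_breaks Passed to [map_synapses()].
#' @return Data frame with `pre_id`, `pre_type` and the [map_synapses()]
#'   columns, one row per input synapse.
#' @export
mapped_inputs <- function(dataset, t4_id, snap_radius_um = 2,
                          region_breaks = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(dataset, "connectome"))
  skel <- dataset$skeletons[[t4_id]]
  if (is.null(skel)) stop("mapped_inputs: no skeleton for ", t4_id)
  sy <- dataset$synapses[dataset$synapses$post_id == t4_id, , drop = FALSE]
  m <- map_synapses(skel, sy$x, sy$y, sy$z, snap_radius_um, region_breaks)
  ty <- cell_type_of(dataset, sy$pre_id)
  ty[ty %in% T4_SUBTYPES] <- "T4"
  cbind(data.frame(pre_id = sy$pre_id, pre_type = ty), m)
}

#' Permutation test of dendritic segregation between two input types
#'
#' Statistic: difference of mean normalized dendritic positions,
#' `mean(norm_pos of type_b) - mean(norm_pos of type_a)`, in `[-1, 1]`.
#' A positive index means `type_b` sits more distally (towards the tips)
#' than `type_a`. The two-sided p-value comes from a seeded label
#' permutation null (type labels shuffled across the pooled positions).
#'
#' @param dataset A [connectome()].
#' @param t4_id Target T4 id (skeleton required).
#' @param type_a,type_b Presynaptic cell types (at least 3 mapped synapses
#'   each).
#' @param n_perm Number of label permutations (>= 1000 recommended).
#' @param seed Integer seed.
#' @param snap_radius_um Passed to [mapped_inputs()].
#' @return A `segregation_result`: `index`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
segregation <- function(dataset, t4_id, type_a, type_b, n_perm = 1000L,
                        seed = 1L, snap_radius_um = 2) {
  m <- mapped_inputs(dataset, t4_id, snap_radius_um)
  m <- m[m$mapped, , drop = FALSE]
  pos_a <- m$norm_pos[m$pre_type == type_a]
  pos_b <- m$norm_pos[m$pre_type == type_b]
  segregation_from_positions(pos_a, pos_b, n_perm, seed,
                             pair = c(type_a, type_b), t4_id = t4_id)
}

#' @rdname segregation
#' @param pos_a,pos_b Normalized positions of the two groups (alternative
#'   entry point when positions are already mapped).
#' @param pair,t4_id Labels carried into the result.
#' @export
segregation_from_positions <- function(pos_a, pos_b, n_perm = 1000L,
                                       seed = 1L, pair = c("A", "B"),
                                       t4_id = NA_character_) {
  na <- length(pos_a)
  nb <- length(pos_b)
  if (na < 3L || nb < 3L) {
    stop("segregation: need >= 3 mapped synapses per type (got ",
         na, " and ", nb, ")")
  }
  obs <- mean(pos_b) - mean(pos_a)
  pool <- c(pos_a, pos_b)
  n <- na + nb
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(n, nb)
      mean(pool[ix]) - mean(pool[-ix])
    }, numeric(1L))
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  structure(list(t4_id = t4_id, pair = pair, index = obs, p_value = p,
                 mean_a = mean(pos_a), mean_b = mean(pos_b),
                 n_a = na, n_b = nb, n_perm = n_perm, seed = seed),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "<segregation> %s vs %s: index %+.3f (means %.3f / %.3f; n = %d / %d), p = %.4g\n",
    x$pair[1L], x$pair[2L], x$index, x$mean_a, x$mean_b, x$n_a, x$n_b,
    x$p_value))
  invisible(x)
}

#' Dendrite orientation and T4 subtype classification
#'
#' Orientation is the angle of the mean displacement vector from the trunk
#' (root) to the arbor nodes, in the x-y plane. The subtype is the nearest
#' cardinal axis by the lattice convention a = +x, b = -x, c = +y, d = -y
#' (each a 90-degree sector); an angle exactly on a 45-degree sector
#' boundary breaks the tie towards the earlier subtype letter.
#'
#' @param skel A [skeleton()] with at least 5 nodes.
#' @return `dendrite_orientation()`: angle in radians in `[0, 2*pi)`.
#' @export
dendrite_orientation <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  if (nrow(skel) < 5L) {
    stop("dendrite_orientation: need >= 5 nodes, got ", nrow(skel))
  }
  root <- skeleton_root(skel)
  others <- skel[skel$parent_id != -1L, , drop = FALSE]
  v <- c(mean(others$x) - root$x, mean(others$y) - root$y)
  if (sqrt(sum(v^2)) < 1e-9) {
    stop("dendrite_orientation: degenerate arbor (zero mean displacement)")
  }
  atan2(v[2L], v[1L]) %% (2 * pi)
}

#' @rdname dendrite_orientation
#' @param angle Arbor orientation in radians.
#' @return `subtype_of()`: one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @export
subtype_of <- function(angle) {
  axes <- c(a = 0, b = pi, c = pi / 2, d = 3 * pi / 2)
  d <- abs(((angle - axes + pi) %% (2 * pi)) - pi)
  # ties (boundary angles) resolve to the earlier letter by stable ordering
  names(axes)[which.min(round(d, 12))]
}

#' Audit T4-T4 subtype selectivity
#'
#' Lists every T4-to-T4 connection with its pre/post subtypes, the
#' retinotopic column offset of the presynaptic cell relative to the
#' postsynaptic cell (ommatidial units), and the projection of that offset
#' onto the postsynaptic cell's preferred direction. A "violation" is a
#' connection between different subtypes -- the reconstructed data show
#' none.
#'
#' @param dataset A [connectome()]; T4 home columns and subtypes must be
#'   recorded in the neuron table.
#' @return A `selectivity_report`: `connections` data frame (`pre_id`,
#'   `post_id`, `pre_subtype`, `post_subtype`, `same_subtype`, `n_synapses`,
#'   `offset_x`, `offset_y`, `dot_pd`), plus `n_connections` and
#'   `n_violations`.
#' @export
t4_selectivity_report <- function(dataset) {
  stopifnot(inherits(dataset, "connectome"))
  sy <- dataset$synapses
  pre_ty <- cell_type_of(dataset, sy$pre_id)
  post_ty <- cell_type_of(dataset, sy$post_id)
  tt <- !is.na(pre_ty) & !is.na(post_ty) &
    pre_ty %in% T4_SUBTYPES & post_ty %in% T4_SUBTYPES
  sy <- sy[tt, , drop = FALSE]
  if (!nrow(sy)) {
    conn <- data.frame(pre_id = character(), post_id = character(),
                       pre_subtype = character(), post_subtype = character(),
                       same_subtype = logical(), n_synapses = integer(),
                       offset_x = numeric(), offset_y = numeric(),
                       dot_pd = numeric())
  } else {
    key <- paste(sy$pre_id, sy$post_id, sep = "\r")
    agg <- stats::aggregate(list(n_synapses = rep(1L, nrow(sy))),
                            by = list(key = key), FUN = sum)
    ids <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
    nr <- dataset$neurons
    pre <- nr[match(ids[, 1L], nr$id), , drop = FALSE]
    post <- nr[match(ids[, 2L], nr$id), , drop = FALSE]
    if (anyNA(pre$home_q) || anyNA(post$home_q)) {
      stop("t4_selectivity_report: T4 cell(s) without a home column")
    }
    pre_xy <- axial_to_cart(pre$home_q, pre$home_r)
    post_xy <- axial_to_cart(post$home_q, post$home_r)
    off_x <- pre_xy[, "x"] - post_xy[, "x"]
    off_y <- pre_xy[, "y"] - post_xy[, "y"]
    pd <- vapply(post$cell_type, pd_angle, numeric(1L))
    conn <- data.frame(
      pre_id = ids[, 1L], post_id = ids[, 2L],
      pre_subtype = sub("^T4", "", pre$cell_type),
      post_subtype = sub("^T4", "", post$cell_type),
      same_subtype = pre$cell_type == post$cell_type,
      n_synapses = agg$n_synapses,
      offset_x = off_x, offset_y = off_y,
      dot_pd = off_x * cos(pd) + off_y * sin(pd))
  }
  structure(list(connections = conn,
                 n_connections = nrow(conn),
                 n_violations = sum(!conn$same_subtype)),
            class = "selectivity_report")
}

#' @export
print.selectivity_report <- function(x, ...) {
  cat(sprintf(
    "<selectivity> %d T4-T4 connections, %d cross-subtype violation(s); %d/%d offsets opposite the PD\n",
    x$n_connections, x$n_violations,
    sum(x$connections$dot_pd <= 0), x$n_connections))
  invisible(x)
}
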