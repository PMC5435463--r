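#' Circuit template for the synthetic connectome generator
#'
#' The template encodes, per presynaptic cell type, the statistical structure
#' the analyses assume: target input fractions onto a T4, a spatial profile
#' over normalized dendritic position (Beta distributions on `[0, 1]`, 0 =
#' dendrite base at the trunk, 1 = tips), a planted anatomical field offset
#' along the T4's arbor-growth axis in ommatidial units, a synaptic sign,
#' and polyadic T-bar grouping. Defaults emulate the reconstructed
#' seven-column medulla volume: Mi1/Tm3 dominate the input budget and spread
#' along the dendrite shaft, Mi9 clusters at the tips, Mi4/C3/CT1 at the
#' bases, and T4-T4 inputs arrive at the tips from the same-subtype T4 of
#' the column displaced opposite the preferred direction. Mi9's sign is
#' physiologically tentative and therefore has no default (`NA`); set it
#' explicitly when it matters.
#'
#' @param ... Named overrides of the default fields (partial lists are
#'   merged recursively).
#' @return A `circuit_template` list.
#' @export
circuit_template <- function(...) {
  tpl <- list(
    n_inputs_per_t4 = 400L,
    # target input fractions (generator defaults, not assertions about data)
    fractions = c(Mi1 = 0.35, Tm3 = 0.16, Mi9 = 0.13, Mi4 = 0.06, C3 = 0.04,
                  TmY15 = 0.08, CT1 = 0.07, T4 = 0.06, Mi10 = 0.006,
                  unknown = 0.044),
    # Beta(shape1, shape2) over normalized dendritic position
    profiles = list(Mi1 = c(2, 2), Tm3 = c(2, 2), Mi9 = c(5, 1.5),
                    Mi4 = c(1.5, 5), C3 = c(1.5, 5), CT1 = c(1.5, 5),
                    TmY15 = c(2, 2), T4 = c(5, 1.5), Mi10 = c(2, 2),
                    unknown = c(2, 2)),
    signs = c(Mi1 = 1, Tm3 = 1, Mi4 = -1, C3 = -1, CT1 = -1, TmY15 = -1,
              Mi9 = NA, T4 = 1, Mi10 = NA, unknown = NA),
    # planted per-type field-centre offset along the arbor axis (ommatidia);
    # magnitudes follow the measured subfield displacements, which reach and
    # sometimes exceed one inter-ommatidial distance between tip- and
    # base-located input types
    field_offset_units = c(Mi1 = 0.25, Mi9 = 1.0, Mi4 = -0.5, C3 = -0.5,
                           CT1 = -0.5, Mi10 = 0),
    kernel_sd = 0.75,          # spatial spread of per-column weight kernels
    weight_maps = list(),      # optional explicit per-type (dq, dr, w) maps
    # Tm3 population feeding each analysed T4
    tm3 = list(n_per_t4 = 8L, target_offset = 0.25, ring_radius = 0.6,
               centre_jitter_sd = 0.1, l1_kernel_sd = 0.7, n_l1 = 30L),
    mi1_l1 = list(n_l1 = 40L, home_weight = 0.85),
    n_tmy15 = 3L, n_unknown = 5L,
    psd_per_tbar_lambda = 5,   # PSDs per T-bar = 1 + Poisson(lambda)
    t4_arbor = list(span_columns = 2.5, n_branches = 5L,
                    angle_spread_deg = 15, nodes_per_branch = 12L,
                    synapse_jitter_um = 0.3),
    column_spacing_um = 8
  )
  overrides <- list(...)
  if (length(overrides)) tpl <- utils::modifyList(tpl, overrides)
  stopifnot(all(tpl$fractions >= 0), abs(sum(tpl$fractions) - 1) < 1e-6)
  class(tpl) <- "circuit_template"
  tpl
}

#' Arbor-growth axis and preferred direction of a T4 subtype
#'
#' By lattice convention the dendritic arbour of subtype a grows along +x,
#' b along -x, c along +y and d along -y. The preferred direction (PD) of
#' each subtype is the opposite axis: PD runs from the excitatory inputs on
#' the dendrite shaft towards the inhibitory inputs at the base, i.e. from
#' the dendrite tips back towards the trunk.
#'
#' @param subtype One of `"a"`, `"b"`, `"c"`, `"d"` (or `"T4a"` etc.).
#' @return Angle in radians.
#' @rdname t4_axes
#' @export
arbor_axis_angle <- function(subtype) {
  s <- sub("^T4", "", subtype)
  ang <- c(a = 0, b = pi, c = pi / 2, d = 3 * pi / 2)
  if (any(!s %in% names(ang))) stop("unknown T4 subtype: ", subtype)
  unname(ang[s])
}

#' @rdname t4_axes
#' @export
pd_angle <- function(subtype) {
  (arbor_axis_angle(subtype) + pi) %% (2 * pi)
}

unit_vec <- function(angle) c(cos(angle), sin(angle))

# axial step most aligned with each subtype's arbor axis (towards the tips,
# where same-subtype presynaptic T4s sit, opposite the PD)
t4_pre_offset <- function(subtype) {
  s <- sub("^T4", "", subtype)
  switch(s,
         a = c(1L, 0L), b = c(-1L, 0L), c = c(0L, 1L), d = c(0L, -1L),
         stop("unknown T4 subtype: ", subtype))
}

#' Generate a synthetic T4 neuron skeleton
#'
#' Builds a rooted tree whose root (the axon's main trunk) sits at the
#' centre of the cell's home column and whose branches spread predominantly
#' along the subtype's arbor axis, spanning roughly 2-3 column spacings, as
#' T4 dendrites do in medulla stratum M10.
#'
#' @param subtype T4 subtype, `"a"` to `"d"`.
#' @param column Axial home-column coordinate, `c(q, r)`.
#' @param seed Integer seed.
#' @param template A [circuit_template()] (only the `t4_arbor` and
#'   `column_spacing_um` fields are used).
#' @return A [skeleton()] with a per-node `branch` attribute used by the
#'   generator for synapse placement.
#' @export
make_t4 <- function(subtype, column = c(0L, 0L), seed = 1L,
                    template = circuit_template()) {
  arb <- template$t4_arbor
  spacing <- template$column_spacing_um
  axis <- arbor_axis_angle(subtype)
  trunk <- axial_to_cart(column[1L], column[2L])[1L, ] * spacing
  with_seed(seed, {
    nb <- arb$n_branches
    npb <- arb$nodes_per_branch
    angles <- axis + stats::runif(nb, -1, 1) * arb$angle_spread_deg * pi / 180
    lens <- arb$span_columns * spacing * stats::runif(nb, 0.85, 1.05)
    nodes <- list(data.frame(node_id = 1L, parent_id = -1L,
                             x = trunk["x"], y = trunk["y"], z = 35,
                             radius = 0.3, branch = 0L))
    nid <- 1L
    for (b in seq_len(nb)) {
      step <- lens[b] / npb
      ang <- angles[b] + cumsum(stats::rnorm(npb, 0, 5 * pi / 180))
      dx <- cumsum(step * cos(ang))
      dy <- cumsum(step * sin(ang))
      dz <- cumsum(stats::rnorm(npb, 0, 0.2))
      ids <- nid + seq_len(npb)
      nodes[[b + 1L]] <- data.frame(
        node_id = ids, parent_id = c(1L, ids[-npb]),
        x = trunk["x"] + dx, y = trunk["y"] + dy, z = 35 + dz,
        radius = 0.15, branch = b)
      nid <- nid + npb
    }
    df <- do.call(rbind, nodes)
    skel <- skeleton(df[, 1:6])
    attr(skel, "branch") <- df$branch
    skel
  })
}

# Gaussian column-weight kernel over the lattice, centred at `centre` (cart,
# ommatidial units). Returns weights aligned with lattice rows.
kernel_weights <- function(lattice, centre, sd) {
  xy <- axial_to_cart(lattice$q, lattice$r)
  d2 <- (xy[, "x"] - centre[1L])^2 + (xy[, "y"] - centre[2L])^2
  w <- exp(-d2 / (2 * sd^2))
  w / sum(w)
}

# Expected per-column weights for one input type onto a T4 at `home`.
# Explicit maps are relative (dq, dr) to the home column and must land on
# the lattice; otherwise a Gaussian kernel at the planted offset is used.
type_column_weights <- function(template, lattice, type, home, axis_angle) {
  if (!is.null(template$weight_maps[[type]])) {
    wm <- template$weight_maps[[type]]
    q <- home[1L] + wm$dq
    r <- home[2L] + wm$dr
    if (!all(lattice_has(lattice, q, r))) {
      stop("circuit template: weight map for ", type,
           " references columns outside the lattice")
    }
    w <- rep(0, nrow(lattice))
    w[match(paste(q, r), paste(lattice$q, lattice$r))] <- wm$w
    return(w / sum(w))
  }
  off <- template$field_offset_units[[type]]
  if (is.null(off) || is.na(off)) off <- 0
  centre <- axial_to_cart(home[1L], home[2L])[1L, ] + off * unit_vec(axis_angle)
  kernel_weights(lattice, centre, template$kernel_sd)
}

# place `n` synapses on a T4 skeleton at Beta-distributed normalized
# dendritic positions; returns data.frame(x, y, z, norm_pos)
place_on_dendrite <- function(skel, n, shape, jitter_um) {
  if (n == 0L) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      norm_pos = numeric()))
  }
  branch <- attr(skel, "branch")
  pd <- skeleton_path_dist(skel)
  maxd <- max(pd)
  p <- stats::rbeta(n, shape[1L], shape[2L])
  b <- sample(max(branch), n, replace = TRUE)
  idx <- vapply(seq_len(n), function(i) {
    on_b <- which(branch == b[i] | branch == 0L)
    on_b[which.min(abs(pd[on_b] - p[i] * maxd))]
  }, integer(1L))
  data.frame(x = skel$x[idx] + stats::rnorm(n, 0, jitter_um),
             y = skel$y[idx] + stats::rnorm(n, 0, jitter_um),
             z = skel$z[idx] + stats::rnorm(n, 0, jitter_um),
             norm_pos = pd[idx] / maxd)
}

# group `n` PSD rows of one presynaptic cell into polyadic T-bars
tbar_ids <- function(pre_id, n, lambda) {
  if (n == 0L) return(character())
  sizes <- integer()
  while (sum(sizes) < n) {
    sizes <- c(sizes, 1L + stats::rpois(max(8L, n %/% 3L), lambda))
  }
  k <- which(cumsum(sizes) >= n)[1L]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (sum(sizes) - n)
  rep(sprintf("tb:%s:%d", pre_id, seq_len(k)), times = sizes)
}

cell_id <- function(type, q, r) sprintf("%s:%d,%d", type, q, r)

#' Generate a seeded synthetic connectome
#'
#' Builds a toy medulla connectome on a hexagonal column lattice with the
#' statistical and spatial structure the analyses assume: one Mi1, Mi4,
#' Mi9, C3, L1 and CT1 terminal unit per column, four T4 subtypes per
#' column, dedicated Tm3 populations and full synaptic input sets for the
#' four Home-column T4s, polyadic T-bar grouping, L1 inputs onto Mi1 and
#' Tm3 (from which anatomical field centres are estimated), and same-subtype
#' T4-T4 inputs from the column displaced opposite each cell's preferred
#' direction. All randomness flows from `seed` through stable per-cell
#' streams, so output is reproducible run-to-run.
#'
#' The returned dataset carries a `ground_truth` list: per-cell true field
#' centres and completeness, per-T4 subtype/preferred direction, and the
#' planted per-type field offsets (exact centroids of the discrete column
#' weights, relative to Mi1) against which estimators can be scored.
#'
#' @param template A [circuit_template()].
#' @param lattice A [make_lattice()] lattice.
#' @param seed Integer seed.
#' @return A [connectome()] with ground truth.
#' @export
make_circuit <- function(template = circuit_template(),
                         lattice = make_lattice(1L), seed = 1L) {
  stopifnot(inherits(template, "circuit_template"),
            inherits(lattice, "hex_lattice"))
  spacing <- template$column_spacing_um

  ## ---- neuron tables -------------------------------------------------
  percol_types <- c("Mi1", "Mi4", "Mi9", "C3", "L1")
  rows <- list()
  for (ty in percol_types) {
    rows[[ty]] <- data.frame(id = cell_id(ty, lattice$q, lattice$r),
                             cell_type = ty, home_q = lattice$q,
                             home_r = lattice$r)
  }
  # CT1 is a single wide-field neuron; its arbour in each column is counted
  # as a separate column-assignable terminal unit
  rows$CT1 <- rbind(
    data.frame(id = "CT1", cell_type = "CT1", home_q = NA, home_r = NA),
    data.frame(id = cell_id("CT1", lattice$q, lattice$r),
               cell_type = "CT1", home_q = lattice$q, home_r = lattice$r))
  rows$T4 <- do.call(rbind, lapply(T4_SUBTYPES, function(ty) {
    data.frame(id = cell_id(ty, lattice$q, lattice$r), cell_type = ty,
               home_q = lattice$q, home_r = lattice$r)
  }))
  rows$Mi10 <- data.frame(id = "Mi10:0,0", cell_type = "Mi10",
                          home_q = 0L, home_r = 0L)
  rows$TmY15 <- data.frame(id = sprintf("TmY15:%d", seq_len(template$n_tmy15)),
                           cell_type = "TmY15", home_q = NA, home_r = NA)
  rows$unknown <- data.frame(id = sprintf("unk:%d", seq_len(template$n_unknown)),
                             cell_type = "unknown", home_q = NA, home_r = NA)

  home_t4s <- cell_id(T4_SUBTYPES, 0L, 0L)
  tm3_rows <- list()
  tm3_meta <- list()   # per Tm3: owner T4, nominal centre
  for (t4 in home_t4s) {
    sub <- sub(":.*$", "", t4)
    axis <- arbor_axis_angle(sub)
    target <- axial_to_cart(0L, 0L)[1L, ] +
      template$tm3$target_offset * unit_vec(axis)
    k <- template$tm3$n_per_t4
    th <- 2 * pi * (seq_len(k) - 1L) / k
    jit <- with_seed(stable_seed(seed, paste0("tm3centres:", t4)),
                     matrix(stats::rnorm(2L * k, 0, template$tm3$centre_jitter_sd),
                            ncol = 2L))
    cx <- target["x"] + template$tm3$ring_radius * cos(th) + jit[, 1L]
    cy <- target["y"] + template$tm3$ring_radius * sin(th) + jit[, 2L]
    ids <- sprintf("Tm3:%s:%d", sub("^T4", "", sub), seq_len(k))
    tm3_rows[[t4]] <- data.frame(id = ids, cell_type = "Tm3",
                                 home_q = NA, home_r = NA)
    tm3_meta[[t4]] <- data.frame(id = ids, owner = t4, cx = cx, cy = cy)
  }
  rows$Tm3 <- do.call(rbind, tm3_rows)
  tm3_meta <- do.call(rbind, tm3_meta)

  nr <- do.call(rbind, rows)
  neurons <- neuron_table(nr$id, nr$cell_type, nr$home_q, nr$home_r,
                          completeness = 1)
  neurons$unit_of[neurons$cell_type == "CT1" & neurons$id != "CT1"] <- "CT1"

  ## ---- volume bounds -------------------------------------------------
  xy <- axial_to_cart(lattice$q, lattice$r) * spacing
  margin <- 2.5 * spacing
  bounds <- c(xmin = min(xy[, "x"]) - margin, xmax = max(xy[, "x"]) + margin,
              ymin = min(xy[, "y"]) - margin, ymax = max(xy[, "y"]) + margin,
              zmin = 0, zmax = 45)

  ## ---- T4 skeletons (analysed Home cells) ----------------------------
  skeletons <- list()
  for (t4 in home_t4s) {
    sub <- sub(":.*$", "", t4)
    skeletons[[t4]] <- make_t4(sub, c(0L, 0L),
                               seed = stable_seed(seed, paste0("skel:", t4)),
                               template = template)
  }

  ## ---- synapses onto the Home T4s ------------------------------------
  syn <- list()
  gt_offsets <- list()
  gt_tm3_mi1 <- list()
  unicol <- c("Mi1", "Mi9", "Mi4", "C3", "CT1", "Mi10")
  lat_xy <- axial_to_cart(lattice$q, lattice$r)

  for (t4 in home_t4s) {
    sub <- sub(":.*$", "", t4)
    axis <- arbor_axis_angle(sub)
    skel <- skeletons[[t4]]
    syn[[t4]] <- with_seed(stable_seed(seed, paste0("inputs:", t4)), {
      counts <- as.vector(stats::rmultinom(1L, template$n_inputs_per_t4,
                                           template$fractions))
      names(counts) <- names(template$fractions)
      parts <- list()
      for (ty in names(counts)) {
        n <- counts[[ty]]
        if (n == 0L) next
        pre <- switch(
          ty,
          Tm3 = {
            ids <- tm3_meta$id[tm3_meta$owner == t4]
            ids[sample(length(ids), n, replace = TRUE)]
          },
          TmY15 = sprintf("TmY15:%d",
                          sample(template$n_tmy15, n, replace = TRUE)),
          unknown = sprintf("unk:%d",
                            sample(template$n_unknown, n, replace = TRUE)),
          T4 = {
            step <- t4_pre_offset(sub)
            if (!lattice_has(lattice, step[1L], step[2L])) {
              stop("make_circuit: lattice too small for T4-T4 inputs")
            }
            rep(cell_id(sub, step[1L], step[2L]), n)
          },
          Mi10 = rep("Mi10:0,0", n),
          { # unicolumnar types drawn from per-column weight maps
            w <- type_column_weights(template, lattice, ty, c(0L, 0L), axis)
            cols <- sample(nrow(lattice), n, replace = TRUE, prob = w)
            cell_id(ty, lattice$q[cols], lattice$r[cols])
          })
        pos <- place_on_dendrite(skel, n, template$profiles[[ty]],
                                 template$t4_arbor$synapse_jitter_um)
        parts[[ty]] <- data.frame(pre_id = pre, post_id = t4, pos)
      }
      df <- do.call(rbind, parts)
      # polyadic grouping per presynaptic cell
      df <- df[order(df$pre_id), , drop = FALSE]
      tb <- unlist(lapply(split(seq_len(nrow(df)), df$pre_id), function(ix) {
        tbar_ids(df$pre_id[ix[1L]], length(ix), template$psd_per_tbar_lambda)
      }), use.names = FALSE)
      df$tbar_id <- tb
      df
    })

    ## planted field offsets (exact discrete centroids, relative to Mi1)
    wmi1 <- type_column_weights(template, lattice, "Mi1", c(0L, 0L), axis)
    cmi1 <- c(sum(lat_xy[, "x"] * wmi1), sum(lat_xy[, "y"] * wmi1))
    for (ty in setdiff(unicol, "Mi1")) {
      w <- type_column_weights(template, lattice, ty, c(0L, 0L), axis)
      cc <- c(sum(lat_xy[, "x"] * w), sum(lat_xy[, "y"] * w))
      gt_offsets[[paste(t4, ty)]] <- data.frame(
        t4_id = t4, pre_type = ty, dx = cc[1L] - cmi1[1L],
        dy = cc[2L] - cmi1[2L])
    }
  }

  ## ---- L1 inputs onto Mi1 cells --------------------------------------
  gt_centres <- list()
  mi1_ids <- neurons$id[neurons$cell_type == "Mi1"]
  for (mid in mi1_ids) {
    home <- neurons[neurons$id == mid, c("home_q", "home_r")]
    nb <- hex_neighbours(home$home_q, home$home_r)
    nb <- nb[lattice_has(lattice, nb$q, nb$r), , drop = FALSE]
    cols <- rbind(data.frame(q = home$home_q, r = home$home_r), nb)
    w <- c(template$mi1_l1$home_weight,
           rep((1 - template$mi1_l1$home_weight) / max(1L, nrow(nb)),
               nrow(nb)))
    w <- w / sum(w)
    cxy <- axial_to_cart(cols$q, cols$r)
    gt_centres[[mid]] <- data.frame(
      id = mid, true_x = sum(cxy[, "x"] * w), true_y = sum(cxy[, "y"] * w))
    syn[[paste0("l1>", mid)]] <- with_seed(stable_seed(seed, paste0("l1:", mid)), {
      n <- template$mi1_l1$n_l1
      drawn <- sample(nrow(cols), n, replace = TRUE, prob = w)
      data.frame(pre_id = cell_id("L1", cols$q[drawn], cols$r[drawn]),
                 post_id = mid,
                 x = cxy[drawn, "x"] * spacing + stats::rnorm(n, 0, 1),
                 y = cxy[drawn, "y"] * spacing + stats::rnorm(n, 0, 1),
                 z = stats::runif(n, 15, 25), norm_pos = NA_real_,
                 tbar_id = tbar_ids(paste0("L1>", mid), n,
                                    template$psd_per_tbar_lambda))
    })
  }

  ## ---- L1 inputs onto Tm3 cells --------------------------------------
  for (i in seq_len(nrow(tm3_meta))) {
    tid <- tm3_meta$id[i]
    centre <- c(tm3_meta$cx[i], tm3_meta$cy[i])
    w <- kernel_weights(lattice, centre, template$tm3$l1_kernel_sd)
    gt_centres[[tid]] <- data.frame(
      id = tid, true_x = sum(lat_xy[, "x"] * w),
      true_y = sum(lat_xy[, "y"] * w))
    syn[[paste0("l1>", tid)]] <- with_seed(stable_seed(seed, paste0("l1:", tid)), {
      n <- template$tm3$n_l1
      drawn <- sample(nrow(lattice), n, replace = TRUE, prob = w)
      data.frame(pre_id = cell_id("L1", lattice$q[drawn], lattice$r[drawn]),
                 post_id = tid,
                 x = lat_xy[drawn, "x"] * spacing + stats::rnorm(n, 0, 1),
                 y = lat_xy[drawn, "y"] * spacing + stats::rnorm(n, 0, 1),
                 z = stats::runif(n, 15, 25), norm_pos = NA_real_,
                 tbar_id = tbar_ids(paste0("L1>", tid), n,
                                    template$psd_per_tbar_lambda))
    })
  }

  ## ---- planted Tm3 - Mi1 offset per analysed T4 ----------------------
  for (t4 in home_t4s) {
    sub <- sub(":.*$", "", t4)
    axis <- arbor_axis_angle(sub)
    meta <- tm3_meta[tm3_meta$owner == t4, , drop = FALSE]
    tc <- do.call(rbind, lapply(meta$id, function(id) gt_centres[[id]]))
    tm3_mean <- c(mean(tc$true_x), mean(tc$true_y))  # equal expected weights
    wmi1 <- type_column_weights(template, lattice, "Mi1", c(0L, 0L), axis)
    mi1_centres <- do.call(rbind, lapply(seq_len(nrow(lattice)), function(j) {
      gt_centres[[cell_id("Mi1", lattice$q[j], lattice$r[j])]]
    }))
    mi1_mean <- c(sum(mi1_centres$true_x * wmi1),
                  sum(mi1_centres$true_y * wmi1))
    gt_tm3_mi1[[t4]] <- data.frame(t4_id = t4,
                                   dx = tm3_mean[1L] - mi1_mean[1L],
                                   dy = tm3_mean[2L] - mi1_mean[2L])
  }

  ## ---- a few inputs onto each CT1 terminal (pathway realism) ---------
  for (j in seq_len(nrow(lattice))) {
    ct <- cell_id("CT1", lattice$q[j], lattice$r[j])
    syn[[paste0("onto>", ct)]] <- with_seed(stable_seed(seed, paste0("ct1in:", ct)), {
      pres <- c(rep(cell_id("Mi1", lattice$q[j], lattice$r[j]), 3L),
                rep(cell_id("Mi9", lattice$q[j], lattice$r[j]), 2L),
                cell_id(sample(T4_SUBTYPES, 2L, replace = TRUE),
                        lattice$q[j], lattice$r[j]))
      n <- length(pres)
      data.frame(pre_id = pres, post_id = ct,
                 x = lat_xy[j, "x"] * spacing + stats::rnorm(n, 0, 1),
                 y = lat_xy[j, "y"] * spacing + stats::rnorm(n, 0, 1),
                 z = stats::runif(n, 33, 37), norm_pos = NA_real_,
                 tbar_id = tbar_ids(paste0("onto>", ct), n,
                                    template$psd_per_tbar_lambda))
    })
  }

  syn <- do.call(rbind, syn)
  rownames(syn) <- NULL
  synapses <- synapse_table(syn$pre_id, syn$post_id, syn$tbar_id,
                            syn$x, syn$y, syn$z)
  # clamp stray jitter inside the volume
  synapses$x <- pmin(pmax(synapses$x, bounds["xmin"]), bounds["xmax"])
  synapses$y <- pmin(pmax(synapses$y, bounds["ymin"]), bounds["ymax"])
  synapses$z <- pmin(pmax(synapses$z, bounds["zmin"]), bounds["zmax"])

  ground_truth <- list(
    seed = seed,
    cells = do.call(rbind, c(gt_centres, list(make.row.names = FALSE))),
    completeness = stats::setNames(rep(1, nrow(neurons)), neurons$id),
    t4 = data.frame(id = home_t4s, subtype = sub("^T4", "", T4_SUBTYPES),
                    home_q = 0L, home_r = 0L,
                    arbor_angle = vapply(T4_SUBTYPES, arbor_axis_angle,
                                         numeric(1L)),
                    pd_angle = vapply(T4_SUBTYPES, pd_angle, numeric(1L)),
                    row.names = NULL),
    field_offsets = do.call(rbind, c(gt_offsets, list(make.row.names = FALSE))),
    tm3_mi1 = do.call(rbind, c(gt_tm3_mi1, list(make.row.names = FALSE))),
    tm3_owner = tm3_meta[, c("id", "owner")]
  )

  connectome(neurons, synapses, lattice, bounds, skeletons,
             ground_truth = ground_truth,
             column_spacing_um = spacing)
}

intersect_bounds <- function(a, b) {
  out <- c(xmin = max(a["xmin"], b["xmin"]), xmax = min(a["xmax"], b["xmax"]),
           ymin = max(a["ymin"], b["ymin"]), ymax = min(a["ymax"], b["ymax"]),
           zmin = max(a["zmin"], b["zmin"]), zmax = min(a["zmax"], b["zmax"]))
  names(out) <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  out
}

# realized completeness per cell: retained / original PSD rows that involve
# the cell as pre- or postsynaptic partner
realized_completeness <- function(original, retained, ids) {
  count_rows <- function(sy) {
    tab <- table(factor(c(sy$pre_id, sy$post_id), levels = ids))
    as.numeric(tab)
  }
  orig <- count_rows(original)
  kept <- count_rows(retained)
  comp <- ifelse(orig > 0, kept / orig, NA_real_)
  stats::setNames(comp, ids)
}

#' Truncate a connectome at a volume boundary
#'
#' Emulates the finite imaged volume: synapses located outside `box` are
#' removed, skeleton subtrees whose nodes leave the box are pruned, and each
#' cell's reconstruction completeness is recorded as the fraction of its
#' original postsynaptic-site rows that survive.
#'
#' @param dataset A [connectome()].
#' @param box Named numeric vector `xmin..zmax` (micrometres); must
#'   intersect the current volume bounds.
#' @return The truncated `connectome`, with updated `completeness` in its
#'   neuron table and ground truth (if present).
#' @export
truncate_connectome <- function(dataset, box) {
  stopifnot(inherits(dataset, "connectome"))
  box <- intersect_bounds(dataset$volume_bounds, box)
  if (box["xmin"] >= box["xmax"] || box["ymin"] >= box["ymax"] ||
      box["zmin"] >= box["zmax"]) {
    stop("truncate_connectome: box does not intersect the volume bounds")
  }
  sy <- dataset$synapses
  keep <- in_bounds(sy$x, sy$y, sy$z, box)
  retained <- sy[keep, , drop = FALSE]
  class(retained) <- class(sy)

  skeletons <- list()
  for (id in names(dataset$skeletons)) {
    sk <- dataset$skeletons[[id]]
    inside <- in_bounds(sk$x, sk$y, sk$z, box)
    if (!inside[sk$parent_id == -1L]) next  # root outside: cell lost
    # prune subtrees rooted at out-of-box nodes
    drop <- !inside
    repeat {
      pidx <- match(sk$parent_id, sk$node_id)
      newdrop <- drop | (!is.na(pidx) & drop[pidx])
      if (identical(newdrop, drop)) break
      drop <- newdrop
    }
    kept <- sk[!drop, , drop = FALSE]
    br <- attr(sk, "branch")
    sk2 <- skeleton(as.data.frame(kept))
    if (!is.null(br)) attr(sk2, "branch") <- br[!drop]
    skeletons[[id]] <- sk2
  }

  comp <- realized_completeness(sy, retained, dataset$neurons$id)
  neurons <- dataset$neurons
  touched <- !is.na(comp)
  neurons$completeness[touched] <- comp[touched]

  gt <- dataset$ground_truth
  if (!is.null(gt)) gt$completeness[names(comp)[touched]] <- comp[touched]

  connectome(neurons, retained, dataset$lattice, box, skeletons,
             ground_truth = gt,
             column_spacing_um = dataset$column_spacing_um)
}

#' Emulate partial Tm3 reconstruction with a completeness ladder
#'
#' Applies the generator's uniform-truncation model to the Tm3 population
#' feeding one analysed T4: the Tm3s are ranked by how far their true field
#' centres project along the T4's arbor-growth axis (cells reaching
#' furthest towards the volume edge beyond the dendrite tips are least
#' complete) and assigned the given completeness ladder in that order. The
#' default ladder reproduces the completeness regime reported for the eight
#' Tm3 cells feeding the front-to-back T4 of the reconstructed volume
#' (100, 100, 94, 85, 72, 61, 49 and 42 percent).
#'
#' @param dataset A synthetic [connectome()] with ground truth.
#' @param t4_id Analysed T4 id.
#' @param ladder Completeness values in (0, 1], one per Tm3 (recycled /
#'   truncated to the number of Tm3s, assigned from most complete to the
#'   most central Tm3).
#' @param seed Integer seed for the random thinning.
#' @return The thinned `connectome`.
#' @export
emulate_partial_tm3 <- function(dataset, t4_id,
                                ladder = c(1, 1, 0.94, 0.85, 0.72, 0.61,
                                           0.49, 0.42),
                                seed = 1L) {
  gt <- dataset$ground_truth
  if (is.null(gt)) stop("emulate_partial_tm3: needs a synthetic dataset")
  ids <- gt$tm3_owner$id[gt$tm3_owner$owner == t4_id]
  if (!length(ids)) stop("emulate_partial_tm3: no Tm3 cells for ", t4_id)
  sub <- dataset$neurons$cell_type[dataset$neurons$id == t4_id]
  u <- unit_vec(arbor_axis_angle(sub))
  centres <- gt$cells[match(ids, gt$cells$id), , drop = FALSE]
  proj <- centres$true_x * u[1L] + centres$true_y * u[2L]
  ladder <- sort(rep_len(ladder, length(ids)), decreasing = TRUE)
  comp <- stats::setNames(ladder[rank(proj, ties.method = "first")], ids)
  thin_cell_synapses(dataset, comp, seed = seed)
}

#' Thin the synapses of selected cells uniformly at random
#'
#' The generator's uniform-truncation model of partial reconstruction: every
#' postsynaptic-site row involving a targeted cell is retained independently
#' with that cell's target completeness, emulating a proofreading process
#' that misses a random fraction of a partially reconstructed cell's
#' synapses. The realized retained fraction is recorded as the cell's
#' completeness. Under this model an inverse-completeness reweighting of
#' synapse counts is unbiased, whereas raw counts under-weight partial
#' cells.
#'
#' @param dataset A [connectome()].
#' @param completeness Named numeric vector in (0, 1], keyed by cell id.
#' @param seed Integer seed.
#' @return The thinned `connectome`.
#' @export
thin_cell_synapses <- function(dataset, completeness, seed = 1L) {
  stopifnot(inherits(dataset, "connectome"),
            all(completeness > 0), all(completeness <= 1))
  missing_ids <- setdiff(names(completeness), dataset$neurons$id)
  if (length(missing_ids)) {
    stop("thin_cell_synapses: unknown cell id(s) ",
         paste(missing_ids, collapse = ", "))
  }
  sy <- dataset$synapses
  p <- rep(1, nrow(sy))
  for (id in names(completeness)) {
    hit <- sy$pre_id == id | sy$post_id == id
    p[hit] <- p[hit] * completeness[[id]]
  }
  keep <- with_seed(seed, stats::runif(nrow(sy)) < p)
  retained <- sy[keep, , drop = FALSE]
  class(retained) <- class(sy)

  comp <- realized_completeness(sy, retained, dataset$neurons$id)
  neurons <- dataset$neurons
  touched <- dataset$neurons$id %in% names(completeness) & !is.na(comp)
  neurons$completeness[touched] <- comp[dataset$neurons$id][touched]

  gt <- dataset$ground_truth
  if (!is.null(gt)) {
    ids <- dataset$neurons$id[touched]
    gt$completeness[ids] <- comp[ids]
  }

  connectome(neurons, retained, dataset$lattice, dataset$volume_bounds,
             dataset$skeletons, ground_truth = gt,
             column_spacing_um = dataset$column_spacing_um)
}
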