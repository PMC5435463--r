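# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Minimal connectome in which each requested (pre_type, column) cell makes a
# given number of synapses onto a single T4a at Home. `count_spec` is a
# named list: type -> data.frame(q, r, n).
fixture_connectome <- function(count_spec, radius = 2L, post_type = "T4a") {
  lat <- make_lattice(radius)
  post_id <- paste0(post_type, ":0,0")
  ids <- character(); types <- character(); hq <- integer(); hr <- integer()
  syn <- list()
  for (ty in names(count_spec)) {
    df <- count_spec[[ty]]
    for (i in seq_len(nrow(df))) {
      id <- sprintf("%s:%d,%d", ty, df$q[i], df$r[i])
      ids <- c(ids, id); types <- c(types, ty)
      hq <- c(hq, df$q[i]); hr <- c(hr, df$r[i])
      n <- df$n[i]
      if (n > 0) {
        syn[[id]] <- data.frame(
          pre_id = id, post_id = post_id,
          tbar_id = sprintf("tb:%s:%d", id, seq_len(n)),
          x = 0, y = 0, z = 0)
      }
    }
  }
  neurons <- neuron_table(c(ids, post_id), c(types, post_type),
                          home_q = c(hq, 0L), home_r = c(hr, 0L))
  sdf <- do.call(rbind, syn)
  synapses <- if (is.null(sdf)) {
    synapse_table(character(), character(), character(),
                  numeric(), numeric(), numeric())
  } else {
    synapse_table(sdf$pre_id, sdf$post_id, sdf$tbar_id, sdf$x, sdf$y, sdf$z)
  }
  bounds <- c(xmin = -100, xmax = 100, ymin = -100, ymax = 100,
              zmin = -10, zmax = 50)
  connectome(neurons, synapses, lat, bounds)
}

# Random rooted tree skeleton with n nodes (seeded), node coords in a box.
random_tree_skeleton <- function(n = 50L, seed = 1L) {
  set.seed(seed)
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1L)))
  skeleton(data.frame(
    node_id = seq_len(n), parent_id = parent,
    x = runif(n, 0, 30), y = runif(n, 0, 30), z = runif(n, 0, 10),
    radius = 0.2))
}

# Template that plants an exact Mi9-vs-Mi1 field offset via explicit
# two-column weight maps; n synapses split evenly between the two types.
offset_recovery_template <- function(offset = 0.5, n = 500L) {
  mi9_map <- if (offset >= 1) {
    data.frame(dq = 1L, dr = 0L, w = 1)
  } else {
    data.frame(dq = c(0L, 1L), dr = 0L, w = c(1 - offset, offset))
  }
  circuit_template(
    n_inputs_per_t4 = as.integer(n),
    fractions = c(Mi1 = 0.5, Tm3 = 0, Mi9 = 0.5, Mi4 = 0, C3 = 0,
                  TmY15 = 0, CT1 = 0, T4 = 0, Mi10 = 0, unknown = 0),
    weight_maps = list(Mi1 = data.frame(dq = 0L, dr = 0L, w = 1),
                       Mi9 = mi9_map))
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("|%s - %s| <= %g",
                              paste(round(actual, 5), collapse = ","),
                              paste(round(expected, 5), collapse = ","), tol))
}
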