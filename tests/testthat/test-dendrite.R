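test_that("synapse mapping snaps to the nearest node with correct path distances", {
  chain <- skeleton(data.frame(node_id = 1:4, parent_id = c(-1, 1, 2, 3),
                               x = c(0, 5, 10, 15), y = 0, z = 0,
                               radius = 0.1))
  m <- map_synapses(chain, x = c(0, 15, 5.4, 40), y = c(0, 0, 0, 0),
                    z = c(0, 0, 0.5, 0))
  expect_equal(m$path_um[1], 0)            # at the root
  expect_equal(m$norm_pos[1], 0)
  expect_equal(m$norm_pos[2], 1)           # at the farthest tip
  expect_equal(m$node_id[3], 2)            # nearest node wins
  expect_false(m$mapped[4])                # beyond the snap radius
  expect_true(all(m$mapped[1:3]))
  expect_equal(as.character(m$region[1:2]), c("base", "tip"))
})

test_that("path distances agree with a breadth-first tree oracle", {
  skel <- random_tree_skeleton(40, seed = 7)
  pd <- skeleton_path_dist(skel)
  # oracle: accumulate parent-edge lengths by walking each node to the root
  oracle <- vapply(seq_len(nrow(skel)), function(i) {
    d <- 0
    while (skel$parent_id[i] != -1) {
      j <- match(skel$parent_id[i], skel$node_id)
      d <- d + sqrt((skel$x[i] - skel$x[j])^2 + (skel$y[i] - skel$y[j])^2 +
                      (skel$z[i] - skel$z[j])^2)
      i <- j
    }
    d
  }, numeric(1))
  expect_equal(pd, oracle, tolerance = 1e-12)
})

test_that("dendritic regions partition [0,1] into base, shaft and tip tertiles", {
  expect_equal(as.character(region_of(c(0, 0.5, 1))),
               c("base", "shaft", "tip"))
  expect_equal(as.character(region_of(c(1 / 3, 2 / 3))), c("shaft", "tip"))
  grid <- seq(0, 1, by = 0.01)
  r <- region_of(grid)
  expect_false(anyNA(r))                       # no gaps
  expect_true(all(diff(as.integer(r)) >= 0))   # no overlaps, ordered
  expect_error(region_of(1.2), "outside")
})

test_that("the segregation index and its permutation null behave at the extremes", {
  same <- segregation_from_positions(rep(c(0.2, 0.5, 0.8), 4),
                                     rep(c(0.2, 0.5, 0.8), 4), seed = 1)
  expect_equal(same$index, 0)
  expect_gt(same$p_value, 0.9)

  sep <- segregation_from_positions(rep(0, 10), rep(1, 10),
                                    n_perm = 2000, seed = 1)
  expect_equal(sep$index, 1)
  expect_lt(sep$p_value, 0.01)

  expect_error(segregation_from_positions(c(0, 1), rep(0.5, 5)), ">= 3")
})

test_that("base- and tip-biased synthetic profiles segregate on T4 dendrites", {
  ds <- make_circuit(seed = 51)
  s <- segregation(ds, "T4a:0,0", "Mi4", "Mi9", n_perm = 1000, seed = 52)
  expect_gt(s$index, 0.2)    # Mi9 is distal to Mi4
  expect_lt(s$p_value, 0.01)
  # reproducible for a fixed seed
  s2 <- segregation(ds, "T4a:0,0", "Mi4", "Mi9", n_perm = 1000, seed = 52)
  expect_identical(s$p_value, s2$p_value)
})

test_that("dendrite orientation classifies subtypes with a deterministic tie-break", {
  skel <- make_t4("a", seed = 61)
  expect_equal(subtype_of(dendrite_orientation(skel)), "a")

  # rotating the arbor 90 degrees CCW turns subtype a into subtype c
  rot <- skel
  root <- skel[skel$parent_id == -1, ]
  dx <- skel$x - root$x; dy <- skel$y - root$y
  rot$x <- root$x - dy
  rot$y <- root$y + dx
  expect_equal(subtype_of(dendrite_orientation(rot)), "c")

  # sector boundaries resolve towards the earlier subtype letter
  expect_equal(subtype_of(pi / 4), "a")       # a/c boundary
  expect_equal(subtype_of(3 * pi / 4), "b")   # b/c boundary
  expect_equal(subtype_of(5 * pi / 4), "b")   # b/d boundary

  few <- skeleton(data.frame(node_id = 1:2, parent_id = c(-1, 1),
                             x = c(0, 1), y = 0, z = 0, radius = 1))
  expect_error(dendrite_orientation(few), ">= 5 nodes")

  # a balanced star arbor has no orientation
  star <- skeleton(data.frame(node_id = 1:5, parent_id = c(-1, 1, 1, 1, 1),
                              x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1),
                              z = 0, radius = 1))
  expect_error(dendrite_orientation(star), "degenerate")
})

test_that("T4-T4 contacts are same-subtype and displaced opposite the PD", {
  ds <- make_circuit(seed = 53)
  rep <- t4_selectivity_report(ds)
  expect_gt(rep$n_connections, 0)
  expect_equal(rep$n_violations, 0)
  expect_true(all(rep$connections$dot_pd <= 0))

  # planting one cross-subtype edge yields exactly one violation
  bad <- ds
  extra <- data.frame(pre_id = "T4a:1,0", post_id = "T4b:0,0",
                      tbar_id = "tb:planted", x = 0, y = 0, z = 35)
  sy <- rbind(as.data.frame(bad$synapses), extra)
  bad$synapses <- synapse_table(sy$pre_id, sy$post_id, sy$tbar_id,
                                sy$x, sy$y, sy$z)
  rep2 <- t4_selectivity_report(bad)
  expect_equal(rep2$n_violations, 1)
  expect_equal(rep2$n_connections, rep$n_connections + 1)
})
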