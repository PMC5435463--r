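test_that("generated T4 arbors grow along the subtype axis with elongated span", {
  for (s in c("a", "b", "c", "d")) {
    skel <- make_t4(s, c(0L, 0L), seed = 21)
    axis <- arbor_axis_angle(s)
    ang <- dendrite_orientation(skel)
    # mean displacement within 45 degrees of the subtype's cardinal axis
    expect_true(cos(ang - axis) > cos(pi / 4))
    expect_equal(subtype_of(ang), s)

    # span along the preferred axis exceeds the orthogonal span by > 1.5x
    root <- skel[skel$parent_id == -1, ]
    dx <- skel$x - root$x; dy <- skel$y - root$y
    u <- c(cos(axis), sin(axis))
    along <- dx * u[1] + dy * u[2]
    ortho <- -dx * u[2] + dy * u[1]
    expect_gt(diff(range(along)) / diff(range(ortho)), 1.5)

    # spans roughly 2-3 column spacings (8 um each)
    expect_gt(max(along), 1.8 * 8)
    expect_lt(max(along), 3.2 * 8)
  }

  # subtype c is subtype a rotated by 90 degrees (same seed geometry)
  a <- make_t4("a", seed = 9); cc <- make_t4("c", seed = 9)
  expect_equal((dendrite_orientation(cc) - dendrite_orientation(a)) %% (2 * pi),
               pi / 2, tolerance = 1e-9)
})

test_that("circuit generation is byte-identical for a fixed seed", {
  a <- make_circuit(seed = 4)
  b <- make_circuit(seed = 4)
  expect_identical(as.data.frame(a$synapses), as.data.frame(b$synapses))
  expect_identical(as.data.frame(a$neurons), as.data.frame(b$neurons))
  expect_identical(a$ground_truth$tm3_mi1, b$ground_truth$tm3_mi1)
  d <- make_circuit(seed = 5)
  expect_false(identical(as.data.frame(a$synapses), as.data.frame(d$synapses)))
})

test_that("a single-type template with all weight on Home uses only the Home cell", {
  tpl <- circuit_template(
    fractions = c(Mi1 = 1, Tm3 = 0, Mi9 = 0, Mi4 = 0, C3 = 0, TmY15 = 0,
                  CT1 = 0, T4 = 0, Mi10 = 0, unknown = 0),
    weight_maps = list(Mi1 = data.frame(dq = 0L, dr = 0L, w = 1)))
  ds <- make_circuit(tpl, make_lattice(1), seed = 2)
  onto_t4 <- ds$synapses[ds$synapses$post_id == "T4a:0,0", ]
  expect_true(all(onto_t4$pre_id == "Mi1:0,0"))
  expect_equal(nrow(onto_t4), tpl$n_inputs_per_t4)
})

test_that("weight maps referencing columns outside the lattice are rejected", {
  tpl <- circuit_template(
    weight_maps = list(Mi1 = data.frame(dq = 5L, dr = 0L, w = 1)))
  expect_error(make_circuit(tpl, make_lattice(1), seed = 1),
               "outside the lattice")
})

test_that("realized input fractions track the template within multinomial error", {
  tpl <- circuit_template()
  ds <- make_circuit(tpl, seed = 6)
  n <- tpl$n_inputs_per_t4
  for (t4 in c("T4a:0,0", "T4c:0,0")) {
    fr <- input_fractions(ds, t4)
    for (ty in c("Mi1", "Tm3", "Mi9", "Mi4", "CT1")) {
      p <- tpl$fractions[[ty]]
      se <- sqrt(p * (1 - p) / n)
      expect_close(fr[[ty]], p, 3 * se)
    }
  }
})

test_that("realized fractions converge to the template at large n", {
  tpl <- circuit_template(n_inputs_per_t4 = 10000L)
  ds <- make_circuit(tpl, seed = 8)
  fr <- input_fractions(ds, "T4b:0,0")
  for (ty in c("Mi1", "Tm3", "Mi9")) {
    expect_close(fr[[ty]], tpl$fractions[[ty]], 0.02)
  }
})

test_that("polyadic grouping yields the expected PSD:T-bar ratio", {
  ds <- make_circuit(seed = 10)
  sy <- ds$synapses
  ratio <- nrow(sy) / length(unique(sy$tbar_id))
  # 1 + Poisson(5) PSDs per T-bar, within sampling slack
  expect_gt(ratio, 4.5)
  expect_lt(ratio, 7.5)
  expect_true(length(unique(sy$tbar_id)) <= nrow(sy))
})

test_that("truncation at the full volume bounds is the identity with completeness 1", {
  ds <- make_circuit(seed = 12)
  tr <- truncate_connectome(ds, ds$volume_bounds)
  expect_equal(nrow(tr$synapses), nrow(ds$synapses))
  touched <- !is.na(tr$neurons$completeness)
  expect_true(all(tr$neurons$completeness[touched] == 1))
})

test_that("volume truncation removes exactly the outside synapses and never increases counts", {
  ds <- make_circuit(template = circuit_template(), lattice = make_lattice(2),
                     seed = 13)
  b <- ds$volume_bounds
  cut1 <- b; cut1["xmax"] <- 0.6 * b["xmax"]
  cut2 <- b; cut2["xmax"] <- 0.3 * b["xmax"]
  t1 <- truncate_connectome(ds, cut1)
  t2 <- truncate_connectome(t1, cut2)
  expect_true(all(t1$synapses$x <= cut1["xmax"]))
  expect_equal(nrow(t1$synapses), sum(ds$synapses$x <= cut1["xmax"]))
  expect_lte(nrow(t2$synapses), nrow(t1$synapses))
  # completeness is monotone non-increasing as the box shrinks
  c1 <- t1$neurons$completeness; c2 <- t2$neurons$completeness
  ok <- !is.na(c1) & !is.na(c2)
  expect_true(all(c2[ok] <= c1[ok] + 1e-12))
  expect_error(truncate_connectome(ds, c(xmin = 1e5, xmax = 2e5,
                                         ymin = 0, ymax = 1, zmin = 0,
                                         zmax = 1)),
               "does not intersect")
})

test_that("an edge-shaving box yields a graded Tm3 completeness ladder", {
  ds <- make_circuit(lattice = make_lattice(2), seed = 14)
  b <- ds$volume_bounds
  cut <- b; cut["xmax"] <- 6   # shave columns beyond ~0.75 ommatidia
  tr <- truncate_connectome(ds, cut)
  tm3 <- tr$neurons[tr$neurons$cell_type == "Tm3", ]
  comp <- tm3$completeness[!is.na(tm3$completeness)]
  expect_gt(max(comp), 0.95)   # central cells fully retained
  expect_lt(min(comp), 0.6)    # edge cells heavily truncated
})

test_that("uniform per-cell thinning records realized completeness near targets", {
  ds <- make_circuit(seed = 15)
  ids <- ds$ground_truth$tm3_owner$id[ds$ground_truth$tm3_owner$owner == "T4b:0,0"]
  targets <- setNames(seq(0.4, 1, length.out = length(ids)), ids)
  th <- thin_cell_synapses(ds, targets, seed = 99)
  got <- th$neurons$completeness[match(ids, th$neurons$id)]
  expect_close(got, unname(targets), 0.25)
  expect_lte(nrow(th$synapses), nrow(ds$synapses))
  # untouched cells keep completeness 1
  mi1 <- th$neurons$completeness[th$neurons$cell_type == "Mi1"]
  expect_true(all(mi1 == 1, na.rm = TRUE))
  expect_error(thin_cell_synapses(ds, c(ghost = 0.5)), "unknown cell id")
})

test_that("the partial-Tm3 ladder is least complete at the arbor's leading edge", {
  ds <- make_circuit(seed = 16)
  th <- emulate_partial_tm3(ds, "T4a:0,0", seed = 17)
  gt <- ds$ground_truth
  ids <- gt$tm3_owner$id[gt$tm3_owner$owner == "T4a:0,0"]
  comp <- th$neurons$completeness[match(ids, th$neurons$id)]
  proj <- gt$cells$true_x[match(ids, gt$cells$id)]  # T4a arbor axis = +x
  expect_lt(cor(comp, proj), 0)
  expect_gt(max(comp), 0.85)
  expect_lt(min(comp), 0.6)
})
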