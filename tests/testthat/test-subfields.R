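test_that("subfield centres follow the weighted-centroid definition", {
  fx <- fixture_connectome(list(Mi1 = data.frame(q = 0, r = 0, n = 12)))
  sf <- subfield_centre(fx, "T4a:0,0", "Mi1")
  expect_equal(sf$centre, c(x = 0, y = 0))
  expect_equal(sf$n_synapses, 12)

  fx2 <- fixture_connectome(list(Mi4 = data.frame(q = c(1, -1), r = 0,
                                                  n = c(4, 4))))
  expect_equal(subfield_centre(fx2, "T4a:0,0", "Mi4")$centre, c(x = 0, y = 0))

  fx3 <- fixture_connectome(list(Mi9 = data.frame(q = c(0, 1), r = 0,
                                                  n = c(30, 10))))
  expect_equal(subfield_centre(fx3, "T4a:0,0", "Mi9")$centre,
               c(x = 0.25, y = 0))

  expect_error(subfield_centre(fx, "T4a:0,0", "Mi9"), "no inputs")
  expect_error(subfield_centre(fx, "T4a:0,0", "Tm3"), "cannot be assigned")
})

test_that("subfield centres equal the brute-force per-synapse centroid", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(1:7, 1)
    cols <- make_lattice(2)[sample(19, k), ]
    n <- sample(1:25, k, replace = TRUE)
    fx <- fixture_connectome(list(Mi1 = data.frame(q = cols$q, r = cols$r,
                                                   n = n)))
    sf <- subfield_centre(fx, "T4a:0,0", "Mi1")
    xy <- axial_to_cart(rep(cols$q, n), rep(cols$r, n))  # unit-mass oracle
    expect_close(sf$centre, c(mean(xy[, "x"]), mean(xy[, "y"])), 1e-12)
  }
})

test_that("offsets referenced to Mi1 are identities and constructed displacements", {
  fx <- fixture_connectome(list(
    Mi1 = data.frame(q = 0, r = 0, n = 20),
    Mi4 = data.frame(q = c(-1, 0), r = 0, n = c(10, 10))))
  self <- offset_from_mi1(fx, "T4a:0,0", "Mi1")
  expect_equal(c(self$dx, self$dy), c(0, 0))
  off <- offset_from_mi1(fx, "T4a:0,0", "Mi4")
  expect_equal(c(off$dx, off$dy), c(-0.5, 0))
  expect_equal(off$mode, "raw")
})

test_that("planted Mi9-Mi1 offsets are recovered from synthetic circuits", {
  errs <- vapply(1:8, function(s) {
    ds <- make_circuit(offset_recovery_template(0.5, n = 500L),
                       make_lattice(2), seed = s)
    off <- offset_from_mi1(ds, "T4a:0,0", "Mi9")
    sqrt((off$dx - 0.5)^2 + off$dy^2)
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})

test_that("L1-based field centres locate cells on the lattice", {
  fx <- fixture_connectome(list(L1 = data.frame(q = 0, r = 0, n = 1)),
                           post_type = "T4a")
  expect_equal(l1_field_centre(fx, "T4a:0,0"), c(x = 0, y = 0))

  fx2 <- fixture_connectome(list(L1 = data.frame(q = c(0, 1), r = 0,
                                                 n = c(3, 1))))
  expect_equal(l1_field_centre(fx2, "T4a:0,0"), c(x = 0.25, y = 0))

  # synthetic Mi1: L1-based centre lands near its home column
  ds <- make_circuit(seed = 42)
  truth <- ds$ground_truth$cells
  for (id in c("Mi1:0,0", "Mi1:1,0", "Mi1:0,-1")) {
    cen <- l1_field_centre(ds, id)
    tr <- truth[truth$id == id, ]
    expect_lt(sqrt((cen["x"] - tr$true_x)^2 + (cen["y"] - tr$true_y)^2), 0.2)
  }
  expect_error(l1_field_centre(ds, "TmY15:1"), "no L1 input")
})

test_that("raw and adjusted Tm3-Mi1 offsets coincide at completeness one", {
  ds <- make_circuit(seed = 43)
  raw <- tm3_mi1_offset(ds, "T4c:0,0", "raw")
  adj <- tm3_mi1_offset(ds, "T4c:0,0", "adjusted")
  expect_equal(c(raw$dx, raw$dy), c(adj$dx, adj$dy), tolerance = 1e-12)
  expect_equal(raw$mode, "raw")
  expect_equal(adj$mode, "adjusted")
})

test_that("an untruncated circuit with near-zero planted Tm3 offset measures near zero", {
  ds <- make_circuit(seed = 44)
  gt <- ds$ground_truth$tm3_mi1
  errs <- vapply(gt$t4_id, function(t4) {
    tr <- gt[gt$t4_id == t4, ]
    expect_lt(sqrt(tr$dx^2 + tr$dy^2), 0.1)  # planted offset is ~zero
    off <- tm3_mi1_offset(ds, t4, "raw")
    sqrt((off$dx - tr$dx)^2 + (off$dy - tr$dy)^2)
  }, numeric(1))
  # sampling noise at the default synapse budget keeps estimates near truth
  expect_lt(mean(errs), 0.15)
  expect_lt(max(errs), 0.3)
})

test_that("adjusted mode demands completeness and reweights by its inverse", {
  ds <- make_circuit(seed = 45)
  th <- emulate_partial_tm3(ds, "T4a:0,0", seed = 46)
  miss <- th
  i <- which(miss$neurons$id == miss$neurons$id[
    miss$neurons$cell_type == "Tm3"][1])
  miss$neurons$completeness[i] <- NA
  expect_error(tm3_mi1_offset(miss, "T4a:0,0", "adjusted"),
               "completeness")
  adj <- tm3_mi1_offset(th, "T4a:0,0", "adjusted")
  expect_equal(adj$tm3$weight, adj$tm3$n_psd / adj$tm3$completeness)
})

test_that("offset alignment is the cosine against the preferred direction", {
  off <- list(dx = 1, dy = 0)
  expect_equal(offset_alignment(off, 0), 1)
  expect_equal(offset_alignment(off, pi), -1)
  expect_equal(offset_alignment(off, pi / 2), 0)
  expect_true(is.nan(offset_alignment(list(dx = 0, dy = 0), 0)))
})

test_that("the subfield report covers every computable (T4, type) pair", {
  ds <- make_circuit(seed = 47)
  rep <- subfield_report(ds, min_synapses = 2)
  expect_true(all(c("t4_id", "pre_type", "dx", "dy", "n_synapses") %in%
                    names(rep)))
  expect_equal(sort(unique(rep$t4_id)), sort(names(ds$skeletons)))
  # Mi1 rows are the self-referenced origin
  mi1 <- rep[rep$pre_type == "Mi1", ]
  expect_true(all(abs(mi1$dx) < 1e-12 & abs(mi1$dy) < 1e-12))
})
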