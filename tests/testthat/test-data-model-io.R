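test_that("synapse tables round-trip through TSV with exact numerics", {
  path <- withr::local_tempfile(fileext = ".tsv")

  # empty table is a valid dataset
  write_synapse_table(empty <- synapse_table(character(), character(),
                                             character(), numeric(),
                                             numeric(), numeric()), path)
  expect_equal(nrow(read_synapse_table(path)), 0)

  syn <- synapse_table(pre_id = c("a", "b", "b"), post_id = rep("t", 3),
                       tbar_id = c("tb1", "tb2", "tb2"),
                       x = c(0.1, 2, 3), y = c(1, 2, 3), z = c(0, 0, 1))
  write_synapse_table(syn, path)
  back <- read_synapse_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(length(unique(back$tbar_id)), 2)  # polyadic ids preserved
  expect_equal(as.data.frame(back), as.data.frame(syn))

  # 1000-row synthetic table: numeric fields identical after write-read
  set.seed(11)
  big <- synapse_table(sprintf("pre%d", 1:1000), "post",
                       sprintf("tb%d", sample(300, 1000, TRUE)),
                       rnorm(1000) * 40, rnorm(1000) * 40, runif(1000, 0, 80))
  write_synapse_table(big, path, header = "seed=11")
  back <- read_synapse_table(big_path <- path)
  expect_identical(back$x, big$x)
  expect_identical(back$y, big$y)
  expect_identical(back$z, big$z)
})

test_that("malformed synapse tables are reported with locations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pre_id\tpost_id\ttbar_id\tx\ty", "a\tb\ttb\t1\t2"), path)
  expect_error(read_synapse_table(path), "missing column.*z")

  writeLines(c("pre_id\tpost_id\ttbar_id\tx\ty\tz",
               "a\tb\ttb\t1\t2\t3",
               "a\tb\ttb\toops\t2\t3"), path)
  expect_error(read_synapse_table(path), "row.* 2")
})

test_that("autapses are rejected by default and kept only on request", {
  expect_error(synapse_table("a", "a", "tb", 0, 0, 0), "autaptic")
  ok <- synapse_table("a", "a", "tb", 0, 0, 0, allow_autapse = TRUE)
  expect_equal(nrow(ok), 1)
})

test_that("neuron tables enforce types and round-trip through TSV", {
  expect_error(neuron_table("a", "NotAType"), "unknown cell_type")
  expect_error(neuron_table(c("a", "a"), c("Mi1", "Mi1")), "duplicated")
  nr <- neuron_table(c("m", "t"), c("Mi1", "Tm3"),
                     home_q = c(0L, NA), home_r = c(0L, NA),
                     completeness = c(1, 0.6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_neuron_table(nr, path)
  expect_equal(as.data.frame(read_neuron_table(path)), as.data.frame(nr))
})

test_that("SWC skeletons obey the rooted-tree contract", {
  path <- withr::local_tempfile(fileext = ".swc")

  # single node
  one <- skeleton(data.frame(node_id = 1, parent_id = -1,
                             x = 1, y = 2, z = 3, radius = 0.5))
  write_swc(one, path)
  back <- read_swc(path)
  expect_equal(nrow(back), 1)
  expect_equal(c(back$x, back$y, back$z), c(1, 2, 3))
  expect_equal(skeleton_cable_length(back), 0)

  # 3-node chain: path length is the sum of the two edges
  chain <- skeleton(data.frame(node_id = 1:3, parent_id = c(-1, 1, 2),
                               x = c(0, 3, 3), y = c(0, 0, 4), z = 0,
                               radius = 0.1))
  expect_equal(skeleton_path_dist(chain), c(0, 3, 7))
  expect_equal(skeleton_cable_length(chain), 7)

  # seeded random tree round-trips with identical topology and coordinates
  tree <- random_tree_skeleton(50, seed = 3)
  write_swc(tree, path, header = "fixture")
  back <- read_swc(path)
  expect_equal(back$node_id, tree$node_id)
  expect_equal(back$parent_id, tree$parent_id)
  expect_equal(back$x, tree$x, tolerance = 1e-12)
  expect_equal(skeleton_path_dist(back), skeleton_path_dist(tree),
               tolerance = 1e-12)
})

test_that("cyclic or multi-root skeletons are structure errors", {
  expect_error(skeleton(data.frame(node_id = 1:2, parent_id = c(-1, -1),
                                   x = 0, y = 0, z = 0, radius = 1)),
               "2 roots")
  expect_error(skeleton(data.frame(node_id = 1:3, parent_id = c(-1, 3, 2),
                                   x = 0, y = 0, z = 0, radius = 1)),
               "cycle|unreachable")
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1"), path)  # 6 fields
  expect_error(read_swc(path), "malformed")
})

test_that("dataset validation reports findings instead of raising", {
  ds <- make_circuit(seed = 5)
  expect_equal(nrow(validate_connectome(ds)), 0)

  # dangling synapse reference
  bad <- ds
  bad$synapses$pre_id[1] <- "ghost"
  rep <- validate_connectome(bad)
  expect_equal(sum(rep$finding == "dangling_reference"), 1)
  expect_true("ghost" %in% rep$id)

  # a multicolumnar Tm3 must not carry a home column
  bad2 <- ds
  i <- which(bad2$neurons$cell_type == "Tm3")[1]
  bad2$neurons$home_q[i] <- 0L
  bad2$neurons$home_r[i] <- 0L
  rep2 <- validate_connectome(bad2)
  expect_equal(sum(rep2$finding == "multicolumnar_home_column"), 1)

  # out-of-bounds synapse location
  bad3 <- ds
  bad3$synapses$x[1] <- 1e6
  expect_equal(sum(validate_connectome(bad3)$finding == "out_of_bounds"), 1)
})
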