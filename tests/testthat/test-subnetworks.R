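test_that("neighborhood is the BFS ball around the root", {
  net <- toy_net(c("A", "B", 0.9), c("B", "C", 0.9), c("C", "D", 0.9))
  expect_setequal(igraph::V(neighborhood(net, "A", 2))$name, c("A", "B", "C"))
  expect_setequal(igraph::V(neighborhood(net, "A", 10))$name,
                  c("A", "B", "C", "D"))
  net2 <- toy_net(c("A", "B", 0.9), c("C", "D", 0.9))
  expect_equal(igraph::V(neighborhood(net2, "A", 3))$name, c("A", "B"))
  expect_error(neighborhood(net, "Z", 2), "not in network")
})

test_that("a single root-leaf edge at depth 1 gives a two-node tree with no intermediates", {
  net <- toy_net(c("R", "L", 0.95), c("R", "X", 0.5))
  sn <- build_subnetwork(net, "R", "L", builder_config(depth = 1))
  expect_equal(sort(names(sn$roles)), c("L", "R"))
  expect_equal(unname(sn$roles[c("R", "L")]), c("root", "leaf"))
  expect_equal(sum(sn$roles == "intermediate"), 0L)
  expect_false(sn$degenerate)
})

test_that("roots with no reachable leaf yield a flagged degenerate sub-network", {
  net <- toy_net(c("R", "A", 0.9), c("X", "L", 0.9))
  sn <- build_subnetwork(net, "R", "L", builder_config(depth = 5))
  expect_true(sn$degenerate)
  expect_equal(names(sn$roles), "R")
  expect_equal(sn$unreachable_leaves, "L")
})

test_that("unreachable leaves are reported, not silently dropped", {
  net <- toy_net(c("R", "A", 0.9), c("A", "L1", 0.9), c("X", "L2", 0.9))
  sn <- build_subnetwork(net, "R", c("L1", "L2"), builder_config(depth = 5))
  expect_equal(sn$collected, "L1")
  expect_equal(sn$unreachable_leaves, "L2")
})

test_that("planted roots collect their planted leaves within the depth limit", {
  sim <- generate_synthetic_data(synth_config(seed = 42))
  cfg <- builder_config(seed = 42)
  for (t in sim$truth$targets[1:3]) {
    sn <- build_subnetwork(sim$network, t, sim$leaves, cfg)
    expect_true(all(sim$truth$leaves_by_target[[t]] %in% sn$collected))
    # depth invariant inside the tree
    hops <- igraph::distances(sn$tree, v = t, weights = NA)[1, ]
    expect_lte(max(hops), cfg$depth)
    # partition is exhaustive and disjoint
    expect_setequal(names(sn$roles), igraph::V(sn$tree)$name)
    expect_equal(sum(sn$roles == "root"), 1L)
  }
})

test_that("selected edges have higher median confidence than the network at large", {
  sim <- generate_synthetic_data(synth_config(seed = 11))
  cfg <- builder_config(seed = 11)
  sn <- build_cohort(sim$network, sim$truth$targets, sim$leaves, cfg)
  sel <- unlist(lapply(sn, function(s) igraph::E(s$tree)$confidence))
  expect_gt(stats::median(sel), stats::median(igraph::E(sim$network)$confidence))
})

test_that("control cohorts are reproducible and drawn from the right universes", {
  sim <- generate_synthetic_data(synth_config(seed = 5))
  net <- sim$network
  r1 <- sample_control_roots(net, sim$leaves, sim$kinases, "R", 16, seed = 9,
                             exclude = sim$truth$targets)
  r2 <- sample_control_roots(net, sim$leaves, sim$kinases, "R", 16, seed = 9,
                             exclude = sim$truth$targets)
  expect_identical(r1, r2)
  expect_length(unique(r1), 16L)
  expect_length(intersect(r1, c(sim$leaves, sim$truth$targets)), 0L)

  l <- sample_control_roots(net, sim$leaves, sim$kinases, "L",
                            length(sim$leaves), seed = 3)
  expect_setequal(l, sim$leaves)  # exhausting the universe returns all of it

  k <- sample_control_roots(net, sim$leaves, sim$kinases, "K", 19, seed = 4)
  expect_true(all(k %in% sim$kinases))
  expect_error(
    sample_control_roots(net, sim$leaves, c("NOPE1", "NOPE2"), "K", 2, seed = 1),
    "universe"
  )
  expect_error(
    sample_control_roots(net, sim$leaves, sim$kinases, "L",
                         length(sim$leaves) + 1, seed = 1),
    "fewer than"
  )
})

test_that("sub-network export writes a node table with roles and depths", {
  net <- toy_net(c("R", "A", 0.9), c("A", "L", 0.9))
  sn <- build_subnetwork(net, "R", "L", builder_config(depth = 3))
  prefix <- file.path(withr::local_tempdir(), "subnet")
  write_subnetwork(sn, prefix)
  tab <- read.delim(paste0(prefix, "_nodes.tsv"))
  expect_setequal(tab$role, c("root", "intermediate", "leaf"))
  expect_equal(tab$depth[tab$node == "L"], 2)
})
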