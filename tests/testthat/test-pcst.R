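# instance: triangle with a cheap two-hop route to the prized leaf
triangle_instance <- function(prize = 1) {
  net <- toy_net(c("R", "A", 0.9), c("A", "L", 0.9), c("R", "L", 0.5))
  pcst_instance(net, "R", c(L = prize))
}

test_that("objective sums edge costs and forfeited prizes", {
  inst <- triangle_instance(prize = 1)
  root_only <- igraph::induced_subgraph(inst$graph, "R")
  expect_equal(pcst_objective(inst, root_only), 1)  # prize forfeited
  chain <- igraph::subgraph_from_edges(
    inst$graph, igraph::get_edge_ids(inst$graph, c("R", "A", "A", "L"))
  )
  expect_equal(pcst_objective(inst, chain), 0.2)
  no_prize <- pcst_instance(inst$graph, "R")
  expect_equal(pcst_objective(no_prize, root_only), 0)
})

test_that("objective rejects invalid trees", {
  inst <- triangle_instance()
  not_root <- igraph::induced_subgraph(inst$graph, c("A", "L"))
  expect_error(pcst_objective(inst, not_root), "root")
  cycle <- inst$graph  # full triangle
  expect_error(pcst_objective(inst, cycle), "cycle")
})

test_that("exact solver matches hand-derived optima", {
  sol <- pcst_solve_exact(triangle_instance(prize = 1))
  expect_equal(sol$objective, 0.2)
  expect_setequal(sol$nodes, c("R", "A", "L"))
  expect_equal(sol$collected, "L")

  # forfeit beats connecting: prize 0.15 < edge cost 0.2
  net <- toy_net(c("R", "L", 0.8))
  sol2 <- pcst_solve_exact(pcst_instance(net, "R", c(L = 0.15)))
  expect_equal(sol2$objective, 0.15)
  expect_equal(sol2$nodes, "R")

  # unreachable prized node can never be collected
  net3 <- toy_net(c("R", "A", 0.9), c("X", "L", 0.9))
  sol3 <- pcst_solve_exact(pcst_instance(net3, "R", c(L = 5)))
  expect_equal(sol3$objective, 5)
  expect_false("L" %in% sol3$nodes)

  expect_error(pcst_solve_exact(random_instance(14, seed = 1)), "heuristic")
})

test_that("exact solver agrees with an independent igraph-based enumeration", {
  for (s in 1:25) {
    inst <- random_instance(sample(4:8, 1), seed = s)
    expect_equal(pcst_solve_exact(inst)$objective,
                 oracle_pcst_objective(inst), tolerance = 1e-9)
  }
})

test_that("solutions are always valid rooted trees", {
  for (s in 1:20) {
    inst <- random_instance(sample(5:10, 1), seed = 100 + s)
    for (sol in list(pcst_solve_exact(inst), pcst_solve_heuristic(inst))) {
      expect_true(inst$root %in% sol$nodes)
      if (length(sol$nodes) > 1) {
        expect_true(igraph::is_connected(sol$tree))
        expect_equal(igraph::ecount(sol$tree), igraph::vcount(sol$tree) - 1L)
      }
      expect_equal(sol$objective, pcst_objective(inst, sol$tree))
    }
  }
})

test_that("heuristic is bounded by the exact optimum and sensible on easy cases", {
  for (s in 1:40) {
    inst <- random_instance(sample(5:10, 1), seed = 200 + s)
    exact <- pcst_solve_exact(inst)$objective
    heur <- pcst_solve_heuristic(inst)$objective
    expect_gte(heur, exact - 1e-9)
    expect_lte(heur, 2 * exact + 1e-9)
  }
  # prizes all zero: nothing worth connecting
  inst0 <- pcst_instance(random_ppi(8, seed = 7), "N01", c(N02 = 0))
  sol0 <- pcst_solve_heuristic(inst0)
  expect_equal(sol0$nodes, "N01")
  expect_equal(sol0$objective, 0)
  # input already a tree, prizes exceed path costs: tree restricted to
  # root-leaf paths is returned
  net <- toy_net(c("R", "A", 0.9), c("A", "L1", 0.9), c("A", "L2", 0.9),
                 c("R", "B", 0.9))
  sol <- pcst_solve_heuristic(pcst_instance(net, "R", c(L1 = 5, L2 = 5)))
  expect_setequal(sol$nodes, c("R", "A", "L1", "L2"))  # dangling B dropped
  expect_equal(sol$objective, 0.3, tolerance = 1e-9)
})

test_that("with saturating prizes the exact solution collects every reachable prized node", {
  for (s in 1:10) {
    inst <- random_instance(sample(5:8, 1), seed = 300 + s, prize_scale = 1)
    total_cost <- sum(igraph::E(inst$graph)$cost)
    big <- pcst_instance(inst$graph, inst$root,
                         stats::setNames(rep(total_cost + 1,
                                             length(inst$prizes)),
                                         names(inst$prizes)))
    sol <- pcst_solve_exact(big)
    comp <- igraph::components(inst$graph)
    reachable <- names(which(comp$membership ==
                               comp$membership[inst$root]))
    expect_setequal(sol$collected,
                    intersect(names(big$prizes), reachable))
  }
})

test_that("decreasing a single edge cost never increases the exact optimum", {
  for (s in 1:15) {
    inst <- random_instance(sample(5:8, 1), seed = 400 + s)
    before <- pcst_solve_exact(inst)$objective
    g2 <- inst$graph
    e <- withr::with_seed(s, sample(igraph::ecount(g2), 1))
    igraph::E(g2)$cost[e] <- igraph::E(g2)$cost[e] / 2
    igraph::E(g2)$confidence[e] <- 1 - igraph::E(g2)$cost[e]
    after <- pcst_solve_exact(pcst_instance(g2, inst$root, inst$prizes))$objective
    expect_lte(after, before + 1e-9)
  }
})

test_that("heuristic hop limit bounds the tree depth", {
  net <- toy_net(c("R", "A", 0.99), c("A", "B", 0.99), c("B", "L", 0.99),
                 c("R", "L", 0.5))
  inst <- pcst_instance(net, "R", c(L = 10))
  free <- pcst_solve_heuristic(inst)
  expect_equal(igraph::ecount(free$tree), 3L)  # cheap 3-hop route
  capped <- pcst_solve_heuristic(inst, max_hops = 1)
  expect_equal(igraph::ecount(capped$tree), 1L)  # forced direct edge
  expect_equal(capped$objective, 0.5, tolerance = 1e-9)
})
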