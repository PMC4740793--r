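# Shared fixtures and independent oracles for the test suite.

# build a ppi_network from a compact edge specification
toy_net <- function(...) {
  spec <- list(...)
  ppi_network(data.frame(
    from = vapply(spec, `[[`, "", 1),
    to = vapply(spec, `[[`, "", 2),
    confidence = vapply(spec, function(e) as.numeric(e[[3]]), 1),
    stringsAsFactors = FALSE
  ))
}

# random connected-ish PPI on n nodes: G(n, p) plus a random spanning tree
# so the root can reach most nodes
random_ppi <- function(n, p = 0.35, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    perm <- sample(nodes)
    spine <- cbind(perm[-n], perm[-1])
    el <- rbind(pairs[keep, , drop = FALSE], spine)
    ppi_network(data.frame(
      from = el[, 1], to = el[, 2],
      confidence = stats::runif(nrow(el), 0.05, 0.95),
      stringsAsFactors = FALSE
    ))
  })
}

# random PCST instance on a random graph
random_instance <- function(n, seed, prize_scale = 1) {
  g <- random_ppi(n, p = 0.3, seed = seed)
  withr::with_seed(seed + 1000L, {
    vn <- igraph::V(g)$name
    root <- sample(vn, 1)
    k <- sample(seq_len(max(1, n - 2)), 1)
    prized <- sample(setdiff(vn, root), k)
    prizes <- stats::setNames(stats::runif(k, 0, prize_scale), prized)
    pcst_instance(g, root, prizes)
  })
}

# independent exact PCST objective: enumerate root-containing node subsets
# with igraph machinery (components + mst), separate from the package's
# pure-R enumeration
oracle_pcst_objective <- function(instance) {
  g <- instance$graph
  vn <- igraph::V(g)$name
  others <- setdiff(vn, instance$root)
  p <- stats::setNames(numeric(length(vn)), vn)
  p[names(instance$prizes)] <- instance$prizes
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    S <- c(instance$root, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    sub <- igraph::induced_subgraph(g, S)
    if (igraph::components(sub)$no != 1L) next
    mst <- igraph::mst(sub, weights = igraph::E(sub)$cost)
    obj <- sum(igraph::E(mst)$cost) + sum(p[setdiff(vn, S)])
    if (obj < best) best <- obj
  }
  best
}

# random labelled tree on n nodes
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_tree(n, method = "prufer")
    igraph::V(g)$name <- sprintf("T%02d", sample(n))
    g
  })
}

# brute-force betweenness on a tree: count, for every unordered node pair,
# the interior nodes of the unique connecting path
oracle_tree_betweenness <- function(tree) {
  vn <- igraph::V(tree)$name
  n <- length(vn)
  b <- stats::setNames(numeric(n), vn)
  if (n >= 3) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        path <- igraph::shortest_paths(tree, vn[i], vn[j],
                                       weights = NA)$vpath[[1]]
        interior <- setdiff(names(path), c(vn[i], vn[j]))
        b[interior] <- b[interior] + 1
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# permutation two-sided p-value for a difference in means (Welch-style
# statistic), used as a Monte-Carlo oracle for welch_test
oracle_permutation_p <- function(x, y, n_perm = 4000, seed = 99) {
  stat <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) +
                                 stats::var(b) / length(b))
  }
  obs <- abs(stat(x, y))
  pool <- c(x, y)
  withr::with_seed(seed, {
    hits <- sum(replicate(n_perm, {
      idx <- sample(length(pool), length(x))
      abs(stat(pool[idx], pool[-idx])) >= obs
    }))
  })
  (hits + 1) / (n_perm + 1)
}
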