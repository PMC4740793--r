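#' Builder configuration for drug-modulation sub-networks
#'
#' @param depth maximum depth of the sub-network (hops from the root),
#'   default 5.
#' @param min_confidence minimum interaction confidence kept in the network.
#' @param lambda uniform leaf prize; `NULL` (default) sets it per root to
#'   twice the largest min-cost root-to-leaf path in the depth-limited
#'   neighborhood, so every reachable leaf is favored but expensive
#'   outliers can still be dropped.
#' @param leaf_weights optional named non-negative multipliers (e.g.
#'   differential-expression magnitudes); prize = lambda * weight.
#' @param n_R,n_L,n_K control cohort sizes (random roots, random leaf roots,
#'   random kinase roots), defaults 16, 20, 19.
#' @param seed integer seed governing control sampling.
#' @return A `builder_config` list.
#' @export
builder_config <- function(depth = 5L, min_confidence = 0, lambda = NULL,
                           leaf_weights = NULL,
                           n_R = 16L, n_L = 20L, n_K = 19L, seed = 1L) {
  stopifnot(depth >= 1, n_R >= 1, n_L >= 1, n_K >= 1)
  structure(list(depth = as.integer(depth), min_confidence = min_confidence,
                 lambda = lambda, leaf_weights = leaf_weights,
                 n_R = as.integer(n_R), n_L = as.integer(n_L),
                 n_K = as.integer(n_K), seed = as.integer(seed)),
            class = "builder_config")
}

#' Depth-limited neighborhood of a root node
#'
#' Induced subgraph on all nodes within `depth` unweighted hops of the
#' root.
#'
#' @param network a [ppi_network()].
#' @param root node name.
#' @param depth hop radius.
#' @return A `ppi_network` subgraph.
#' @export
neighborhood <- function(network, root, depth) {
  if (!root %in% igraph::V(network)$name) {
    stop("root '", root, "' not in network")
  }
  vs <- igraph::ego(network, order = depth, nodes = root)[[1]]
  sub <- igraph::induced_subgraph(network, vs)
  class(sub) <- unique(c("ppi_network", class(sub)))
  sub
}

#' Build the drug-modulation sub-network for one root
#'
#' The depth-limited neighborhood of the root becomes a PCST instance with
#' prizes on the reachable leaf genes; the heuristic solver (hop-limited to
#' `depth`) returns a tree whose nodes are partitioned into root, collected
#' leaves, and intermediate (cryptic) nodes. Leaves outside the
#' neighborhood are reported as unreachable, never silently dropped.
#'
#' @param network a [ppi_network()].
#' @param root node name (drug target).
#' @param leaves character vector of differentially expressed gene symbols.
#' @param config a [builder_config()].
#' @return A `drug_subnetwork`: list with `root`, `tree` (igraph), `roles`
#'   (named character: root/intermediate/leaf), `depth`, `lambda`,
#'   `collected`, `unreachable_leaves`, `degenerate`.
#' @export
build_subnetwork <- function(network, root, leaves, config = builder_config()) {
  if (length(leaves) == 0L) stop("leaves must be non-empty")
  nb <- neighborhood(network, root, config$depth)
  cand <- setdiff(intersect(leaves, igraph::V(nb)$name), root)
  dist0 <- hop_limited_distances(nb, root, config$depth)
  reachable <- cand[is.finite(dist0[cand])]
  if (length(reachable) == 0L) {
    tree <- igraph::induced_subgraph(network, root)
    class(tree) <- "igraph"
    return(structure(list(
      root = root, tree = tree,
      roles = stats::setNames("root", root),
      depth = config$depth, lambda = NA_real_,
      collected = character(0),
      unreachable_leaves = setdiff(leaves, root),
      degenerate = TRUE
    ), class = "drug_subnetwork"))
  }
  lambda <- config$lambda
  if (is.null(lambda)) lambda <- 2 * max(dist0[reachable])
  if (lambda <= 0) lambda <- 1  # all leaves adjacent at confidence 1
  w <- rep(1, length(reachable))
  if (!is.null(config$leaf_weights)) {
    hit <- reachable %in% names(config$leaf_weights)
    w[hit] <- config$leaf_weights[reachable[hit]]
  }
  inst <- pcst_instance(nb, root, stats::setNames(lambda * w, reachable))
  sol <- pcst_solve_heuristic(inst, max_hops = config$depth)
  nodes <- sol$nodes
  roles <- stats::setNames(rep("intermediate", length(nodes)), nodes)
  roles[sol$collected] <- "leaf"
  roles[root] <- "root"
  # depth invariant: every tree node within `depth` tree-hops of the root
  if (igraph::vcount(sol$tree) > 1) {
    hops <- igraph::distances(sol$tree, v = root, weights = NA)[1, ]
    stopifnot(all(hops <= config$depth))
  }
  structure(list(
    root = root, tree = sol$tree, roles = roles,
    depth = config$depth, lambda = lambda,
    collected = sol$collected,
    unreachable_leaves = setdiff(setdiff(leaves, root), reachable),
    degenerate = FALSE
  ), class = "drug_subnetwork")
}

#' @export
print.drug_subnetwork <- function(x, ...) {
  cat("Drug-modulation sub-network rooted at", x$root, "\n")
  cat("  nodes:", length(x$roles),
      "(", sum(x$roles == "intermediate"), "intermediate,",
      sum(x$roles == "leaf"), "leaves )\n")
  cat("  depth limit:", x$depth, "| lambda:", format(x$lambda),
      "| unreachable leaves:", length(x$unreachable_leaves), "\n")
  invisible(x)
}

# tree graph with role vertex attribute attached (for export)
subnetwork_graph <- function(subnet) {
  g <- subnet$tree
  igraph::V(g)$role <- unname(subnet$roles[igraph::V(g)$name])
  g
}

#' Intermediate (cryptic) nodes of a sub-network
#' @param subnet a `drug_subnetwork`.
#' @return character vector of node names that are neither the root nor
#'   collected leaves.
#' @export
intermediate_nodes <- function(subnet) {
  names(subnet$roles)[subnet$roles == "intermediate"]
}

#' Sample control root cohorts
#'
#' Draws the roots for the three control cohorts: `R` samples random
#' network genes (excluding the leaf set and the true drug-target roots),
#' `L` samples from the leaf genes, `K` samples from kinase genes present
#' in the network. Sampling is without replacement and reproducible under
#' `seed`.
#'
#' @param network a [ppi_network()].
#' @param leaves leaf gene symbols.
#' @param kinases kinase gene symbols (used for `kind = "K"`).
#' @param kind one of `"R"`, `"L"`, `"K"`.
#' @param n cohort size.
#' @param seed integer seed.
#' @param exclude additional node names to exclude from the `R` universe
#'   (typically the experimental roots).
#' @return character vector of `n` distinct root names.
#' @export
sample_control_roots <- function(network, leaves, kinases = character(0),
                                 kind = c("R", "L", "K"), n, seed,
                                 exclude = character(0)) {
  kind <- match.arg(kind)
  vn <- igraph::V(network)$name
  universe <- switch(kind,
    R = setdiff(vn, c(leaves, exclude)),
    L = intersect(leaves, vn),
    K = intersect(kinases, vn)
  )
  if (length(universe) < n) {
    stop(kind, "-control universe has ", length(universe),
         " genes, fewer than n = ", n)
  }
  withr::with_seed(seed, sample(sort(universe), n))
}

#' Build sub-networks for a cohort of roots
#'
#' @param network a [ppi_network()].
#' @param roots character vector of root names.
#' @param leaves leaf gene symbols.
#' @param config a [builder_config()].
#' @return named list of `drug_subnetwork` objects.
#' @export
build_cohort <- function(network, roots, leaves, config = builder_config()) {
  stats::setNames(
    lapply(roots, build_subnetwork, network = network, leaves = leaves,
           config = config),
    roots
  )
}

#' Write a sub-network as GraphML plus a node table
#'
#' @param subnet a `drug_subnetwork`.
#' @param prefix output path prefix; writes `<prefix>.graphml` and
#'   `<prefix>_nodes.tsv` (node, role, depth, betweenness).
#' @export
write_subnetwork <- function(subnet, prefix) {
  write_graphml(subnet, paste0(prefix, ".graphml"))
  g <- subnet$tree
  depth <- if (igraph::vcount(g) > 1) {
    igraph::distances(g, v = subnet$root, weights = NA)[1, ]
  } else {
    stats::setNames(0, subnet$root)
  }
  btw <- node_betweenness(subnet)
  tab <- data.frame(
    node = igraph::V(g)$name,
    role = unname(subnet$roles[igraph::V(g)$name]),
    depth = unname(depth[igraph::V(g)$name]),
    betweenness = unname(btw[igraph::V(g)$name]),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
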