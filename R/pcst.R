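#' Rooted Prize-Collecting Steiner Tree instance
#'
#' A PCST instance is an interaction network, a root node (the drug-binding
#' target), and non-negative prizes on nodes (typically the differentially
#' expressed leaf genes). A solution is a tree containing the root; its
#' objective is the total edge cost of the tree plus the forfeited prizes of
#' prized nodes left out, so the optimizer connects the root to as many
#' prized nodes as is worth their cost.
#'
#' @param network a [ppi_network()].
#' @param root node name; must be present in the network.
#' @param prizes named numeric vector of non-negative prizes; names must be
#'   network nodes. Nodes not named have prize 0.
#' @return A `pcst_instance` object.
#' @export
pcst_instance <- function(network, root, prizes = numeric(0)) {
  vn <- igraph::V(network)$name
  if (!root %in% vn) stop("root '", root, "' not in network")
  if (length(prizes)) {
    if (is.null(names(prizes)) || any(!nzchar(names(prizes)))) {
      stop("prizes must be a named vector")
    }
    if (!all(names(prizes) %in% vn)) {
      stop("prize on node absent from network: ",
           setdiff(names(prizes), vn)[1])
    }
    if (any(!is.finite(prizes)) || any(prizes < 0)) stop("prizes must be >= 0")
  }
  structure(list(graph = network, root = root, prizes = prizes),
            class = "pcst_instance")
}

# prized nodes with strictly positive prize
prized_nodes <- function(instance) {
  names(instance$prizes)[instance$prizes > 0]
}

# tree given as an igraph; validates root membership, connectivity, acyclicity
validate_tree <- function(instance, tree) {
  vn <- igraph::V(tree)$name
  if (!instance$root %in% vn) stop("tree does not contain the root")
  if (igraph::vcount(tree) > 1) {
    if (!igraph::is_connected(tree)) stop("tree is not connected")
    if (igraph::ecount(tree) != igraph::vcount(tree) - 1L) {
      stop("tree has a cycle or redundant edges")
    }
  }
  invisible(TRUE)
}

#' PCST objective of a candidate tree
#'
#' Sum of edge costs in the tree plus prizes of prized nodes not in the
#' tree.
#'
#' @param instance a [pcst_instance()].
#' @param tree an igraph tree containing the root (e.g. the `tree` of a
#'   solution), with edge attribute `cost`.
#' @return numeric objective value.
#' @export
pcst_objective <- function(instance, tree) {
  validate_tree(instance, tree)
  edge_sum <- if (igraph::ecount(tree)) sum(igraph::E(tree)$cost) else 0
  excluded <- setdiff(names(instance$prizes), igraph::V(tree)$name)
  edge_sum + sum(instance$prizes[excluded])
}

# build the tree subgraph of instance$graph from an m x 2 matrix of node-name
# pairs; preserves confidence/cost edge attributes. Empty matrix -> root only.
tree_from_pairs <- function(instance, pairs) {
  g <- instance$graph
  if (is.null(pairs) || nrow(pairs) == 0L) {
    tr <- igraph::induced_subgraph(g, instance$root)
  } else {
    eids <- igraph::get_edge_ids(g, t(pairs))
    if (any(eids == 0)) stop("internal error: tree edge not in network")
    tr <- igraph::subgraph_from_edges(g, eids, delete.vertices = TRUE)
  }
  class(tr) <- "igraph"
  tr
}

finalize_solution <- function(instance, pairs) {
  tree <- tree_from_pairs(instance, pairs)
  validate_tree(instance, tree)
  nodes <- igraph::V(tree)$name
  sol <- structure(list(
    tree = tree,
    nodes = nodes,
    collected = intersect(prized_nodes(instance), nodes),
    objective = pcst_objective(instance, tree),
    root = instance$root
  ), class = "pcst_solution")
  sol
}

#' @export
print.pcst_solution <- function(x, ...) {
  cat("PCST solution: root", x$root, "|", length(x$nodes), "nodes,",
      igraph::ecount(x$tree), "edges,", length(x$collected),
      "prized nodes collected | objective", format(x$objective), "\n")
  invisible(x)
}

#' Exact PCST solver by exhaustive enumeration
#'
#' Enumerates every root-containing connected node subset; for a fixed
#' subset the cheapest tree is its minimum spanning tree on edge costs, so
#' the global optimum is found directly. Intended as a small-instance
#' oracle; ties are broken toward fewer edges, then the lexicographically
#' smallest sorted node tuple.
#'
#' @param instance a [pcst_instance()].
#' @param max_nodes refuse instances larger than this (default 12).
#' @return A `pcst_solution`.
#' @export
pcst_solve_exact <- function(instance, max_nodes = 12L) {
  g <- instance$graph
  vn <- sort(igraph::V(g)$name)
  n <- length(vn)
  if (n > max_nodes) {
    stop("instance has ", n, " nodes (> ", max_nodes,
         "); use pcst_solve_heuristic()")
  }
  W <- matrix(Inf, n, n, dimnames = list(vn, vn))
  el <- igraph::as_edgelist(g)
  co <- igraph::E(g)$cost
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    W[a, b] <- min(W[a, b], co[i])
    W[b, a] <- W[a, b]
  }
  p <- stats::setNames(numeric(n), vn)
  p[names(instance$prizes)] <- instance$prizes
  r <- match(instance$root, vn)
  others <- setdiff(seq_len(n), r)
  m <- length(others)
  total_prize <- sum(p)

  best <- list(obj = Inf, S = integer(0), key = "")
  for (mask in 0:(2^m - 1)) {
    S <- c(r, others[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0])
    k <- length(S)
    # connectivity by BFS within S
    if (k > 1) {
      sub <- W[S, S, drop = FALSE]
      reached <- logical(k); reached[1] <- TRUE
      frontier <- 1L
      while (length(frontier)) {
        nb <- which(!reached &
                      apply(is.finite(sub[frontier, , drop = FALSE]), 2, any))
        reached[nb] <- TRUE
        frontier <- nb
      }
      if (!all(reached)) next
      mst_cost <- prim_cost(sub)
    } else {
      mst_cost <- 0
    }
    obj <- mst_cost + total_prize - sum(p[S])
    if (obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 &&
         (k < length(best$S) ||
          (k == length(best$S) &&
           paste(vn[S], collapse = "|") < best$key)))) {
      best <- list(obj = obj, S = S, key = paste(vn[S], collapse = "|"))
    }
  }
  pairs <- if (length(best$S) > 1) {
    prim_edges(W[best$S, best$S, drop = FALSE])
  } else {
    matrix(character(0), 0, 2)
  }
  sol <- finalize_solution(instance, pairs)
  stopifnot(abs(sol$objective - best$obj) < 1e-9)
  sol
}

# Prim's MST cost on a small symmetric cost matrix (Inf = no edge).
prim_cost <- function(sub) {
  k <- nrow(sub)
  in_tree <- logical(k); in_tree[1] <- TRUE
  key <- sub[1, ]
  total <- 0
  for (step in seq_len(k - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(key[cand])]
    total <- total + key[v]
    in_tree[v] <- TRUE
    key <- pmin(key, sub[v, ])
  }
  total
}

# Prim's MST edges (node-name pairs), deterministic smallest-index tie-break
prim_edges <- function(sub) {
  k <- nrow(sub)
  vn <- rownames(sub)
  in_tree <- logical(k); in_tree[1] <- TRUE
  key <- sub[1, ]
  parent <- rep(1L, k)
  pairs <- matrix(character(0), 0, 2)
  for (step in seq_len(k - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(key[cand])]
    pairs <- rbind(pairs, c(vn[parent[v]], vn[v]))
    in_tree[v] <- TRUE
    upd <- !in_tree & sub[v, ] < key
    parent[upd] <- v
    key <- pmin(key, sub[v, ])
  }
  pairs
}

# directed edge arrays (both orientations) for hop-limited relaxation
directed_edges <- function(g) {
  vn <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$cost
  list(
    vn = vn,
    u = match(c(el[, 1], el[, 2]), vn),
    v = match(c(el[, 2], el[, 1]), vn),
    ww = c(w, w)
  )
}

# level-indexed relaxation: D[k, x] = min cost to reach x using at most
# k - 1 edges from the seed set (a seed at tree depth d becomes available
# at row d + 1 with cost 0). When `block_seeds` is TRUE, edges into seeds
# are removed so seeds act as sources only and segments can never pass
# through the existing tree. Returns the (rounds + 1) x n matrix.
level_costs <- function(de, seed_levels, rounds, block_seeds = FALSE) {
  n <- length(de$vn)
  u <- de$u; v <- de$v; ww <- de$ww
  if (block_seeds) {
    keep <- !(de$vn[v] %in% names(seed_levels))
    u <- u[keep]; v <- v[keep]; ww <- ww[keep]
  }
  D <- matrix(Inf, rounds + 1L, n)
  for (x in names(seed_levels)) {
    lev <- seed_levels[[x]] + 1L
    if (lev <= rounds + 1L) D[lev:(rounds + 1L), match(x, de$vn)] <- 0
  }
  for (k in seq_len(rounds)) {
    cand <- D[k, u] + ww
    ok <- is.finite(cand)
    if (any(ok)) {
      agg <- tapply(cand[ok], v[ok], min)
      idx <- as.integer(names(agg))
      D[k + 1L, idx] <- pmin(D[k + 1L, idx], agg)
    }
  }
  D
}

# hop-limited min-cost distances from a single root
hop_limited_distances <- function(g, root, max_hops) {
  de <- directed_edges(g)
  rounds <- as.integer(min(max_hops, length(de$vn) - 1L))
  D <- level_costs(de, stats::setNames(0L, root), max(rounds, 1L))
  stats::setNames(D[nrow(D), ], de$vn)
}

# reconstruct the min-cost segment ending at `target`, walking back through
# the level matrix until a seed (tree) node is met; lexicographic
# tie-breaks. Returns node names from the attachment seed to the target,
# or NULL if unreachable.
trace_segment <- function(de, D, seed_names, target) {
  ti <- match(target, de$vn)
  lv <- which(is.finite(D[, ti]))
  if (!length(lv)) return(NULL)
  k <- lv[which.min(D[lv, ti])]  # ties: smallest level = fewest hops
  x <- ti
  seg <- de$vn[x]
  while (!(de$vn[x] %in% seed_names)) {
    inc <- which(de$v == x)
    cand <- D[k - 1L, de$u[inc]] + de$ww[inc]
    hit <- inc[abs(cand - D[k, x]) <= 1e-9]
    if (!length(hit)) return(NULL)  # defensive; should not happen
    x <- de$u[hit[order(de$vn[de$u[hit]])[1]]]
    seg <- c(de$vn[x], seg)
    k <- k - 1L
  }
  seg
}

#' Deterministic PCST heuristic (shortest-path growth with pruning)
#'
#' Grow phase: prized nodes are attached one at a time, in order of
#' increasing min-cost distance from the root, each by the cheapest path
#' from the current tree under the hop budget (a level-indexed relaxation;
#' all tie-breaks lexicographic on node name, so results are fully
#' deterministic). Prune phase: repeatedly drop the prized node whose
#' exclusive branch cost exceeds its prize by the largest margin, together
#' with its then-dangling unshared branch, until no drop lowers the
#' objective. The root-only solution is returned if it is at least as
#' good.
#'
#' @param instance a [pcst_instance()].
#' @param max_hops maximum depth (edges) of any node below the root
#'   (default unlimited); used to enforce the sub-network depth limit.
#' @return A `pcst_solution`.
#' @export
pcst_solve_heuristic <- function(instance, max_hops = Inf) {
  g <- instance$graph
  root <- instance$root
  de <- directed_edges(g)
  rounds <- as.integer(min(max_hops, length(de$vn) - 1L))
  rounds <- max(rounds, 1L)
  dist0 <- hop_limited_distances(g, root, rounds)
  targets <- setdiff(prized_nodes(instance), root)
  targets <- targets[is.finite(dist0[targets])]
  targets <- targets[order(dist0[targets], targets)]

  depth <- stats::setNames(0L, root)
  parent <- stats::setNames(NA_character_, root)
  for (t in targets) {
    if (t %in% names(depth)) next
    # tree nodes are sources only: drop edges into them so the new branch
    # attaches at exactly one tree node, at a level matching its depth
    keep <- !(de$vn[de$v] %in% names(depth))
    deb <- list(vn = de$vn, u = de$u[keep], v = de$v[keep], ww = de$ww[keep])
    D <- level_costs(deb, depth, rounds)
    seg <- trace_segment(deb, D, names(depth), t)
    if (is.null(seg)) next
    for (i in seq_along(seg)[-1]) {
      parent[seg[i]] <- seg[i - 1]
      depth[seg[i]] <- depth[[seg[i - 1]]] + 1L
    }
  }
  kept <- intersect(targets, names(depth))
  path_to <- function(t) {
    pa <- t
    while (pa[1] != root) pa <- c(parent[[pa[1]]], pa)
    pa
  }
  paths <- stats::setNames(lapply(kept, path_to), kept)
  cost_of <- function(a, b) {
    igraph::E(g)$cost[igraph::get_edge_ids(g, c(a, b))]
  }
  repeat {
    if (!length(kept)) break
    counts <- table(unlist(lapply(paths[kept], unique)))
    worst <- NULL; worst_margin <- 0
    for (t in kept) {
      pa <- paths[[t]]
      # exclusive suffix: branch nodes used by this prized node only
      marg <- 0
      for (i in rev(seq_along(pa))[-length(pa)]) {  # down to index 2
        if (counts[[pa[i]]] > 1) break
        marg <- marg + cost_of(pa[i - 1], pa[i])
      }
      margin <- marg - instance$prizes[[t]]
      if (margin > worst_margin + 1e-12) {
        worst <- t; worst_margin <- margin
      }
    }
    if (is.null(worst)) break
    kept <- setdiff(kept, worst)
  }
  pairs <- matrix(character(0), 0, 2)
  if (length(kept)) {
    seen <- character(0)
    for (t in kept) {
      pa <- paths[[t]]
      for (i in seq_len(length(pa) - 1)) {
        key <- paste(min(pa[i], pa[i + 1]), max(pa[i], pa[i + 1]))
        if (!key %in% seen) {
          seen <- c(seen, key)
          pairs <- rbind(pairs, c(pa[i], pa[i + 1]))
        }
      }
    }
  }
  sol <- finalize_solution(instance, pairs)
  root_only <- finalize_solution(instance, NULL)
  if (root_only$objective <= sol$objective + 1e-12) root_only else sol
}
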