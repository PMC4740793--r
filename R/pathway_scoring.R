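#' Over-representation analysis of a gene set against pathways
#'
#' Hypergeometric upper-tail test of the overlap between a query gene set
#' and each pathway, within a fixed gene universe, with Benjamini-Hochberg
#' FDR across pathways.
#'
#' @param query character vector of genes; must be contained in `universe`.
#' @param pathways named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector defining the background.
#' @param alpha FDR threshold for the `enriched` flag (default 0.05).
#' @return data.frame: pathway, overlap `k`, pathway size `K`, query size
#'   `n`, universe size `N`, `p`, BH `q`, `enriched`.
#' @export
ora_enrichment <- function(query, pathways, universe, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 3), collapse = ", "))
  }
  if (length(pathways) == 0L) stop("empty pathway collection")
  N <- length(universe)
  n <- length(query)
  K <- vapply(pathways, function(s) length(intersect(s, universe)), 1L)
  k <- vapply(pathways, function(s) length(intersect(s, query)), 1L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    pathway = names(pathways), k = k, K = K, n = n, N = N,
    p = p, q = q, enriched = q < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Key-pathway participation score of a sub-network
#'
#' Counts, for each key pathway, how many intermediate (cryptic) nodes of
#' the sub-network belong to it. A node in m pathways contributes m
#' instances, so the total participation P is the sum over pathways.
#'
#' @param subnet a `drug_subnetwork` from [build_subnetwork()].
#' @param key_pathways named list of gene sets.
#' @param include_leaves also count collected leaf nodes (default FALSE:
#'   intermediates only; the root is never counted).
#' @return list with `root`, per-pathway `counts`, and total `P`.
#' @export
participation <- function(subnet, key_pathways, include_leaves = FALSE) {
  if (length(key_pathways) == 0L) stop("empty key-pathway collection")
  nodes <- intermediate_nodes(subnet)
  if (include_leaves) nodes <- c(nodes, subnet$collected)
  counts <- vapply(key_pathways, function(s) length(intersect(s, nodes)), 1L)
  structure(list(root = subnet$root, counts = counts, P = sum(counts)),
            class = "participation_score")
}

#' Z-score of a participation score against a reference cohort
#'
#' Normalizes a participation score against the mean and sample standard
#' deviation of a reference cohort's scores (the random-root R-control).
#'
#' @param P participation score (scalar).
#' @param reference_scores numeric vector of reference participation
#'   scores; needs length >= 2 and non-zero spread.
#' @return list with `P`, `mu_ref`, `sd_ref`, `z`.
#' @export
participation_zscore <- function(P, reference_scores) {
  if (length(reference_scores) < 2) stop("need >= 2 reference scores")
  mu <- mean(reference_scores)
  s <- stats::sd(reference_scores)
  if (s == 0) stop("reference scores have zero standard deviation")
  list(P = P, mu_ref = mu, sd_ref = s, z = (P - mu) / s)
}

#' Welch's unequal-variance t-test from summary statistics
#'
#' Two-sided Welch test computed from group means, standard deviations and
#' sizes, with the Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p` (two-sided), and the inputs.
#' @export
welch_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p,
       mean1 = mean1, sd1 = sd1, n1 = n1,
       mean2 = mean2, sd2 = sd2, n2 = n2)
}

#' Count enriched pathways, overall and cancer-related
#'
#' @param results an [ora_enrichment()] data.frame.
#' @param alpha FDR threshold.
#' @param cancer_related character vector of pathway names considered
#'   cancer-related.
#' @return named numeric: `total` and `cancer` counts of pathways with
#'   `q < alpha`.
#' @export
count_enriched <- function(results, alpha = 0.05, cancer_related = character(0)) {
  hit <- results$pathway[results$q < alpha]
  c(total = length(hit), cancer = length(intersect(hit, cancer_related)))
}
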