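#' Construct a confidence-weighted interaction network
#'
#' Builds an undirected PPI network from an edge table. Every edge carries a
#' `confidence` in (0, 1] and a `cost = 1 - confidence`; self-loops are
#' dropped and duplicate pairs are collapsed to the maximum confidence.
#'
#' @param edges data.frame with columns `from`, `to`, `confidence`.
#' @return An [igraph::igraph] object of class `ppi_network` with edge
#'   attributes `confidence` and `cost`.
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "confidence") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(!is.finite(edges$confidence)) ||
      any(edges$confidence < 0) || any(edges$confidence > 1)) {
    stop("edge confidences must lie in [0, 1]")
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) == 0L) stop("network has no edges after removing self-loops")
  # canonical unordered pair, max-confidence wins on duplicates
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$confidence)
  keep <- !duplicated(key[ord])
  edges <- data.frame(
    from = a[ord][keep], to = b[ord][keep],
    confidence = edges$confidence[ord][keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$confidence > 0, , drop = FALSE]
  if (nrow(edges) == 0L) stop("network has no edges with positive confidence")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$cost <- edge_cost(igraph::E(g)$confidence)
  class(g) <- unique(c("ppi_network", class(g)))
  g
}

#' Edge cost from interaction confidence
#'
#' Cost of including an interaction is one minus its confidence, so
#' high-confidence interactions are cheap to traverse.
#'
#' @param confidence numeric vector in \[0, 1\].
#' @return `1 - confidence`.
#' @export
#' @examples
#' edge_cost(0.9) # 0.1
edge_cost <- function(confidence) {
  if (any(!is.finite(confidence)) || any(confidence < 0) || any(confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  1 - confidence
}

#' Read a STRING-style protein links file
#'
#' Parses whitespace-separated `protein1 protein2 score` lines (optional
#' header). Scores are either STRING integer combined scores (0-1000) or
#' fractions in \[0, 1\]; if any score exceeds 1 the whole file is treated as
#' 0-1000 and divided by 1000.
#'
#' @param path file path.
#' @param min_confidence edges with confidence below this fraction are
#'   dropped (default 0, keep all positive-confidence edges).
#' @return A [ppi_network()].
#' @export
read_string_links <- function(path, min_confidence = 0) {
  stopifnot(file.exists(path), min_confidence >= 0, min_confidence <= 1)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty network file: ", path)
  toks <- strsplit(trimws(lines[nonblank]), "[[:space:]]+")
  first <- toks[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  if (has_header) {
    toks <- toks[-1]
    nonblank <- nonblank[-1]
  }
  if (length(toks) == 0L) stop("no data lines in ", path)
  bad <- which(vapply(toks, length, 1L) < 3L)
  if (length(bad)) {
    stop("malformed line ", nonblank[bad[1]], " in ", path,
         ": expected 'node node score'")
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
  if (anyNA(score)) {
    stop("malformed line ", nonblank[which(is.na(score))[1]], " in ", path,
         ": score is not numeric")
  }
  if (any(score > 1)) score <- score / 1000
  if (any(score < 0) || any(score > 1)) {
    stop("scores outside [0, 1] (or [0, 1000]) in ", path)
  }
  edges <- data.frame(from = from, to = to, confidence = score,
                      stringsAsFactors = FALSE)
  edges <- edges[edges$confidence >= min_confidence & edges$from != edges$to, ,
                 drop = FALSE]
  if (nrow(edges) == 0L) {
    stop("no edges remain after filtering at min_confidence = ", min_confidence)
  }
  ppi_network(edges)
}

#' Write a network as STRING-style protein links
#'
#' @param network a [ppi_network()].
#' @param path output path.
#' @param scale `"fraction"` writes confidences in \[0,1\]; `"integer"`
#'   writes STRING 0-1000 combined scores.
#' @param header write a `protein1 protein2 combined_score` header line.
#' @export
write_string_links <- function(network, path, scale = c("fraction", "integer"),
                               header = TRUE) {
  scale <- match.arg(scale)
  el <- igraph::as_edgelist(network)
  conf <- igraph::E(network)$confidence
  score <- if (scale == "integer") as.character(round(conf * 1000)) else sprintf("%.6f", conf)
  lines <- paste(el[, 1], el[, 2], score)
  if (header) lines <- c("protein1 protein2 combined_score", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then member genes. Genes are
#' de-duplicated within a set; empty sets and duplicated set names are
#' errors.
#'
#' @param path file path.
#' @return Named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name in ", path, ": ", nm[duplicated(nm)][1])
  }
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "", "")
  sets <- lapply(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes[nzchar(genes)]
  })
  n0 <- vapply(sets, length, 1L)
  if (any(n0 == 0L)) stop("gene set with zero genes in ", path, ": ", nm[n0 == 0L][1])
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list
#'
#' One symbol per line; lines starting with `#` are comments. Order is
#' preserved; duplicates are removed with a warning.
#'
#' @param path file path.
#' @param role optional tag (`"leaves"`, `"kinases"`, `"roots"`).
#' @return Character vector with a `role` attribute.
#' @export
read_gene_list <- function(path, role = NULL) {
  stopifnot(file.exists(path))
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) stop("empty gene list: ", path)
  if (anyDuplicated(x)) {
    warning("duplicate symbols removed from ", path)
    x <- x[!duplicated(x)]
  }
  attr(x, "role") <- role
  x
}

#' Export a network or sub-network tree to GraphML
#'
#' Node `role` (root/intermediate/leaf) and edge `confidence` attributes are
#' preserved so the file renders directly in Cytoscape.
#'
#' @param x a `ppi_network` or the `tree` of a [build_subnetwork()] result.
#' @param path output path.
#' @export
write_graphml <- function(x, path) {
  g <- if (inherits(x, "drug_subnetwork")) subnetwork_graph(x) else x
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network to SIF (simple interaction format)
#' @param x a `ppi_network` or sub-network.
#' @param path output path.
#' @param interaction interaction type string (default `"pp"`).
#' @export
write_sif <- function(x, path, interaction = "pp") {
  g <- if (inherits(x, "drug_subnetwork")) subnetwork_graph(x) else x
  el <- igraph::as_edgelist(g)
  writeLines(paste(el[, 1], interaction, el[, 2]), path)
  invisible(path)
}
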