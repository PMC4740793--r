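#' Configuration of the synthetic PPI benchmark generator
#'
#' The generator emulates the structure the pipeline is designed for: a
#' sparse scale-free-ish background PPI whose confidences sit mostly in
#' the low range, a set of "drug target" roots with planted high-confidence
#' (>= 0.9) paths to their assigned differentially expressed leaves, key
#' pathways that preferentially contain the planted intermediate nodes,
#' and uniform decoy pathways.
#'
#' @param n_nodes number of genes (default 250).
#' @param attach_m preferential-attachment edges per new node (default 3).
#' @param bg_shape1,bg_shape2 Beta parameters of background confidences
#'   (default 4, 6: mode near 0.4).
#' @param planted_conf range of planted-path confidences (default
#'   c(0.9, 0.99)).
#' @param n_planted_targets number of planted drug-target roots (default 6).
#' @param n_leaves size of the leaf gene set (default 40).
#' @param leaves_per_target leaves assigned a planted path per target
#'   (default 8).
#' @param planted_path_len edges on each planted root-to-leaf path
#'   (default 3); must not exceed `depth`.
#' @param depth sub-network depth limit the data are generated for
#'   (default 5).
#' @param n_key_pathways,pathway_size planted key pathways and their size
#'   (defaults 8 and 25).
#' @param key_planted_prob probability that a planted intermediate is
#'   included in each key pathway (default 0.8).
#' @param n_decoy_pathways uniformly drawn decoy pathways (default 8).
#' @param kinase_fraction fraction of genes labeled as kinases
#'   (default 0.1).
#' @param seed integer seed; all outputs are reproducible under it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_nodes = 250L, attach_m = 3L,
                         bg_shape1 = 4, bg_shape2 = 6,
                         planted_conf = c(0.9, 0.99),
                         n_planted_targets = 6L, n_leaves = 40L,
                         leaves_per_target = 8L, planted_path_len = 3L,
                         depth = 5L,
                         n_key_pathways = 8L, pathway_size = 25L,
                         key_planted_prob = 0.8,
                         n_decoy_pathways = 8L,
                         kinase_fraction = 0.1, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  if (cfg$planted_path_len > cfg$depth) {
    stop("planted_path_len (", cfg$planted_path_len,
         ") exceeds the depth limit (", cfg$depth, ")")
  }
  if (cfg$leaves_per_target > cfg$n_leaves) {
    stop("leaves_per_target cannot exceed n_leaves")
  }
  needed <- cfg$n_planted_targets * (cfg$planted_path_len - 1) +
    cfg$n_planted_targets + cfg$n_leaves
  if (needed > cfg$n_nodes) stop("n_nodes too small for the planted structure")
  cfg
}

#' Generate a synthetic PPI benchmark with planted drug-target structure
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, writes `network.txt`
#'   (STRING-dialect links), `leaves.txt`, `kinases.txt`, `pathways.gmt`
#'   and `truth.json` there.
#' @return list with `network` (a [ppi_network()]), `leaves`, `kinases`,
#'   `pathways` (key + decoy gene sets), `key_pathway_names`, and `truth`
#'   (planted targets, their leaves and planted intermediates).
#' @export
generate_synthetic_data <- function(config = synth_config(), dir = NULL) {
  withr::with_seed(config$seed, {
    n <- config$n_nodes
    genes <- sprintf("G%03d", seq_len(n))
    base <- igraph::sample_pa(n, power = 1, m = config$attach_m,
                              directed = FALSE)
    el <- igraph::as_edgelist(base)
    edges <- data.frame(
      from = genes[as.integer(el[, 1])],
      to = genes[as.integer(el[, 2])],
      confidence = stats::rbeta(nrow(el), config$bg_shape1, config$bg_shape2),
      stringsAsFactors = FALSE
    )

    targets <- sample(genes, config$n_planted_targets)
    leaves <- sample(setdiff(genes, targets), config$n_leaves)
    pool <- setdiff(genes, c(targets, leaves))
    n_int <- config$planted_path_len - 1L
    leaves_by_target <- list()
    intermediates_by_target <- list()
    planted_edges <- list()
    for (t in targets) {
      assigned <- sample(leaves, config$leaves_per_target)
      chain <- if (n_int > 0) sample(pool, n_int) else character(0)
      pool <- setdiff(pool, chain)
      path_nodes <- c(t, chain)
      spine <- if (length(path_nodes) > 1) {
        cbind(path_nodes[-length(path_nodes)], path_nodes[-1])
      } else {
        NULL
      }
      tip <- path_nodes[length(path_nodes)]
      fan <- cbind(rep(tip, length(assigned)), assigned)
      pe <- rbind(spine, fan)
      planted_edges[[t]] <- data.frame(
        from = pe[, 1], to = pe[, 2],
        confidence = stats::runif(nrow(pe), config$planted_conf[1],
                                  config$planted_conf[2]),
        stringsAsFactors = FALSE
      )
      leaves_by_target[[t]] <- assigned
      intermediates_by_target[[t]] <- chain
    }
    edges <- rbind(edges, do.call(rbind, planted_edges))
    network <- ppi_network(edges)

    planted_int <- unlist(intermediates_by_target, use.names = FALSE)
    cancer_names <- load_fixture("cancer_pathways")
    key_names <- paste0(
      "KEY_", seq_len(config$n_key_pathways), "_",
      gsub(" ", "_", cancer_names[((seq_len(config$n_key_pathways) - 1) %%
                                     length(cancer_names)) + 1])
    )
    pathways <- list()
    for (nm in key_names) {
      core <- planted_int[stats::runif(length(planted_int)) <
                            config$key_planted_prob]
      fill <- sample(setdiff(genes, core),
                     max(config$pathway_size - length(core), 1))
      pathways[[nm]] <- unique(c(core, fill))
    }
    for (i in seq_len(config$n_decoy_pathways)) {
      pathways[[paste0("DECOY_", i)]] <- sample(genes, config$pathway_size)
    }
    kinases <- sample(setdiff(genes, targets),
                      max(round(config$kinase_fraction * n), 1))

    truth <- list(
      targets = targets,
      leaves_by_target = leaves_by_target,
      intermediates_by_target = intermediates_by_target,
      planted_intermediates = planted_int
    )
    out <- list(network = network, leaves = leaves, kinases = kinases,
                pathways = pathways, key_pathway_names = key_names,
                truth = truth, config = config)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_string_links(network, file.path(dir, "network.txt"))
      writeLines(leaves, file.path(dir, "leaves.txt"))
      writeLines(kinases, file.path(dir, "kinases.txt"))
      write_gmt(pathways, file.path(dir, "pathways.gmt"))
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           auto_unbox = FALSE, pretty = TRUE)
      out$files <- file.path(dir, c("network.txt", "leaves.txt",
                                    "kinases.txt", "pathways.gmt",
                                    "truth.json"))
    }
    out
  })
}

.fixture_files <- c(
  table1 = "table1.tsv", table2 = "table2.tsv", table3 = "table3.tsv",
  table4 = "table4.tsv", table5 = "table5.tsv",
  group_stats = "group_stats.tsv", kinases = "kinases.txt",
  dspathnet_hubs = "dspathnet_hubs.txt",
  cancer_pathways = "synthetic_cancer_pathways.txt"
)

#' Load a bundled fixture table or gene list
#'
#' Fixtures bundle the published structural-screen table (`table1`),
#' binding-assay results (`table2`), participation Z-scores (`table3`),
#' critical-node counts (`table4`), cross-cohort criticality percentages
#' (`table5`), cohort participation summary statistics (`group_stats`), a
#' kinase gene list, an external hub-gene list (`dspathnet_hubs`), and a
#' curated stand-in list of cancer-related pathway names
#' (`cancer_pathways`).
#'
#' @param name one of `table1`, `table2`, `table3`, `table4`, `table5`,
#'   `group_stats`, `kinases`, `dspathnet_hubs`, `cancer_pathways`.
#' @return data.frame for tables, character vector for gene/pathway lists.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(.fixture_files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_files), collapse = ", "))
  }
  path <- system.file("extdata", .fixture_files[[name]], package = "pcstnet",
                      mustWork = TRUE)
  if (grepl("\\.tsv$", path)) {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    x <- trimws(readLines(path))
    x[nzchar(x) & !startsWith(x, "#")]
  }
}
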