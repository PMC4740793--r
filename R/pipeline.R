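#' Run the full drug-modulation sub-network pipeline
#'
#' For each experimental root and for the R/L/K control cohorts this
#' builds the depth-limited PCST sub-network, scores key-pathway
#' participation, runs over-representation analysis of the intermediate
#' nodes, Z-normalizes experimental participation against the R-control,
#' compares cohorts with Welch's t-test, calls critical nodes by
#' betweenness percentile, tabulates cross-cohort criticality, and
#' intersects frequently-critical genes with an optional external hub
#' list.
#'
#' @param network a [ppi_network()].
#' @param leaves differentially expressed leaf gene symbols.
#' @param key_pathways named list of key-pathway gene sets.
#' @param kinases kinase gene symbols (K-control universe).
#' @param roots experimental root gene symbols (drug targets).
#' @param config a [builder_config()]; its `seed` drives control sampling.
#' @param pathways gene sets used for enrichment (default: `key_pathways`).
#' @param hubs optional external hub gene list for cross-validation.
#' @param cancer_related pathway names counted as cancer-related.
#' @param alpha FDR threshold for enrichment.
#' @param percentile betweenness percentile for critical nodes.
#' @param z_cuts Z thresholds for stratified criticality columns.
#' @param min_spread minimum criticality spread (percentage points).
#' @param out_dir optional output directory for TSV/GraphML/JSON reports.
#' @return A `pcstnet_run` list; see Details.
#'
#' @details The returned list contains `subnetworks` (per cohort),
#'   `participation` (data.frame root/cohort/P), `zscores`, `welch`
#'   (experimental vs each control cohort), `enrichment_counts`,
#'   `criticality` (table, discrepancy genes, hub overlap), and `summary`.
#' @export
run_pipeline <- function(network, leaves, key_pathways, kinases, roots,
                         config = builder_config(), pathways = key_pathways,
                         hubs = NULL, cancer_related = character(0),
                         alpha = 0.05, percentile = 95, z_cuts = c(1, 2),
                         min_spread = 25, out_dir = NULL) {
  vn <- igraph::V(network)$name
  missing_roots <- setdiff(roots, vn)
  if (length(missing_roots)) {
    stop("experimental roots absent from network: ",
         paste(missing_roots, collapse = ", "))
  }
  cohort_roots <- list(
    experimental = roots,
    R = sample_control_roots(network, leaves, kinases, "R", config$n_R,
                             seed = config$seed + 1L, exclude = roots),
    L = sample_control_roots(network, leaves, kinases, "L", config$n_L,
                             seed = config$seed + 2L),
    K = sample_control_roots(network, leaves, kinases, "K", config$n_K,
                             seed = config$seed + 3L)
  )
  subnetworks <- lapply(cohort_roots, build_cohort, network = network,
                        leaves = leaves, config = config)

  part <- do.call(rbind, lapply(names(subnetworks), function(co) {
    data.frame(
      root = names(subnetworks[[co]]),
      cohort = co,
      P = vapply(subnetworks[[co]],
                 function(s) participation(s, key_pathways)$P, 1L),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))

  ref <- part$P[part$cohort == "R"]
  z_exp <- vapply(part$P[part$cohort == "experimental"],
                  function(p) participation_zscore(p, ref)$z, 1)
  zscores <- data.frame(root = part$root[part$cohort == "experimental"],
                        P = part$P[part$cohort == "experimental"],
                        z = z_exp, row.names = NULL, stringsAsFactors = FALSE)
  zscores <- zscores[order(-zscores$z), ]

  grp <- function(co) {
    p <- part$P[part$cohort == co]
    list(mean = mean(p), sd = stats::sd(p), n = length(p))
  }
  e <- grp("experimental")
  welch <- lapply(c(R = "R", L = "L", K = "K"), function(co) {
    g <- grp(co)
    welch_test(e$mean, e$sd, e$n, g$mean, g$sd, g$n)
  })

  universe <- vn
  enr_counts <- do.call(rbind, lapply(names(subnetworks), function(co) {
    cnts <- t(vapply(subnetworks[[co]], function(s) {
      q <- intermediate_nodes(s)
      if (length(q) == 0L) return(c(total = 0, cancer = 0))
      count_enriched(ora_enrichment(q, pathways, universe, alpha),
                     alpha, cancer_related)
    }, c(total = 0, cancer = 0)))
    data.frame(root = names(subnetworks[[co]]), cohort = co,
               n_enriched = cnts[, "total"], n_cancer = cnts[, "cancer"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  critical_sets <- lapply(unlist(subnetworks, recursive = FALSE),
                          function(s) critical_nodes(node_betweenness(s),
                                                     percentile))
  names(critical_sets) <- unlist(lapply(subnetworks, names),
                                 use.names = FALSE)
  cohorts <- stats::setNames(
    rep(c("experimental", "control", "L", "K"),
        vapply(subnetworks, length, 1L)),
    names(critical_sets)
  )
  zmap <- stats::setNames(zscores$z, zscores$root)
  crit_table <- criticality_counts(
    critical_sets[cohorts %in% c("experimental", "control")],
    cohorts, zmap, z_cuts
  )
  disc <- discrepancy_rows(crit_table, min_spread)
  hubs_hit <- if (!is.null(hubs)) hub_overlap(crit_table, hubs) else NULL

  summary <- list(
    cohort_sizes = vapply(cohort_roots, length, 1L),
    participation_mean = vapply(c("experimental", "R", "L", "K"),
                                function(co) grp(co)$mean, 1),
    participation_sd = vapply(c("experimental", "R", "L", "K"),
                              function(co) grp(co)$sd, 1),
    welch_p = vapply(welch, `[[`, 1, "p"),
    mean_z_experimental = mean(zscores$z),
    mean_enriched = vapply(
      c(experimental = "experimental", R = "R", L = "L", K = "K"),
      function(co) mean(enr_counts$n_enriched[enr_counts$cohort == co]), 1
    ),
    n_discrepancy_genes = length(disc),
    hub_overlap = hubs_hit,
    depth = config$depth, seed = config$seed,
    percentile = percentile, alpha = alpha
  )

  run <- structure(list(
    subnetworks = subnetworks, cohort_roots = cohort_roots,
    participation = part, zscores = zscores, welch = welch,
    enrichment_counts = enr_counts, critical_sets = critical_sets,
    criticality = list(table = crit_table, discrepancy = disc,
                       hub_overlap = hubs_hit),
    summary = summary
  ), class = "pcstnet_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pcstnet_run <- function(x, ...) {
  s <- x$summary
  cat("pcstnet pipeline run (depth", s$depth, ", seed", s$seed, ")\n")
  cat("  cohorts:", paste(names(s$cohort_sizes), s$cohort_sizes,
                          sep = "=", collapse = ", "), "\n")
  cat("  participation means:",
      paste(names(s$participation_mean),
            sprintf("%.1f", s$participation_mean),
            sep = "=", collapse = ", "), "\n")
  cat("  Welch p (experimental vs):",
      paste(names(s$welch_p), signif(s$welch_p, 3),
            sep = "=", collapse = ", "), "\n")
  cat("  mean experimental Z:", sprintf("%.2f", s$mean_z_experimental), "\n")
  cat("  discrepancy genes:", s$n_discrepancy_genes, "\n")
  if (length(s$hub_overlap)) {
    cat("  hub overlap:", paste(s$hub_overlap, collapse = ", "), "\n")
  }
  invisible(x)
}

# write TSV/JSON/GraphML reports for a pipeline run
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, nm) {
    utils::write.table(df, file.path(out_dir, nm), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(run$zscores, "zscores.tsv")
  wt(run$participation, "participation.tsv")
  wt(run$enrichment_counts, "enrichment_counts.tsv")
  wt(run$criticality$table, "criticality.tsv")
  smry <- lapply(run$summary, function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  net_dir <- file.path(out_dir, "subnetworks")
  if (!dir.exists(net_dir)) dir.create(net_dir)
  for (co in names(run$subnetworks)) {
    for (s in run$subnetworks[[co]]) {
      write_subnetwork(s, file.path(net_dir, paste0(co, "_", s$root)))
    }
  }
  invisible(out_dir)
}
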