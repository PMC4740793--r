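#' %Control from competition binding-assay signals
#'
#' KINOMEscan-style readout: 100 * (test - positive) / (negative -
#' positive), where the negative control (DMSO) defines "no binding" (100)
#' and the positive control (a picomolar inhibitor) defines full
#' displacement (0). Lower values mean stronger binding. The readout is
#' invariant under a common positive affine rescaling of all three
#' signals.
#'
#' @param test_signal measured signal with the compound.
#' @param positive_signal positive-control signal.
#' @param negative_signal negative-control signal.
#' @return percent of control (vectorized).
#' @export
percent_control <- function(test_signal, positive_signal, negative_signal) {
  if (any(negative_signal == positive_signal)) {
    stop("negative and positive control signals must differ")
  }
  100 * (test_signal - positive_signal) / (negative_signal - positive_signal)
}

#' Putative drug targets from a structural-screen table
#'
#' Drops template rows (structures used as the search query, which carry no
#' similarity p-value) and optionally template homologs, then sorts by
#' binding-site similarity p-value ascending.
#'
#' @param records data.frame with columns `pdb_code`, `gene`, `smap_p`,
#'   `vina_score`, `is_template`, `is_template_homolog`, `is_kinase`
#'   (e.g. `load_fixture("table1")`).
#' @param exclude_homologs also drop template homologs (default FALSE).
#' @return filtered, sorted data.frame.
#' @export
putative_targets <- function(records, exclude_homologs = FALSE) {
  out <- records[!records$is_template, , drop = FALSE]
  if (exclude_homologs) out <- out[!out$is_template_homolog, , drop = FALSE]
  out <- out[order(out$smap_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kinase subset of the putative targets
#'
#' @param records the structural-screen table (see [putative_targets()]).
#' @param kinase_set character vector of kinase gene symbols.
#' @return data.frame of putative targets whose gene is in `kinase_set`.
#' @export
kinase_targets <- function(records, kinase_set) {
  put <- putative_targets(records)
  out <- put[put$gene %in% kinase_set, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split assay measurements into bound and unbound genes
#'
#' Genes whose %Control is strictly below the no-binding level are called
#' bound, sorted ascending (strongest binder first, ties broken by gene
#' symbol); the rest are unbound.
#'
#' @param measurements data.frame with columns `gene`, `percent_control`.
#' @param no_binding_level %Control meaning "no interaction" (default 100).
#' @return list with character vectors `bound` and `unbound`.
#' @export
binding_summary <- function(measurements, no_binding_level = 100) {
  stopifnot(all(c("gene", "percent_control") %in% names(measurements)))
  m <- measurements[order(measurements$percent_control, measurements$gene), ,
                    drop = FALSE]
  list(
    bound = m$gene[m$percent_control < no_binding_level],
    unbound = m$gene[m$percent_control >= no_binding_level]
  )
}
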