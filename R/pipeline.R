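#' Run the full event-ordering pipeline on a count matrix
#'
#' Convenience wrapper chaining the standard steps: (optional QC), log-CPM
#' normalization, PC1 pseudotime over the module-gene union rooted at
#' `root_module`, equal-count binning, module scoring with all non-module
#' genes as the control set (see [score_modules()]), per-module logistic
#' fits, and event ordering.
#'
#' @param em counts [expression_matrix()].
#' @param modules list of [gene_module()] objects.
#' @param root_module name of the module whose high scorers mark the early
#'   end of the trajectory (default `"OXPHOS"`).
#' @param n_bins number of pseudotime groups (default 100).
#' @param qc apply [qc_filter()] first? (default FALSE; the synthetic
#'   generator produces no failing cells at default depth).
#' @param r2_min,tie_eps passed to the fitting/ordering steps.
#' @return List with `normalized`, `pt`, `profile`, `fits`, `order`.
#' @export
run_event_ordering <- function(em, modules, root_module = "OXPHOS",
                               n_bins = 100, qc = FALSE,
                               r2_min = 0.3, tie_eps = 1.0) {
  if (qc) em <- qc_filter(em)
  norm <- normalize_log_cpm(em)
  root <- modules[[root_module]]
  if (is.null(root)) stop_(sprintf("unknown root module '%s'", root_module))
  pt <- infer_pseudotime(norm, module_union(modules), root)
  pt <- bin_pseudotime(pt, n_bins)
  control <- setdiff(norm$gene_ids, module_union(modules))
  profile <- score_modules(norm, modules, pt, control_genes = control)
  fits <- fit_module_curves(profile, r2_min)
  ord <- order_events(fits, tie_eps)
  list(normalized = norm, pt = pt, profile = profile, fits = fits,
       order = ord)
}
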