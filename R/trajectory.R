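#' Quality-control filter on a count matrix
#'
#' Removes cells detecting fewer than `min_genes_per_cell` genes, then genes
#' detected in fewer than `min_cells_per_gene` of the remaining cells, in
#' that order. Thresholds of (0, 0) leave the input unchanged.
#'
#' @param em counts [expression_matrix()].
#' @param min_genes_per_cell minimum detected genes per cell (default 200).
#' @param min_cells_per_gene minimum cells per gene (default 3).
#' @return Filtered counts [expression_matrix()].
#' @export
qc_filter <- function(em, min_genes_per_cell = 200, min_cells_per_gene = 3) {
  check_kind(em, "counts", "qc_filter")
  detected <- em$values > 0
  keep_cells <- Matrix::rowSums(detected) >= min_genes_per_cell
  if (!any(keep_cells)) {
    stop_(sprintf(
      "all %d cells removed at min_genes_per_cell = %d; lower the threshold",
      nrow(em$values), min_genes_per_cell))
  }
  v <- em$values[keep_cells, , drop = FALSE]
  keep_genes <- Matrix::colSums(v > 0) >= min_cells_per_gene
  message(sprintf("qc_filter: removed %d/%d cells and %d/%d genes",
                  sum(!keep_cells), length(keep_cells),
                  sum(!keep_genes), length(keep_genes)))
  expression_matrix(v[, keep_genes, drop = FALSE], kind = "counts")
}

#' Log-CPM normalization
#'
#' Scales each cell to 10,000 total counts then applies log(1 + x). The
#' normalized profile of a cell is invariant to scaling its counts by a
#' constant.
#'
#' @param em counts [expression_matrix()].
#' @return Normalized [expression_matrix()] (kind `"normalized"`).
#' @export
normalize_log_cpm <- function(em) {
  check_kind(em, "counts", "normalize_log_cpm")
  totals <- Matrix::rowSums(em$values)
  if (any(totals == 0)) {
    stop_(sprintf("%d cell(s) have zero total counts; run qc_filter first",
                  sum(totals == 0)))
  }
  if (inherits(em$values, "sparseMatrix")) {
    v <- methods::as(Matrix::Diagonal(x = 1e4 / totals) %*% em$values,
                     "CsparseMatrix")
    v@x <- log1p(v@x)
  } else {
    v <- log1p(em$values / totals * 1e4)
  }
  dimnames(v) <- dimnames(em$values)
  expression_matrix(v, kind = "normalized")
}

#' Infer a per-cell pseudotime on \[0, 100\]
#'
#' Deterministic principal-component pseudotime: the ordering genes are
#' z-scored across cells, the first principal component of that submatrix is
#' extracted, its direction is fixed using `root_spec`, and the oriented
#' scores are rank-transformed onto \[0, 100\] (average ranks for ties).
#'
#' @param em normalized [expression_matrix()].
#' @param ordering_genes gene identifiers defining the trajectory signal; at
#'   least 10 must be present in the matrix.
#' @param root_spec either a [gene_module()] whose high scorers mark the
#'   early end of the trajectory, or a character vector of root cell
#'   identifiers.
#' @return A `PseudotimeAssignment`: list with `cell`, `t` (on \[0, 100\]),
#'   `bin` (`NA` until [bin_pseudotime()]), `n_bins`, and
#'   `orientation_evidence` (the signed score used to fix the direction).
#' @export
infer_pseudotime <- function(em, ordering_genes, root_spec) {
  check_kind(em, "normalized", "infer_pseudotime")
  shared <- intersect(ordering_genes, em$gene_ids)
  if (length(shared) < 10L) {
    stop_(sprintf("only %d ordering genes found in the matrix; need >= 10",
                  length(shared)))
  }
  x <- as_dense(em[, shared])
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0L) stop_("ordering-gene submatrix is constant; no signal to order on")
  z <- scale(x)
  pc1 <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = 1)$x[, 1]
  if (inherits(root_spec, "GeneModule")) {
    root_genes <- intersect(root_spec$genes, colnames(z))
    if (!length(root_genes)) {
      stop_(sprintf("root module '%s' shares no genes with the ordering set",
                    root_spec$name))
    }
    root_score <- rowMeans(z[, root_genes, drop = FALSE])
    evidence <- stats::cor(pc1, root_score)
  } else {
    root_cells <- intersect(as.character(root_spec), em$row_ids)
    if (!length(root_cells)) stop_("no root cells found in the matrix")
    evidence <- mean(pc1[match(root_cells, em$row_ids)]) - stats::median(pc1)
  }
  # root (high root-module scorers, or the root cells) must sit at low t
  if (is.finite(evidence) && evidence > 0) pc1 <- -pc1
  n <- length(pc1)
  t <- 100 * (rank(pc1, ties.method = "average") - 1) / (n - 1)
  structure(list(cell = em$row_ids, t = t, bin = rep(NA_integer_, n),
                 n_bins = NA_integer_, orientation_evidence = evidence),
            class = "PseudotimeAssignment")
}

#' @method print PseudotimeAssignment
#' @export
print.PseudotimeAssignment <- function(x, ...) {
  cat(sprintf("PseudotimeAssignment: %d cells%s\n", length(x$cell),
              if (is.na(x$n_bins)) " (unbinned)"
              else sprintf(", %d bins", x$n_bins)))
  invisible(x)
}

#' Bin cells into equal-count pseudotime groups
#'
#' Cells ordered by t (ties broken by lexicographic cell identifier) are
#' split into `n_bins` contiguous groups whose sizes differ by at most one;
#' the bin index increases with t.
#'
#' @param pt a `PseudotimeAssignment` from [infer_pseudotime()].
#' @param n_bins number of groups (default 100); requires at least as many
#'   cells as bins.
#' @return The assignment with `bin` and `n_bins` filled in.
#' @export
bin_pseudotime <- function(pt, n_bins = 100) {
  n_bins <- check_count(n_bins, "n_bins", lower = 2L)
  n <- length(pt$cell)
  if (n < n_bins) {
    stop_(sprintf("cannot form %d bins from %d cells", n_bins, n))
  }
  ord <- order(pt$t, pt$cell)
  sizes <- diff(floor((0:n_bins) * n / n_bins))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  pt$bin <- bin
  pt$n_bins <- n_bins
  pt
}

subset_pseudotime <- function(pt, idx, cells = NULL) {
  structure(list(cell = cells %||% pt$cell[idx], t = pt$t[idx],
                 bin = pt$bin[idx], n_bins = pt$n_bins,
                 orientation_evidence = pt$orientation_evidence),
            class = "PseudotimeAssignment")
}

#' Score gene modules per cell and per pseudotime bin
#'
#' The per-cell score of a module is the mean, over the module genes present
#' in the matrix, of the gene-wise z-scored normalized expression; per-bin
#' scores are means over member cells. Bin centroids (per-bin mean
#' normalized expression over the union of module genes) are retained for
#' reference building and projection.
#'
#' With `control_genes` supplied, the per-cell mean normalized expression of
#' the control set is subtracted from every gene's normalized expression
#' before z-scoring (a control-set correction in the spirit of Seurat's
#' AddModuleScore). Library-size normalization couples every gene to the
#' total transcriptional output, so when the trajectory shifts transcriptome
#' composition all log-CPM values share a smooth pseudotime trend;
#' subtracting a progression-independent control set removes that shared
#' trend (exactly so in the noiseless limit) and de-biases the fitted event
#' times.
#'
#' @param em normalized [expression_matrix()].
#' @param modules list of [gene_module()] objects; each must share at least
#'   one gene with the matrix.
#' @param pt binned `PseudotimeAssignment` covering the same cells.
#' @param control_genes optional gene identifiers used as a control set
#'   (default `NULL`: plain z-score means).
#' @return A `BinProfile`: list with `bins`, `module_scores`
#'   (n_bins x modules), `bin_centroids` (n_bins x union genes),
#'   `cells_per_bin`, and `cell_scores` (data frame: cell, t, bin, one
#'   column per module).
#' @export
score_modules <- function(em, modules, pt, control_genes = NULL) {
  check_kind(em, "normalized", "score_modules")
  if (is.na(pt$n_bins)) stop_("pseudotime must be binned first (bin_pseudotime)")
  if (!identical(pt$cell, em$row_ids)) {
    stop_("pseudotime cells do not match the matrix rows")
  }
  shared <- lapply(modules, function(m) intersect(m$genes, em$gene_ids))
  empty <- vapply(shared, length, integer(1)) == 0L
  if (any(empty)) {
    stop_(sprintf("module(s) with no genes in the matrix: %s",
                  paste(vapply(modules[empty], `[[`, character(1), "name"),
                        collapse = ", ")))
  }
  union_genes <- unique(unlist(shared, use.names = FALSE))
  ctrl <- intersect(control_genes %||% character(0), em$gene_ids)
  ctrl <- setdiff(ctrl, union_genes)
  x <- as_dense(em[, union_genes])
  xs <- x
  if (length(ctrl)) {
    ctrl_mean <- Matrix::rowMeans(em$values[, ctrl, drop = FALSE])
    xs <- x - ctrl_mean               # remove the shared library-size trend
  }
  mu <- colMeans(xs)
  sd <- apply(xs, 2, stats::sd)
  sd[sd == 0] <- 1                     # flat genes contribute zero, not NaN
  z <- sweep(sweep(xs, 2, mu), 2, sd, "/")
  cell_scores <- vapply(shared, function(g) {
    rowMeans(z[, g, drop = FALSE])
  }, numeric(nrow(z)))
  mod_names <- vapply(modules, `[[`, character(1), "name")
  colnames(cell_scores) <- mod_names
  binf <- factor(pt$bin, levels = seq_len(pt$n_bins))
  n_per_bin <- as.integer(table(binf))
  bin_scores <- rowsum(cell_scores, binf) / n_per_bin
  centroids <- rowsum(x[, union_genes, drop = FALSE], binf) / n_per_bin
  cs <- data.frame(cell = pt$cell, t = pt$t, bin = pt$bin,
                   stringsAsFactors = FALSE)
  cs[mod_names] <- as.data.frame(cell_scores)
  structure(list(bins = seq_len(pt$n_bins), module_scores = bin_scores,
                 bin_centroids = centroids, cells_per_bin = n_per_bin,
                 cell_scores = cs),
            class = "BinProfile")
}

#' @method print BinProfile
#' @export
print.BinProfile <- function(x, ...) {
  cat(sprintf("BinProfile: %d bins x %d modules (%d centroid genes)\n",
              length(x$bins), ncol(x$module_scores), ncol(x$bin_centroids)))
  invisible(x)
}
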