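#' Read a Matrix Market triplet directory
#'
#' Reads `matrix.mtx` together with its `barcodes.tsv` and `features.tsv`
#' sidecars. The returned matrix is always oriented rows = cells, columns =
#' genes regardless of the on-disk orientation: the orientation is inferred
#' from the sidecar lengths (the CellRanger convention of genes x cells is
#' detected and transposed). Entries must be non-negative integers.
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return An [expression_matrix()] of kind `"counts"`.
#' @export
read_mtx_triplet <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_(sprintf("missing file(s): %s", paste(basename(missing), collapse = ", ")))
  }
  m <- Matrix::readMM(paths[1])
  barcodes <- readLines(paths[2], warn = FALSE)
  feat_raw <- readLines(paths[3], warn = FALSE)
  features <- vapply(strsplit(feat_raw, "\t", fixed = TRUE), `[[`, character(1), 1L)
  nb <- length(barcodes); nf <- length(features)
  if (nrow(m) == nf && ncol(m) == nb) {
    m <- Matrix::t(m)                       # genes x cells on disk
  } else if (!(nrow(m) == nb && ncol(m) == nf)) {
    bad <- if (nb != nrow(m) && nb != ncol(m)) "barcodes.tsv" else "features.tsv"
    stop_(sprintf("%s length does not match matrix.mtx dimensions (%d x %d; %d barcodes, %d features)",
                  bad, nrow(m), ncol(m), nb, nf))
  }
  if (any(abs(m@x - round(m@x)) > 1e-8)) {
    stop_("matrix.mtx contains non-integer entries; counts expected")
  }
  expression_matrix(methods::as(m, "CsparseMatrix"),
                    row_ids = barcodes, gene_ids = features, kind = "counts")
}

#' Write an ExpressionMatrix as a Matrix Market triplet directory
#'
#' Written in the CellRanger orientation (genes x cells on disk);
#' [read_mtx_triplet()] inverts this exactly.
#'
#' @param em an [expression_matrix()] of kind `"counts"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx_triplet <- function(em, dir) {
  check_kind(em, "counts", "write_mtx_triplet")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- methods::as(Matrix::t(Matrix::Matrix(em$values, sparse = TRUE)),
                    "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(em$row_ids, file.path(dir, "barcodes.tsv"))
  writeLines(em$gene_ids, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a clinical cohort CSV
#'
#' Expects columns `sample_id`, `nuclear_fraction`, `stage`, `time`, `event`
#' (extra columns, e.g. a 5mC measurement, are passed through unmodified).
#' Each sample is classified into one of the four TET2-localization
#' categories via [classify_sample()].
#'
#' @param path path to a CSV file.
#' @param thresholds classification cut points passed to [classify_sample()].
#' @return A data frame of cohort records with an added `category` column.
#' @export
read_cohort_csv <- function(path, thresholds = c(0.1, 0.5, 0.9)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "nuclear_fraction", "stage", "time", "event")
  absent <- setdiff(required, names(df))
  if (length(absent)) {
    stop_(sprintf("missing column(s) %s; required columns are: %s",
                  paste(absent, collapse = ", "), paste(required, collapse = ", ")))
  }
  f <- as.numeric(df$nuclear_fraction)
  bad <- which(!is.finite(f) | f < 0 | f > 1)
  if (length(bad)) {
    stop_(sprintf("nuclear_fraction outside [0, 1] for sample(s): %s",
                  paste(df$sample_id[bad], collapse = ", ")))
  }
  tm <- as.numeric(df$time)
  bad <- which(!is.finite(tm) | tm < 0)
  if (length(bad)) {
    stop_(sprintf("negative or missing survival time for sample(s): %s",
                  paste(df$sample_id[bad], collapse = ", ")))
  }
  ev <- as.integer(df$event)
  if (any(!ev %in% c(0L, 1L))) {
    stop_("'event' column must contain only 0 and 1")
  }
  df$nuclear_fraction <- f
  df$time <- tm
  df$event <- ev
  df$category <- classify_sample(f, thresholds = thresholds)
  df
}

#' Load and validate a pipeline configuration from JSON
#'
#' Unknown keys are rejected (with a nearest-name suggestion); omitted keys
#' are filled with the package defaults of [default_config()].
#'
#' @param path path to a JSON file. An empty object (`{}`) yields the full
#'   default configuration.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(user)) stop_("config must be a JSON object")
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(defaults))
      cand <- names(defaults)[which.min(d)]
      if (min(d) <= 3) sprintf("'%s' (did you mean '%s'?)", k, cand)
      else sprintf("'%s'", k)
    }, character(1))
    stop_(sprintf("unknown config key(s): %s", paste(hints, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  validate_config(cfg)
}
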