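#' Named gene set
#'
#' A gene module is a named, duplicate-free list of gene identifiers with a
#' free-text provenance note (e.g. the KEGG map it was drawn from). Gene
#' identifier matching throughout the package is case-sensitive exact string
#' match, so that mapping bugs fail loudly instead of being papered over by
#' case folding.
#'
#' @param name module identifier, e.g. `"WNT_TARGETS"`.
#' @param genes character vector of gene identifiers; duplicates are removed
#'   with a warning.
#' @param provenance free text recording where the set came from.
#' @return A `GeneModule` object.
#' @export
gene_module <- function(name, genes, provenance = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_("module 'name' must be a non-empty string")
  }
  genes <- as.character(genes)
  if (length(genes) == 0L) stop_(sprintf("module '%s' has an empty gene list", name))
  if (anyDuplicated(genes)) {
    warning(sprintf("module '%s': duplicate genes removed", name), call. = FALSE)
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "GeneModule")
}

#' @method print GeneModule
#' @export
print.GeneModule <- function(x, ...) {
  cat(sprintf("GeneModule '%s': %d genes (%s)\n", x$name, length(x$genes),
              if (nzchar(x$provenance)) x$provenance else "no provenance"))
  invisible(x)
}

#' Read gene modules from a GMT file
#'
#' One module per tab-separated line: name, description, then gene names.
#' The description field is kept as the module's provenance.
#'
#' @param path path to a GMT file.
#' @return Named list of [gene_module()] objects (empty list for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  mods <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                    i, length(fields)))
    }
    mods[[i]] <- gene_module(fields[1], fields[-(1:2)], provenance = fields[2])
  }
  names(mods) <- vapply(mods, `[[`, character(1), "name")
  mods
}

#' Write gene modules to a GMT file
#'
#' @param modules list of [gene_module()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    paste(c(m$name, if (nzchar(m$provenance)) m$provenance else "NA", m$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

module_union <- function(modules) {
  unique(unlist(lapply(modules, `[[`, "genes"), use.names = FALSE))
}
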