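#' Pathway catalogs
#'
#' A `PathwayCatalog` is a named collection of gene sets (one per metabolic
#' pathway or sub-pathway) together with the minimum number of measured genes
#' a set must retain to be eligible for rank testing. Gene symbols are matched
#' case-insensitively after whitespace trimming, because array annotation
#' tables and RNA-seq gene models disagree on symbol case more often than on
#' the symbols themselves.
#'
#' @name PathwayCatalog
#' @keywords internal
NULL

.norm_symbol <- function(x) toupper(trimws(x))

#' Construct a pathway catalog
#'
#' @param pathways named list; each element a character vector of gene symbols.
#' @param descriptions optional named character vector of free-text descriptions.
#' @param min_testable_genes minimum (post-intersection) gene count for a
#'   pathway to enter rank tests. Default 6: sets with fewer than 6 genes are
#'   excluded from Wilcoxon testing.
#' @return a `PathwayCatalog` object.
#' @export
pathway_catalog <- function(pathways, descriptions = NULL,
                            min_testable_genes = 6L) {
  stopifnot(is.list(pathways))
  nm <- names(pathways)
  if (length(pathways) && (is.null(nm) || any(!nzchar(nm))))
    stop("every pathway must have a non-empty name")
  if (anyDuplicated(nm))
    stop("duplicate pathway name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!is.numeric(min_testable_genes) || min_testable_genes < 1)
    stop("min_testable_genes must be >= 1")
  pw <- lapply(seq_along(pathways), function(i) {
    g <- .norm_symbol(as.character(pathways[[i]]))
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning(sprintf("pathway '%s': %d duplicate gene symbol(s) removed",
                      nm[i], sum(duplicated(g))), call. = FALSE)
      g <- unique(g)
    }
    list(name = nm[i],
         genes = g,
         description = if (!is.null(descriptions) && nm[i] %in% names(descriptions))
           unname(descriptions[nm[i]]) else "",
         coverage = NA_real_,
         empty = length(g) == 0L)
  })
  names(pw) <- nm
  structure(list(pathways = pw,
                 min_testable_genes = as.integer(min_testable_genes)),
            class = "PathwayCatalog")
}

#' @export
print.PathwayCatalog <- function(x, ...) {
  sizes <- pathway_sizes(x)
  if (length(sizes) == 0) {
    cat("PathwayCatalog: empty\n")
    return(invisible(x))
  }
  cat(sprintf("PathwayCatalog: %d pathways, gene-set sizes %d-%d (testable floor %d)\n",
              length(sizes), min(sizes), max(sizes), x$min_testable_genes))
  invisible(x)
}

#' Pathway names and sizes
#' @param catalog a `PathwayCatalog`.
#' @return `pathway_names`: character vector; `pathway_sizes`: named integer
#'   vector of gene counts.
#' @export
pathway_names <- function(catalog) {
  stopifnot(inherits(catalog, "PathwayCatalog"))
  names(catalog$pathways)
}

#' @rdname pathway_names
#' @export
pathway_sizes <- function(catalog) {
  stopifnot(inherits(catalog, "PathwayCatalog"))
  vapply(catalog$pathways, function(p) length(p$genes), integer(1))
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set format: one set per line, fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate symbols within a
#' line are dropped with a warning; a duplicate set name is an error.
#'
#' @param path path to a UTF-8 GMT file.
#' @param min_testable_genes passed to [pathway_catalog()].
#' @return a `PathwayCatalog`.
#' @export
load_gmt <- function(path, min_testable_genes = 6L) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d in '%s': fewer than 3 tab-separated fields",
                 bad[1], path))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate pathway name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  names(desc) <- nm
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  pathway_catalog(sets, descriptions = desc,
                  min_testable_genes = min_testable_genes)
}

#' Write a catalog back to GMT
#' @param catalog a `PathwayCatalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "PathwayCatalog"))
  lines <- vapply(catalog$pathways, function(p) {
    paste(c(p$name, if (nzchar(p$description)) p$description else "na",
            p$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' The bundled 23-pathway metabolic catalog
#'
#' Loads the package's reconstructed catalog of 23 metabolic
#' pathways/sub-pathways (glycolysis through oxidative-phosphorylation
#' complexes, choline and proline metabolism, one-carbon metabolism). The
#' gene memberships are a synthetic reconstruction assembled from standard
#' pathway references -- they are deliberate stand-ins, not the curation any
#' particular study used -- and the file name carries a `synthetic` marker
#' for that reason.
#'
#' @inheritParams load_gmt
#' @return a `PathwayCatalog` with 23 pathways.
#' @export
default_catalog <- function(min_testable_genes = 6L) {
  load_gmt(system.file("extdata", "metabolic_pathways_23.synthetic.gmt",
                       package = "mpathscore", mustWork = TRUE),
           min_testable_genes = min_testable_genes)
}

#' Restrict a catalog to measured genes
#'
#' Replaces each pathway's gene set by its intersection with the genes present
#' in an expression matrix, recording per-pathway coverage. Pathways left with
#' zero genes are retained but flagged empty (they are excluded later by the
#' scoring step).
#'
#' @param catalog a `PathwayCatalog`.
#' @param measured_genes character vector of measured gene symbols (or an
#'   `ExpressionMatrix`, from which gene names are taken).
#' @return a `PathwayCatalog` with intersected sets and `coverage` filled in.
#' @export
intersect_with_matrix <- function(catalog, measured_genes) {
  stopifnot(inherits(catalog, "PathwayCatalog"))
  if (inherits(measured_genes, "ExpressionMatrix"))
    measured_genes <- rownames(measured_genes$values)
  measured <- .norm_symbol(as.character(measured_genes))
  if (length(measured) == 0) stop("measured_genes is empty")
  catalog$pathways <- lapply(catalog$pathways, function(p) {
    kept <- p$genes[p$genes %in% measured]
    p$coverage <- if (length(p$genes)) length(kept) / length(p$genes) else 0
    p$genes <- kept
    p$empty <- length(kept) == 0L
    p
  })
  catalog
}

#' Per-pathway coverage after intersection
#' @param catalog an intersected `PathwayCatalog`.
#' @return named numeric vector, fraction of each original set still measured.
#' @export
pathway_coverage <- function(catalog) {
  stopifnot(inherits(catalog, "PathwayCatalog"))
  vapply(catalog$pathways, function(p) p$coverage, numeric(1))
}

#' Pathways eligible for rank testing
#'
#' Returns the pathways whose (post-intersection) gene count is at least
#' `min_testable_genes`; sets with fewer genes are not tested.
#'
#' @param catalog a `PathwayCatalog`.
#' @return character vector of pathway names.
#' @export
testable <- function(catalog) {
  stopifnot(inherits(catalog, "PathwayCatalog"))
  sz <- pathway_sizes(catalog)
  names(sz)[sz >= catalog$min_testable_genes]
}
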