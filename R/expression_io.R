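#' Expression matrices and sample annotations
#'
#' An `ExpressionMatrix` wraps a gene-by-sample numeric matrix with a platform
#' tag (`"counts"` for RNA-seq raw counts, `"continuous"` for array-type
#' intensities or already-normalized values) and a `normalized` flag. Missing
#' values are not supported: the downstream mean/SD machinery has no defined
#' NA policy, so any NA cell is rejected at construction.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param platform `"counts"` or `"continuous"`.
#' @param normalized logical flag carried through the normalization steps.
#' @param collapse_duplicates how to handle duplicate gene symbols:
#'   `"max_mean"` keeps the row with the highest mean signal (the usual
#'   multi-probe-per-gene convention on arrays), `"error"` refuses.
#' @return an `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, platform = c("continuous", "counts"),
                              normalized = FALSE,
                              collapse_duplicates = c("max_mean", "error")) {
  platform <- match.arg(platform)
  collapse_duplicates <- match.arg(collapse_duplicates)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("NA cell at gene '%s', sample '%s': missing values are not supported",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  rownames(values) <- .norm_symbol(rownames(values))
  if (anyDuplicated(rownames(values))) {
    if (collapse_duplicates == "error") stop("duplicate gene symbols present")
    n_dup <- sum(duplicated(rownames(values)))
    means <- rowMeans(values)
    ord <- order(rownames(values), -means)
    values <- values[ord, , drop = FALSE][!duplicated(rownames(values)[ord]), , drop = FALSE]
    warning(sprintf("%d duplicate gene row(s) collapsed (kept highest-mean row)", n_dup),
            call. = FALSE)
  }
  if (platform == "counts" && !normalized) {
    if (any(values < 0)) stop("counts platform requires non-negative values")
    if (any(abs(values - round(values)) > 1e-8))
      stop("counts platform requires integer values before normalization")
  }
  structure(list(values = values, platform = platform, normalized = normalized),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s%s]\n",
              nrow(x$values), ncol(x$values), x$platform,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read a gene-by-sample TSV expression matrix
#'
#' Expects a header row of sample ids and a first column of gene symbols.
#' Duplicate gene rows are collapsed to the highest-mean row with a warning.
#'
#' @param path TSV file path.
#' @param platform `"counts"` or `"continuous"`.
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(path, platform = c("continuous", "counts")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >=1 sample column")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, ncol = ncol(vals), dimnames = dimnames(vals))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                 idx[1], genes[idx[1]], colnames(vals)[idx[2]]))
  }
  rownames(num) <- genes
  expression_matrix(num, platform = platform)
}

#' Write an expression matrix as TSV
#' @param matrix an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.group_aliases <- c(benign = "benign", b = "benign", normal = "benign",
                    control = "benign",
                    tumour = "tumour", tumor = "tumour", t = "tumour",
                    cancer = "tumour", carcinoma = "tumour")

#' Read a sample-annotation table
#'
#' TSV with required columns `sample_id` and `group` (benign/tumour, with the
#' usual aliases `B`/`T`/`normal`/`cancer` accepted) and optional columns
#' `cohort`, `pair_id`, `time` (months to event or censoring), `event`
#' (0/1/yes/no), and `stage` (ordinal). A row recording an event without a
#' time is rejected; negative times are rejected.
#'
#' @param path TSV file path.
#' @return a data.frame with columns sample_id, group, cohort, pair_id,
#'   time, event, stage.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  sample_annotations(df)
}

#' Validate/normalize an annotation data.frame
#' @param df data.frame with at least sample_id and group columns.
#' @return normalized annotation data.frame.
#' @export
sample_annotations <- function(df) {
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s) in annotations")
  grp_raw <- tolower(trimws(as.character(df$group)))
  unknown <- setdiff(unique(grp_raw), names(.group_aliases))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         " (expected benign/tumour or an alias)")
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    group = unname(.group_aliases[grp_raw]),
    cohort = if ("cohort" %in% names(df)) as.character(df$cohort) else NA_character_,
    pair_id = if ("pair_id" %in% names(df)) as.character(df$pair_id) else NA_character_,
    time = if ("time" %in% names(df)) suppressWarnings(as.numeric(df$time)) else NA_real_,
    event = NA, stage = if ("stage" %in% names(df))
      suppressWarnings(as.numeric(df$stage)) else NA_real_,
    stringsAsFactors = FALSE)
  if ("event" %in% names(df)) {
    ev <- tolower(trimws(as.character(df$event)))
    ev[ev %in% c("", "na")] <- NA
    map <- c("1" = TRUE, "0" = FALSE, yes = TRUE, no = FALSE,
             "true" = TRUE, "false" = FALSE, y = TRUE, n = FALSE)
    bad <- setdiff(unique(ev[!is.na(ev)]), names(map))
    if (length(bad)) stop("unparseable event value(s): ", paste(bad, collapse = ", "))
    out$event <- unname(map[ev])
  } else out$event <- NA
  if (any(!is.na(out$time) & out$time < 0)) stop("negative time_to_event")
  orphan <- !is.na(out$event) & out$event & is.na(out$time)
  if (any(orphan))
    stop("sample(s) with event recorded but no time: ",
         paste(out$sample_id[orphan], collapse = ", "))
  out
}

#' Align a matrix and its annotations on shared samples
#'
#' Restricts both to the intersection of their sample ids, in matrix column
#' order, reporting dropped ids via message.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @return list with elements `matrix` and `annotations`.
#' @export
align_samples <- function(matrix, annotations) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  shared <- intersect(colnames(matrix$values), annotations$sample_id)
  if (length(shared) == 0) stop("no samples shared between matrix and annotations")
  dropped <- c(setdiff(colnames(matrix$values), shared),
               setdiff(annotations$sample_id, shared))
  if (length(dropped))
    message("align_samples: dropped ", length(dropped), " unmatched sample id(s): ",
            paste(dropped, collapse = ", "))
  keep <- colnames(matrix$values)[colnames(matrix$values) %in% shared]
  matrix$values <- matrix$values[, keep, drop = FALSE]
  ann <- annotations[match(keep, annotations$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(matrix = matrix, annotations = ann)
}
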