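#' Quantile normalization
#'
#' Forces every sample (column) onto the identical empirical distribution:
#' the value at rank r in each sample is replaced by the mean, across
#' samples, of their rank-r values. Ties within a sample receive the mean of
#' the replacement values their rank span covers (the usual published
#' convention; scanner software tie rules are undocumented, so this one is
#' stated and tested).
#'
#' @param matrix an `ExpressionMatrix` with `platform = "continuous"` and at
#'   least 2 samples.
#' @return the normalized `ExpressionMatrix` (`normalized = TRUE`).
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$platform != "continuous")
    stop("quantile_normalize expects continuous platform (normalize counts with size factors)")
  x <- matrix$values
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(x, 2, sort))   # mean across samples at each ascending rank
  out <- apply(x, 2, function(col) {
    ord <- order(col)
    grp <- cumsum(!duplicated(col[ord]))       # tie groups along the sorted column
    res <- numeric(length(col))
    res[ord] <- stats::ave(ref, grp)           # tie span gets the mean of its ref values
    res
  })
  dimnames(out) <- dimnames(x)
  matrix$values <- out
  matrix$normalized <- TRUE
  matrix
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over genes with a
#' positive geometric mean across samples, of that sample's count divided by
#' the gene's geometric mean. This is the size-factor normalization RNA-seq
#' count pipelines use to remove sequencing-depth differences before any
#' cross-sample comparison.
#'
#' Factors are returned as raw medians by default. `unit_geomean = TRUE`
#' rescales them to geometric mean 1; because downstream z-scoring is
#' location/scale-normalized per gene, the convention cannot change pathway
#' scores (asserted in the test suite).
#'
#' @param matrix an `ExpressionMatrix` with `platform = "counts"`.
#' @param unit_geomean rescale factors to geometric mean 1.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(matrix, unit_geomean = FALSE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$platform != "counts")
    stop("size_factors expects counts platform")
  x <- matrix$values
  log_gm <- rowMeans(log(x))            # -Inf for genes with any zero
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no gene has positive counts in all samples; consider adding a pseudo-count")
  f <- apply(x[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_gm[use])))
  if (unit_geomean) f <- f / exp(mean(log(f)))
  f
}

#' Divide a count matrix by its size factors
#'
#' @param matrix an `ExpressionMatrix` (counts).
#' @param factors named factor vector from [size_factors()]; must cover every
#'   sample.
#' @return an `ExpressionMatrix`, platform `"continuous"` (counts-derived),
#'   `normalized = TRUE`.
#' @export
apply_size_factors <- function(matrix, factors) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  miss <- setdiff(colnames(matrix$values), names(factors))
  if (length(miss)) stop("size factors missing for sample(s): ",
                         paste(miss, collapse = ", "))
  if (any(factors <= 0)) stop("size factors must be positive")
  matrix$values <- sweep(matrix$values, 2,
                         factors[colnames(matrix$values)], "/")
  matrix$platform <- "continuous"
  matrix$normalized <- TRUE
  matrix
}

#' Elementwise log2 transform
#'
#' @param matrix an `ExpressionMatrix`.
#' @param pseudocount non-negative offset added before taking log2
#'   (default 1, the usual choice for normalized counts).
#' @return transformed `ExpressionMatrix`.
#' @export
log2_transform <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (any(matrix$values + pseudocount <= 0))
    stop("log2 of non-positive value; increase the pseudocount")
  matrix$values <- log2(matrix$values + pseudocount)
  matrix$platform <- "continuous"
  matrix
}
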