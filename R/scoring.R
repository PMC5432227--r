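#' Reference-anchored per-gene z-scores
#'
#' The central statistic: each gene's expression is standardized against the
#' mean and SD of a reference population, and pathway activity per sample is
#' then the average of these z-scores over the pathway's genes.
#'
#' Two reference schemes are supported, matching the two study designs the
#' method serves:
#' \describe{
#'   \item{`"cohort"`}{mean/SD of all tumour samples in the cohort. Used when
#'     there is no benign arm (e.g. a xenograft panel); scores read as
#'     deviation from the tumour average.}
#'   \item{`"benign"`}{mean/SD of the benign samples. Used for tumour-vs-benign
#'     cohorts; scores read as deviation from normal tissue.}
#' }
#'
#' The SD uses the n-1 (sample) denominator, appropriate for the small
#' reference sets these designs have (a dozen tumours, a few dozen benign).
#' Genes whose reference SD is zero carry no standardizable information and
#' are dropped with a message.
#'
#' @param matrix an `ExpressionMatrix` (normalized, continuous scale).
#' @param annotations annotation data.frame aligned to the matrix (see
#'   [align_samples()]).
#' @param scheme `"cohort"` or `"benign"`.
#' @return a `ZScoreMatrix`: genes x samples z-value matrix plus the scheme
#'   and the reference sample ids.
#' @export
zscore <- function(matrix, annotations, scheme = c("cohort", "benign")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  x <- matrix$values
  if (!all(colnames(x) %in% annotations$sample_id))
    stop("annotations do not cover all matrix samples; run align_samples() first")
  grp <- annotations$group[match(colnames(x), annotations$sample_id)]
  ref_ids <- if (scheme == "cohort") colnames(x)[grp == "tumour"]
             else colnames(x)[grp == "benign"]
  if (length(ref_ids) < 2)
    stop(sprintf("reference scheme '%s' needs >= 2 reference samples, found %d",
                 scheme, length(ref_ids)))
  ref <- x[, ref_ids, drop = FALSE]
  m <- rowMeans(ref)
  s <- apply(ref, 1, stats::sd)
  keep <- s > 0
  if (!all(keep)) {
    message("zscore: dropped ", sum(!keep),
            " gene(s) with zero reference SD: ",
            paste(utils::head(rownames(x)[!keep], 10), collapse = ", "),
            if (sum(!keep) > 10) ", ..." else "")
    x <- x[keep, , drop = FALSE]; m <- m[keep]; s <- s[keep]
  }
  z <- (x - m) / s
  structure(list(z = z, scheme = scheme, reference_sample_ids = ref_ids),
            class = "ZScoreMatrix")
}

#' @export
print.ZScoreMatrix <- function(x, ...) {
  cat(sprintf("ZScoreMatrix: %d genes x %d samples, %s-referenced (%d reference samples)\n",
              nrow(x$z), ncol(x$z), x$scheme, length(x$reference_sample_ids)))
  invisible(x)
}

#' Average z-scores into pathway scores
#'
#' For each sample and pathway, the score is the arithmetic mean of the
#' sample's z-scores over the pathway's measured genes. Pathways with no
#' measured genes are excluded (with a message) rather than reported as NA.
#'
#' @param z a `ZScoreMatrix`.
#' @param catalog a `PathwayCatalog`; it is intersected with the z-matrix
#'   genes automatically.
#' @return a `PathwayScoreMatrix`: samples x pathways score matrix, with the
#'   per-pathway measured gene counts, the scheme, and the reference ids.
#' @export
pathway_scores <- function(z, catalog) {
  stopifnot(inherits(z, "ZScoreMatrix"), inherits(catalog, "PathwayCatalog"))
  rownames(z$z) <- .norm_symbol(rownames(z$z))
  catalog <- intersect_with_matrix(catalog, rownames(z$z))
  sz <- pathway_sizes(catalog)
  empty <- names(sz)[sz == 0]
  if (length(empty))
    message("pathway_scores: excluded pathway(s) with no measured genes: ",
            paste(empty, collapse = ", "))
  keep <- names(sz)[sz > 0]
  if (length(keep) == 0) stop("no pathway has any measured gene")
  scores <- vapply(keep, function(p) {
    g <- catalog$pathways[[p]]$genes
    colMeans(z$z[g, , drop = FALSE])
  }, numeric(ncol(z$z)))
  scores <- matrix(scores, nrow = ncol(z$z), ncol = length(keep),
                   dimnames = list(colnames(z$z), keep))
  structure(list(scores = scores, n_genes = sz[keep], scheme = z$scheme,
                 reference_sample_ids = z$reference_sample_ids,
                 catalog = catalog),
            class = "PathwayScoreMatrix")
}

#' @export
print.PathwayScoreMatrix <- function(x, ...) {
  cat(sprintf("PathwayScoreMatrix: %d samples x %d pathways (%s-referenced)\n",
              nrow(x$scores), ncol(x$scores), x$scheme))
  invisible(x)
}

#' Re-standardize pathway scores against the benign score distribution
#'
#' Averaging z-scores shrinks the score SD below 1 (for m independent genes,
#' toward 1/sqrt(m)), so a raw +/-2 cut on averaged z would be nearly
#' unattainable. Outlier calling therefore measures each pathway score in
#' units of the reference samples' own score distribution: subtract the
#' reference-sample score mean and divide by their score SD, per pathway.
#'
#' @param scores a `PathwayScoreMatrix`.
#' @return a `PathwayScoreMatrix` with re-standardized scores
#'   (`restandardized = TRUE` attribute).
#' @export
restandardize_scores <- function(scores) {
  stopifnot(inherits(scores, "PathwayScoreMatrix"))
  ref <- scores$scores[scores$reference_sample_ids, , drop = FALSE]
  m <- colMeans(ref)
  s <- apply(ref, 2, stats::sd)
  if (any(s == 0)) stop("zero reference-score SD for pathway(s): ",
                        paste(colnames(ref)[s == 0], collapse = ", "))
  scores$scores <- sweep(sweep(scores$scores, 2, m), 2, s, "/")
  scores$restandardized <- TRUE
  scores
}

#' Call per-sample pathway outliers at a strict SD threshold
#'
#' A tumour is an "up" outlier for a pathway when its score exceeds
#' `+threshold_sd` and a "down" outlier below `-threshold_sd`, strict
#' inequalities (a score sitting exactly on the boundary is `none`). The
#' conventional threshold is 2 SD relative to controls; accordingly scores
#' are first re-standardized against the benign score distribution
#' ([restandardize_scores()]) unless `rescale = FALSE` requests the raw
#' averaged-z scale.
#'
#' @param scores a `PathwayScoreMatrix` computed under the benign scheme.
#' @param annotations annotation data.frame (outliers are called for tumour
#'   samples only).
#' @param threshold_sd positive threshold, default 2.
#' @param rescale re-standardize against the benign score distribution first
#'   (default TRUE; see Details in [restandardize_scores()]).
#' @return data.frame with columns sample_id, pathway, score (on the scale
#'   thresholded), direction (`"up"`, `"down"`, `"none"`), threshold_sd.
#' @export
flag_outliers <- function(scores, annotations, threshold_sd = 2,
                          rescale = TRUE) {
  stopifnot(inherits(scores, "PathwayScoreMatrix"), threshold_sd > 0)
  if (rescale && !isTRUE(scores$restandardized))
    scores <- restandardize_scores(scores)
  tum <- annotations$sample_id[annotations$group == "tumour"]
  tum <- intersect(rownames(scores$scores), tum)
  if (length(tum) == 0) stop("no tumour samples to call outliers on")
  s <- scores$scores[tum, , drop = FALSE]
  out <- data.frame(
    sample_id = rep(rownames(s), times = ncol(s)),
    pathway = rep(colnames(s), each = nrow(s)),
    score = as.vector(s),
    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$score > threshold_sd, "up",
                          ifelse(out$score < -threshold_sd, "down", "none"))
  out$threshold_sd <- threshold_sd
  out
}
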