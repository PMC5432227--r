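#' Two-sample Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Rank-sum test of `x` (e.g. tumour pathway scores) versus `y` (benign).
#' For combined sample size at most `exact_max` the null distribution is
#' obtained by enumerating every assignment of the pooled mid-ranks to the
#' two groups; the two-sided p-value is the probability, over assignments,
#' that the rank-sum deviates from its null mean at least as much as
#' observed (tie-safe, since mid-ranks are enumerated as pooled). Larger
#' samples use the normal approximation with tie correction and a 0.5
#' continuity correction.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max largest combined n for exact enumeration (default 12).
#' @return list: `statistic` (rank-sum W of `x`), `p_value`, `method`
#'   ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                       # mid-ranks handle ties
  w <- sum(r[seq_len(n1)])
  ew <- n1 * (N + 1) / 2
  if (N <= exact_max) {
    idx <- utils::combn(N, n1)
    ws <- colSums(matrix(r[idx], nrow = n1))
    p <- mean(abs(ws - ew) >= abs(w - ew) - 1e-9)
    list(statistic = w, p_value = p, method = "exact")
  } else {
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) return(list(statistic = w, p_value = 1, method = "normal"))
    d <- w - ew
    d <- sign(d) * max(0, abs(d) - 0.5)    # continuity correction toward the mean
    p <- min(1, 2 * stats::pnorm(-abs(d) / sqrt(sig2)))
    list(statistic = w, p_value = p, method = "normal")
  }
}

#' Pathway-level Wilcoxon rank tests, tumour versus benign
#'
#' For each pathway whose measured gene count meets the testable floor
#' (default: at least 6 genes; smaller sets are reported `not tested`), the
#' per-sample pathway scores of the tumour group are compared with those of
#' the benign group by [wilcoxon_rank_sum()]. A pathway is called
#' upregulated/downregulated when p < alpha, with the direction given by the
#' sign of (tumour median - benign median).
#'
#' @param scores a `PathwayScoreMatrix` (benign-referenced scores are the
#'   usual input, but any scheme is accepted).
#' @param annotations aligned annotation data.frame.
#' @param alpha significance level for the direction call (default 0.05).
#' @param adjust `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjusted p-values used in the direction call.
#' @return data.frame: pathway, test, statistic, p_value, direction
#'   (upregulated/downregulated/ns/not tested), n_genes, n_tumour, n_benign.
#' @export
wilcoxon_pathway_test <- function(scores, annotations, alpha = 0.05,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(scores, "PathwayScoreMatrix"))
  grp <- annotations$group[match(rownames(scores$scores), annotations$sample_id)]
  if (!any(grp == "tumour") || !any(grp == "benign"))
    stop("both a tumour and a benign group are required")
  floorn <- scores$catalog$min_testable_genes
  res <- lapply(colnames(scores$scores), function(p) {
    ng <- scores$n_genes[[p]]
    row <- data.frame(pathway = p, test = "wilcoxon", statistic = NA_real_,
                      p_value = NA_real_, direction = "not tested",
                      n_genes = ng, n_tumour = sum(grp == "tumour"),
                      n_benign = sum(grp == "benign"),
                      stringsAsFactors = FALSE)
    if (ng < floorn) return(row)
    tu <- scores$scores[grp == "tumour", p]
    be <- scores$scores[grp == "benign", p]
    wt <- wilcoxon_rank_sum(tu, be)
    row$statistic <- wt$statistic
    row$p_value <- wt$p_value
    row$direction <- "ns"
    row
  })
  out <- do.call(rbind, res)
  p_eff <- out$p_value
  if (adjust == "BH") p_eff <- stats::p.adjust(p_eff, method = "BH")
  tested <- !is.na(out$p_value)
  sig <- tested & p_eff < alpha
  if (any(sig)) {
    meddiff <- vapply(out$pathway[sig], function(p) {
      stats::median(scores$scores[grp == "tumour", p]) -
        stats::median(scores$scores[grp == "benign", p])
    }, numeric(1))
    out$direction[sig] <- ifelse(meddiff > 0, "upregulated",
                                 ifelse(meddiff < 0, "downregulated", "ns"))
  }
  if (adjust == "BH") out$p_adjusted <- p_eff
  out
}

#' Pathway-level Welch t-tests on log2 expression
#'
#' For each pathway (no gene floor here; the floor applies to rank tests
#' only), each sample is summarized as the mean log2 expression of the
#' pathway's measured genes, and tumour vs benign summaries are compared by
#' Welch's unequal-variance t-test. Degenerate zero-variance cases are
#' resolved by an equality check: identical group values give p = 1, a
#' noiseless shift is an error the caller should not be silently handed.
#'
#' @param matrix a log2-scale `ExpressionMatrix`.
#' @param catalog a `PathwayCatalog`.
#' @param annotations aligned annotation data.frame.
#' @param alpha significance level for the direction call.
#' @return data.frame in the same shape as [wilcoxon_pathway_test()].
#' @export
ttest_pathway <- function(matrix, catalog, annotations, alpha = 0.05) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(catalog, "PathwayCatalog"))
  catalog <- intersect_with_matrix(catalog, rownames(matrix$values))
  grp <- annotations$group[match(colnames(matrix$values), annotations$sample_id)]
  if (sum(grp == "tumour") < 2 || sum(grp == "benign") < 2)
    stop("Welch t-test needs >= 2 samples in each group")
  sz <- pathway_sizes(catalog)
  keep <- names(sz)[sz > 0]
  res <- lapply(keep, function(p) {
    g <- catalog$pathways[[p]]$genes
    summ <- colMeans(matrix$values[g, , drop = FALSE])
    tu <- summ[grp == "tumour"]; be <- summ[grp == "benign"]
    if (stats::sd(tu) == 0 && stats::sd(be) == 0) {
      if (isTRUE(all.equal(mean(tu), mean(be)))) {
        tt <- list(statistic = 0, p.value = 1)
      } else stop(sprintf(
        "pathway '%s': zero variance in both groups with unequal means; t-test undefined", p))
    } else {
      tt <- stats::t.test(tu, be, var.equal = FALSE)
    }
    dir <- if (tt$p.value < alpha) {
      if (mean(tu) > mean(be)) "upregulated" else "downregulated"
    } else "ns"
    data.frame(pathway = p, test = "t", statistic = unname(tt$statistic),
               p_value = tt$p.value, direction = dir, n_genes = sz[[p]],
               n_tumour = sum(grp == "tumour"), n_benign = sum(grp == "benign"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Inter-tumour heterogeneity summary
#'
#' Dispersion of tumour pathway scores per pathway: SD, IQR, range, and the
#' fraction of tumours whose re-standardized score magnitude exceeds 1
#' benign-SD. Rows are sorted by SD descending, so the most heterogeneous
#' pathways lead.
#'
#' @param scores a `PathwayScoreMatrix`.
#' @param annotations aligned annotation data.frame.
#' @return data.frame: pathway, sd, iqr, range, frac_beyond_1sd.
#' @export
heterogeneity_summary <- function(scores, annotations) {
  stopifnot(inherits(scores, "PathwayScoreMatrix"))
  tum <- annotations$sample_id[annotations$group == "tumour"]
  tum <- intersect(rownames(scores$scores), tum)
  if (length(tum) < 2) stop("need >= 2 tumour samples")
  s <- scores$scores[tum, , drop = FALSE]
  rs <- tryCatch(restandardize_scores(scores)$scores[tum, , drop = FALSE],
                 error = function(e) s * NA)
  out <- data.frame(
    pathway = colnames(s),
    sd = apply(s, 2, stats::sd),
    iqr = apply(s, 2, stats::IQR),
    range = apply(s, 2, function(v) diff(range(v))),
    frac_beyond_1sd = colMeans(abs(rs) > 1),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$sd), , drop = FALSE]
}
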