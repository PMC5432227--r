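#' Survival datasets
#'
#' A small validated container for right-censored two-group survival data:
#' per sample a follow-up time (months), an event flag (e.g. biochemical
#' recurrence or death), and a stratum label. Ties between an event and a
#' censoring at the same time are resolved events-first (the standard
#' convention: the censored subject is still at risk at that event time).
#'
#' @param time non-negative numeric vector (months).
#' @param event logical (or 0/1) event indicator.
#' @param stratum stratum label per sample.
#' @param sample_id optional ids.
#' @param horizon optional administrative-censoring horizon in months (e.g.
#'   60 for a 5-year analysis): events/follow-up beyond it are censored at
#'   the horizon.
#' @return a `SurvivalDataset` data.frame.
#' @export
survival_dataset <- function(time, event, stratum, sample_id = NULL,
                             horizon = NULL) {
  time <- as.numeric(time); event <- as.logical(event)
  if (any(is.na(time)) || any(is.na(event))) stop("time/event must be complete")
  if (any(time < 0)) stop("negative survival time")
  if (length(time) != length(event) || length(time) != length(stratum))
    stop("time, event, stratum lengths differ")
  if (!is.null(horizon)) {
    event <- event & time <= horizon
    time <- pmin(time, horizon)
  }
  out <- data.frame(
    sample_id = if (is.null(sample_id)) paste0("s", seq_along(time)) else sample_id,
    time = time, event = event, stratum = as.character(stratum),
    stringsAsFactors = FALSE)
  class(out) <- c("SurvivalDataset", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' For each stratum, S(t) is the product over distinct event times t_i <= t
#' of (1 - d_i/n_i), with d_i events among the n_i subjects still at risk;
#' subjects censored exactly at an event time count as at risk there.
#'
#' @param data a `SurvivalDataset`.
#' @return named list (one element per stratum) of data.frames with columns
#'   time, n_risk, n_event, n_censor, surv (rows at all distinct observed
#'   times; `surv` steps only at event times).
#' @export
km_estimate <- function(data) {
  stopifnot(inherits(data, "SurvivalDataset"))
  if (!any(data$event))
    warning("no events observed: all survival curves are flat at 1")
  lapply(split(data, data$stratum), function(d) {
    tt <- sort(unique(d$time))
    n_risk <- vapply(tt, function(t) sum(d$time >= t), numeric(1))
    n_event <- vapply(tt, function(t) sum(d$time == t & d$event), numeric(1))
    n_censor <- vapply(tt, function(t) sum(d$time == t & !d$event), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(time = tt, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, surv = surv)
  })
}

#' Weighted two-group log-rank tests (Mantel-Cox, Gehan-Breslow)
#'
#' At each distinct event time j, with n_1j at risk in group 1 of n_j total
#' and d_j events overall, the observed minus hypergeometric-expected events
#' in group 1 is O_j - E_j = d_1j - d_j n_1j / n_j with variance
#' V_j = d_j (n_1j/n_j) (1 - n_1j/n_j) (n_j - d_j) / (n_j - 1). The test
#' statistic is (sum w_j (O_j - E_j))^2 / (sum w_j^2 V_j), chi-square with
#' 1 df. Mantel-Cox uses w_j = 1; Gehan-Breslow weights each event time by
#' the total number at risk (w_j = n_j), making it sensitive to early
#' differences.
#'
#' @param data a `SurvivalDataset` with exactly 2 strata and >= 1 event.
#' @param weights `"mantel_cox"` (default) or `"gehan_breslow"`.
#' @return list: test, chi_square, df (= 1), p_value, observed/expected per
#'   stratum.
#' @export
logrank_test <- function(data, weights = c("mantel_cox", "gehan_breslow")) {
  weights <- match.arg(weights)
  stopifnot(inherits(data, "SurvivalDataset"))
  strata <- sort(unique(data$stratum))
  if (length(strata) != 2) stop("logrank_test needs exactly 2 strata, found ",
                                length(strata))
  if (!any(data$event)) stop("no events: test undefined")
  g1 <- data$stratum == strata[1]
  et <- sort(unique(data$time[data$event]))
  num <- 0; den <- 0; o1 <- 0; e1 <- 0
  for (t in et) {
    at <- data$time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(data$time == t & data$event)
    d1 <- sum(data$time == t & data$event & g1)
    e <- d * n1 / n
    v <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    w <- if (weights == "mantel_cox") 1 else n
    num <- num + w * (d1 - e)
    den <- den + w^2 * v
    o1 <- o1 + d1; e1 <- e1 + e
  }
  chi <- if (den > 0) num^2 / den else 0
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  list(test = weights, chi_square = chi, df = 1L, p_value = p,
       strata = strata,
       observed = c(o1, sum(data$event) - o1),
       expected = c(e1, sum(data$event) - e1))
}

#' Stratify tumours by pathway outlier status
#'
#' Splits tumour samples into the outliers of a pathway (in the requested
#' direction, at the threshold used in the calls) versus all other tumours,
#' carrying their survival fields. `split = "median"` or `"tertile"` are
#' provided as alternative expression-split designs (high half / top tertile
#' versus the rest by score, same direction semantics).
#'
#' @param outliers outlier data.frame from [flag_outliers()].
#' @param pathway pathway name.
#' @param direction `"up"` or `"down"`.
#' @param annotations annotation data.frame with time/event for all tumours.
#' @param split `"outlier"` (default), `"median"`, or `"tertile"`.
#' @param horizon optional censoring horizon (months), see
#'   [survival_dataset()].
#' @return a `SurvivalDataset` with strata `"outlier"` and `"rest"`.
#' @export
stratify_by_outlier <- function(outliers, pathway, direction = c("up", "down"),
                                annotations, split = c("outlier", "median", "tertile"),
                                horizon = NULL) {
  direction <- match.arg(direction)
  split <- match.arg(split)
  oc <- outliers[outliers$pathway == pathway, , drop = FALSE]
  if (nrow(oc) == 0) stop("no outlier calls for pathway: ", pathway)
  ann <- annotations[match(oc$sample_id, annotations$sample_id), , drop = FALSE]
  if (any(is.na(ann$time)) || any(is.na(ann$event)))
    stop("survival fields missing for some tumour samples")
  flag <- switch(split,
    outlier = oc$direction == direction,
    median = if (direction == "up") oc$score > stats::median(oc$score)
             else oc$score < stats::median(oc$score),
    tertile = if (direction == "up")
                oc$score > stats::quantile(oc$score, 2 / 3)
              else oc$score < stats::quantile(oc$score, 1 / 3))
  if (!any(flag) || all(flag))
    stop(sprintf("stratification degenerate for '%s' (%d of %d flagged); test undefined",
                 pathway, sum(flag), length(flag)))
  survival_dataset(ann$time, ann$event,
                   ifelse(flag, "outlier", "rest"),
                   sample_id = oc$sample_id, horizon = horizon)
}

#' Tie-corrected Spearman correlation with small-n exact p-value
#'
#' rho is the Pearson correlation of mid-ranks (tie-corrected by
#' construction). For n <= `exact_max` the two-sided p-value is exact by
#' enumerating all permutations of one rank vector; larger n uses the
#' t-approximation with n-2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, length >= 4.
#' @param exact_max largest n for exact enumeration (default 8).
#' @return list: rho, p_value, method.
#' @export
spearman_correlation <- function(x, y, exact_max = 8L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- (matrix(rxc[perms], nrow = nrow(perms)) %*% ryc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, method = "exact")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    list(rho = rho, p_value = min(1, p), method = "t")
  }
}

# all permutations of 1..n as a matrix (n! x n); n <= 8 keeps this small
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Pathway score versus ordinal stage
#'
#' Convenience wrapper joining one pathway's scores to an ordinal stage
#' annotation and running [spearman_correlation()].
#'
#' @param scores a `PathwayScoreMatrix`.
#' @param pathway pathway name.
#' @param annotations annotation data.frame with a `stage` column.
#' @return list: rho, p_value, method, n.
#' @export
stage_correlation <- function(scores, pathway, annotations) {
  stopifnot(inherits(scores, "PathwayScoreMatrix"))
  s <- scores$scores[, pathway]
  st <- annotations$stage[match(rownames(scores$scores), annotations$sample_id)]
  ok <- !is.na(st)
  res <- spearman_correlation(s[ok], st[ok])
  res$n <- sum(ok)
  res
}
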