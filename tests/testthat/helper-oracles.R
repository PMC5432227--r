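# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles (enumeration, centroid algebra, counting) rather than
# calling the implementation paths they check.

# Exhaustive two-sided rank-sum p: enumerate every assignment of the pooled
# observations to a group of size n1, recompute the rank-sum from scratch for
# each, and count assignments at least as extreme (|W - E|) as observed.
oracle_wilcoxon_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); N <- length(pool)
  # midranks by counting, not rank(): r_i = #<x_i> below + (ties + 1)/2
  midrank <- vapply(pool, function(v)
    sum(pool < v) + (sum(pool == v) + 1) / 2, numeric(1))
  e <- n1 * (N + 1) / 2
  obs <- sum(midrank[seq_len(n1)])
  sets <- utils::combn(N, n1)
  ws <- apply(sets, 2, function(ix) sum(midrank[ix]))
  mean(abs(ws - e) >= abs(obs - e) - 1e-9)
}

# Exhaustive permutation p for the weighted log-rank statistic: the observed
# chi-square is referenced against all relabelings of subjects to strata.
# Mid-p convention: labelings tied with the observed statistic count half,
# the standard convention when comparing a discrete permutation null against
# a continuous approximation.
oracle_logrank_perm_p <- function(data, weights = "mantel_cox") {
  obs <- logrank_test(data, weights)$chi_square
  n1 <- sum(data$stratum == sort(unique(data$stratum))[1])
  sets <- utils::combn(nrow(data), n1)
  stats <- apply(sets, 2, function(ix) {
    d <- data
    d$stratum <- "b"; d$stratum[ix] <- "a"
    logrank_test(survival_dataset(d$time, d$event, d$stratum), weights)$chi_square
  })
  mean(stats > obs + 1e-9) + 0.5 * mean(abs(stats - obs) <= 1e-9)
}

# Fixed <=8-subject two-group survival battery: complete separation,
# censored interleaved, tied event/censor times, a paired shift, and two
# deep-null instances (crossing and near-exchangeable).
logrank_battery <- function() list(
  separation = list(t = c(1, 2, 3, 10, 11, 12), e = rep(TRUE, 6),
                    g = rep(c("a", "b"), each = 3)),
  censored   = list(t = c(1, 5, 2, 6, 3, 7, 4, 8),
                    e = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
                    g = rep(c("a", "b"), 4)),
  tied       = list(t = c(2, 2, 4, 4, 9, 9),
                    e = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                    g = rep(c("a", "b"), each = 3)),
  shift      = list(t = c(1, 4, 2, 5, 3, 6), e = rep(TRUE, 6),
                    g = rep(c("a", "b"), 3)),
  crossing   = list(t = c(1, 2, 8, 9, 3, 4, 6, 7),
                    e = c(TRUE, TRUE, TRUE, FALSE, rep(TRUE, 4)),
                    g = rep(c("a", "b"), each = 4)),
  null_like  = list(t = c(2, 3, 5, 7, 4, 6, 8, 10), e = rep(TRUE, 8),
                    g = rep(c("a", "b"), each = 4)))

# Greedy Ward agglomeration from centroid algebra: at each step merge the
# pair of clusters with the smallest increase in within-cluster sum of
# squares; report heights on the ward.D2 scale, sqrt(2 * delta-ESS).
oracle_ward_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) x[i, , drop = FALSE])
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      ni <- nrow(clusters[[i]]); nj <- nrow(clusters[[j]])
      ci <- colMeans(clusters[[i]]); cj <- colMeans(clusters[[j]])
      d_ess <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (d_ess < best_d) { best_d <- d_ess; best <- c(i, j) }
    }
    heights <- c(heights, sqrt(2 * best_d))
    clusters[[best[1]]] <- rbind(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Spearman rho from the covariance of counting-based midranks.
oracle_spearman_rho <- function(x, y) {
  mr <- function(v) vapply(v, function(a)
    sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
  rx <- mr(x); ry <- mr(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Adjusted Rand index between two partitions (closed-form from the
# contingency table); used to compare recovered clusters to planted truth.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(n) n * (n - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  expct <- si * sj / ch2(sum(tab))
  (sij - expct) / ((si + sj) / 2 - expct)
}
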