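test_that("exact rank-sum p matches the enumerated toy and the brute-force oracle", {
  wt <- wilcoxon_rank_sum(c(1, 2, 3), c(-1, 0))
  expect_equal(wt$statistic, 12)        # ranks 3+4+5
  expect_equal(wt$p_value, 0.2)         # 2/10 assignments as extreme
  expect_equal(wt$method, "exact")

  set.seed(41)
  for (rep in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq(-3, 3, 0.5), n1, replace = TRUE)  # replacement forces ties
    y <- sample(seq(-3, 3, 0.5), n2, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcoxon_p(x, y),
                 info = sprintf("rep %d", rep))
  }
})

test_that("identical groups give p = 1; exact and normal paths agree at n = 12", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(42)
  for (rep in 1:25) {
    x <- rnorm(6); y <- rnorm(6)
    pe <- wilcoxon_rank_sum(x, y, exact_max = 12)$p_value
    pn <- wilcoxon_rank_sum(x, y, exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.05)
  }
})

test_that("pathway Wilcoxon tests apply the gene floor and call directions", {
  set.seed(43)
  cfg <- synthetic_config(n_benign = 15, n_tumour = 15, n_genes = 33,
                          effects = list(SYNP01 = list(delta = 2)),
                          seed = 4301)
  sim <- simulate_cohort(cfg)
  sc <- pathway_scores(zscore(sim$matrix, sim$annotations, "benign"),
                       cfg$catalog)
  res <- wilcoxon_pathway_test(sc, sim$annotations)
  expect_equal(nrow(res), 4L)
  # SYNP04 has 5 genes: below the floor, reported but not tested
  p4 <- res[res$pathway == "SYNP04", ]
  expect_equal(p4$direction, "not tested")
  expect_true(is.na(p4$p_value))
  expect_equal(p4$n_genes, 5L)
  # the planted 2-SD shift on all tumours is found and called upregulated
  p1 <- res[res$pathway == "SYNP01", ]
  expect_lt(p1$p_value, 0.05)
  expect_equal(p1$direction, "upregulated")
  expect_equal(p1$n_tumour, 15L)
  expect_equal(p1$n_benign, 15L)

  down <- cfg
  res_bh <- wilcoxon_pathway_test(sc, sim$annotations, adjust = "BH")
  expect_true("p_adjusted" %in% names(res_bh))
  expect_true(all(res_bh$p_adjusted >= res_bh$p_value, na.rm = TRUE))

  solo <- sim$annotations[sim$annotations$group == "tumour", ]
  sc_t <- sc; sc_t$scores <- sc$scores[solo$sample_id, ]
  expect_error(wilcoxon_pathway_test(sc_t, solo), "benign")
})

test_that("Welch pathway t-test matches hand-computed values and handles degeneracy", {
  # single-gene pathway so per-sample summaries are the raw values:
  # x = {1,2,3}, y = {2,4,6} -> t = -2 / sqrt(1/3 + 4/3) = -1.549193
  vals <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 1,
                 dimnames = list("gX", sprintf("s%d", 1:6)))
  m <- expression_matrix(vals)
  ann <- make_annotations(colnames(vals), rep(c("tumour", "benign"), each = 3))
  cat <- pathway_catalog(list(P = "gX"))
  res <- ttest_pathway(m, cat, ann)
  expect_equal(res$statistic, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(-abs(-2 / sqrt(5 / 3)), df = (5 / 3)^2 / (17 / 18)),
               tolerance = 1e-9)
  expect_equal(res$direction, "ns")    # p ~ 0.22 at alpha 0.05

  # equal groups, nonzero variance -> t = 0, p = 1
  vals2 <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
                  dimnames = list("gX", sprintf("s%d", 1:6)))
  res2 <- ttest_pathway(expression_matrix(vals2), cat, ann)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$direction, "ns")

  # zero variance in both groups: equal means -> p 1; pure shift -> error
  flat <- matrix(rep(5, 6), nrow = 1, dimnames = list("gX", sprintf("s%d", 1:6)))
  expect_equal(ttest_pathway(expression_matrix(flat), cat, ann)$p_value, 1)
  shift <- matrix(rep(c(6, 5), each = 3), nrow = 1,
                  dimnames = list("gX", sprintf("s%d", 1:6)))
  expect_error(ttest_pathway(expression_matrix(shift), cat, ann),
               "zero variance")
})

test_that("a noiseless constant shift is called upregulated by the t path", {
  set.seed(44)
  base <- matrix(rnorm(40, 7), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  shifted <- base
  shifted[, 6:10] <- shifted[, 6:10] + 1.5
  ann <- make_annotations(colnames(base), rep(c("benign", "tumour"), each = 5))
  cat <- pathway_catalog(list(P = paste0("g", 1:4)))
  res <- ttest_pathway(expression_matrix(shifted), cat, ann)
  expect_equal(res$direction, "upregulated")
})

test_that("heterogeneity summary ranks the injected pathway first", {
  set.seed(45)
  cfg <- synthetic_config(n_benign = 20, n_tumour = 40, n_genes = 33,
                          effects = list(SYNP02 = list(delta = 3, fraction = 0.5)),
                          seed = 4501)
  sim <- simulate_cohort(cfg)
  sc <- pathway_scores(zscore(sim$matrix, sim$annotations, "benign"),
                       cfg$catalog)
  het <- heterogeneity_summary(sc, sim$annotations)
  expect_equal(nrow(het), ncol(sc$scores))
  expect_equal(het$pathway[1], "SYNP02")   # subgroup shift dominates the SD ranking
  expect_gt(het$sd[1], 1.5 * max(het$sd[-1]))
  expect_true(all(diff(het$sd) <= 0))
  expect_true(all(het$frac_beyond_1sd >= 0 & het$frac_beyond_1sd <= 1))

  flat_scores <- manual_scores(rbind(b1 = c(P = 0.3), b2 = c(P = -0.3),
                                     t1 = c(P = 1), t2 = c(P = 1)),
                               ref_ids = c("b1", "b2"))
  ann2 <- make_annotations(c("b1", "b2", "t1", "t2"),
                           c("benign", "benign", "tumour", "tumour"))
  expect_equal(heterogeneity_summary(flat_scores, ann2)$sd, 0)
})

test_that("detection power rises with effect size and pathway size", {
  set.seed(46)
  power_at <- function(delta, sizes, reps = 120) {
    mean(vapply(seq_len(reps), function(i) {
      cfg <- synthetic_config(n_benign = 12, n_tumour = 12,
                              n_genes = sum(sizes),
                              catalog = synthetic_catalog(sizes = sizes),
                              effects = list(SYNP01 = list(delta = delta)),
                              seed = 46000 + i + round(1000 * delta) * 7)
      sim <- simulate_cohort(cfg)
      sc <- pathway_scores(zscore(sim$matrix, sim$annotations, "benign"),
                           cfg$catalog)
      wilcoxon_pathway_test(sc, sim$annotations)$p_value[1] < 0.05
    }, logical(1)))
  }
  p_small <- power_at(0.3, c(10L, 6L))
  p_mid <- power_at(0.8, c(10L, 6L))
  p_big <- power_at(1.5, c(10L, 6L))
  expect_lte(p_small, p_mid + 0.05)
  expect_lte(p_mid, p_big + 0.05)
  expect_gt(p_big, p_small)
  # more genes average away noise -> higher power at a fixed effect
  p_6 <- power_at(0.6, c(6L, 6L))
  p_12 <- power_at(0.6, c(12L, 6L))
  expect_gt(p_12, p_6 - 0.05)
  expect_gt(p_big, 0.9)
})
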