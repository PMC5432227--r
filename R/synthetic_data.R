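#' Synthetic cohort configuration
#'
#' Describes the generative world the test suite assumes: a benign group and
#' a tumour group measured on a log-scale continuous platform (array-like)
#' or re-sampled through a Poisson layer (counts); per-gene baselines with
#' i.i.d. Gaussian sample noise; pathway-coherent additive shifts injected
#' into a tumour subgroup (inter-tumour heterogeneity); optional matched
#' pairs sharing a latent profile; survival times whose hazard depends on a
#' designated pathway's outlier truth, with independent censoring.
#'
#' Defaults emulate a benign-referenced validation cohort: 112 tumours and
#' 28 benign tissues, effects expressed in benign-SD units (noise_sd = 1),
#' exponential baseline hazard 0.02/month and 30% censoring.
#'
#' @param n_benign,n_tumour group sizes (defaults 28 and 112).
#' @param n_genes total measured genes; must cover the catalog's genes.
#' @param catalog `PathwayCatalog` over the synthetic gene universe; default
#'   [synthetic_catalog()].
#' @param effects named list: per affected pathway a list with `delta`
#'   (shift in benign-SD units) and `fraction` (affected tumour fraction in
#'   (0,1], default 1).
#' @param baseline_mean,baseline_sd log-scale per-gene baseline distribution
#'   (defaults 7 and 1.5, typical of log2 array intensities).
#' @param noise_sd per-sample i.i.d. noise SD on the log scale (default 1;
#'   this is the unit `delta` is expressed in).
#' @param pair_correlation within-pair correlation for matched pairs, in
#'   (0,1); NA for no pairs.
#' @param n_pairs number of matched pairs (each adds one extra paired sample
#'   duplicated from a tumour).
#' @param hazard baseline event hazard per month for non-outlier tumours.
#' @param hazard_ratio hazard multiplier for truth-outlier tumours.
#' @param censoring_rate expected fraction censored, in [0,1).
#' @param seed integer seed; mandatory, every draw is derived from it.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_benign = 28L, n_tumour = 112L, n_genes = 60L,
                             catalog = synthetic_catalog(),
                             effects = list(),
                             baseline_mean = 7, baseline_sd = 1.5,
                             noise_sd = 1,
                             pair_correlation = NA_real_, n_pairs = 0L,
                             hazard = 0.02, hazard_ratio = 1,
                             censoring_rate = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_benign >= 1, n_tumour >= 1, n_genes >= 1, noise_sd > 0,
            hazard > 0, hazard_ratio > 0,
            censoring_rate >= 0, censoring_rate < 1)
  bad <- setdiff(names(effects), pathway_names(catalog))
  if (length(bad)) stop("effect pathway(s) absent from catalog: ",
                        paste(bad, collapse = ", "))
  effects <- lapply(effects, function(e) {
    if (is.numeric(e) && is.null(names(e))) e <- list(delta = e)
    if (is.null(e$fraction)) e$fraction <- 1
    if (e$fraction <= 0 || e$fraction > 1) stop("effect fraction must be in (0,1]")
    e
  })
  n_cat_genes <- length(unique(unlist(lapply(catalog$pathways, `[[`, "genes"))))
  if (n_genes < n_cat_genes)
    stop("n_genes smaller than the catalog's gene universe")
  if (!is.na(pair_correlation) &&
      (pair_correlation <= 0 || pair_correlation >= 1))
    stop("pair_correlation must lie strictly inside (0,1)")
  structure(list(n_benign = as.integer(n_benign), n_tumour = as.integer(n_tumour),
                 n_genes = as.integer(n_genes), catalog = catalog,
                 effects = effects, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 pair_correlation = pair_correlation, n_pairs = as.integer(n_pairs),
                 hazard = hazard, hazard_ratio = hazard_ratio,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' A small synthetic pathway catalog
#'
#' Pathways named `SYNP01..` over a synthetic gene universe `G0001..`;
#' gene ids never collide with real symbols, keeping provenance obvious.
#'
#' @param sizes integer vector of pathway gene-set sizes (default: four
#'   pathways of 10, 10, 8 and 5 genes -- the 5-gene set deliberately sits
#'   below the default testable floor).
#' @param min_testable_genes passed through to [pathway_catalog()].
#' @return a `PathwayCatalog`.
#' @export
synthetic_catalog <- function(sizes = c(10L, 10L, 8L, 5L),
                              min_testable_genes = 6L) {
  start <- cumsum(c(1L, sizes))
  sets <- lapply(seq_along(sizes), function(i)
    sprintf("G%04d", seq(start[i], length.out = sizes[i])))
  names(sets) <- sprintf("SYNP%02d", seq_along(sizes))
  pathway_catalog(sets, min_testable_genes = min_testable_genes)
}

#' Simulate an expression cohort with planted pathway effects
#'
#' Benign samples are per-gene baseline plus noise. Tumour samples
#' additionally receive, for every configured effect, an additive shift of
#' `delta * noise_sd` on each gene of the affected pathway, applied to the
#' first `fraction` of tumour samples (the affected subgroup). The returned
#' truth record lists affected samples per pathway, so every planted effect
#' is recoverable downstream.
#'
#' @param config a `SyntheticConfig`.
#' @param platform `"continuous"` (default; log-scale array-like values) or
#'   `"counts"` (the same signal pushed through 2^x scaling and a Poisson
#'   draw, exercising the size-factor path).
#' @return list: `matrix` (`ExpressionMatrix`), `annotations` (data.frame),
#'   `truth` (list with per-pathway affected sample ids and deltas).
#' @export
simulate_cohort <- function(config, platform = c("continuous", "counts")) {
  platform <- match.arg(platform)
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  ids <- c(sprintf("B%03d", seq_len(config$n_benign)),
           sprintf("T%03d", seq_len(config$n_tumour)))
  group <- rep(c("benign", "tumour"), c(config$n_benign, config$n_tumour))
  baseline <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  x <- baseline + matrix(stats::rnorm(length(genes) * length(ids),
                                      sd = config$noise_sd),
                         nrow = length(genes))
  dimnames(x) <- list(genes, ids)
  truth <- list(effects = list(), config = config)
  tum_ids <- ids[group == "tumour"]
  for (p in names(config$effects)) {
    e <- config$effects[[p]]
    aff <- tum_ids[seq_len(max(1L, round(e$fraction * length(tum_ids))))]
    g <- config$catalog$pathways[[p]]$genes
    x[g, aff] <- x[g, aff] + e$delta * config$noise_sd
    truth$effects[[p]] <- list(delta = e$delta, affected_samples = aff)
  }
  if (platform == "counts") {
    lambda <- 2^(x - config$baseline_mean) * 100   # keep counts O(100)
    x <- matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda),
                dimnames = dimnames(lambda))
  }
  ann <- data.frame(sample_id = ids, group = group, cohort = "SYN",
                    pair_id = NA_character_, time = NA_real_, event = NA,
                    stage = NA_real_, stringsAsFactors = FALSE)
  list(matrix = expression_matrix(x, platform = platform),
       annotations = ann, truth = truth)
}

#' Simulate matched sample pairs
#'
#' Extends a simulated cohort with `n_pairs` matched partner samples (e.g.
#' xenograft lines matched to their source tumours): each partner mixes its
#' mate's noise profile with fresh noise so that the within-pair correlation
#' of the noise component equals `pair_correlation` in expectation
#' (partner = sqrt(rho) * mate + sqrt(1-rho) * fresh).
#'
#' @param config a `SyntheticConfig` with `pair_correlation` in (0,1) and
#'   `n_pairs >= 1`.
#' @param platform passed to [simulate_cohort()].
#' @return as [simulate_cohort()], with partner samples `P001..` and
#'   `pair_id` filled for both members of each pair.
#' @export
simulate_pairs <- function(config, platform = c("continuous", "counts")) {
  platform <- match.arg(platform)
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.na(config$pair_correlation))
    stop("pair_correlation must be set (strictly inside (0,1))")
  if (config$n_pairs < 1) stop("n_pairs must be >= 1")
  if (config$n_pairs > config$n_tumour)
    stop("more pairs than tumour samples")
  sim <- simulate_cohort(config, platform = "continuous")
  x <- sim$matrix$values
  baseline <- rowMeans(x[, sim$annotations$group == "benign", drop = FALSE])
  tum_ids <- sim$annotations$sample_id[sim$annotations$group == "tumour"]
  mates <- tum_ids[seq_len(config$n_pairs)]
  rho <- config$pair_correlation
  partners <- vapply(mates, function(id) {
    dev <- x[, id] - baseline
    baseline + sqrt(rho) * dev +
      sqrt(1 - rho) * stats::rnorm(nrow(x), sd = config$noise_sd)
  }, numeric(nrow(x)))
  colnames(partners) <- sprintf("P%03d", seq_len(config$n_pairs))
  xx <- cbind(x, partners)
  ann <- rbind(sim$annotations,
               data.frame(sample_id = colnames(partners), group = "tumour",
                          cohort = "SYN-PDX", pair_id = NA_character_,
                          time = NA_real_, event = NA, stage = NA_real_,
                          stringsAsFactors = FALSE))
  pid <- sprintf("pair%02d", seq_len(config$n_pairs))
  ann$pair_id[match(mates, ann$sample_id)] <- pid
  ann$pair_id[match(colnames(partners), ann$sample_id)] <- pid
  if (platform == "counts") {
    lambda <- 2^(xx - config$baseline_mean) * 100
    xx <- matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda),
                 dimnames = dimnames(lambda))
  }
  sim$matrix <- expression_matrix(xx, platform = platform)
  sim$annotations <- ann
  sim$truth$pairs <- data.frame(pair_id = pid, mate = mates,
                                partner = colnames(partners),
                                stringsAsFactors = FALSE)
  sim
}

#' Simulate outlier-dependent survival annotations
#'
#' Event times are exponential with hazard `hazard` for non-outlier tumours
#' and `hazard * hazard_ratio` for tumours flagged in the truth record (the
#' affected subgroup of `outlier_pathway`). Censoring times are independent
#' uniform on (0, c], with c solved per subject so each subject's censoring
#' probability equals `censoring_rate`.
#'
#' @param sim a cohort from [simulate_cohort()] / [simulate_pairs()].
#' @param outlier_pathway pathway whose planted effect defines the high-risk
#'   stratum; must be present in the truth record (or NULL for a null
#'   cohort, all tumours at baseline hazard).
#' @return `sim` with tumour `time`/`event` annotations filled and
#'   `truth$outlier_samples` recorded.
#' @export
simulate_survival <- function(sim, outlier_pathway = NULL) {
  config <- sim$truth$config
  tum <- sim$annotations$group == "tumour"
  n <- sum(tum)
  outl <- rep(FALSE, n)
  if (!is.null(outlier_pathway)) {
    if (is.null(sim$truth$effects[[outlier_pathway]]))
      stop("no planted effect for pathway: ", outlier_pathway)
    outl <- sim$annotations$sample_id[tum] %in%
      sim$truth$effects[[outlier_pathway]]$affected_samples
  }
  h <- config$hazard * ifelse(outl, config$hazard_ratio, 1)
  tev <- stats::rexp(n, rate = h)
  if (config$censoring_rate > 0) {
    cmax <- vapply(h, function(hh) {
      # P(C < T) for C ~ U(0,c), T ~ Exp(hh) is (1 - exp(-hh c)) / (hh c); solve for c
      f <- function(cc) (1 - exp(-hh * cc)) / (hh * cc) - config$censoring_rate
      stats::uniroot(f, c(1e-6, 1e6), tol = 1e-10)$root
    }, numeric(1))
    cens <- stats::runif(n, 0, cmax)
    ev <- tev <= cens
    tobs <- pmin(tev, cens)
  } else {
    ev <- rep(TRUE, n)
    tobs <- tev
  }
  sim$annotations$time[tum] <- tobs
  sim$annotations$event[tum] <- ev
  sim$truth$outlier_samples <- sim$annotations$sample_id[tum][outl]
  sim
}
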