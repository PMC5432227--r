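#' Assemble a pipeline run configuration
#'
#' Inputs may be given as file paths (TSV/GMT) or as in-memory objects, so
#' the same entry point serves the command line and programmatic use.
#'
#' @param expression path to an expression TSV or an `ExpressionMatrix`.
#' @param annotations path to an annotation TSV or a data.frame.
#' @param catalog path to a GMT file or a `PathwayCatalog`; NULL for the
#'   bundled 23-pathway catalog.
#' @param platform `"continuous"` or `"counts"` (ignored when `expression`
#'   is already an `ExpressionMatrix`).
#' @param reference z-score reference scheme, `"benign"` or `"cohort"`.
#' @param quantile quantile-normalize continuous input (default TRUE; set
#'   FALSE for matrices already normalized upstream).
#' @param threshold_sd outlier threshold (default 2).
#' @param alpha significance level (default 0.05).
#' @param distance,linkage clustering options, see [cluster_samples()].
#' @param survival_pathway,survival_direction optional: run the
#'   outlier-stratified survival analysis for this pathway/direction.
#' @param horizon optional censoring horizon in months.
#' @param out_dir output directory; created (with a timestamp + config-hash
#'   name) under `out_root` when NULL.
#' @param out_root parent for auto-named run directories (default tempdir()).
#' @param seed integer seed echoed into the run summary.
#' @return a `RunConfig` list.
#' @export
run_config <- function(expression, annotations, catalog = NULL,
                       platform = c("continuous", "counts"),
                       reference = c("benign", "cohort"),
                       quantile = TRUE,
                       threshold_sd = 2, alpha = 0.05,
                       distance = "euclidean", linkage = "average",
                       survival_pathway = NULL, survival_direction = "up",
                       horizon = NULL,
                       out_dir = NULL, out_root = tempdir(), seed = 1L) {
  platform <- match.arg(platform)
  reference <- match.arg(reference)
  for (p in Filter(is.character, list(expression, annotations, catalog)))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(expression = expression, annotations = annotations,
                 catalog = catalog, platform = platform, reference = reference,
                 quantile = quantile, threshold_sd = threshold_sd,
                 alpha = alpha, distance = distance, linkage = linkage,
                 survival_pathway = survival_pathway,
                 survival_direction = survival_direction, horizon = horizon,
                 out_dir = out_dir, out_root = out_root, seed = as.integer(seed)),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full scoring pipeline
#'
#' Sequence: load inputs, normalize (size factors + log2 for counts,
#' quantile for arrays), align samples, z-score against the configured
#' reference, average into pathway scores, rank/t tests, hierarchical
#' clustering with Newick export, outlier calls, and (when survival fields
#' and a target pathway are configured) outlier-stratified Kaplan-Meier
#' with Mantel-Cox and Gehan-Breslow tests. All tables are written as TSV
#' into the run directory plus a machine-readable `summary.json`; the run is
#' deterministic given the config and seed.
#'
#' @param config a `RunConfig` from [run_config()].
#' @return the run directory path, invisibly; the parsed summary is attached
#'   as attribute `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  mat <- .stage("read_expression",
    if (inherits(config$expression, "ExpressionMatrix")) config$expression
    else read_expression(config$expression, platform = config$platform))
  ann <- .stage("read_annotations",
    if (is.data.frame(config$annotations)) sample_annotations(config$annotations)
    else read_annotations(config$annotations))
  cat0 <- .stage("load_catalog",
    if (is.null(config$catalog)) default_catalog()
    else if (inherits(config$catalog, "PathwayCatalog")) config$catalog
    else load_gmt(config$catalog))

  out_dir <- config$out_dir
  if (is.null(out_dir)) {
    hash <- substr(paste(as.hexmode(utils::head(utf8ToInt(
      paste(config$reference, config$threshold_sd, config$seed)), 8)),
      collapse = ""), 1, 12)
    out_dir <- file.path(config$out_root,
                         paste0("run_", format(Sys.time(), "%Y%m%d-%H%M%S"),
                                "_", hash))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (mat$platform == "counts") {
    sf <- .stage("size_factors", size_factors(mat))
    note("size factors: %s", paste(sprintf("%s=%.4g", names(sf), sf), collapse = ", "))
    mat <- apply_size_factors(mat, sf)
    mat <- log2_transform(mat, pseudocount = 1)
  } else if (config$quantile && !mat$normalized) {
    mat <- .stage("quantile_normalize", quantile_normalize(mat))
    note("quantile normalized %d samples", ncol(mat$values))
  }

  al <- .stage("align", withCallingHandlers(
    align_samples(mat, ann),
    message = function(m) { note("%s", trimws(conditionMessage(m))); invokeRestart("muffleMessage") }))
  mat <- al$matrix; ann <- al$annotations

  z <- .stage("zscore", withCallingHandlers(
    zscore(mat, ann, scheme = config$reference),
    message = function(m) { note("%s", trimws(conditionMessage(m))); invokeRestart("muffleMessage") }))
  scores <- .stage("pathway_scores", withCallingHandlers(
    pathway_scores(z, cat0),
    message = function(m) { note("%s", trimws(conditionMessage(m))); invokeRestart("muffleMessage") }))
  utils::write.table(data.frame(sample_id = rownames(scores$scores),
                                scores$scores, check.names = FALSE),
                     file.path(out_dir, "pathway_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(seed = config$seed, reference = config$reference,
                  n_samples = ncol(mat$values), n_genes = nrow(mat$values),
                  n_pathways = ncol(scores$scores))

  has_benign <- any(ann$group == "benign")
  tests <- NULL
  if (has_benign && sum(ann$group == "tumour") >= 1) {
    tests <- .stage("group_tests", wilcoxon_pathway_test(scores, ann,
                                                         alpha = config$alpha))
    if (sum(ann$group == "benign") >= 2 && sum(ann$group == "tumour") >= 2) {
      tt <- .stage("ttest", ttest_pathway(mat, cat0, ann, alpha = config$alpha))
      tests <- rbind(tests, tt)
    }
    utils::write.table(tests, file.path(out_dir, "pathway_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_significant <- sum(tests$direction %in%
                                   c("upregulated", "downregulated"))
  }

  het <- .stage("heterogeneity",
    if (sum(ann$group == "tumour") >= 2) heterogeneity_summary(scores, ann) else NULL)
  if (!is.null(het))
    utils::write.table(het, file.path(out_dir, "heterogeneity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  dend <- .stage("clustering",
    cluster_samples(scores, distance = config$distance, linkage = config$linkage))
  write_newick(dend, file.path(out_dir, "dendrogram.newick"))
  k2 <- cut_dendrogram(dend, min(2L, length(dend$labels)))
  utils::write.table(data.frame(sample_id = names(k2), cluster = k2),
                     file.path(out_dir, "clusters_k2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dend$labels[dend$order],
                       file.path(out_dir, "leaf_order.json"))

  outliers <- NULL
  if (has_benign && config$reference == "benign") {
    outliers <- .stage("outliers",
      flag_outliers(scores, ann, threshold_sd = config$threshold_sd))
    utils::write.table(outliers, file.path(out_dir, "outlier_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_outlier_calls <- sum(outliers$direction != "none")
  }

  if (!is.null(config$survival_pathway) && !is.null(outliers) &&
      any(!is.na(ann$time))) {
    sdat <- .stage("stratify", stratify_by_outlier(
      outliers, config$survival_pathway, config$survival_direction,
      ann, horizon = config$horizon))
    km <- km_estimate(sdat)
    km_tab <- do.call(rbind, lapply(names(km), function(s)
      cbind(stratum = s, km[[s]])))
    utils::write.table(km_tab, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lr <- logrank_test(sdat, "mantel_cox")
    gb <- logrank_test(sdat, "gehan_breslow")
    summary$survival <- list(pathway = config$survival_pathway,
                             direction = config$survival_direction,
                             n_outlier = sum(sdat$stratum == "outlier"),
                             n_rest = sum(sdat$stratum == "rest"),
                             mantel_cox_p = lr$p_value,
                             gehan_breslow_p = gb$p_value)
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  saved_cfg <- config[!vapply(config, function(v)
    is.data.frame(v) || inherits(v, c("ExpressionMatrix", "PathwayCatalog")),
    logical(1))]
  jsonlite::write_json(saved_cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, force = TRUE)
  attr(out_dir, "summary") <- summary
  invisible(out_dir)
}
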