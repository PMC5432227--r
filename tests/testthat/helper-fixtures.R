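# Small in-code fixtures shared across test files.

make_matrix <- function(values, genes = NULL, samples = NULL,
                        platform = "continuous", ...) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, platform = platform, ...)
}

make_annotations <- function(sample_ids, groups, ...) {
  extra <- list(...)
  df <- data.frame(sample_id = sample_ids, group = groups,
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  sample_annotations(df)
}

# Benign/tumour toy: g1 has benign values 1,3 (mean 2, sd sqrt(2)); one
# tumour at 4 checks the hand-computed z of ~1.4142.
toy_cohort <- function() {
  vals <- rbind(G1 = c(1, 3, 4, 2),
                G2 = c(2, 2.5, 5, 1.5),
                G3 = c(10, 11, 9, 12))
  m <- make_matrix(vals, genes = rownames(vals),
                   samples = c("b1", "b2", "t1", "t2"))
  ann <- make_annotations(c("b1", "b2", "t1", "t2"),
                          c("benign", "benign", "tumour", "tumour"))
  list(matrix = m, annotations = ann)
}

# A PathwayScoreMatrix with chosen raw scores, for boundary tests.
manual_scores <- function(scores, ref_ids, scheme = "benign",
                          n_genes = rep(6L, ncol(scores))) {
  names(n_genes) <- colnames(scores)
  cat <- pathway_catalog(stats::setNames(
    lapply(seq_len(ncol(scores)), function(i) sprintf("x%d_%d", i, 1:6)),
    colnames(scores)))
  structure(list(scores = scores, n_genes = n_genes, scheme = scheme,
                 reference_sample_ids = ref_ids, catalog = cat),
            class = "PathwayScoreMatrix")
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
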