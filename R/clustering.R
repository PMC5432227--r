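#' Agglomerative hierarchical clustering of sample score profiles
#'
#' Bottom-up clustering of the samples-by-pathways score matrix, written with
#' an explicit deterministic tie rule so that dendrograms are reproducible
#' across platforms and input orderings: among merge candidates at exactly
#' the minimal distance, the pair whose (lexicographically smallest leaf
#' label, then second label) sorts first is merged. Cluster-cluster
#' distances are updated by the Lance-Williams recurrences; `ward` follows
#' the ward.D2 convention (heights on the original Euclidean scale, each
#' merge minimizing the increase in within-cluster sum of squares).
#'
#' @param scores a `PathwayScoreMatrix`, or a plain numeric matrix with rows
#'   as the objects to cluster.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r between
#'   row profiles).
#' @param linkage `"average"`, `"complete"`, `"ward"`, or `"single"`.
#' @return a `Dendrogram`: merge matrix (hclust convention), merge heights,
#'   leaf labels and leaf order.
#' @export
cluster_samples <- function(scores,
                            distance = c("euclidean", "correlation"),
                            linkage = c("average", "complete", "ward", "single")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- if (inherits(scores, "PathwayScoreMatrix")) scores$scores else scores
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("scores contain undefined values")
  n <- nrow(x)
  if (n < 2) stop("clustering needs >= 2 samples")
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  d <- if (distance == "euclidean") as.matrix(stats::dist(x))
       else 1 - stats::cor(t(x))
  diag(d) <- Inf

  size <- rep(1L, n)
  rep_lab <- labels                 # lexicographic representative per cluster
  node <- -seq_len(n)               # hclust code: negative leaf, positive merge
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    dm <- d[idx, idx, drop = FALSE]
    mn <- min(dm)
    cand <- which(dm == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on sorted representative label pairs
    key <- apply(cand, 1, function(rc) {
      pr <- sort(c(rep_lab[idx[rc[1]]], rep_lab[idx[rc[2]]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- idx[pick[1]]; j <- idx[pick[2]]

    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- mn
    ni <- size[i]; nj <- size[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- size[k]
      d[i, k] <- d[k, i] <- switch(linkage,
        average  = (ni * d[i, k] + nj * d[j, k]) / (ni + nj),
        complete = max(d[i, k], d[j, k]),
        single   = min(d[i, k], d[j, k]),
        ward     = sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                           nk * mn^2) / (ni + nj + nk)))
    }
    size[i] <- ni + nj
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    node[i] <- step
    active[j] <- FALSE
    d[j, ] <- d[, j] <- Inf
  }

  ord <- integer(0)
  expand <- function(m) {
    if (m < 0) return(-m)
    c(expand(merge[m, 1]), expand(merge[m, 2]))
  }
  ord <- expand(n - 1L)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, distance = distance, linkage = linkage),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d leaves, %s distance, %s linkage, heights %.4g-%.4g\n",
              length(x$labels), x$distance, x$linkage,
              min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a Dendrogram to a base-R hclust object
#' @param dendrogram a `Dendrogram`.
#' @return an object of class `hclust`.
#' @export
as_hclust <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "Dendrogram"))
  structure(list(merge = dendrogram$merge, height = dendrogram$height,
                 order = dendrogram$order, labels = dendrogram$labels,
                 method = dendrogram$linkage,
                 dist.method = dendrogram$distance,
                 call = match.call()),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges (with nondecreasing merge heights this is
#' the last k-1 agglomerations) and returns the resulting partition.
#'
#' @param dendrogram a `Dendrogram`.
#' @param k number of clusters, 1..n_samples.
#' @return named integer vector of cluster labels (1..k), named by sample,
#'   numbered by first appearance in leaf order.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "Dendrogram"))
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples")
  grp <- -seq_len(n)                         # provisional: cluster id per leaf
  if (n - k >= 1) {
    memb <- vector("list", n - 1L)
    for (m in seq_len(n - k)) {
      pull <- function(e) if (e < 0) -e else memb[[e]]
      memb[[m]] <- c(pull(dendrogram$merge[m, 1]), pull(dendrogram$merge[m, 2]))
      grp[memb[[m]]] <- m
    }
  }
  # renumber 1..k by first appearance along the leaf order
  first <- grp[dendrogram$order]
  lab <- match(grp, unique(first))
  names(lab) <- dendrogram$labels
  lab
}

#' Fraction of annotated pairs that are mutual nearest leaves
#'
#' A pair is "adjacent" when its two members merge with each other before
#' either merges with any third sample, i.e. some agglomeration joins
#' exactly those two singletons. Used to quantify how faithfully matched
#' xenograft/patient pairs co-cluster.
#'
#' @param dendrogram a `Dendrogram`.
#' @param pairs data.frame with columns `sample_id` and `pair_id`, or a named
#'   list of length-2 sample-id vectors.
#' @return list: `per_pair` named logical vector, `fraction` of adjacent pairs.
#' @export
pair_adjacency <- function(dendrogram, pairs) {
  stopifnot(inherits(dendrogram, "Dendrogram"))
  if (is.data.frame(pairs)) {
    pr <- pairs[!is.na(pairs$pair_id), , drop = FALSE]
    pairs <- split(pr$sample_id, pr$pair_id)
  }
  pairs <- pairs[vapply(pairs, length, integer(1)) == 2L]
  if (length(pairs) == 0) stop("no complete (size-2) pairs supplied")
  leaf <- function(id) {
    w <- match(id, dendrogram$labels)
    if (is.na(w)) stop("pair member missing from tree: ", id)
    w
  }
  flags <- vapply(pairs, function(p) {
    a <- -leaf(p[1]); b <- -leaf(p[2])
    any(dendrogram$merge[, 1] == min(a, b) & dendrogram$merge[, 2] == max(a, b))
  }, logical(1))
  list(per_pair = flags, fraction = mean(flags))
}

#' Export a dendrogram to Newick
#'
#' Branch lengths follow the merge heights (ultrametric tree).
#'
#' @param dendrogram a `Dendrogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(as_hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cophenetic distance matrix of a dendrogram
#' @param dendrogram a `Dendrogram`.
#' @return symmetric matrix of heights at which sample pairs first co-cluster.
#' @export
cophenetic_distances <- function(dendrogram) {
  as.matrix(stats::cophenetic(as_hclust(dendrogram)))
}
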