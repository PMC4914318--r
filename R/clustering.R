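#' UPGMA clustering of samples on Pearson correlation distance
#'
#' Hierarchical clustering of the samples (columns) of an expression matrix
#' restricted to a signature's miRNAs, with distance \eqn{d = 1 - r}
#' (Pearson correlation between sample profiles) and average (UPGMA)
#' linkage. Ties in the minimum inter-cluster distance are broken
#' deterministically by lexicographic pair order on the smallest original
#' sample index of each cluster, so the merge history is reproducible.
#'
#' @param values Numeric matrix (miRNA x sample), at least two samples,
#'   each with non-zero variance.
#' @return A \code{mirna_dendrogram}: list with hclust-style \code{merge},
#'   \code{height}, \code{order}, \code{labels}.
#' @export
pearson_average_hclust <- function(values) {
  n <- ncol(values)
  if (n < 2L) stop("need at least two samples")
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample: ", colnames(values)[which(sds == 0)[1L]])
  d <- 1 - stats::cor(values)
  labels <- colnames(values)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters: hclust-style code (negative leaf / positive merge id),
  # size, smallest original leaf index (tie-break key)
  code <- -seq_len(n)
  size <- rep(1L, n)
  minleaf <- seq_len(n)
  active <- rep(TRUE, n + 0L)
  dm <- d
  diag(dm) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; best_d <- Inf
    for (ii in seq_len(length(idx) - 1L)) for (jj in (ii + 1L):length(idx)) {
      i <- idx[ii]; j <- idx[jj]
      dij <- dm[i, j]
      key <- sort(c(minleaf[i], minleaf[j]))
      if (dij < best_d - 1e-12 ||
          (abs(dij - best_d) <= 1e-12 && !is.null(best) &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
        best <- list(i = i, j = j, key = key); best_d <- dij
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- best_d
    # Lance-Williams update for average linkage
    for (k in which(active)) if (k != i && k != j) {
      dk <- (size[i] * dm[i, k] + size[j] * dm[j, k]) / (size[i] + size[j])
      dm[i, k] <- dk; dm[k, i] <- dk
    }
    active[j] <- FALSE
    code[i] <- step
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
  }

  ord <- dendro_leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average",
                 dist.method = "pearson"),
            class = "mirna_dendrogram")
}

dendro_leaf_order <- function(merge, n) {
  expand <- function(code) {
    if (code < 0L) return(-code)
    c(expand(merge[code, 1L]), expand(merge[code, 2L]))
  }
  expand(n - 1L)
}

#' @export
print.mirna_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram of", length(x$labels),
      "samples (Pearson correlation distance)\n")
  invisible(x)
}

#' Convert to a base-R hclust object
#'
#' @param x A \code{mirna_dendrogram}.
#' @param ... Unused.
#' @return An \code{hclust} object.
#' @export
as.hclust.mirna_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 dist.method = x$dist.method,
                 call = match.call()),
            class = "hclust")
}

#' @export
plot.mirna_dendrogram <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
}

#' Cut a dendrogram into k clusters
#'
#' Cuts below the (k-1)-th largest merge, i.e. applies only the first
#' \eqn{n - k} merges. Cluster ids are numbered by first sample occurrence
#' in the original column order.
#'
#' @param dendro A \code{mirna_dendrogram}.
#' @param k Number of clusters, between 1 and the number of samples.
#' @return Named integer vector, sample to cluster id in 1..k.
#' @export
cut_clusters <- function(dendro, k) {
  n <- length(dendro$labels)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  grp <- seq_len(n)
  if (n - k >= 1L) {
    cluster_members <- vector("list", n - 1L)
    for (step in seq_len(n - k)) {
      members <- unlist(lapply(dendro$merge[step, ], function(code)
        if (code < 0L) -code else cluster_members[[code]]))
      cluster_members[[step]] <- members
      grp[members] <- min(grp[members])
    }
  }
  ids <- match(grp, unique(grp))
  stats::setNames(ids, dendro$labels)
}

#' Label-enrichment test per cluster
#'
#' For every (cluster, label) pair builds the 2x2 table of cluster
#' membership against label and reports the one-sided Fisher exact p-value
#' for over-representation of the label inside the cluster. P-values are
#' reported unadjusted by default, matching the per-cluster reporting
#' convention; set \code{adjust = TRUE} for a BH-adjusted column.
#'
#' @param assignment Named integer vector (sample to cluster), e.g. from
#'   \code{\link{cut_clusters}}.
#' @param labels Named character vector (sample to label) covering all
#'   samples.
#' @param adjust Add a BH-adjusted q column (default FALSE).
#' @return Data frame: cluster, label, a, b, c, d, p (and q if requested),
#'   where (a, b, c, d) = (in-cluster with label, in-cluster without,
#'   out-of-cluster with, out-of-cluster without).
#' @export
cluster_enrichment <- function(assignment, labels, adjust = FALSE) {
  labels <- labels[names(assignment)]
  if (anyNA(labels)) stop("labels must cover all samples")
  out <- list()
  for (cl in sort(unique(assignment))) {
    inc <- assignment == cl
    for (lab in sort(unique(labels))) {
      hasl <- labels == lab
      a <- sum(inc & hasl); b <- sum(inc & !hasl)
      cc <- sum(!inc & hasl); dd <- sum(!inc & !hasl)
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, label = lab, a = a, b = b, c = cc, d = dd,
        p = fisher_one_sided(a, b, cc, dd), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (adjust) res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}

#' Write a dendrogram in newick format
#'
#' @param dendro A \code{mirna_dendrogram}.
#' @param path Output path.
#' @export
write_newick <- function(dendro, path) {
  ape::write.tree(ape::as.phylo(stats::as.hclust(dendro)), file = path)
  invisible(path)
}
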