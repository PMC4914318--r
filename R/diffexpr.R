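#' Filter miRNAs by detection count
#'
#' Keeps the rows (miRNAs) whose detection flag is TRUE in at least
#' \code{min_samples} samples; the column set is unchanged. This mirrors the
#' array-platform practice of discarding probes not reliably detected.
#'
#' @param values Numeric matrix, rows = mature accessions, columns = samples
#'   (log2 scale).
#' @param detected Logical (or 0/1) matrix of the same shape.
#' @param min_samples Minimum number of detected samples (default 15).
#' @return The filtered value matrix.
#' @export
detection_filter <- function(values, detected, min_samples = 15) {
  if (is.null(detected)) stop("no detection flags")
  if (!all(dim(detected) == dim(values)))
    stop("detection flags do not match matrix shape")
  if (min_samples < 0) stop("min_samples must be non-negative")
  if (min_samples > ncol(values))
    stop("min_samples exceeds the number of samples (", ncol(values), ")")
  counts <- rowSums(detected != 0)
  values[counts >= min_samples, , drop = FALSE]
}

signed_linear_fc <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Per-miRNA log2 and signed linear fold-change between two groups
#'
#' log2 fold-change is the difference of group means on the log2 scale
#' (case minus control), i.e. a geometric-mean fold-change on the linear
#' scale. The signed linear fold-change satisfies
#' \eqn{|FC| = 2^{|log2FC|}} with \eqn{FC = +1} at log2FC = 0.
#'
#' @param values Numeric log2 matrix (miRNA x sample).
#' @param groups Named character vector mapping sample id to group label.
#' @param case,control Labels of the two groups (defaults "tumor", "normal").
#' @return Data frame with accession, log2fc, linear_fc.
#' @export
log2_fold_change <- function(values, groups, case = "tumor",
                             control = "normal") {
  groups <- groups[colnames(values)]
  if (anyNA(groups)) stop("groups missing for some samples")
  a <- colnames(values)[groups == case]
  b <- colnames(values)[groups == control]
  if (length(a) == 0L) stop("group '", case, "' has zero samples")
  if (length(b) == 0L) stop("group '", control, "' has zero samples")
  l2 <- rowMeans(values[, a, drop = FALSE]) -
    rowMeans(values[, b, drop = FALSE])
  data.frame(accession = rownames(values), log2fc = unname(l2),
             linear_fc = unname(signed_linear_fc(l2)),
             stringsAsFactors = FALSE)
}

#' Differential expression between two groups
#'
#' Tests every miRNA for a location difference between the case and control
#' samples (Wilcoxon rank-sum by default, Welch's t as an option), computes
#' log2 and signed linear fold-changes from group means, and adjusts
#' p-values with the Benjamini-Hochberg step-up procedure.
#'
#' @inheritParams log2_fold_change
#' @param test \code{"wilcoxon"} (default) or \code{"welch"}.
#' @param exact_max_n Passed to \code{\link{rank_sum_test}}.
#' @return A \code{mirna_de} data frame with columns accession, log2fc,
#'   linear_fc, p, fdr.
#' @export
differential_expression <- function(values, groups, case = "tumor",
                                    control = "normal",
                                    test = c("wilcoxon", "welch"),
                                    exact_max_n = 10) {
  test <- match.arg(test)
  fc <- log2_fold_change(values, groups, case, control)
  groups <- groups[colnames(values)]
  a <- groups == case
  b <- groups == control
  p <- apply(values, 1L, function(v) {
    if (test == "wilcoxon") rank_sum_test(v[a], v[b], exact_max_n)
    else stats::t.test(v[a], v[b])$p.value
  })
  out <- data.frame(accession = fc$accession, log2fc = fc$log2fc,
                    linear_fc = fc$linear_fc, p = unname(p),
                    fdr = bh_adjust(unname(p)), stringsAsFactors = FALSE)
  class(out) <- c("mirna_de", "data.frame")
  out
}

#' @export
print.mirna_de <- function(x, ...) {
  cat("Differential expression over", nrow(x), "miRNAs;",
      sum(x$fdr < 0.05), "at FDR < 0.05\n")
  NextMethod()
}

#' Call a significance signature from differential-expression results
#'
#' Retains miRNAs with \eqn{|FC| \ge} \code{fc_cut} (linear scale) and
#' FDR strictly below \code{fdr_cut}; direction is "up" for positive log2
#' fold-change, "down" otherwise. The output is sorted by decreasing
#' |log2fc|, ties broken by accession.
#'
#' @param de A \code{mirna_de} data frame (or any data frame with columns
#'   accession, log2fc, linear_fc, fdr).
#' @param fc_cut Linear fold-change threshold, at least 1 (default 1.5).
#' @param fdr_cut FDR threshold, strict inequality (default 0.05).
#' @return Signature data frame: accession, direction, linear_fc, log2fc,
#'   p, fdr.
#' @export
call_signature <- function(de, fc_cut = 1.5, fdr_cut = 0.05) {
  if (fc_cut < 1) stop("fc_cut must be >= 1")
  keep <- abs(de$linear_fc) >= fc_cut & de$fdr < fdr_cut
  keep[is.na(keep)] <- FALSE
  s <- de[keep, , drop = FALSE]
  s <- as.data.frame(s, stringsAsFactors = FALSE)
  s$direction <- ifelse(s$log2fc > 0, "up", "down")
  s <- s[order(-abs(s$log2fc), s$accession),
         c("accession", "direction", "linear_fc", "log2fc", "p", "fdr"),
         drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Apply per-dataset thresholds to a differential-expression result
#'
#' Convenience wrapper used when the datasets entering an intersection carry
#' their own cutoffs: when \code{fdr_cut} is NULL only the fold-change filter
#' applies (as for datasets without a usable FDR).
#'
#' @inheritParams call_signature
#' @param fdr_cut FDR threshold or NULL to skip the FDR filter.
#' @export
apply_dataset_thresholds <- function(de, fc_cut, fdr_cut = NULL) {
  if (is.null(fdr_cut)) {
    de2 <- de
    de2$fdr <- 0   # FDR filter bypassed
    out <- call_signature(de2, fc_cut, fdr_cut = Inf)
    out$fdr <- de$fdr[match(out$accession, de$accession)]
    out
  } else call_signature(de, fc_cut, fdr_cut)
}

#' Read / write helpers for the TSV interchange formats
#'
#' Expression matrices are TSV with the accession in the first column and a
#' header row of sample ids; detection flags are a parallel 0/1 TSV; group
#' and stratum labels are 2-column TSVs (sample, label).
#'
#' @param path File path.
#' @return \code{read_expression_matrix}/\code{read_detection_flags} return
#'   a numeric/logical matrix; \code{read_sample_groups} a named character
#'   vector.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname expression_io
#' @export
read_detection_flags <- function(path) {
  m <- read_expression_matrix(path)
  m != 0
}

#' @rdname expression_io
#' @export
read_sample_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}

#' @rdname expression_io
#' @param m Matrix to write (row names = accessions).
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(accession = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @param signature Signature data frame.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(signature, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_signature <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
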