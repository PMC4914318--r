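#' Aggregate isoform-level read counts to mature accessions
#'
#' Sums the read counts of all isoform records of a sample that map to the
#' same mature accession of the reference release, reannotating source
#' accessions through \code{release_map}. Records whose accession is absent
#' from the map are excluded from the matrix and returned in the
#' \code{unmapped} report rather than carried under stale identifiers.
#'
#' @param records Data frame with columns sample_id, mature_accession,
#'   read_count (non-negative integers; repeated (sample, accession) pairs
#'   are isoforms and are summed).
#' @param release_map Named character vector mapping source-release
#'   accessions to current accessions (identity entries included for
#'   accessions already current).
#' @return List with \code{counts} (matrix, rows = current accessions,
#'   columns = sample ids, both sorted) and \code{unmapped} (data frame of
#'   excluded records).
#' @export
aggregate_isoforms <- function(records, release_map) {
  need <- c("sample_id", "mature_accession", "read_count")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (nrow(records) == 0L)
    return(list(counts = matrix(0, 0, 0,
                                dimnames = list(character(0), character(0))),
                unmapped = records))
  if (any(is.na(records$read_count)) || any(records$read_count < 0))
    stop("negative or missing read count")
  cur <- unname(release_map[records$mature_accession])
  unmapped <- records[is.na(cur), , drop = FALSE]
  rownames(unmapped) <- NULL
  keep <- !is.na(cur)
  if (!any(keep))
    return(list(counts = matrix(0, 0, 0,
                                dimnames = list(character(0), character(0))),
                unmapped = unmapped))
  acc <- cur[keep]
  smp <- as.character(records$sample_id[keep])
  cnt <- as.numeric(records$read_count[keep])
  rows <- sort(unique(acc)); cols <- sort(unique(smp))
  m <- tapply(cnt, list(factor(acc, rows), factor(smp, cols)), sum)
  m[is.na(m)] <- 0
  dimnames(m) <- list(rows, cols)
  list(counts = m, unmapped = unmapped)
}

#' Reads-per-million normalization
#'
#' Scales each sample (column) so counts sum to one million:
#' \eqn{RPM = count / total \times 10^6}, the total being the sample's
#' aggregated mature-miRNA reads.
#'
#' @param counts Count matrix (miRNA x sample).
#' @return RPM matrix of the same shape.
#' @export
rpm_normalize <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop("sample with zero total count: ",
         colnames(counts)[which(totals <= 0)[1L]])
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Log2 transform with zero replacement
#'
#' Replaces zeros with the minimum non-zero value before taking log2, so the
#' output is finite everywhere. By default the minimum is global over the
#' matrix; \code{scope = "per_mirna"} uses each row's own minimum non-zero
#' value instead (rows that are entirely zero fall back to the global one).
#'
#' @param m Non-negative matrix (e.g. RPM values).
#' @param scope \code{"global"} (default) or \code{"per_mirna"}.
#' @return Log2 matrix.
#' @export
log2_with_zero_replacement <- function(m, scope = c("global", "per_mirna")) {
  scope <- match.arg(scope)
  if (length(m) == 0L || all(m == 0)) stop("matrix has no non-zero values")
  gmin <- min(m[m > 0])
  if (scope == "global") {
    m[m == 0] <- gmin
  } else {
    for (i in seq_len(nrow(m))) {
      z <- m[i, ] == 0
      if (any(z)) {
        rmin <- if (all(z)) gmin else min(m[i, !z])
        m[i, z] <- rmin
      }
    }
  }
  log2(m)
}

#' Two-group validation of a miRNA subset
#'
#' Wilcoxon rank-sum test per miRNA of the subset between the case and
#' control samples, with Benjamini-Hochberg adjustment over the subset only
#' (m = subset size). The direction is that of the median difference.
#'
#' @param log2m Log2 expression matrix (miRNA x sample).
#' @param groups Named character vector, sample id to group label.
#' @param subset Accessions to test (all must be rows of \code{log2m}).
#' @param case,control Group labels (defaults "tumor", "normal").
#' @param exact_max_n Passed to \code{\link{rank_sum_test}}.
#' @return Data frame: accession, direction, median_diff, p, q.
#' @export
two_group_validation <- function(log2m, groups, subset, case = "tumor",
                                 control = "normal", exact_max_n = 10) {
  subset <- as.character(subset)
  if (length(subset) == 0L) stop("subset is empty")
  missing <- setdiff(subset, rownames(log2m))
  if (length(missing))
    stop("accession missing from matrix: ", missing[1L])
  groups <- groups[colnames(log2m)]
  a <- which(groups == case); b <- which(groups == control)
  if (!length(a) || !length(b)) stop("both groups must be present")
  p <- numeric(length(subset)); md <- numeric(length(subset))
  for (i in seq_along(subset)) {
    v <- log2m[subset[i], ]
    p[i] <- rank_sum_test(v[a], v[b], exact_max_n)
    md[i] <- stats::median(v[a]) - stats::median(v[b])
  }
  data.frame(accession = subset,
             direction = ifelse(md > 0, "up", ifelse(md < 0, "down", "none")),
             median_diff = md, p = p, q = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Pairwise Wilcoxon tests across strata
#'
#' For a single miRNA's per-sample values stratified into groups, tests the
#' reference stratum (e.g. normal thyroid) against every other stratum and
#' all non-reference stratum pairs against each other. P-values are reported
#' unadjusted, pair by pair; the global Kruskal-Wallis test gates
#' interpretation.
#'
#' @param values Numeric vector of per-sample values.
#' @param strata Stratum label per sample.
#' @param reference Reference stratum label.
#' @param exact_max_n Passed to \code{\link{rank_sum_test}}.
#' @return Data frame: group1, group2, n1, n2, p.
#' @export
pairwise_strata_tests <- function(values, strata, reference,
                                  exact_max_n = 10) {
  strata <- as.character(strata)
  labs <- unique(strata)
  if (!reference %in% labs)
    stop("reference stratum absent: ", reference)
  others <- sort(setdiff(labs, reference))
  pairs <- list()
  for (o in others) pairs[[length(pairs) + 1L]] <- c(reference, o)
  if (length(others) > 1L)
    for (i in seq_len(length(others) - 1L))
      for (j in (i + 1L):length(others))
        pairs[[length(pairs) + 1L]] <- c(others[i], others[j])
  out <- do.call(rbind, lapply(pairs, function(pr) {
    x <- values[strata == pr[1L]]; y <- values[strata == pr[2L]]
    data.frame(group1 = pr[1L], group2 = pr[2L],
               n1 = length(x), n2 = length(y),
               p = rank_sum_test(x, y, exact_max_n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read isoform quantification records
#'
#' @param paths One or more 3-column TSV files (sample_id,
#'   mature_accession, read_count), with header.
#' @return Combined data frame of records.
#' @export
read_isoform_records <- function(paths) {
  do.call(rbind, lapply(paths, function(p)
    utils::read.delim(p, stringsAsFactors = FALSE)))
}

#' Read a release map (old accession -> current accession)
#'
#' @param path 2-column TSV with header.
#' @return Named character vector.
#' @export
read_release_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}
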