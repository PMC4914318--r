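#' Collapse the datasets of one study into a single study call
#'
#' A study published as several datasets counts once in the meta-analysis.
#' A miRNA reported by at least one dataset, always with the same direction,
#' takes that direction; opposing directions across the study's datasets
#' yield a \code{"conflict"} call; miRNAs reported by no dataset are absent.
#'
#' @param datasets List of harmonized signature data frames (columns
#'   accession, direction), one per dataset of the study.
#' @return Data frame with columns accession and call
#'   (\code{"up"}, \code{"down"} or \code{"conflict"}).
#' @export
collapse_datasets <- function(datasets) {
  if (length(datasets) < 1L) stop("need at least one dataset signature")
  acc <- sort(unique(unlist(lapply(datasets, `[[`, "accession"))))
  call <- vapply(acc, function(a) {
    ds <- unique(unlist(lapply(datasets, function(d)
      d$direction[d$accession == a])))
    if (length(ds) > 1L) "conflict" else ds
  }, "")
  data.frame(accession = acc, call = unname(call), stringsAsFactors = FALSE)
}

#' Build the study-miRNA vote-counting matrix
#'
#' Rows are the union of reported mature accessions; one column per study
#' (multi-dataset studies collapsed first). Cells record the study's call;
#' the per-miRNA scores count the studies reporting each direction, with
#' conflicted studies supporting neither. Fold-change magnitudes are never
#' aggregated: this is a vote-counting meta-analysis.
#'
#' @param studies List of studies; each study is a list with
#'   \code{study_id} (string) and \code{datasets} (list of harmonized
#'   signature data frames).
#' @return A \code{study_mirna_matrix}: list with \code{calls} (character
#'   matrix, cells in \{"up","down","none","conflict"\}) and \code{scores}
#'   (data frame: accession, up_count, down_count).
#' @export
build_study_matrix <- function(studies) {
  ids <- vapply(studies, `[[`, "", "study_id")
  if (anyDuplicated(ids)) stop("duplicate study_id: ", ids[duplicated(ids)][1L])
  cols <- lapply(studies, function(s) collapse_datasets(s$datasets))
  acc <- sort(unique(unlist(lapply(cols, `[[`, "accession"))))
  calls <- matrix("none", length(acc), length(ids),
                  dimnames = list(acc, ids))
  for (j in seq_along(cols)) {
    cj <- cols[[j]]
    calls[cj$accession, j] <- cj$call
  }
  scores <- data.frame(
    accession = acc,
    up_count = rowSums(calls == "up"),
    down_count = rowSums(calls == "down"),
    stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(calls = calls, scores = scores),
            class = "study_mirna_matrix")
}

#' @export
print.study_mirna_matrix <- function(x, ...) {
  cat("Study-miRNA matrix:", nrow(x$calls), "miRNAs x",
      ncol(x$calls), "studies;", sum(x$calls == "conflict"),
      "conflict cells\n")
  invisible(x)
}

#' Frequency scores and ranked lists per direction
#'
#' The score of a miRNA in a direction is the number of studies reporting it
#' in that direction (conflict cells count toward neither). Returns the up-
#' and down-regulated ranked lists, score descending, ties by accession.
#'
#' @param m A \code{study_mirna_matrix}.
#' @return List with \code{up} and \code{down} data frames
#'   (accession, score).
#' @export
frequency_score <- function(m) {
  stopifnot(inherits(m, "study_mirna_matrix"))
  ranked <- function(count) {
    d <- data.frame(accession = m$scores$accession, score = count,
                    stringsAsFactors = FALSE)
    d <- d[d$score > 0, , drop = FALSE]
    d <- d[order(-d$score, d$accession), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(up = ranked(m$scores$up_count), down = ranked(m$scores$down_count))
}

#' Keep miRNAs reported by at least k independent studies
#'
#' @param m A \code{study_mirna_matrix}.
#' @param k Minimum number of reporting studies (default 2; conflicted
#'   studies do not count as reporting).
#' @return Filtered \code{study_mirna_matrix}.
#' @export
filter_min_studies <- function(m, k = 2) {
  stopifnot(inherits(m, "study_mirna_matrix"))
  if (k < 1) stop("k must be >= 1")
  keep <- m$scores$up_count + m$scores$down_count >= k
  structure(list(calls = m$calls[keep, , drop = FALSE],
                 scores = {
                   s <- m$scores[keep, , drop = FALSE]
                   rownames(s) <- NULL
                   s
                 }),
            class = "study_mirna_matrix")
}

#' Write a study-miRNA matrix as TSV
#'
#' Cells are encoded 1 (up), -1 (down), 0 (not reported), C (conflict); a
#' second file holds the per-miRNA scores.
#'
#' @param m A \code{study_mirna_matrix}.
#' @param matrix_path,score_path Output paths.
#' @export
write_study_matrix <- function(m, matrix_path, score_path = NULL) {
  stopifnot(inherits(m, "study_mirna_matrix"))
  enc <- m$calls
  enc[m$calls == "up"] <- "1"
  enc[m$calls == "down"] <- "-1"
  enc[m$calls == "none"] <- "0"
  enc[m$calls == "conflict"] <- "C"
  df <- data.frame(accession = rownames(enc), enc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(score_path))
    utils::write.table(m$scores, score_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(matrix_path)
}

#' Read per-study signature tables and a studies manifest
#'
#' The manifest is a TSV with columns study_id, dataset_id, file (path to a
#' per-dataset table of raw_name, direction, optional fc), mirroring a
#' typical literature-review study table. Each per-dataset table is
#' harmonized against the registry; the result feeds
#' \code{\link{build_study_matrix}}.
#'
#' @param manifest_path Manifest TSV path.
#' @param registry A \code{mirna_registry}.
#' @param base_dir Directory the manifest's file column is relative to
#'   (default: the manifest's own directory).
#' @return List with \code{studies} (as consumed by
#'   \code{\link{build_study_matrix}}) and \code{reports} (per-dataset
#'   resolution reports).
#' @export
read_study_signatures <- function(manifest_path, registry,
                                  base_dir = dirname(manifest_path)) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  studies <- list(); reports <- list()
  for (sid in unique(man$study_id)) {
    rows <- man[man$study_id == sid, , drop = FALSE]
    datasets <- list()
    for (i in seq_len(nrow(rows))) {
      tab <- utils::read.delim(file.path(base_dir, rows$file[i]),
                               stringsAsFactors = FALSE)
      h <- harmonize_signature(tab, registry)
      datasets[[rows$dataset_id[i]]] <- h$signature
      reports[[paste(sid, rows$dataset_id[i], sep = "/")]] <- h$report
    }
    studies[[length(studies) + 1L]] <- list(study_id = sid,
                                            datasets = datasets)
  }
  list(studies = studies, reports = reports)
}
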