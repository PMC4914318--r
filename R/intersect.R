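#' Declare the tumor orientation of a dataset signature
#'
#' Whether "up" in the dataset corresponds to the tumor-active state. For a
#' tumor-vs-normal comparison this is \code{"tumor_like_is_up"}; for an
#' oncogene-inhibition model where the untreated (oncogene-active) state is
#' the baseline of the comparison the flag must be set accordingly — the
#' orientation is always declared, never inferred.
#'
#' @param signature Signature data frame (columns accession, direction, and
#'   optionally fold-changes).
#' @param orientation \code{"tumor_like_is_up"} or
#'   \code{"tumor_like_is_down"}.
#' @return An \code{oriented_signature} list.
#' @export
oriented_signature <- function(signature,
                               orientation = c("tumor_like_is_up",
                                               "tumor_like_is_down")) {
  if (length(orientation) != 1L ||
      !orientation %in% c("tumor_like_is_up", "tumor_like_is_down"))
    stop("orientation must be declared as 'tumor_like_is_up' or 'tumor_like_is_down'")
  structure(list(signature = signature, orientation = orientation),
            class = "oriented_signature")
}

tumor_oriented_directions <- function(os) {
  d <- os$signature$direction
  if (os$orientation == "tumor_like_is_down")
    d <- ifelse(d == "up", "down", "up")
  stats::setNames(d, os$signature$accession)
}

#' Concordant intersection of oriented signatures
#'
#' A miRNA belongs to the intersection iff it is present in every dataset's
#' signature and its tumor-oriented direction is identical across all of
#' them. The result is split into concordant-up and concordant-down lists,
#' sorted by accession.
#'
#' @param datasets List of two or more \code{oriented_signature} objects
#'   (plain lists with \code{signature} and \code{orientation} are
#'   accepted).
#' @return List with \code{up} and \code{down} character vectors of
#'   accessions.
#' @export
concordant_intersection <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least two datasets")
  dirs <- lapply(datasets, function(d) {
    if (is.null(d$orientation))
      stop("dataset without a declared orientation")
    tumor_oriented_directions(oriented_signature(d$signature, d$orientation))
  })
  common <- Reduce(intersect, lapply(dirs, names))
  up <- character(0); down <- character(0)
  for (a in common) {
    da <- unique(vapply(dirs, function(d) unname(d[[a]]), ""))
    if (length(da) == 1L) {
      if (da == "up") up <- c(up, a) else down <- c(down, a)
    }
  }
  list(up = sort(up), down = sort(down))
}
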