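#' Normalize a miRNA name for matching
#'
#' Lowercases, trims whitespace and strips a leading species prefix of the
#' form \code{"xxx-"} (e.g. \code{"hsa-"}) when it is followed by a
#' \code{mir}/\code{let} stem, so that \code{"miR-451a"} and
#' \code{"hsa-miR-451a"} compare equal. The star suffix \code{"*"} and
#' arm suffixes are kept verbatim: legacy forms resolve only through
#' recorded aliases, never by guessing an arm.
#'
#' @param x Character vector of miRNA names.
#' @return Normalized names.
#' @export
normalize_mirna_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  sub("^[a-z0-9]{3,4}-(?=(mir|let)\\b|(mir|let)-)", "", x, perl = TRUE)
}

#' Load a miRNA registry from alias and precursor tables
#'
#' Parses a two-column aliases table (miRBase \code{aliases.txt} dialect:
#' accession, then a semicolon-terminated name list where the \emph{last}
#' name is the current one and earlier names are historical) and an optional
#' GFF3-like precursor table. In the precursor table,
#' \code{miRNA_primary_transcript} rows describe hairpin precursors
#' (attributes \code{ID=MI...;Name=...;family=...}) and \code{miRNA} rows
#' link mature accessions to their precursor via
#' \code{ID=MIMAT...;Derives_from=MI...}.
#'
#' @param alias_table Path to the aliases TSV.
#' @param precursor_table Optional path to the GFF3-like precursor table.
#' @param release_label Label of the registry release (e.g. "v21").
#' @return An object of class \code{mirna_registry}.
#' @export
load_registry <- function(alias_table, precursor_table = NULL,
                          release_label = "v21") {
  lines <- readLines(alias_table)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no mature records in ", alias_table)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed alias row at line ", bad[1L], ": expected 2 columns")
  acc <- vapply(parts, `[[`, "", 1L)
  badacc <- which(!grepl("^MIMAT[0-9]+$", acc))
  if (length(badacc))
    stop("malformed mature accession '", acc[badacc[1L]],
         "' at line ", badacc[1L])
  dup <- which(duplicated(acc))
  if (length(dup))
    stop("duplicate mature accession: ", acc[dup[1L]])
  namelists <- lapply(parts, function(p) {
    nm <- strsplit(p[[2L]], ";", fixed = TRUE)[[1L]]
    nm <- trimws(nm)
    nm[nzchar(nm)]
  })
  empty <- which(lengths(namelists) == 0L)
  if (length(empty))
    stop("empty name list at line ", empty[1L])
  current <- vapply(namelists, function(nm) nm[length(nm)], "")
  previous <- lapply(namelists, function(nm) nm[-length(nm)])
  dupname <- which(duplicated(normalize_mirna_name(current)))
  if (length(dupname))
    stop("current name maps to more than one accession: ", current[dupname[1L]])
  arm <- rep("unspecified", length(acc))
  arm[grepl("-5p$", current)] <- "5p"
  arm[grepl("-3p$", current)] <- "3p"

  matures <- data.frame(accession = acc, current_name = current,
                        arm = arm, stringsAsFactors = FALSE)
  matures$previous_names <- previous
  matures$precursor_accessions <- rep(list(character(0)), nrow(matures))

  precursors <- data.frame(accession = character(0), name = character(0),
                           chromosome = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           family_id = character(0), stringsAsFactors = FALSE)
  if (!is.null(precursor_table)) {
    gff <- readLines(precursor_table)
    gff <- gff[nzchar(gff) & !startsWith(gff, "#")]
    fields <- strsplit(gff, "\t", fixed = TRUE)
    badg <- which(lengths(fields) != 9L)
    if (length(badg))
      stop("malformed GFF row at line ", badg[1L], ": expected 9 columns")
    type <- vapply(fields, `[[`, "", 3L)
    attr_get <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))[[1L]]
      if (length(m) >= 3L) m[[3L]] else ""
    }
    pre_rows <- fields[type == "miRNA_primary_transcript"]
    if (length(pre_rows)) {
      precursors <- data.frame(
        accession = vapply(pre_rows, function(f) attr_get(f[[9L]], "ID"), ""),
        name = vapply(pre_rows, function(f) attr_get(f[[9L]], "Name"), ""),
        chromosome = vapply(pre_rows, `[[`, "", 1L),
        start = as.integer(vapply(pre_rows, `[[`, "", 4L)),
        end = as.integer(vapply(pre_rows, `[[`, "", 5L)),
        strand = vapply(pre_rows, `[[`, "", 7L),
        family_id = vapply(pre_rows, function(f) attr_get(f[[9L]], "family"), ""),
        stringsAsFactors = FALSE)
      if (any(!grepl("^MI[0-9]+$", precursors$accession)))
        stop("malformed precursor accession in ", precursor_table)
      if (anyDuplicated(precursors$accession))
        stop("duplicate precursor accession")
      if (any(precursors$start > precursors$end))
        stop("precursor with start > end")
    }
    mat_rows <- fields[type == "miRNA"]
    if (length(mat_rows)) {
      macc <- vapply(mat_rows, function(f) attr_get(f[[9L]], "ID"), "")
      from <- vapply(mat_rows, function(f) attr_get(f[[9L]], "Derives_from"), "")
      unknown_pre <- setdiff(from, precursors$accession)
      if (length(unknown_pre))
        stop("mature derives from unknown precursor: ", unknown_pre[1L])
      for (i in seq_along(macc)) {
        j <- match(macc[i], matures$accession)
        if (is.na(j))
          stop("GFF mature accession absent from alias table: ", macc[i])
        matures$precursor_accessions[[j]] <-
          union(matures$precursor_accessions[[j]], from[i])
      }
    }
  }

  alias_index <- new.env(parent = emptyenv())
  add_alias <- function(name, accession) {
    key <- normalize_mirna_name(name)
    cur <- if (exists(key, envir = alias_index, inherits = FALSE))
      get(key, envir = alias_index) else character(0)
    assign(key, union(cur, accession), envir = alias_index)
  }
  for (i in seq_len(nrow(matures))) {
    add_alias(matures$current_name[i], matures$accession[i])
    for (nm in matures$previous_names[[i]]) add_alias(nm, matures$accession[i])
  }

  structure(list(release_label = release_label, matures = matures,
                 precursors = precursors, alias_index = alias_index),
            class = "mirna_registry")
}

#' @export
print.mirna_registry <- function(x, ...) {
  cat("miRNA registry (", x$release_label, "): ",
      nrow(x$matures), " matures, ", nrow(x$precursors), " precursors, ",
      length(ls(x$alias_index)), " distinct names\n", sep = "")
  invisible(x)
}

#' Resolve a miRNA name to a mature accession
#'
#' Case-insensitive lookup of a (possibly historical) miRNA name against the
#' registry's alias index. The species prefix is optional. A name recorded
#' for exactly one accession resolves; one recorded for several accessions
#' (a nomenclature collision) is ambiguous; an unrecorded name is unknown.
#' No arm is ever guessed for arm-less legacy names.
#'
#' @param name Query name (non-empty string).
#' @param registry A \code{mirna_registry}.
#' @return List with \code{query}, \code{status} (one of
#'   \code{"resolved"}, \code{"ambiguous"}, \code{"unknown"}),
#'   \code{accessions} and \code{note}.
#' @export
resolve_name <- function(name, registry) {
  stopifnot(inherits(registry, "mirna_registry"))
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("name must be a non-empty string")
  key <- normalize_mirna_name(name)
  accs <- if (exists(key, envir = registry$alias_index, inherits = FALSE))
    sort(get(key, envir = registry$alias_index)) else character(0)
  if (length(accs) == 1L)
    list(query = name, status = "resolved", accessions = accs, note = "")
  else if (length(accs) > 1L)
    list(query = name, status = "ambiguous", accessions = accs,
         note = paste0("matches ", length(accs), " accessions: ",
                       paste(accs, collapse = ",")))
  else
    list(query = name, status = "unknown", accessions = character(0),
         note = "name not recorded in registry")
}

#' Harmonize a raw study signature to registry accessions
#'
#' Resolves each raw miRNA name to its univocal mature accession and merges
#' duplicates. Entries mapping to the same accession with the same direction
#' are merged, keeping the fold-change of largest magnitude. An accession
#' reported in both directions within the same study is an intra-study
#' conflict: it is excluded from the signature and reported. Ambiguous and
#' unknown names are likewise excluded but reported, never silently dropped.
#'
#' @param entries Data frame with columns \code{raw_name},
#'   \code{direction} (\code{"up"} or \code{"down"}) and optionally
#'   \code{fc} (signed linear fold-change).
#' @param registry A \code{mirna_registry}.
#' @return List with \code{signature} (data frame: accession, name,
#'   direction, fc) and \code{report} (data frame: query, status,
#'   candidates, note).
#' @export
harmonize_signature <- function(entries, registry) {
  stopifnot(inherits(registry, "mirna_registry"))
  empty_sig <- data.frame(accession = character(0), name = character(0),
                          direction = character(0), fc = numeric(0),
                          stringsAsFactors = FALSE)
  empty_rep <- data.frame(query = character(0), status = character(0),
                          candidates = character(0), note = character(0),
                          stringsAsFactors = FALSE)
  if (is.null(entries) || nrow(entries) == 0L)
    return(list(signature = empty_sig, report = empty_rep))
  if (!all(c("raw_name", "direction") %in% names(entries)))
    stop("entries need columns raw_name and direction")
  if (!all(entries$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  fc <- if ("fc" %in% names(entries)) as.numeric(entries$fc)
        else rep(NA_real_, nrow(entries))

  rep_rows <- list(); res_acc <- character(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    r <- resolve_name(entries$raw_name[i], registry)
    res_acc[i] <- if (r$status == "resolved") r$accessions else NA_character_
    if (r$status != "resolved")
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        query = r$query, status = r$status,
        candidates = paste(r$accessions, collapse = ";"), note = r$note,
        stringsAsFactors = FALSE)
  }
  keep <- !is.na(res_acc)
  acc <- res_acc[keep]; dirs <- entries$direction[keep]
  fcs <- fc[keep]; raw <- entries$raw_name[keep]

  sig_rows <- list()
  for (a in unique(acc)) {
    sel <- acc == a
    ds <- unique(dirs[sel])
    if (length(ds) > 1L) {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        query = paste(unique(raw[sel]), collapse = ";"),
        status = "conflict", candidates = a,
        note = "intra-study conflict: reported in both directions",
        stringsAsFactors = FALSE)
      next
    }
    f <- fcs[sel]
    f <- if (all(is.na(f))) NA_real_ else f[which.max(abs(f))]
    j <- match(a, registry$matures$accession)
    sig_rows[[length(sig_rows) + 1L]] <- data.frame(
      accession = a, name = registry$matures$current_name[j],
      direction = ds, fc = f, stringsAsFactors = FALSE)
  }
  sig <- if (length(sig_rows)) do.call(rbind, sig_rows) else empty_sig
  sig <- sig[order(sig$accession), , drop = FALSE]
  rownames(sig) <- NULL
  rpt <- if (length(rep_rows)) do.call(rbind, rep_rows) else empty_rep
  rownames(rpt) <- NULL
  list(signature = sig, report = rpt)
}

#' Group mature miRNAs by family, genomic cluster and shared precursor
#'
#' Partitions a set of mature accessions three ways: by shared family label,
#' by genomic cluster (precursors on the same chromosome and strand whose
#' inter-precursor gap is at most \code{cluster_window_bp}, closed
#' transitively), and by shared hairpin precursor (-5p/-3p pairs). Only
#' groups of two or more members are reported.
#'
#' @param accessions Mature accessions, all present in the registry.
#' @param registry A \code{mirna_registry} with precursor annotation.
#' @param cluster_window_bp Maximum gap in bp between clustered precursors
#'   (default 10000).
#' @return List with components \code{family}, \code{cluster} and
#'   \code{shared_precursor}, each a named list of sorted accession vectors.
#' @export
group_mirnas <- function(accessions, registry, cluster_window_bp = 10000) {
  stopifnot(inherits(registry, "mirna_registry"))
  accessions <- unique(as.character(accessions))
  idx <- match(accessions, registry$matures$accession)
  if (anyNA(idx))
    stop("unknown accession: ", accessions[which(is.na(idx))[1L]])
  pre_of <- registry$matures$precursor_accessions[idx]
  names(pre_of) <- accessions
  pre <- registry$precursors

  keep2 <- function(groups) {
    groups <- lapply(groups, function(g) sort(unique(g)))
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) == 0L) return(stats::setNames(list(), character(0)))
    groups[order(names(groups))]
  }

  # shared precursor: >=2 input matures derive from one hairpin
  by_pre <- list()
  for (a in accessions)
    for (p in pre_of[[a]]) by_pre[[p]] <- c(by_pre[[p]], a)
  shared <- keep2(by_pre)

  # family: via the family label of the precursor(s)
  by_fam <- list()
  for (a in accessions) {
    fams <- unique(pre$family_id[match(pre_of[[a]], pre$accession)])
    fams <- fams[!is.na(fams) & nzchar(fams)]
    for (f in fams) by_fam[[f]] <- c(by_fam[[f]], a)
  }
  family <- keep2(by_fam)

  # genomic cluster: chain precursors within the window on one chrom/strand
  pids <- unique(unlist(pre_of, use.names = FALSE))
  clusters <- list()
  if (length(pids)) {
    pd <- pre[match(pids, pre$accession), , drop = FALSE]
    comp <- rep(NA_integer_, nrow(pd)); nc <- 0L
    for (key in unique(paste(pd$chromosome, pd$strand))) {
      sel <- which(paste(pd$chromosome, pd$strand) == key)
      sel <- sel[order(pd$start[sel])]
      nc <- nc + 1L
      comp[sel[1L]] <- nc
      run_end <- pd$end[sel[1L]]
      if (length(sel) > 1L) for (k in 2L:length(sel)) {
        gap <- pd$start[sel[k]] - run_end
        if (gap <= cluster_window_bp) {
          comp[sel[k]] <- nc
          run_end <- max(run_end, pd$end[sel[k]])
        } else {
          nc <- nc + 1L
          comp[sel[k]] <- nc
          run_end <- pd$end[sel[k]]
        }
      }
    }
    for (ci in unique(comp)) {
      members <- pd$accession[comp == ci]
      accs <- accessions[vapply(pre_of, function(p) any(p %in% members), TRUE)]
      if (length(accs) >= 2L && length(members) >= 2L) {
        lab <- paste0(pd$chromosome[match(members[1L], pd$accession)], ":",
                      paste(sort(members), collapse = "/"))
        clusters[[lab]] <- accs
      }
    }
  }
  list(family = family, cluster = keep2(clusters),
       shared_precursor = shared)
}

#' Write a name-resolution report to TSV
#'
#' @param report Report data frame from \code{\link{harmonize_signature}}.
#' @param path Output path.
#' @export
write_resolution_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
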