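#' Simulate a two-release miRNA registry with planted renames
#'
#' Emits an aliases table and a GFF3-like precursor table emulating two
#' nomenclature eras: a configurable fraction of matures carry legacy
#' previous names (arm-less forms for -5p matures, star forms for -3p
#' matures, letter-less forms for lettered names), some precursor pairs are
#' placed within a genomic-cluster window of each other, some precursors
#' yield both a -5p and a -3p mature, and (optionally) planted alias
#' collisions give one legacy name to two accessions. Generation is fully
#' deterministic given the seed; with \code{audit = TRUE} (default) the
#' written files are re-read and checked against the ground truth.
#'
#' @param n_precursors Number of hairpin precursors (default 120).
#' @param two_mature_fraction Fraction of precursors yielding both arms
#'   (default 0.4).
#' @param rename_fraction Fraction of matures given a legacy previous name
#'   (default 0.5).
#' @param n_collisions Number of planted alias collisions (default 0).
#' @param cluster_pair_fraction Fraction of precursors placed within the
#'   cluster window of the preceding one (default 0.2).
#' @param cluster_window_bp Cluster window in bp (default 10000).
#' @param family_fraction Fraction of precursors assigned to a (shared)
#'   family label (default 0.3).
#' @param seed Random seed.
#' @param dir Output directory (default: fresh temporary directory).
#' @param audit Re-read the emitted files and verify them against the
#'   ground truth (default TRUE).
#' @return List with \code{alias_file}, \code{precursor_file} and
#'   \code{truth} (data frames \code{names}: accession, current_name,
#'   previous_name; \code{collisions}; \code{cluster_pairs};
#'   \code{shared_precursors}).
#' @export
simulate_registry <- function(n_precursors = 120, two_mature_fraction = 0.4,
                              rename_fraction = 0.5, n_collisions = 0,
                              cluster_pair_fraction = 0.2,
                              cluster_window_bp = 10000,
                              family_fraction = 0.3, seed = 1,
                              dir = tempfile("sim_registry_"),
                              audit = TRUE) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base_num <- sort(sample(1000:9999, n_precursors))
  two_arm <- stats::runif(n_precursors) < two_mature_fraction
  lettered <- stats::runif(n_precursors) < 0.3

  # precursor coordinates: consecutive precursors sometimes clustered
  chrom <- character(n_precursors); start <- integer(n_precursors)
  strand <- character(n_precursors)
  pos <- 0L; cur_chr <- 1L; cur_strand <- "+"
  for (i in seq_len(n_precursors)) {
    clustered <- i > 1L && stats::runif(1) < cluster_pair_fraction
    if (clustered) {
      pos <- pos + 80L + sample.int(as.integer(cluster_window_bp / 2), 1L)
    } else {
      if (stats::runif(1) < 0.1) { cur_chr <- cur_chr + 1L; pos <- 0L }
      pos <- pos + cluster_window_bp * 5L + sample.int(50000L, 1L)
      cur_strand <- sample(c("+", "-"), 1L)
    }
    chrom[i] <- paste0("chr", cur_chr)
    start[i] <- pos
    strand[i] <- cur_strand
  }
  end <- start + 79L

  fam <- rep("", n_precursors)
  famsel <- which(stats::runif(n_precursors) < family_fraction)
  if (length(famsel) >= 2L)
    fam[famsel] <- paste0("mipf-fam-", 1L + (seq_along(famsel) %% 5L))

  pre_acc <- sprintf("MI%07d", seq_len(n_precursors))
  pre_name <- paste0("hsa-mir-", base_num, ifelse(lettered, "a", ""))

  mat_rows <- list(); alias_rows <- list(); truth_names <- list()
  midx <- 0L
  for (i in seq_len(n_precursors)) {
    stem <- paste0(base_num[i], ifelse(lettered[i], "a", ""))
    arms <- if (two_arm[i]) c("5p", "3p") else sample(c("5p", "3p"), 1L)
    for (arm in arms) {
      midx <- midx + 1L
      acc <- sprintf("MIMAT%07d", midx)
      cur <- paste0("hsa-miR-", stem, "-", arm)
      prev <- character(0)
      if (stats::runif(1) < rename_fraction) {
        prev <- if (arm == "5p") paste0("hsa-miR-", stem)
                else if (two_arm[i]) paste0("hsa-miR-", stem, "*")
                else paste0("hsa-miR-", stem)
        # letter-less legacy alias only on the first arm, so it stays
        # unambiguous unless a collision is planted explicitly
        if (lettered[i] && arm == arms[1L] && stats::runif(1) < 0.5)
          prev <- c(paste0("hsa-miR-", base_num[i]), prev)
      }
      mat_rows[[midx]] <- data.frame(accession = acc, current_name = cur,
                                     precursor = pre_acc[i],
                                     stringsAsFactors = FALSE)
      alias_rows[[midx]] <- data.frame(
        accession = acc,
        names = paste0(paste(c(prev, cur), collapse = ";"), ";"),
        stringsAsFactors = FALSE)
      truth_names[[midx]] <- data.frame(
        accession = acc, current_name = cur,
        previous_name = if (length(prev)) prev else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  matures <- do.call(rbind, mat_rows)
  aliases <- do.call(rbind, alias_rows)
  truth <- do.call(rbind, truth_names)

  # planted collisions: one fabricated legacy name shared by two accessions
  collisions <- data.frame(previous_name = character(0),
                           accessions = character(0),
                           stringsAsFactors = FALSE)
  if (n_collisions > 0L) {
    victims <- matrix(sample(nrow(matures), 2L * n_collisions), ncol = 2L)
    coll_name <- paste0("hsa-miR-coll", seq_len(n_collisions))
    for (k in seq_len(n_collisions)) {
      for (v in victims[k, ]) {
        nm <- aliases$names[v]
        aliases$names[v] <- paste0(coll_name[k], ";", nm)
      }
      collisions <- rbind(collisions, data.frame(
        previous_name = coll_name[k],
        accessions = paste(sort(matures$accession[victims[k, ]]),
                           collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }

  alias_file <- file.path(dir, "aliases.tsv")
  writeLines(paste(aliases$accession, aliases$names, sep = "\t"), alias_file)

  gff <- c("##gff-version 3",
           paste(chrom, "simulated", "miRNA_primary_transcript", start, end,
                 ".", strand, ".",
                 paste0("ID=", pre_acc, ";Name=", pre_name,
                        ifelse(nzchar(fam), paste0(";family=", fam), "")),
                 sep = "\t"))
  mstart <- start[match(matures$precursor, pre_acc)] + 10L
  gff <- c(gff,
           paste(chrom[match(matures$precursor, pre_acc)], "simulated",
                 "miRNA", mstart, mstart + 21L, ".",
                 strand[match(matures$precursor, pre_acc)], ".",
                 paste0("ID=", matures$accession,
                        ";Name=", matures$current_name,
                        ";Derives_from=", matures$precursor),
                 sep = "\t"))
  precursor_file <- file.path(dir, "hairpins.gff")
  writeLines(gff, precursor_file)

  # ground truth for grouping
  shared <- matures[matures$precursor %in%
                      matures$precursor[duplicated(matures$precursor)], ]
  shared_precursors <- if (nrow(shared)) {
    sp <- split(shared$accession, shared$precursor)
    data.frame(precursor = names(sp),
               accessions = vapply(sp, function(a)
                 paste(sort(a), collapse = ";"), ""),
               stringsAsFactors = FALSE)
  } else data.frame(precursor = character(0), accessions = character(0))

  cp <- list()
  for (i in seq_len(n_precursors - 1L)) {
    same <- chrom[i + 1L] == chrom[i] && strand[i + 1L] == strand[i] &&
      (start[i + 1L] - end[i]) <= cluster_window_bp
    if (same) cp[[length(cp) + 1L]] <-
        data.frame(pre1 = pre_acc[i], pre2 = pre_acc[i + 1L],
                   stringsAsFactors = FALSE)
  }
  cluster_pairs <- if (length(cp)) do.call(rbind, cp)
    else data.frame(pre1 = character(0), pre2 = character(0))

  out <- list(alias_file = alias_file, precursor_file = precursor_file,
              truth = list(names = truth, collisions = collisions,
                           cluster_pairs = cluster_pairs,
                           shared_precursors = shared_precursors))
  if (audit) audit_registry(out)
  out
}

audit_registry <- function(sim) {
  reg <- load_registry(sim$alias_file, sim$precursor_file)
  tn <- sim$truth$names
  stopifnot(all(tn$accession %in% reg$matures$accession),
            all(reg$matures$current_name[
              match(tn$accession, reg$matures$accession)] == tn$current_name))
  invisible(TRUE)
}

#' Simulate a log2 expression matrix with planted differential expression
#'
#' Per-miRNA baselines are uniform on [4, 12] log2 units; planted rows get a
#' signed shift of \code{effect_log2fc} in the tumor group; Gaussian noise
#' of \code{noise_sd} log2 units is added everywhere. Detection flags are
#' FALSE for the configurable low-intensity tail of the value distribution.
#'
#' @param n_mirnas,n_tumor,n_normal Matrix dimensions (defaults 500, 19, 5,
#'   the discovery-cohort design).
#' @param n_de Number of planted differentially expressed miRNAs
#'   (default 18).
#' @param effect_log2fc Planted |log2 fold-change| (default 2).
#' @param noise_sd Noise standard deviation in log2 units (default 0.5).
#' @param detect_tail Fraction of lowest values flagged undetected
#'   (default 0.02).
#' @param seed Random seed.
#' @param accessions Optional row names (default synthetic MIMAT ids).
#' @param dir Optional output directory; when given, matrix, detection and
#'   group TSVs are written and audited.
#' @return List with \code{values}, \code{detected}, \code{groups} and
#'   \code{truth} (data frame accession, direction), plus file paths when
#'   \code{dir} is given.
#' @export
simulate_expression <- function(n_mirnas = 500, n_tumor = 19, n_normal = 5,
                                n_de = 18, effect_log2fc = 2, noise_sd = 0.5,
                                detect_tail = 0.02, seed = 1,
                                accessions = NULL, dir = NULL) {
  stopifnot(n_de <= n_mirnas, noise_sd > 0)
  set.seed(seed)
  if (is.null(accessions))
    accessions <- sprintf("MIMAT%07d", seq_len(n_mirnas))
  samples <- c(sprintf("T%03d", seq_len(n_tumor)),
               sprintf("N%03d", seq_len(n_normal)))
  groups <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                            samples)
  baseline <- stats::runif(n_mirnas, 4, 12)
  de_idx <- sort(sample.int(n_mirnas, n_de))
  de_dir <- sample(c(1, -1), n_de, replace = TRUE)
  values <- matrix(baseline, n_mirnas, length(samples),
                   dimnames = list(accessions, samples))
  values[de_idx, seq_len(n_tumor)] <-
    values[de_idx, seq_len(n_tumor)] + de_dir * effect_log2fc
  values <- values + matrix(stats::rnorm(length(values), 0, noise_sd),
                            n_mirnas, length(samples))
  detected <- values > stats::quantile(values, detect_tail)
  truth <- data.frame(accession = accessions[de_idx],
                      direction = ifelse(de_dir > 0, "up", "down"),
                      stringsAsFactors = FALSE)
  out <- list(values = values, detected = detected, groups = groups,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$matrix_file <- write_expression_matrix(
      values, file.path(dir, "expression.tsv"))
    out$detection_file <- write_expression_matrix(
      detected + 0, file.path(dir, "detected.tsv"))
    gf <- file.path(dir, "groups.tsv")
    utils::write.table(data.frame(sample = samples, label = unname(groups)),
                       gf, sep = "\t", quote = FALSE, row.names = FALSE)
    out$groups_file <- gf
    stopifnot(max(abs(read_expression_matrix(out$matrix_file) - values))
              < 1e-6)
  }
  out
}

#' Simulate isoform quantification files with planted group shifts
#'
#' Each sample's reads are drawn multinomially over per-miRNA abundances
#' (log-normal); planted miRNAs have their tumor-group abundance multiplied
#' by \code{2^shift_log2}, and additionally by \code{2^stratum_extra_log2}
#' in one designated tumor stratum, so stratified tests have a signal. The
#' count of each (sample, miRNA) pair is split across 1 to
#' \code{max_isoforms} isoform records; a configurable fraction of miRNAs
#' is emitted under old-release accessions so aggregation must use the
#' release map.
#'
#' @param n_mirnas,n_tumor,n_normal Problem size (defaults 300, 100, 12,
#'   the validation-cohort design scaled down).
#' @param n_shifted Number of planted shifted miRNAs (default 18).
#' @param shift_log2 Planted tumor shift in log2 units (default -2).
#' @param stratum_extra_log2 Extra shift of planted miRNAs in the
#'   \code{"tall_cell"} stratum (default -1).
#' @param depth Reads per sample (default 200000).
#' @param old_accession_fraction Fraction of miRNAs keyed by old-release
#'   accessions (default 0.3).
#' @param max_isoforms Maximum isoform records per (sample, miRNA)
#'   (default 5).
#' @param seed Random seed.
#' @param dir Optional output directory for the per-sample TSVs, release
#'   map, group and stratum files.
#' @return List with \code{records} (data frame), \code{release_map}
#'   (named vector), \code{groups}, \code{strata}, and \code{truth}
#'   (shifted accessions with directions, planted per-(miRNA, sample)
#'   counts as matrix \code{counts}).
#' @export
simulate_isoforms <- function(n_mirnas = 300, n_tumor = 100, n_normal = 12,
                              n_shifted = 18, shift_log2 = -2,
                              stratum_extra_log2 = -1, depth = 200000,
                              old_accession_fraction = 0.3, max_isoforms = 5,
                              seed = 1, dir = NULL) {
  set.seed(seed)
  acc <- sprintf("MIMAT%07d", seq_len(n_mirnas))
  old_sel <- stats::runif(n_mirnas) < old_accession_fraction
  source_acc <- ifelse(old_sel, sprintf("MIMAT%07d", 5e6 + seq_len(n_mirnas)),
                       acc)
  release_map <- stats::setNames(acc, source_acc)

  samples <- c(sprintf("TCGA-T%03d", seq_len(n_tumor)),
               sprintf("TCGA-N%03d", seq_len(n_normal)))
  groups <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                            samples)
  strata <- stats::setNames(
    c(sample(c("classic", "follicular", "tall_cell"), n_tumor,
             replace = TRUE),
      rep("normal", n_normal)), samples)

  abundance <- stats::rlnorm(n_mirnas, meanlog = 4, sdlog = 1.5)
  shifted_idx <- sort(sample.int(n_mirnas, n_shifted))
  counts <- matrix(0, n_mirnas, length(samples),
                   dimnames = list(acc, samples))
  for (s in samples) {
    ab <- abundance
    if (groups[[s]] == "tumor") {
      ab[shifted_idx] <- ab[shifted_idx] * 2^shift_log2
      if (strata[[s]] == "tall_cell")
        ab[shifted_idx] <- ab[shifted_idx] * 2^stratum_extra_log2
    }
    counts[, s] <- stats::rmultinom(1L, depth, ab)
  }

  # split each cell across isoform records (vectors, not frame-binding)
  rec_s <- list(); rec_a <- list(); rec_c <- list()
  for (s in samples) {
    nz <- which(counts[, s] > 0)
    k <- sample.int(max_isoforms, length(nz), replace = TRUE)
    parts <- vector("list", length(nz))
    for (jj in seq_along(nz)) {
      total <- counts[nz[jj], s]
      pp <- if (k[jj] == 1L) total else
        as.vector(stats::rmultinom(1L, total, rep(1, k[jj])))
      parts[[jj]] <- pp[pp > 0]
    }
    lens <- lengths(parts)
    rec_s[[s]] <- rep(s, sum(lens))
    rec_a[[s]] <- rep(source_acc[nz], lens)
    rec_c[[s]] <- unlist(parts, use.names = FALSE)
  }
  records <- data.frame(
    sample_id = unlist(rec_s, use.names = FALSE),
    mature_accession = unlist(rec_a, use.names = FALSE),
    read_count = unlist(rec_c, use.names = FALSE),
    stringsAsFactors = FALSE)

  truth <- list(
    shifted = data.frame(accession = acc[shifted_idx],
                         direction = if (shift_log2 < 0) "down" else "up",
                         stringsAsFactors = FALSE),
    counts = counts)
  out <- list(records = records, release_map = release_map, groups = groups,
              strata = strata, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rf <- file.path(dir, "isoforms.tsv")
    utils::write.table(records, rf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mf <- file.path(dir, "release_map.tsv")
    utils::write.table(
      data.frame(source_accession = source_acc, current_accession = acc),
      mf, sep = "\t", quote = FALSE, row.names = FALSE)
    sf <- file.path(dir, "strata.tsv")
    utils::write.table(data.frame(sample = samples, stratum = unname(strata)),
                       sf, sep = "\t", quote = FALSE, row.names = FALSE)
    gf <- file.path(dir, "groups.tsv")
    utils::write.table(data.frame(sample = samples, label = unname(groups)),
                       gf, sep = "\t", quote = FALSE, row.names = FALSE)
    out$records_file <- rf; out$release_map_file <- mf
    out$strata_file <- sf; out$groups_file <- gf
    agg <- aggregate_isoforms(read_isoform_records(rf), read_release_map(mf))
    stopifnot(all(agg$counts[rownames(counts), colnames(counts)] == counts))
  }
  out
}

#' Simulate heterogeneous study signature tables with a planted consensus
#'
#' Emulates a literature corpus: \code{n_studies} studies each report the
#' planted consensus miRNAs (directions fixed across studies) minus
#' independent dropouts at \code{dropout_rate}, plus study-specific random
#' extras. Studies are assigned a nomenclature era: "old"-era studies write
#' legacy previous names where the registry records one, "new"-era studies
#' write current names. One study is emitted as three datasets to exercise
#' within-study collapsing. The designated most-reported down-regulated
#' miRNA (the consensus member with the smallest accession) is emitted by
#' every study, emulating the field's hallmark reporting pattern.
#'
#' @param registry_sim Output of \code{\link{simulate_registry}}.
#' @param n_studies Number of studies (default 15).
#' @param n_consensus Size of the planted consensus set (default 10; half
#'   up, half down).
#' @param dropout_rate Per-study probability that a non-anchor consensus
#'   miRNA is not reported (default 0.2).
#' @param n_extra Study-specific random non-consensus miRNAs (default 8).
#' @param old_era_fraction Fraction of studies writing legacy names
#'   (default 0.5).
#' @param multi_dataset_study Emit the first study as three datasets
#'   (default TRUE).
#' @param seed Random seed.
#' @param dir Optional output directory for per-dataset TSVs and a
#'   manifest.
#' @return List with \code{studies} (raw, un-harmonized entries as consumed
#'   after harmonization by \code{\link{build_study_matrix}}),
#'   \code{manifest} and \code{truth} (consensus data frame with realized
#'   reporting counts and the anchor accession).
#' @export
simulate_study_signatures <- function(registry_sim, n_studies = 15,
                                      n_consensus = 10, dropout_rate = 0.2,
                                      n_extra = 8, old_era_fraction = 0.5,
                                      multi_dataset_study = TRUE, seed = 1,
                                      dir = NULL) {
  set.seed(seed)
  tn <- registry_sim$truth$names
  # candidate pool: matures with a recorded legacy alias, so old-era
  # studies genuinely exercise harmonization
  with_alias <- tn[!is.na(tn$previous_name), , drop = FALSE]
  with_alias <- with_alias[!duplicated(with_alias$accession), , drop = FALSE]
  stopifnot(nrow(with_alias) >= n_consensus)
  cons <- with_alias[sort(sample.int(nrow(with_alias), n_consensus)), ]
  n_dn <- ceiling(n_consensus / 2)
  # anchor: smallest accession, forced down-regulated and never dropped
  cons <- cons[order(cons$accession), ]
  dirs <- c(rep("down", n_dn), rep("up", n_consensus - n_dn))
  consensus <- data.frame(accession = cons$accession,
                          current_name = cons$current_name,
                          previous_name = cons$previous_name,
                          direction = dirs, stringsAsFactors = FALSE)
  anchor <- consensus$accession[1L]
  pool <- tn[!tn$accession %in% consensus$accession, , drop = FALSE]

  eras <- sample(rep(c("old", "new"),
                     c(round(n_studies * old_era_fraction),
                       n_studies - round(n_studies * old_era_fraction))))
  study_ids <- sprintf("S%02d", seq_len(n_studies))

  name_for <- function(row, era) {
    if (era == "old" && !is.na(row$previous_name)) row$previous_name
    else row$current_name
  }

  reported <- matrix(FALSE, n_consensus, n_studies)
  studies <- list(); manifest <- list()
  for (j in seq_len(n_studies)) {
    keep <- stats::runif(n_consensus) >= dropout_rate
    keep[consensus$accession == anchor] <- TRUE
    reported[, j] <- keep
    rows <- consensus[keep, , drop = FALSE]
    entries <- data.frame(
      raw_name = vapply(seq_len(nrow(rows)), function(i)
        name_for(rows[i, ], eras[j]), ""),
      direction = rows$direction,
      fc = round(ifelse(rows$direction == "up", 1, -1) *
                   stats::runif(nrow(rows), 1.5, 6), 2),
      stringsAsFactors = FALSE)
    if (n_extra > 0L && nrow(pool) > 0L) {
      ex <- pool[sample.int(nrow(pool), min(n_extra, nrow(pool))), ]
      entries <- rbind(entries, data.frame(
        raw_name = vapply(seq_len(nrow(ex)), function(i)
          name_for(ex[i, ], eras[j]), ""),
        direction = sample(c("up", "down"), nrow(ex), replace = TRUE),
        fc = round(stats::runif(nrow(ex), -4, 4), 2),
        stringsAsFactors = FALSE))
    }
    if (multi_dataset_study && j == 1L) {
      # spread entries over three datasets with overlap
      k <- nrow(entries)
      dsets <- lapply(1:3, function(d) {
        sel <- sort(unique(c(sample.int(k, ceiling(k * 0.6)))))
        entries[sel, , drop = FALSE]
      })
      names(dsets) <- paste0(study_ids[j], letters[1:3])
      studies[[j]] <- list(study_id = study_ids[j], era = eras[j],
                           datasets = dsets)
    } else {
      studies[[j]] <- list(study_id = study_ids[j], era = eras[j],
                           datasets = stats::setNames(
                             list(entries), paste0(study_ids[j], "a")))
    }
  }
  realized <- rowSums(reported)
  consensus$n_studies_reporting <- realized

  out <- list(studies = studies,
              truth = list(consensus = consensus, anchor = anchor))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    man <- list()
    for (s in out$studies) for (dn in names(s$datasets)) {
      f <- paste0(dn, ".tsv")
      utils::write.table(s$datasets[[dn]], file.path(dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      man[[length(man) + 1L]] <- data.frame(
        study_id = s$study_id, dataset_id = dn, file = f, era = s$era,
        stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, man)
    mf <- file.path(dir, "manifest.tsv")
    utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$manifest_file <- mf
    out$manifest <- manifest
  }
  out
}

#' Harmonize simulated studies and build the study-miRNA matrix
#'
#' Convenience driver used in examples and validation runs: harmonizes each
#' simulated study's raw entries against a registry and builds the
#' vote-counting matrix.
#'
#' @param study_sim Output of \code{\link{simulate_study_signatures}}.
#' @param registry A \code{mirna_registry}.
#' @return A \code{study_mirna_matrix}.
#' @export
harmonized_study_matrix <- function(study_sim, registry) {
  studies <- lapply(study_sim$studies, function(s) {
    list(study_id = s$study_id,
         datasets = lapply(s$datasets, function(d)
           harmonize_signature(d, registry)$signature))
  })
  build_study_matrix(studies)
}
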