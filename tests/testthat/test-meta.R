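test_that("dataset collapsing applies the union rule with conflict flags", {
  up <- sig_frame("MIMAT0000001", "up")
  dn <- sig_frame("MIMAT0000001", "down")
  none <- sig_frame(character(0), character(0))
  expect_equal(collapse_datasets(list(up, up, none))$call, "up")
  expect_equal(collapse_datasets(list(up, dn))$call, "conflict")
  expect_equal(collapse_datasets(list(dn)),
               data.frame(accession = "MIMAT0000001", call = "down",
                          stringsAsFactors = FALSE))
  expect_error(collapse_datasets(list()), "at least one")
})

test_that("the study-miRNA matrix counts votes per direction", {
  st <- function(id, ...) list(study_id = id, datasets = list(...))
  A <- "MIMAT0000001"; B <- "MIMAT0000002"
  m <- build_study_matrix(list(
    st("S1", sig_frame(c(A, B), c("up", "down"))),
    st("S2", sig_frame(A, "up")),
    st("S3", sig_frame(c(A, B), c("up", "up")))))
  expect_equal(m$scores$up_count[m$scores$accession == A], 3)
  expect_equal(m$scores$up_count[m$scores$accession == B], 1)
  expect_equal(m$scores$down_count[m$scores$accession == B], 1)
  expect_equal(m$calls[B, "S2"], "none")
  expect_error(build_study_matrix(list(st("S1", sig_frame(A, "up")),
                                       st("S1", sig_frame(A, "up")))),
               "duplicate study_id")

  fs <- frequency_score(m)
  expect_equal(fs$up$accession[1], A)
  expect_equal(fs$up$score[1], 3)
  expect_true(B %in% fs$up$accession && B %in% fs$down$accession)

  # a study reporting nothing changes no score
  m2 <- build_study_matrix(list(
    st("S1", sig_frame(c(A, B), c("up", "down"))),
    st("S2", sig_frame(A, "up")),
    st("S3", sig_frame(c(A, B), c("up", "up"))),
    st("S4", none = sig_frame(character(0), character(0)))))
  expect_equal(m2$scores[, c("up_count", "down_count")],
               m$scores[, c("up_count", "down_count")])

  # conflicted studies support neither direction
  mc <- build_study_matrix(list(
    st("S1", sig_frame(A, "up"), sig_frame(A, "down")),
    st("S2", sig_frame(A, "up"))))
  expect_equal(mc$calls[A, "S1"], "conflict")
  expect_equal(mc$scores$up_count, 1)
  expect_equal(mc$scores$down_count, 0)
  # a conflict-only miRNA is dropped by the min-studies filter
  expect_equal(nrow(filter_min_studies(mc, 2)$scores), 0)
})

test_that("min-studies filter keeps miRNAs reported at least k times", {
  st <- function(id, sig) list(study_id = id, datasets = list(sig))
  m <- build_study_matrix(list(
    st("S1", sig_frame(c("A", "B"), c("up", "up"))),
    st("S2", sig_frame("A", "up"))))
  f <- filter_min_studies(m, 2)
  expect_equal(f$scores$accession, "A")
  expect_equal(filter_min_studies(m, 1)$scores, m$scores)
  expect_error(filter_min_studies(m, 0), ">= 1")
})

test_that("scores are invariant to study order and nomenclature era", {
  sim <- simulate_registry(n_precursors = 80, seed = 31)
  reg <- load_registry(sim$alias_file, sim$precursor_file)
  ss <- simulate_study_signatures(sim, n_studies = 8, seed = 31)
  m1 <- harmonized_study_matrix(ss, reg)
  ss_rev <- ss; ss_rev$studies <- rev(ss$studies)
  m2 <- harmonized_study_matrix(ss_rev, reg)
  expect_equal(m1$scores, m2$scores)
  expect_equal(m1$calls, m2$calls[, colnames(m1$calls)])

  # rewriting every study in the current era leaves scores unchanged
  tn <- sim$truth$names
  to_current <- function(d) {
    key <- normalize_mirna_name(d$raw_name)
    idx_prev <- match(key, normalize_mirna_name(tn$previous_name))
    idx_cur <- match(key, normalize_mirna_name(tn$current_name))
    idx <- ifelse(is.na(idx_cur), idx_prev, idx_cur)
    d$raw_name <- tn$current_name[idx]
    d
  }
  ss_new <- ss
  ss_new$studies <- lapply(ss$studies, function(s) {
    s$datasets <- lapply(s$datasets, to_current); s
  })
  m3 <- harmonized_study_matrix(ss_new, reg)
  expect_equal(m1$scores, m3$scores)
})

test_that("planted consensus is recovered across eras after harmonization", {
  sim <- simulate_registry(n_precursors = 120, seed = 17)
  reg <- load_registry(sim$alias_file, sim$precursor_file)
  ss <- simulate_study_signatures(sim, n_studies = 15, dropout_rate = 0.2,
                                  seed = 17)
  m <- filter_min_studies(harmonized_study_matrix(ss, reg), 2)
  cons <- ss$truth$consensus
  expect_true(all(cons$accession %in% m$scores$accession))
  got <- m$scores[match(cons$accession, m$scores$accession), ]
  reported <- ifelse(cons$direction == "up", got$up_count, got$down_count)
  expect_equal(unname(reported), cons$n_studies_reporting)
  fs <- frequency_score(m)
  expect_equal(fs$down$accession[1], ss$truth$anchor)
})

test_that("study tables round-trip through the manifest reader", {
  dir <- tempfile()
  sim <- simulate_registry(n_precursors = 60, seed = 23)
  reg <- load_registry(sim$alias_file, sim$precursor_file)
  ss <- simulate_study_signatures(sim, n_studies = 5, seed = 23, dir = dir)
  loaded <- read_study_signatures(ss$manifest_file, reg)
  m_file <- build_study_matrix(loaded$studies)
  m_mem <- harmonized_study_matrix(ss, reg)
  expect_equal(m_file$scores, m_mem$scores)
  # multi-dataset study present as three datasets
  n_ds <- vapply(loaded$studies, function(s) length(s$datasets), 1L)
  expect_true(3 %in% n_ds)
})
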