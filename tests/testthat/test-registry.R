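test_that("alias table parsing takes the last name as current", {
  path <- write_alias_fixture("MIMAT0000011\thsa-miR-9001;hsa-miR-9001-5p;")
  reg <- load_registry(path)
  expect_equal(reg$matures$current_name, "hsa-miR-9001-5p")
  expect_equal(reg$matures$previous_names[[1]], "hsa-miR-9001")
  expect_equal(reg$matures$arm, "5p")
})

test_that("malformed or degenerate alias tables are hard errors", {
  empty <- write_alias_fixture(character(0))
  expect_error(load_registry(empty), "no mature records")
  bad <- write_alias_fixture(c("MIMAT0000001\ta;", "MIRX123\tb;"))
  expect_error(load_registry(bad), "line 2")
  dup <- write_alias_fixture(c("MIMAT0000001\ta;", "MIMAT0000001\tb;"))
  expect_error(load_registry(dup), "duplicate")
})

test_that("a rename chain resolves under both the legacy and current name", {
  path <- write_alias_fixture("MIMAT0001631\thsa-miR-451;hsa-miR-451a;")
  reg <- load_registry(path)
  for (q in c("miR-451", "hsa-miR-451", "miR-451a", "MIR-451A")) {
    r <- resolve_name(q, reg)
    expect_equal(r$status, "resolved")
    expect_equal(r$accessions, "MIMAT0001631")
  }
})

test_that("resolution statuses: resolved, ambiguous, unknown", {
  reg <- tiny_registry()
  r <- resolve_name("miR-451", reg)
  expect_equal(r$status, "resolved")
  expect_equal(r$accessions, "MIMAT0000001")
  # 'hsa-miR-222' is a previous name of both arms in the fixture
  amb <- resolve_name("miR-222", reg)
  expect_equal(amb$status, "ambiguous")
  expect_equal(amb$accessions, c("MIMAT0000005", "MIMAT0000006"))
  unk <- resolve_name("miR-00000", reg)
  expect_equal(unk$status, "unknown")
  expect_length(unk$accessions, 0)
  # arm-less names never get an arm guessed: miR-144 has no recorded alias
  expect_equal(resolve_name("miR-144", reg)$status, "unknown")
  expect_error(resolve_name("", reg), "non-empty")
})

test_that("harmonization merges duplicates and reports the rest", {
  reg <- tiny_registry()
  ent <- data.frame(raw_name = c("miR-146b", "hsa-miR-146b-5p"),
                    direction = c("up", "up"), fc = c(2.1, 3.4),
                    stringsAsFactors = FALSE)
  h <- harmonize_signature(ent, reg)
  expect_equal(nrow(h$signature), 1)
  expect_equal(h$signature$accession, "MIMAT0000007")
  expect_equal(h$signature$fc, 3.4)   # largest magnitude kept
  expect_equal(nrow(h$report), 0)

  h0 <- harmonize_signature(data.frame(), reg)
  expect_equal(nrow(h0$signature), 0)
  expect_equal(nrow(h0$report), 0)

  conf <- harmonize_signature(
    data.frame(raw_name = c("miR-451a", "miR-451a"),
               direction = c("up", "down"), stringsAsFactors = FALSE), reg)
  expect_equal(nrow(conf$signature), 0)
  expect_equal(conf$report$status, "conflict")

  mixed <- harmonize_signature(
    data.frame(raw_name = c("miR-451a", "miR-222", "miR-xyz"),
               direction = c("down", "up", "up"), stringsAsFactors = FALSE),
    reg)
  expect_equal(mixed$signature$accession, "MIMAT0000001")
  expect_setequal(mixed$report$status, c("ambiguous", "unknown"))
})

test_that("grouping recovers shared precursors, clusters and families", {
  reg <- tiny_registry()
  accs <- sprintf("MIMAT%07d", 1:7)
  g <- group_mirnas(accs, reg, cluster_window_bp = 10000)
  # miR-221-3p/5p share one hairpin
  expect_true(any(vapply(g$shared_precursor, function(x)
    identical(x, c("MIMAT0000003", "MIMAT0000004")), TRUE)))
  # 451a and 144 hairpins 100 bp apart on one strand
  expect_true(any(vapply(g$cluster, function(x)
    identical(x, c("MIMAT0000001", "MIMAT0000002")), TRUE)))
  # 221 and 222 precursors 11 kb apart: clustered at window 15k, not 10k
  g2 <- group_mirnas(accs, reg, cluster_window_bp = 15000)
  expect_true(any(vapply(g2$cluster, function(x)
    identical(x, sprintf("MIMAT%07d", 3:6)), TRUE)))
  expect_false(any(vapply(g$cluster, function(x)
    "MIMAT0000003" %in% x, TRUE)))
  # family labels from the GFF attributes
  expect_true(any(vapply(g$family, function(x)
    identical(x, sprintf("MIMAT%07d", 3:6)), TRUE)))
  expect_error(group_mirnas("MIMAT9999999", reg), "MIMAT9999999")
})

test_that("opposite strands never cluster regardless of distance", {
  alias <- write_alias_fixture(c("MIMAT0000001\thsa-miR-1-5p;",
                                 "MIMAT0000002\thsa-miR-2-5p;"))
  gff <- tempfile(fileext = ".gff")
  writeLines(c(gff_pre("chr1", 100, 180, "+", "MI0000001", "hsa-mir-1"),
               gff_pre("chr1", 200, 280, "-", "MI0000002", "hsa-mir-2"),
               gff_mat("chr1", 110, "+", "MIMAT0000001", "hsa-miR-1-5p",
                       "MI0000001"),
               gff_mat("chr1", 210, "-", "MIMAT0000002", "hsa-miR-2-5p",
                       "MI0000002")), gff)
  reg <- load_registry(alias, gff)
  g <- group_mirnas(c("MIMAT0000001", "MIMAT0000002"), reg, 10000)
  expect_length(g$cluster, 0)
})

test_that("generated registries round-trip every name; collisions stay ambiguous", {
  sim <- simulate_registry(n_precursors = 60, rename_fraction = 0.5,
                           n_collisions = 3, seed = 13)
  reg <- load_registry(sim$alias_file, sim$precursor_file)
  tn <- sim$truth$names
  for (i in seq_len(nrow(tn))) {
    r <- resolve_name(tn$current_name[i], reg)
    expect_identical(r$status, "resolved")
    expect_identical(r$accessions, tn$accession[i])
    if (!is.na(tn$previous_name[i])) {
      r2 <- resolve_name(tn$previous_name[i], reg)
      expect_identical(r2$status, "resolved")
      expect_identical(r2$accessions, tn$accession[i])
    }
  }
  for (i in seq_len(nrow(sim$truth$collisions))) {
    r <- resolve_name(sim$truth$collisions$previous_name[i], reg)
    expect_identical(r$status, "ambiguous")
    expect_identical(paste(r$accessions, collapse = ";"),
                     sim$truth$collisions$accessions[i])
  }
})

test_that("grouping is invariant to input order and cluster relation is transitive", {
  sim <- simulate_registry(n_precursors = 50, cluster_pair_fraction = 0.4,
                           seed = 21)
  reg <- load_registry(sim$alias_file, sim$precursor_file)
  accs <- reg$matures$accession
  set.seed(1)
  g1 <- group_mirnas(accs, reg)
  g2 <- group_mirnas(sample(accs), reg)
  expect_equal(g1, g2)
  # transitivity: planted consecutive pairs chain into one group
  cp <- sim$truth$cluster_pairs
  if (nrow(cp) >= 2) {
    for (i in seq_len(nrow(cp))) {
      in_one <- vapply(g1$cluster, function(grp) {
        m1 <- reg$matures$accession[vapply(reg$matures$precursor_accessions,
                                           function(p) cp$pre1[i] %in% p, TRUE)]
        m2 <- reg$matures$accession[vapply(reg$matures$precursor_accessions,
                                           function(p) cp$pre2[i] %in% p, TRUE)]
        all(c(m1, m2) %in% grp)
      }, TRUE)
      expect_true(any(in_one))
    }
  }
})
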