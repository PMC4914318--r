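test_that("isoform aggregation sums per accession and reports unmapped", {
  rec <- data.frame(sample_id = c("S1", "S1", "S1", "S2"),
                    mature_accession = c("MIMAT-A", "MIMAT-A", "MIMAT-Z",
                                         "MIMAT-A"),
                    read_count = c(10, 5, 7, 3), stringsAsFactors = FALSE)
  map <- c("MIMAT-A" = "MIMAT0000001")
  agg <- aggregate_isoforms(rec, map)
  expect_equal(agg$counts["MIMAT0000001", "S1"], 15)
  expect_equal(agg$counts["MIMAT0000001", "S2"], 3)
  expect_equal(agg$unmapped$mature_accession, "MIMAT-Z")
  # read conservation for mapped accessions
  expect_equal(sum(agg$counts), sum(rec$read_count) - 7)

  empty <- aggregate_isoforms(rec[0, ], map)
  expect_equal(dim(empty$counts), c(0L, 0L))
  rec$read_count[1] <- -1
  expect_error(aggregate_isoforms(rec, map), "negative")
})

test_that("RPM columns sum to one million and zero-total samples error", {
  m <- matrix(c(2000, 1998000, 5, 0), 2, 2,
              dimnames = list(c("a", "b"), c("S1", "S2")))
  r <- rpm_normalize(m)
  expect_equal(r["a", "S1"], 1000)
  expect_equal(r["a", "S2"], 1e6)  # single-miRNA sample
  set.seed(5)
  rm <- matrix(rpois(60, 50) + 1, 6, 10)
  colnames(rm) <- paste0("S", 1:10)
  expect_lt(max(abs(colSums(rpm_normalize(rm)) - 1e6)), 1e-6)
  rm[, 3] <- 0
  expect_error(rpm_normalize(rm), "S3")
})

test_that("zero replacement uses the minimum non-zero value before log2", {
  m <- matrix(c(0, 2, 4, 8), 2, 2)
  expect_equal(log2_with_zero_replacement(m), matrix(c(1, 1, 2, 3), 2, 2))
  m2 <- matrix(c(1, 2, 4, 8), 2, 2)
  expect_equal(log2_with_zero_replacement(m2), log2(m2))
  expect_error(log2_with_zero_replacement(matrix(0, 1, 1)), "non-zero")
  # per-miRNA scope replaces with each row's own minimum
  m3 <- matrix(c(0, 0, 4, 2, 8, 16), 2, 3)
  pm <- log2_with_zero_replacement(m3, scope = "per_mirna")
  expect_equal(2^pm[1, 1], 4)  # row 1 min non-zero is 4
  expect_equal(2^pm[2, 1], 2)  # row 2 min non-zero is 2
})

test_that("two-group validation recovers planted shifts and reduces to p at m=1", {
  iso <- simulate_isoforms(n_mirnas = 80, n_tumor = 40, n_normal = 10,
                           n_shifted = 6, depth = 50000, seed = 6)
  agg <- aggregate_isoforms(iso$records, iso$release_map)
  lg <- log2_with_zero_replacement(rpm_normalize(agg$counts))
  tv <- two_group_validation(lg, iso$groups, iso$truth$shifted$accession)
  expect_true(all(tv$q < 0.01))
  expect_true(all(tv$direction == "down"))
  one <- two_group_validation(lg, iso$groups, rownames(lg)[1])
  expect_equal(one$q, one$p)
  expect_error(two_group_validation(lg, iso$groups, "MIMAT9999999"),
               "MIMAT9999999")
})

test_that("pairwise strata tests cover reference and tumor-stratum pairs", {
  set.seed(2)
  v <- c(rnorm(10, 8), rnorm(8, 6), rnorm(8, 7), rnorm(9, 7))
  s <- rep(c("normal", "tall_cell", "classic", "follicular"),
           c(10, 8, 8, 9))
  tab <- pairwise_strata_tests(v, s, reference = "normal")
  expect_equal(nrow(tab), 3 + 3)  # 3 vs reference + 3 tumor pairs
  expect_true(all(tab$group1 != tab$group2))
  expect_error(pairwise_strata_tests(v, s, "missing"), "absent")
  # identical strata give p = 1
  same <- pairwise_strata_tests(rep(1:4, 2), rep(c("a", "b"), each = 4), "a")
  expect_equal(same$p, 1)
  # two strata reduce to the plain rank-sum test
  two <- pairwise_strata_tests(v[s %in% c("normal", "classic")],
                               s[s %in% c("normal", "classic")], "normal")
  expect_equal(nrow(two), 1)
  expect_equal(two$p, rank_sum_test(v[s == "normal"], v[s == "classic"]))
})

test_that("isoform files round-trip and conserve planted counts", {
  dir <- tempfile()
  iso <- simulate_isoforms(n_mirnas = 30, n_tumor = 10, n_normal = 4,
                           depth = 20000, seed = 3, dir = dir)
  rec <- read_isoform_records(iso$records_file)
  map <- read_release_map(iso$release_map_file)
  agg <- aggregate_isoforms(rec, map)
  expect_equal(agg$counts, iso$truth$counts[rownames(agg$counts),
                                            colnames(agg$counts)])
  expect_equal(nrow(agg$unmapped), 0)
  # per-sample totals conserved through aggregation
  tot_in <- tapply(rec$read_count, rec$sample_id, sum)
  expect_equal(unname(colSums(agg$counts)[names(tot_in)]),
               unname(as.numeric(tot_in)))
})

test_that("fully old-release records with an empty map all land unmapped", {
  iso <- simulate_isoforms(n_mirnas = 20, n_tumor = 5, n_normal = 2,
                           old_accession_fraction = 1, depth = 5000,
                           seed = 9)
  agg <- aggregate_isoforms(iso$records, c(X = "Y"))
  expect_equal(dim(agg$counts), c(0L, 0L))
  expect_equal(nrow(agg$unmapped), nrow(iso$records))
})
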