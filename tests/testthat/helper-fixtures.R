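# Small hand-written registry fixtures built in code.

write_alias_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(rows, path)
  path
}

gff_pre <- function(chrom, start, end, strand, id, name, family = "") {
  attrs <- paste0("ID=", id, ";Name=", name,
                  if (nzchar(family)) paste0(";family=", family) else "")
  paste(chrom, "fixture", "miRNA_primary_transcript", start, end, ".",
        strand, ".", attrs, sep = "\t")
}

gff_mat <- function(chrom, start, strand, id, name, from) {
  paste(chrom, "fixture", "miRNA", start, start + 21L, ".", strand, ".",
        paste0("ID=", id, ";Name=", name, ";Derives_from=", from),
        sep = "\t")
}

# A registry fixture covering renames, a 5p/3p shared precursor, a tight
# genomic cluster (451a/144-like) and an ambiguous legacy name shared by
# the two arms of an 222-like duplex.
tiny_registry <- function() {
  alias <- write_alias_fixture(c(
    "MIMAT0000001\thsa-miR-451;hsa-miR-451a;",
    "MIMAT0000002\thsa-miR-144-5p;",
    "MIMAT0000003\thsa-miR-221;hsa-miR-221-3p;",
    "MIMAT0000004\thsa-miR-221*;hsa-miR-221-5p;",
    "MIMAT0000005\thsa-miR-222;hsa-miR-222-3p;",
    "MIMAT0000006\thsa-miR-222;hsa-miR-222-5p;",
    "MIMAT0000007\thsa-miR-146b;hsa-miR-146b-5p;"))
  gff <- tempfile(fileext = ".gff")
  writeLines(c(
    "##gff-version 3",
    gff_pre("chr17", 1000, 1084, "-", "MI0000100", "hsa-mir-451a"),
    gff_pre("chr17", 1184, 1269, "-", "MI0000101", "hsa-mir-144"),
    gff_pre("chrX", 50000, 50109, "-", "MI0000102", "hsa-mir-221",
            family = "mir-221"),
    gff_pre("chrX", 61000, 61109, "-", "MI0000103", "hsa-mir-222",
            family = "mir-221"),
    gff_pre("chr10", 9000, 9099, "+", "MI0000104", "hsa-mir-146b",
            family = "mir-146"),
    gff_mat("chr17", 1010, "-", "MIMAT0000001", "hsa-miR-451a", "MI0000100"),
    gff_mat("chr17", 1200, "-", "MIMAT0000002", "hsa-miR-144-5p", "MI0000101"),
    gff_mat("chrX", 50010, "-", "MIMAT0000003", "hsa-miR-221-3p", "MI0000102"),
    gff_mat("chrX", 50050, "-", "MIMAT0000004", "hsa-miR-221-5p", "MI0000102"),
    gff_mat("chrX", 61010, "-", "MIMAT0000005", "hsa-miR-222-3p", "MI0000103"),
    gff_mat("chrX", 61050, "-", "MIMAT0000006", "hsa-miR-222-5p", "MI0000103"),
    gff_mat("chr10", 9010, "+", "MIMAT0000007", "hsa-miR-146b-5p",
            "MI0000104")), gff)
  load_registry(alias, gff)
}

# A minimal mirna_de-like frame from explicit columns.
de_frame <- function(accession, log2fc, p, fdr = NULL) {
  if (is.null(fdr)) fdr <- bh_adjust(p)
  data.frame(accession = accession, log2fc = log2fc,
             linear_fc = ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc))),
             p = p, fdr = fdr, stringsAsFactors = FALSE)
}

sig_frame <- function(accession, direction) {
  data.frame(accession = accession, direction = direction,
             stringsAsFactors = FALSE)
}

random_signature <- function(pool, n) {
  sig_frame(sample(pool, n), sample(c("up", "down"), n, replace = TRUE))
}

# Accessions of the four hallmark miRNAs used in the toy intersection
# fixture: miR-222-3p up; miR-451a, miR-199a-3p, miR-214-3p down
# (tumor-oriented).
hallmark <- c(mir222 = "MIMAT0000279", mir451a = "MIMAT0001631",
              mir199a = "MIMAT0000232", mir214 = "MIMAT0000271")

toy_triple <- function() {
  clinical <- sig_frame(
    c(hallmark, "MIMAT0000011", "MIMAT0000012"),
    c("up", "down", "down", "down", "up", "down"))
  model1 <- sig_frame(
    c(hallmark, "MIMAT0000013"),
    c("up", "down", "down", "down", "down"))
  # inhibition model: the comparison baseline is the oncogene-active state,
  # so the written directions flip under tumor orientation
  model2 <- sig_frame(
    c(hallmark, "MIMAT0000011"),
    c("down", "up", "up", "up", "up"))
  list(oriented_signature(clinical, "tumor_like_is_up"),
       oriented_signature(model1, "tumor_like_is_up"),
       oriented_signature(model2, "tumor_like_is_down"))
}
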