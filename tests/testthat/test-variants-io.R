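write_test_vcf <- function(path, rows,
                           format = "GT:AD:DP",
                           sample = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"Reference depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  writeLines(c(header, rows), path)
  path
}

test_that("VCF records map to observations (GATK-style AD)", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path,
    "chrM\t1888\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP\t0/1:4500,500:5000")
  prof <- read_vcf_profile(path, tissue = "tumor")
  expect_equal(nrow(prof$observations), 1L)
  obs <- prof$observations
  expect_equal(obs$position, 1888L)
  expect_equal(obs$ref_base, "G")
  expect_equal(obs$alt_base, "A")
  expect_equal(obs$total_depth, 5000L)
  expect_equal(obs$ref_reads, 4500L)
  expect_equal(obs$alt_reads, 500L)
})

test_that("VarScan-style RD/AD encoding is recognised", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path,
    "chrM\t1888\t.\tG\tA\t.\tPASS\t.\tGT:AD:RD:DP\t0/1:500:4500:5000")
  obs <- read_vcf_profile(path, tissue = "tumor")$observations
  expect_equal(obs$ref_reads, 4500L)
  expect_equal(obs$alt_reads, 500L)
})

test_that("multi-allelic records split; indels are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "chrM\t100\t.\tG\tA,T\t.\tPASS\t.\tGT:AD:DP\t0/1:4000,600,400:5000",
    "chrM\t200\t.\tGA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:4000,1000:5000",
    "chrM\t300\t.\tC\tCTT\t.\tPASS\t.\tGT:AD:DP\t0/1:4000,1000:5000"))
  prof <- read_vcf_profile(path, tissue = "tumor")
  expect_equal(nrow(prof$observations), 2L)
  expect_equal(prof$observations$alt_base, c("A", "T"))
  expect_equal(prof$observations$alt_reads, c(600L, 400L))
  expect_equal(unname(prof$skipped["non_snv"]), 2L)
})

test_that("records off the mitochondrial contig are skipped with warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "chr1\t100\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP\t0/1:4000,1000:5000",
    "MT\t500\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:4000,1000:5000"))
  expect_warning(prof <- read_vcf_profile(path, tissue = "normal"),
                 "non-mitochondrial")
  expect_equal(nrow(prof$observations), 1L)
  expect_equal(prof$observations$position, 500L)
})

test_that("missing depth fields raise a format error naming the record", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, "chrM\t100\t.\tG\tA\t.\tPASS\t.\tGT\t0/1")
  expect_error(read_vcf_profile(path, tissue = "tumor"), "100")
})

test_that("catalog TSV round-trips through sample profiles", {
  df <- data.frame(
    sample_id = c("A", "A", "B"), tissue = c("tumor", "tumor", "normal"),
    mean_coverage = c(4800, 4800, 5100),
    position = c(3842L, 7953L, 263L),
    ref_base = c("G", "T", "A"), alt_base = c("A", "G", "G"),
    total_depth = c(5000L, 4000L, 4500L),
    ref_reads = c(4000L, 3000L, 100L), alt_reads = c(1000L, 1000L, 4400L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  profs <- read_catalog_tsv(path)
  expect_named(profs, c("A", "B"))
  expect_equal(nrow(profs$A$observations), 2L)
  expect_equal(profs$B$tissue, "normal")
  expect_equal(profs$A$observations$position, c(3842L, 7953L))
})

test_that("unknown tissue labels and empty catalogs behave per contract", {
  df <- data.frame(sample_id = "A", tissue = "serum", mean_coverage = 5000,
                   position = 100L, ref_base = "G", alt_base = "A",
                   total_depth = 100L, ref_reads = 50L, alt_reads = 50L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_catalog_tsv(path), "tissue")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[0, ], path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_length(read_catalog_tsv(path2), 0L)
})

test_that("annotated catalogs round-trip without loss", {
  pair <- make_pair()
  mut <- call_somatic(pair$tumor, pair$normal, patient_id = "P1")
  mut <- flag_known(mut)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_catalog(mut, path)
  back <- read_annotated_catalog(path)
  for (col in c("patient_id", "position", "ref_base", "alt_base", "gene",
                "region_class", "complex", "substitution_class",
                "heteroplasmy", "novel", "pathogenic")) {
    expect_equal(back[[col]], mut[[col]], info = col)
  }
  expect_equal(back$maf_percent, mut$maf_percent, tolerance = 1e-12)
  # empty catalog -> header-only file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_catalog(mut[0, ], path2)
  expect_equal(length(readLines(path2)), 1L)
  expect_equal(nrow(read_annotated_catalog(path2)), 0L)
})

test_that("known-variant tables validate and key uniquely", {
  df <- data.frame(position = c(263L, 263L), ref_base = "A", alt_base = "G",
                   reported_in_databases = "yes", pathogenic = "no",
                   haplogroup_marker = "yes")
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_known_variants(path), "duplicate")
  write.table(df[1, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  kv <- read_known_variants(path)
  expect_true(kv$haplogroup_marker)
  expect_false(kv$pathogenic)
  empty <- read_known_variants(NULL)
  expect_equal(nrow(empty), 0L)
})

test_that("manifests reject duplicate tissue entries per patient", {
  df <- data.frame(patient_id = c("P1", "P1"), sample_id = c("a", "b"),
                   tissue = c("tumor", "tumor"), ancestry = "European",
                   stage = "II", age = "60")
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest_tsv(path), "more than one")
})
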