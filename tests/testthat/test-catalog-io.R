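test_that("VCF catalogs are parsed, typed by allele length and sorted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(path, c(
    "chr1\t5000\t.\tG\tA\t.\tPASS\t.",
    "chr1\t100\t.\tC\tT\t.\tPASS\tAF=0.41",
    "chr1\t101\t.\tA\tG\t.\tPASS\tAF=0.44"))
  cat <- read_catalog(path, format = "vcf", sample_id = "s1")
  expect_equal(n_mutations(cat), 3L)
  expect_equal(cat$records$pos, c(100L, 101L, 5000L))
  expect_true(all(cat$records$class == "SBS"))
  expect_equal(cat$records$vaf[1:2], c(0.41, 0.44))

  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(path2, "chr1\t100\t.\tCT\tC\t.\tPASS\t.")
  cat2 <- read_catalog(path2, format = "vcf")
  expect_equal(cat2$records$class, "INDEL")
  expect_equal(cat2$records$pos, 100L)
})

test_that("duplicate positions are deduplicated with the first kept", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(path, c(
    "chr1\t100\t.\tC\tT\t.\tPASS\t.",
    "chr1\t100\t.\tC\tG\t.\tPASS\t."))
  expect_message(cat <- read_catalog(path, format = "vcf"), "duplicate")
  expect_equal(n_mutations(cat), 1L)
  expect_equal(cat$records$alt, "T")
})

test_that("multi-allelic rows are split before deduplication", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(path, c(
    "chr1\t100\t.\tC\tT,G\t.\tPASS\t.",
    "chr1\t500\t.\tA\tC,ACC\t.\tPASS\t."))
  # the split happens first; same-position alternates then collapse to one
  expect_message(cat <- read_catalog(path, format = "vcf"), "duplicate")
  expect_equal(cat$records$pos, c(100L, 500L))
  expect_equal(cat$records$alt, c("T", "C"))
})

test_that("MAF and text dialects load with VAF/CCF", {
  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    paste("Chromosome", "Start_Position", "Reference_Allele",
          "Tumor_Seq_Allele2", "Tumor_Sample_Barcode", "t_alt_count",
          "t_depth", sep = "\t"),
    "chr1\t200\tC\tA\tTCGA-XX\t30\t100",
    "chr1\t900\tT\tG\tTCGA-XX\t10\t40"), maf)
  cm <- read_catalog(maf, format = "maf")
  expect_equal(cm$sample_id, "TCGA-XX")
  expect_equal(cm$records$vaf, c(0.30, 0.25))

  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("sample\tchrom\tpos\tref\talt\tvaf\tccf",
               "s2\tchr1\t10\tA\tT\t0.5\t0.9",
               "s2\tchr1\t40\tC\tG\t0.2\t0.4"), txt)
  ct <- read_catalog(txt, format = "text")
  expect_equal(ct$sample_id, "s2")
  expect_equal(ct$records$ccf, c(0.9, 0.4))
})

test_that("records on chromosomes absent from the reference are dropped", {
  g <- tiny_genome(strrep("ACGT", 10))
  rec <- data.frame(chrom = c("chr1", "chrMadeUp"), pos = c(5L, 5L),
                    ref = "A", alt = "T")
  expect_message(cat <- mutation_catalog(rec, "s", genome = g), "absent")
  expect_equal(n_mutations(cat), 1L)
})

test_that("sequence context extraction handles centre, ends and k = 1", {
  g <- tiny_genome("AACGTAA")
  expect_equal(extract_context(g, "chr1", 4, k = 5), "ACGTA")
  expect_true(is.na(extract_context(g, "chr1", 1, k = 5)))
  expect_equal(extract_context(g, "chr1", 3, k = 1), "C")
  # k = 5 agrees with k = 3 on the central trimer wherever both exist
  pos <- 3:5
  k5 <- extract_context(g, "chr1", pos, k = 5)
  k3 <- extract_context(g, "chr1", pos, k = 3)
  expect_equal(substr(k5, 2, 4), k3)
})

test_that("BED and GFF-like interval conversion is exact", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t4\t10\tgeneA\t0\t+", bed)
  ann_bed <- read_annotation(bed)
  expect_equal(IRanges::start(ann_bed$gr), 5L)   # 0-based start 4 -> 1-based 5
  expect_equal(IRanges::end(ann_bed$gr), 10L)    # half-open end unchanged

  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines("chr1\t5\t10\t+", gff)
  ann_gff <- read_annotation(gff)
  expect_equal(IRanges::start(ann_gff$gr), IRanges::start(ann_bed$gr))
  expect_equal(IRanges::end(ann_gff$gr), IRanges::end(ann_bed$gr))
})

test_that("catalog VCF write/read round-trips coordinates and alleles", {
  rec <- data.frame(chrom = "chr1", pos = c(11L, 60L, 90L),
                    ref = c("A", "CT", "G"), alt = c("T", "C", "C"),
                    vaf = c(0.4, NA, 0.6))
  cat <- mutation_catalog(rec, "rt")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_catalog_vcf(cat, path)
  back <- read_catalog(path, format = "vcf", sample_id = "rt")
  expect_equal(back$records$pos, cat$records$pos)
  expect_equal(back$records$ref, cat$records$ref)
  expect_equal(back$records$alt, cat$records$alt)
  expect_equal(back$records$class, cat$records$class)
  expect_equal(back$records$vaf, cat$records$vaf)
})

test_that("partition outputs conserve every record exactly once", {
  g <- make_genome(5e4, seed = 5)
  pc <- plant_catalog(g, n_background = 8, plants = list(
    plant_spec("DBS", 2, c(1, 1), vaf = 0.5, count = 1)),
    seed = 6, margin = 1000)
  fit <- list(catalog = pc$catalog,
              thresholds = threshold_model(100L),
              events = classify_catalog(pc$catalog,
                                        threshold_model(100L))$events,
              nonclustered = classify_catalog(
                pc$catalog, threshold_model(100L))$nonclustered,
              sample_id = pc$catalog$sample_id,
              ensemble = NULL, params = list())
  class(fit) <- "mutclust"
  out <- withr::local_tempdir()
  write_partitions(fit, out)
  vcfs <- list.files(out, pattern = "\\.vcf$", recursive = TRUE,
                     full.names = TRUE)
  n_out <- sum(vapply(vcfs, function(p)
    n_mutations(read_catalog(p, format = "vcf")), numeric(1)))
  expect_equal(n_out, n_mutations(pc$catalog))
})
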