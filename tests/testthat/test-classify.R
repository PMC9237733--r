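test_that("the subclass rule table reproduces its defining examples", {
  expect_equal(classify_event(gaps = 1, vaf = c(0.40, 0.42)), "DBS")
  expect_equal(classify_event(gaps = c(200, 150, 900),
                              vaf = c(0.4, 0.42, 0.45, 0.41)), "kataegis")
  expect_equal(classify_event(gaps = c(1, 500),
                              vaf = c(0.40, 0.41, 0.80)), "other")
  expect_equal(classify_event(gaps = c(1, 1)), "MBS")
  expect_equal(classify_event(gaps = 700, vaf = c(0.4, 0.45)), "omikli")
  expect_equal(classify_event(gaps = c(5, 5), class = "INDEL"),
               "clustered_indel")
  # CCF takes precedence over VAF when both are present
  expect_equal(classify_event(gaps = 1, vaf = c(0.2, 0.5),
                              ccf = c(0.5, 0.7)), "DBS")
})

test_that("classification agrees with brute-force enumeration of the rules", {
  cutoff <- 1000
  gap_choices <- c(1, 2, 10, cutoff - 1)
  for (size in 2:6) {
    grids <- do.call(expand.grid, rep(list(gap_choices), size - 1))
    for (r in seq_len(nrow(grids))) {
      gaps <- as.numeric(grids[r, ])
      for (vafs in list(NULL, rep(0.4, size),
                        c(0.4, rep(0.8, size - 1)))) {
        expect_equal(
          classify_event(gaps, vaf = vafs),
          oracle_subclass(gaps, vaf = vafs),
          info = sprintf("size %d gaps %s", size,
                         paste(gaps, collapse = ",")))
      }
    }
  }
})

test_that("boundary shapes never cross subclass borders", {
  expect_false(classify_event(gaps = 1) == "omikli")       # size 2, gap 1
  expect_equal(classify_event(gaps = c(1, 1, 1, 1)), "MBS") # size 5, all 1
  expect_equal(classify_event(gaps = c(1, 1, 2)), "kataegis")
  expect_equal(classify_event(gaps = c(2, 1)), "omikli")
})

test_that("chaining respects cutoffs, chromosomes and mutation class", {
  mk <- function(pos, class = "SBS") {
    ref <- if (class == "SBS") "C" else "CT"
    mutation_catalog(data.frame(chrom = "chr1", pos = pos, ref = ref,
                                alt = "T"), "s")
  }
  m <- threshold_model(1000L)
  cands <- extract_clusters(mk(c(100L, 101L, 5000L)), m)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$gaps, 1)
  cands2 <- extract_clusters(mk(c(100L, 600L, 1100L)), m)
  expect_length(cands2, 1)
  expect_equal(length(cands2[[1]]$indices), 3L)

  # substitutions and indels chain separately
  rec <- data.frame(chrom = "chr1", pos = c(100L, 150L, 200L, 260L),
                    ref = c("C", "CT", "C", "CT"),
                    alt = c("T", "C", "A", "C"))
  mixed <- mutation_catalog(rec, "s")
  cm <- extract_clusters(mixed, m)
  expect_length(cm, 2)
  expect_setequal(vapply(cm, `[[`, character(1), "class"),
                  c("SBS", "INDEL"))
})

test_that("a gap straddling a dense window breaks at the local cutoff", {
  w <- data.frame(chrom = "chr1", start = 1L, end = 1000L, real_n = 0L,
                  sim_mean = 0, fold = 10, local_cutoff = 100L,
                  window_p = NA_real_, window_q = NA_real_)
  m <- threshold_model(1000L, windows = w)
  cat <- mutation_catalog(
    data.frame(chrom = "chr1", pos = c(400L, 900L, 1400L), ref = "C",
               alt = "T"), "s")
  cands <- extract_clusters(cat, m)
  # gap 400-900 (midpoint 650, dense window, cutoff 100) breaks;
  # gap 900-1400 (midpoint 1150, outside) passes under the global cutoff
  expect_length(cands, 1)
  expect_equal(cat$records$pos[cands[[1]]$indices], c(900L, 1400L))
})

test_that("classify_catalog partitions every record exactly once", {
  g <- make_genome(1e6, seed = 31)
  pc <- plant_catalog(g, n_background = 40, plants = list(
    plant_spec("DBS", 2, c(1, 1), vaf = 0.5, count = 1),
    plant_spec("MBS", 3, c(1, 1), vaf = 0.5, count = 1),
    plant_spec("omikli", 3, c(2, 200), vaf = 0.5, count = 1),
    plant_spec("kataegis", 5, c(2, 200), vaf = 0.5, count = 1)),
    seed = 32, margin = 2000)
  res <- classify_catalog(pc$catalog, threshold_model(500L))
  members <- unlist(res$events$members, use.names = FALSE)
  expect_equal(anyDuplicated(members), 0L)
  expect_setequal(c(members, res$nonclustered),
                  seq_len(n_mutations(pc$catalog)))
  expect_equal(as.integer(res$summary[c("DBS", "MBS", "omikli",
                                        "kataegis")]),
               c(1L, 1L, 1L, 1L))
})

test_that("no sub-cutoff gaps means no events", {
  cat <- mutation_catalog(
    data.frame(chrom = "chr1", pos = c(1000L, 50000L, 99000L), ref = "C",
               alt = "T"), "s")
  res <- classify_catalog(cat, threshold_model(100L))
  expect_equal(nrow(res$events), 0L)
  expect_equal(res$nonclustered, 1:3)
})

test_that("event ids are stable and descriptive", {
  cat <- mutation_catalog(
    data.frame(chrom = "chr7", pos = c(500L, 501L), ref = "C", alt = "T"),
    "sampleX")
  res <- classify_catalog(cat, threshold_model(100L))
  expect_equal(res$events$event_id, "sampleX_chr7_500_2")
})
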