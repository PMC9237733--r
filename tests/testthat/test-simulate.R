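make_sim_fixture <- function(seed = 11, n_bg = 60, with_annotation = FALSE) {
  g <- make_genome(1e5, gc = 0.5, n_chroms = 2, seed = seed)
  ann <- if (with_annotation)
    gene_annotation(c("chr1", "chr1", "chr2"), c(5001L, 30001L, 10001L),
                    c(15000L, 38000L, 22000L), c("+", "-", "+"))
  else NULL
  pc <- plant_catalog(g, n_background = n_bg, seed = seed + 1,
                      margin = 500)
  cat <- annotate_regions(pc$catalog, ann)
  idx <- build_context_index(g, ann, k = 5)
  list(genome = g, catalog = cat, index = idx, annotation = ann)
}

test_that("a single-position posting forces the draw for every seed", {
  g <- tiny_genome("AAAAACGTAAAAA")   # ACGTA occurs once, centred at 7
  rec <- data.frame(chrom = "chr1", pos = 7L, ref = "G", alt = "T")
  cat <- mutation_catalog(rec, "s")
  idx <- build_context_index(g, k = 5)
  for (seed in c(1, 99, 12345)) {
    sim <- simulate_catalog(cat, idx, seed)
    expect_equal(sim$records$pos, 7L)
  }
})

test_that("per-chromosome burden is conserved in every simulation", {
  fx <- make_sim_fixture()
  real_tab <- table(fx$catalog$records$chrom)
  for (seed in 1:5) {
    sim <- simulate_catalog(fx$catalog, fx$index, seed)
    expect_equal(table(sim$records$chrom), real_tab)
  }
})

test_that("the centred 5-mer is conserved at every simulated position", {
  fx <- make_sim_fixture()
  real_ctx <- extract_context(fx$genome, fx$catalog$records$chrom,
                              fx$catalog$records$pos, k = 5)
  sim <- simulate_catalog(fx$catalog, fx$index, 42)
  expect_equal(attr(sim, "fallbacks"), 0L)
  # alleles identify the mutation across the re-shuffle
  key_real <- paste(fx$catalog$records$chrom, fx$catalog$records$ref,
                    fx$catalog$records$alt)
  sim_ctx <- extract_context(fx$genome, sim$records$chrom,
                             sim$records$pos, k = 5)
  key_sim <- paste(sim$records$chrom, sim$records$ref, sim$records$alt)
  expect_equal(sort(paste(key_sim, sim_ctx)),
               sort(paste(key_real, real_ctx)))
})

test_that("genic/intergenic and strand-class counts are conserved", {
  fx <- make_sim_fixture(with_annotation = TRUE)
  sim <- simulate_catalog(fx$catalog, fx$index, 7)
  expect_equal(attr(sim, "fallbacks"), 0L)
  for (chr in unique(fx$catalog$records$chrom)) {
    real <- fx$catalog$records[fx$catalog$records$chrom == chr, ]
    simr <- sim$records[sim$records$chrom == chr, ]
    expect_equal(table(simr$region), table(real$region))
    real_cls <- mutclust:::position_region_class(real$chrom, real$pos,
                                                 fx$annotation)
    sim_cls <- mutclust:::position_region_class(simr$chrom, simr$pos,
                                                fx$annotation)
    expect_equal(sort(sim_cls), sort(real_cls))
  }
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  fx <- make_sim_fixture()
  a <- simulate_catalog(fx$catalog, fx$index, 5)
  b <- simulate_catalog(fx$catalog, fx$index, 5)
  c <- simulate_catalog(fx$catalog, fx$index, 6)
  expect_identical(a$records, b$records)
  expect_false(identical(a$records$pos, c$records$pos))

  e1 <- simulate_ensemble(fx$catalog, fx$index, n_sims = 3,
                          master_seed = 9) |> suppressWarnings()
  e2 <- simulate_ensemble(fx$catalog, fx$index, n_sims = 3,
                          master_seed = 9) |> suppressWarnings()
  e3 <- simulate_ensemble(fx$catalog, fx$index, n_sims = 3,
                          master_seed = 10) |> suppressWarnings()
  expect_identical(e1$positions, e2$positions)
  expect_false(identical(e1$positions, e3$positions))
  expect_equal(length(unique(e1$seeds)), 3L)
})

test_that("simulated positions are uniform over the posting", {
  # one mutation whose 3-mer occurs at several positions; draw repeatedly
  g <- tiny_genome(strrep("ACGTT", 40))   # ACG recurs every 5 bp
  idx <- build_context_index(g, k = 3)
  posting <- idx$postings$chr1$all[["ACG"]]
  expect_gte(length(posting), 30)
  rec <- data.frame(chrom = "chr1", pos = posting[1], ref = "C", alt = "T")
  cat <- mutation_catalog(rec, "s")
  draws <- vapply(1:1500, function(s)
    simulate_catalog(cat, idx, s)$records$pos, numeric(1))
  tab <- table(factor(draws, levels = posting))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("substitutions at chromosome ends are excluded identically", {
  g <- tiny_genome(strrep("ACGT", 10))
  rec <- data.frame(chrom = "chr1", pos = c(1L, 20L), ref = c("A", "T"),
                    alt = c("T", "A"))
  cat <- mutation_catalog(rec, "s")
  idx <- build_context_index(g, k = 5)
  expect_message(sim <- simulate_catalog(cat, idx, 1), "context")
  expect_equal(n_mutations(sim), 1L)
  expect_equal(sim$records$ref, "T")
})
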