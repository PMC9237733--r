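test_that("gaps and nearest-neighbour IMDs follow their definitions", {
  expect_equal(compute_imds(c(100, 101)),
               list(gaps = 1, imd = c(1, 1)))
  expect_equal(compute_imds(c(10, 20, 35)),
               list(gaps = c(10, 15), imd = c(10, 10, 15)))
  one <- compute_imds(5)
  expect_length(one$gaps, 0)
  expect_true(is.na(one$imd))
  expect_error(compute_imds(c(5, 5)), "strictly increasing")
})

test_that("sub-cutoff counting is strict and monotone in the cutoff", {
  imds <- c(1, 1, 10, 10, 15)
  expect_equal(subcutoff_count(imds, 2), 2L)
  expect_equal(subcutoff_count(imds, 1), 0L)
  expect_equal(subcutoff_count(c(10, 10, 15), 16), 3L)
  set.seed(1)
  for (rep in 1:20) {
    v <- sample.int(500, 40, replace = TRUE)
    counts <- vapply(1:600, function(d) subcutoff_count(v, d), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("add-one empirical p-values and chance fractions match closed forms", {
  expect_equal(empirical_pvalue(50, rep(10, 100)), 1 / 101)
  expect_equal(empirical_pvalue(0, rep(3, 10)), 1)
  expect_equal(empirical_pvalue(5, c(3, 4, 5, 6)), 3 / 5)
  expect_equal(chance_fraction(100, rep(5, 10)), 0.05)
  expect_equal(chance_fraction(100, rep(100, 10)), 1)
  expect_equal(chance_fraction(0, rep(5, 10)), 1)
})

test_that("VAF/CCF consistency uses adjacent differences and kind tolerances", {
  expect_true(vaf_consistent(c(0.40, 0.45, 0.38)))
  expect_false(vaf_consistent(c(0.40, 0.55)))
  expect_true(vaf_consistent(c(0.5, 0.7), kind = "CCF"))
  expect_false(vaf_consistent(c(0.5, 0.8), kind = "CCF"))
  expect_true(vaf_consistent(c(0.4, NA, 0.9)))     # missing pairs pass
  expect_true(vaf_consistent(numeric(0)))
})

test_that("the global cutoff search matches the exhaustive-scan oracle", {
  set.seed(404)
  for (rep in 1:4) {
    L <- 5e5
    n <- 120
    real_pos <- sort(sample.int(L, n))
    # plant a couple of tight runs so some fixtures yield a cutoff
    if (rep %% 2 == 0)
      real_pos <- sort(unique(c(real_pos,
                                30000 + cumsum(sample(20:80, 15, TRUE)))))
    sims <- lapply(1:20, function(i)
      list(chr1 = sort(sample.int(L, length(real_pos)))))
    ens <- manual_ensemble(sims)
    rec <- data.frame(chrom = "chr1", pos = real_pos, ref = "C", alt = "T")
    cat <- mutation_catalog(rec, "synthetic")
    for (qa in c(0.01, 0.10)) {
      m <- find_global_cutoff(cat, ens, cap = 3000, q_alpha = qa)
      o <- oracle_global_cutoff(
        mutclust:::catalog_imd_profile(cat)$pooled,
        ens$pooled_imds, cap = 3000, q_alpha = qa)
      expect_equal(m$global_cutoff, o,
                   info = sprintf("rep %d q_alpha %.2f", rep, qa))
    }
  }
})

test_that("the criterion re-evaluates cleanly at the returned cutoff", {
  g <- make_genome(2e6, seed = 21)
  pc <- plant_catalog(g, n_background = 30, plants = list(
    plant_spec("kataegis", 6, c(50, 300), vaf = 0.5, count = 5)),
    seed = 22)
  idx <- build_context_index(
    g, k = 5, kmers = unique(stats::na.omit(extract_context(
      g, pc$catalog$records$chrom, pc$catalog$records$pos, k = 5))))
  ens <- simulate_ensemble(pc$catalog, idx, n_sims = 100, master_seed = 23)
  m <- find_global_cutoff(pc$catalog, ens)
  expect_false(is.na(m$global_cutoff))
  expect_lte(m$global_cutoff, 10000L)
  real <- mutclust:::catalog_imd_profile(pc$catalog)$pooled
  rc <- subcutoff_count(real, m$global_cutoff)
  sc <- vapply(ens$pooled_imds, subcutoff_count, numeric(1),
               cutoff = m$global_cutoff)
  expect_lte(chance_fraction(rc, sc), 0.10)
  expect_lt(m$qvalue_at_cutoff, 0.01)
  expect_equal(m$chance_fraction_at_cutoff, chance_fraction(rc, sc))
})

test_that("regional correction keeps balanced windows and shrinks dense ones", {
  # hand-built ensemble: chr1 window [1,1e6] balanced, window 2 is 10x dense
  set.seed(77)
  real <- list(chr1 = sort(c(sample.int(9e5, 50),
                             1200000 + sample.int(6e5, 200))))
  sims <- lapply(1:50, function(i)
    list(chr1 = sort(c(sample.int(9e5, 50), 1200000 + sample.int(6e5, 20)))))
  cat <- mutation_catalog(
    data.frame(chrom = "chr1", pos = real$chr1, ref = "C", alt = "T"),
    "synthetic")
  ens <- manual_ensemble(sims)
  m0 <- threshold_model(1000L, n_sims = 50)
  m <- regional_correction(cat, ens, m0, window = 1e6, step = 5e5)
  w <- m$windows
  expect_true(all(w$local_cutoff <= m$global_cutoff))
  balanced <- w$fold <= 1
  expect_true(all(w$local_cutoff[balanced] == m$global_cutoff))
  dense <- which(w$fold > 5)
  expect_true(length(dense) >= 1)
  for (i in dense) {
    cand <- floor(m$global_cutoff / w$fold[i])
    expect_lte(w$local_cutoff[i], max(1L, cand))
    # window-restricted chance criterion holds at the final cutoff
    prof <- mutclust:::catalog_imd_profile(cat)
    inw <- prof$positions$chr1 >= w$start[i] & prof$positions$chr1 <= w$end[i]
    rc <- subcutoff_count(prof$imds$chr1[inw], w$local_cutoff[i])
    sc <- vapply(seq_len(ens$n_sims), function(j) {
      sp <- ens$positions[[j]]$chr1
      ins <- sp >= w$start[i] & sp <= w$end[i]
      subcutoff_count(ens$imds[[j]]$chr1[ins], w$local_cutoff[i])
    }, numeric(1))
    if (rc > 0) expect_lte(chance_fraction(rc, sc), 0.10)
  }
})

test_that("positions inherit the minimum cutoff among overlapping windows", {
  w <- data.frame(chrom = "chr1", start = c(1, 500001), end = c(1e6, 15e5),
                  real_n = 0L, sim_mean = 0, fold = 2,
                  local_cutoff = c(400L, 150L), window_p = NA_real_,
                  window_q = NA_real_)
  m <- threshold_model(1000L, windows = w)
  expect_equal(local_cutoff_at(m, "chr1", c(100, 600000, 1200000, 2e6)),
               c(400L, 150L, 150L, 1000L))
})
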