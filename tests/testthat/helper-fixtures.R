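# Shared fixtures and independent oracles for the test suite.

tiny_genome <- function(seq = "AACGTAA", id = "toy") {
  reference_genome(c(chr1 = seq), id)
}

write_mini_vcf <- function(path, rows, sample = NULL, format_af = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                  if (!is.null(sample)) paste0("\tFORMAT\t", sample)))
  writeLines(c(hdr, rows), path)
  path
}

# Independent oracle for the global-cutoff search: naive per-cutoff loop,
# change-point BH family, exhaustive scan for the largest accepted cutoff.
oracle_global_cutoff <- function(real_imds, sim_imds_list, cap = 10000,
                                 max_chance = 0.10, q_alpha = 0.01) {
  n_sims <- length(sim_imds_list)
  ds <- 2:cap
  real <- vapply(ds, function(d) sum(real_imds < d, na.rm = TRUE), numeric(1))
  pvec <- numeric(length(ds)); chance <- numeric(length(ds))
  simmat <- matrix(0, nrow = length(ds), ncol = n_sims)
  for (j in seq_len(n_sims))
    simmat[, j] <- vapply(ds, function(d)
      sum(sim_imds_list[[j]] < d, na.rm = TRUE), numeric(1))
  for (i in seq_along(ds)) {
    pvec[i] <- (1 + sum(simmat[i, ] >= real[i])) / (n_sims + 1)
    chance[i] <- if (real[i] == 0) 1 else mean(simmat[i, ]) / real[i]
  }
  # nested (totally ordered) candidate hypotheses: each is tested at level
  # alpha directly (fixed-sequence testing), no across-candidate adjustment
  accept <- chance <= max_chance & real > 0 & pvec < q_alpha
  if (!any(accept)) return(NA_integer_)
  ds[max(which(accept))]
}

# Independent subclass oracle: a direct transcription of the published rule
# table, structured as a flat decision list.
oracle_subclass <- function(gaps, class = "SBS", vaf = NULL, ccf = NULL,
                            tol_vaf = 0.10, tol_ccf = 0.25) {
  if (class == "INDEL") return("clustered_indel")
  size <- length(gaps) + 1
  consistent <- TRUE
  for (i in seq_len(size - 1)) {
    a_ccf <- if (is.null(ccf)) NA else ccf[i]
    b_ccf <- if (is.null(ccf)) NA else ccf[i + 1]
    a_vaf <- if (is.null(vaf)) NA else vaf[i]
    b_vaf <- if (is.null(vaf)) NA else vaf[i + 1]
    if (!is.na(a_ccf) && !is.na(b_ccf)) {
      if (abs(a_ccf - b_ccf) > tol_ccf) consistent <- FALSE
    } else if (!is.na(a_vaf) && !is.na(b_vaf)) {
      if (abs(a_vaf - b_vaf) > tol_vaf) consistent <- FALSE
    }
  }
  if (!consistent) return("other")
  if (size == 2 && gaps[1] == 1) return("DBS")
  if (size >= 3 && max(gaps) == 1) return("MBS")
  if (size <= 3 && max(gaps) > 1) return("omikli")
  if (size >= 4 && max(gaps) > 1) return("kataegis")
  stop("unreachable")
}

# lazily cached large genome shared by the expensive acceptance fixtures
fixture_cache <- new.env(parent = emptyenv())

big_genome <- function() {
  if (is.null(fixture_cache$big))
    fixture_cache$big <- make_genome(1e7, gc = 0.5, n_chroms = 1, seed = 9001)
  fixture_cache$big
}

# fake ensemble with known per-chromosome simulated positions, for testing
# threshold components against hand-computable counts
manual_ensemble <- function(pos_lists, sample_id = "synthetic") {
  imds <- lapply(pos_lists, function(sim)
    lapply(sim, function(p) compute_imds(p)$imd))
  structure(list(
    n_sims = length(pos_lists), seeds = seq_along(pos_lists),
    positions = pos_lists, imds = imds,
    pooled_imds = lapply(imds, function(x)
      sort(unlist(x, use.names = FALSE))),
    catalogs = NULL, sample_id = sample_id), class = "sim_ensemble")
}
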