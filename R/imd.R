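#' Inter-mutational distances of a sorted position vector
#'
#' @param positions strictly increasing integer positions on one chromosome.
#' @return list with `gaps` (consecutive differences, length n-1) and `imd`
#'   (per-mutation nearest-neighbour IMD: minimum of the flanking gaps;
#'   chromosome-end mutations use their single flanking gap). A single
#'   position yields no gaps and an undefined (`NA`) IMD; callers exclude
#'   `NA`s from all counts.
#' @examples
#' compute_imds(c(10, 20, 35))  # gaps 10,15; imd 10,10,15
#' @export
compute_imds <- function(positions) {
  n <- length(positions)
  if (n >= 2L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (n < 2L)
    return(list(gaps = numeric(0), imd = rep(NA_real_, n)))
  g <- as.numeric(diff(positions))
  list(gaps = g, imd = pmin(c(Inf, g), c(g, Inf)))
}

# per-chromosome IMD profile of a catalog's substitutions
catalog_imd_profile <- function(catalog, class = "SBS") {
  rec <- catalog$records[catalog$records$class == class, , drop = FALSE]
  by_chr <- split(rec$pos, rec$chrom)
  imds <- lapply(by_chr, function(p) compute_imds(p)$imd)
  list(positions = by_chr, imds = imds,
       pooled = sort(unlist(imds, use.names = FALSE)))
}

#' Count mutations with a nearest-neighbour IMD below a cutoff
#'
#' The comparison is strict (`IMD < cutoff`); undefined IMDs are excluded.
#'
#' @param imds numeric vector of nearest-neighbour IMDs (may contain `NA`).
#' @param cutoff integer cutoff in bp.
#' @return integer count.
#' @export
subcutoff_count <- function(imds, cutoff) {
  sum(imds < cutoff, na.rm = TRUE)
}

#' Add-one empirical p-value of a real count against simulated counts
#'
#' `p = (1 + #\{simulations with count >= real\}) / (n_sims + 1)`, so p is
#' always positive and at least `1/(n_sims+1)`.
#'
#' @param real_count observed count.
#' @param sim_counts integer vector of simulated counts (length >= 2).
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(real_count, sim_counts) {
  if (length(sim_counts) < 2L) stop("need at least 2 simulated counts")
  (1 + sum(sim_counts >= real_count)) / (length(sim_counts) + 1)
}

#' Fraction of sub-cutoff mutations expected by chance
#'
#' The mean simulated sub-cutoff count divided by the real sub-cutoff count;
#' defined as 1 when the real count is 0. The threshold criterion demands
#' this fraction be at most 0.10 ("90% of mutations below the chosen cutoff
#' are unlikely to appear by chance").
#'
#' @param real_count observed sub-cutoff count.
#' @param sim_counts simulated sub-cutoff counts.
#' @return fraction (can exceed 1).
#' @export
chance_fraction <- function(real_count, sim_counts) {
  if (real_count <= 0) return(1)
  mean(sim_counts) / real_count
}

#' Adjacent VAF/CCF consistency of an ordered mutation run
#'
#' True when every adjacent pair differs by at most the kind-specific
#' tolerance (defaults 0.10 for VAF, 0.25 for CCF). `NA` pairs pass
#' vacuously (the filter applies only where data are available).
#'
#' @param values ordered numeric vector of VAFs or CCFs.
#' @param kind `"VAF"` or `"CCF"`.
#' @param tol_vaf,tol_ccf the kind-specific tolerances.
#' @return logical scalar.
#' @examples
#' vaf_consistent(c(0.40, 0.45, 0.38))           # TRUE
#' vaf_consistent(c(0.40, 0.55))                 # FALSE
#' vaf_consistent(c(0.5, 0.7), kind = "CCF")     # TRUE (0.20 <= 0.25)
#' @export
vaf_consistent <- function(values, kind = c("VAF", "CCF"),
                           tol_vaf = 0.10, tol_ccf = 0.25) {
  kind <- match.arg(kind)
  tol <- if (kind == "CCF") tol_ccf else tol_vaf
  if (length(values) < 2L) return(TRUE)
  d <- abs(diff(values))
  all(d <= tol | is.na(d))
}

#' Construct a threshold model by hand
#'
#' Mostly useful for tests and for applying a fixed permissive cutoff;
#' [find_global_cutoff()] and [regional_correction()] build these objects
#' from data.
#'
#' @param global_cutoff integer global IMD cutoff in bp, or `NA` when no
#'   cutoff satisfies the criterion.
#' @param cap maximum allowed global cutoff (default 10000 bp).
#' @param windows data.frame of regional corrections (may be empty), with
#'   columns `chrom`, `start`, `end`, `real_n`, `sim_mean`, `fold`,
#'   `local_cutoff`, `window_p`, `window_q`.
#' @param chance_fraction_at_cutoff,pvalue_at_cutoff,qvalue_at_cutoff
#'   diagnostics of the criterion at the global cutoff.
#' @param n_sims,max_chance,q_alpha,window,step calibration parameters.
#' @return an object of class `"threshold_model"`.
#' @export
threshold_model <- function(global_cutoff, cap = 10000L, windows = NULL,
                            chance_fraction_at_cutoff = NA_real_,
                            pvalue_at_cutoff = NA_real_,
                            qvalue_at_cutoff = NA_real_,
                            n_sims = NA_integer_, max_chance = 0.10,
                            q_alpha = 0.01, window = 1e6L, step = window / 2) {
  if (!is.na(global_cutoff) && global_cutoff > cap)
    stop("global cutoff exceeds the cap")
  if (is.null(windows))
    windows <- data.frame(chrom = character(), start = integer(),
                          end = integer(), real_n = integer(),
                          sim_mean = numeric(), fold = numeric(),
                          local_cutoff = integer(), window_p = numeric(),
                          window_q = numeric(), stringsAsFactors = FALSE)
  structure(list(global_cutoff = as.integer(global_cutoff),
                 cap = as.integer(cap), windows = windows,
                 chance_fraction_at_cutoff = chance_fraction_at_cutoff,
                 pvalue_at_cutoff = pvalue_at_cutoff,
                 qvalue_at_cutoff = qvalue_at_cutoff,
                 n_sims = n_sims, max_chance = max_chance,
                 q_alpha = q_alpha, window = as.numeric(window),
                 step = as.numeric(step)),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  if (is.na(x$global_cutoff)) {
    cat("Threshold model: no IMD cutoff satisfies the criterion",
        sprintf("(<=%.0f%% by chance, q < %g)\n", 100 * x$max_chance,
                x$q_alpha))
  } else {
    cat(sprintf(paste0("Threshold model: global IMD cutoff %d bp (cap %d)\n",
                       "  chance fraction %.3f, q-value %.4g, n_sims %s\n"),
                x$global_cutoff, x$cap, x$chance_fraction_at_cutoff,
                x$qvalue_at_cutoff, x$n_sims))
    corr <- x$windows[!is.na(x$windows$local_cutoff) &
                        x$windows$local_cutoff < x$global_cutoff, ,
                      drop = FALSE]
    cat("  ", nrow(x$windows), " window(s), ", nrow(corr),
        " with a reduced local cutoff\n", sep = "")
  }
  invisible(x)
}

# criterion arrays over all integer candidate cutoffs in [2, cap]:
# real/simulated sub-cutoff counts, chance fraction and add-one empirical p
# per cutoff. The distinct hypotheses are the cutoffs at which the real
# count changes (observed IMD + 1); BH runs across those change points and
# every cutoff inherits the q of its run.
criterion_curve <- function(real_sorted, sim_sorted_list, cap,
                            max_chance, q_alpha) {
  ds <- seq(2L, as.integer(cap))
  real_counts <- findInterval(ds - 1L, real_sorted)
  simc <- vapply(sim_sorted_list, function(s) findInterval(ds - 1L, s),
                 integer(length(ds)))
  if (is.null(dim(simc))) simc <- matrix(simc, nrow = length(ds))
  sim_mean <- rowMeans(simc)
  chance <- ifelse(real_counts == 0L, 1, sim_mean / real_counts)
  n_sims <- length(sim_sorted_list)
  p <- (1 + rowSums(simc >= real_counts)) / (n_sims + 1)
  # the candidate cutoffs are a nested, totally ordered family (sub-cutoff
  # counts are monotone in d): fixed-sequence testing controls the error
  # rate at level alpha with no multiplicity penalty, so the adjusted
  # p-value of each candidate equals its raw empirical p. BH is applied at
  # the regional stage, where windows are parallel hypotheses.
  eligible <- chance <= max_chance & real_counts > 0L
  data.frame(d = ds, real = real_counts, sim_mean = sim_mean,
             chance = chance, p = p, q = p,
             accept = eligible & p < q_alpha)
}

#' Derive the sample-dependent global IMD cutoff
#'
#' Selects the largest cutoff d in `[2, cap]` such that (i) at most
#' `max_chance` of the mutations with nearest-neighbour IMD below d are
#' expected from the simulated background (mean simulated sub-cutoff count /
#' real sub-cutoff count) and (ii) the adjusted add-one empirical p-value of
#' the real sub-cutoff count is below `q_alpha`. The candidate cutoffs form
#' a nested, totally ordered family of hypotheses (sub-cutoff counts are
#' monotone in d), which fixed-sequence testing controls at level `q_alpha`
#' with no further multiplicity penalty, so each candidate's adjusted p
#' equals its raw empirical p; multiplicity across parallel hypotheses is
#' handled at the regional stage ([regional_correction()], BH across
#' windows). The criterion is evaluated at every integer candidate
#' (vectorised), making the selection a pure function of the data; the
#' largest accepted candidate is located by a binary search over the
#' acceptance indicator, verified by direct re-evaluation, with a linear
#' scan as a fallback for non-interval acceptance regions. Returns a model
#' with an `NA` cutoff when no candidate satisfies the criterion.
#'
#' @param catalog a `mutation_catalog` (substitution IMDs drive the search).
#' @param ensemble a `sim_ensemble` built from the same catalog.
#' @param cap maximum global cutoff (default 10 kb).
#' @param max_chance maximum tolerated chance fraction (default 0.10).
#' @param q_alpha q-value threshold (default 0.01).
#' @return a `threshold_model` (global part; `windows` empty). The full
#'   candidate criterion curve is attached as attribute `"curve"`.
#' @export
find_global_cutoff <- function(catalog, ensemble, cap = 10000L,
                               max_chance = 0.10, q_alpha = 0.01) {
  if (!identical(catalog$sample_id, ensemble$sample_id))
    stop("ensemble was built from a different sample than the catalog")
  prof <- catalog_imd_profile(catalog)
  curve <- criterion_curve(prof$pooled, ensemble$pooled_imds, cap,
                           max_chance, q_alpha)
  d_star <- NA_integer_
  if (any(curve$accept)) {
    acc <- curve$accept
    lo <- 1L; hi <- nrow(curve)
    # binary search for the last TRUE, assuming acceptance is
    # downward-closed above the smallest candidate
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (acc[mid]) lo <- mid else hi <- mid - 1L
    }
    d_star <- curve$d[lo]
    ok <- acc[lo] && (lo == nrow(curve) || !any(acc[(lo + 1L):nrow(curve)]))
    if (!ok) d_star <- curve$d[max(which(acc))]  # non-interval region
  }
  if (is.na(d_star)) {
    model <- threshold_model(NA_integer_, cap = cap,
                             n_sims = ensemble$n_sims,
                             max_chance = max_chance, q_alpha = q_alpha)
  } else {
    row <- curve[curve$d == d_star, ]
    model <- threshold_model(d_star, cap = cap,
                             chance_fraction_at_cutoff = row$chance,
                             pvalue_at_cutoff = row$p,
                             qvalue_at_cutoff = row$q,
                             n_sims = ensemble$n_sims,
                             max_chance = max_chance, q_alpha = q_alpha)
  }
  attr(model, "curve") <- curve
  model
}

# counts of sorted values below a strict cutoff
count_below <- function(sorted, cutoff) findInterval(cutoff - 1L, sorted)

# windows tiling each chromosome with 50% overlap by default
make_windows <- function(chrom_lengths, window, step) {
  out <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    starts <- seq(1, max(1, len - 1), by = step)
    starts <- starts[starts <= len]
    ends <- pmin(starts + window - 1, len)
    out[[chr]] <- data.frame(chrom = chr, start = starts,
                             end = ends, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Regional correction of the IMD cutoff in sliding windows
#'
#' In every sliding genomic window (default 1 Mb, 50\% overlap) the fold
#' difference between real and mean simulated mutation counts is computed
#' (`fold = real / max(sim, 0.5)`). Mutation-dense windows (`fold > 1`) get
#' a candidate local cutoff `floor(global_cutoff / fold)`, which is lowered
#' further, if needed, until at most `max_chance` of the window's sub-cutoff
#' mutations are expected by chance and the window's empirical p-value
#' survives BH adjustment across windows; the local cutoff is floored at
#' 1 bp. Windows with `fold <= 1` keep the global cutoff (cutoffs are never
#' raised).
#'
#' @param catalog a `mutation_catalog`.
#' @param ensemble the `sim_ensemble` used for the global search.
#' @param model a `threshold_model` with a non-`NA` global cutoff.
#' @param window window width in bp (default 1 Mb).
#' @param step window step in bp (default half the width).
#' @param genome optional `reference_genome` supplying chromosome lengths;
#'   otherwise the maximum observed position per chromosome is used.
#' @return the `threshold_model` with its `windows` table filled in.
#' @export
regional_correction <- function(catalog, ensemble, model,
                                window = 1e6, step = window / 2,
                                genome = NULL) {
  if (is.na(model$global_cutoff))
    stop("regional correction requires a non-NA global cutoff")
  g <- model$global_cutoff
  prof <- catalog_imd_profile(catalog)
  lens <- if (!is.null(genome)) {
    genome$lengths[names(genome$lengths) %in% names(prof$positions)]
  } else {
    vapply(prof$positions, max, numeric(1))
  }
  win <- make_windows(lens, window, step)
  n_win <- nrow(win)
  if (n_win == 0L) { model$windows <- model$windows[0, ]; return(model) }

  n_sims <- ensemble$n_sims
  real_n <- integer(n_win); sim_mean_n <- numeric(n_win)
  real_w_imds <- vector("list", n_win)   # sorted real IMDs within window
  sim_w_imds <- vector("list", n_win)    # list of sorted sim IMDs per sim

  for (w in seq_len(n_win)) {
    chr <- win$chrom[w]
    pos <- prof$positions[[chr]]
    imd <- prof$imds[[chr]]
    inw <- pos >= win$start[w] & pos <= win$end[w]
    real_n[w] <- sum(inw)
    real_w_imds[[w]] <- sort(imd[inw])
    per_sim <- vector("list", n_sims)
    cnt <- numeric(n_sims)
    for (i in seq_len(n_sims)) {
      sp <- ensemble$positions[[i]][[chr]]
      si <- ensemble$imds[[i]][[chr]]
      if (is.null(sp)) { per_sim[[i]] <- numeric(0); next }
      ins <- sp >= win$start[w] & sp <= win$end[w]
      cnt[i] <- sum(ins)
      per_sim[[i]] <- sort(si[ins])
    }
    sim_mean_n[w] <- mean(cnt)
    sim_w_imds[[w]] <- per_sim
  }

  fold <- real_n / pmax(sim_mean_n, 0.5)
  local <- rep(g, n_win)
  window_p <- rep(NA_real_, n_win)
  dense <- which(fold > 1)

  candidate <- pmax(1L, as.integer(floor(g / fold)))
  p_at <- function(w, d) {
    rc <- count_below(real_w_imds[[w]], d)
    sc <- vapply(sim_w_imds[[w]], count_below, numeric(1), cutoff = d)
    list(p = empirical_pvalue(rc, sc), chance = chance_fraction(rc, sc),
         rc = rc)
  }
  if (length(dense)) {
    stats0 <- lapply(dense, function(w) p_at(w, candidate[w]))
    p0 <- vapply(stats0, `[[`, numeric(1), "p")
    q0 <- p.adjust(p0, method = "BH")
    # raw-p level implied by the BH pass: the largest raw p that survived
    pass0 <- q0 < model$q_alpha
    p_star <- if (any(pass0)) max(p0[pass0]) else model$q_alpha / length(dense)
    for (j in seq_along(dense)) {
      w <- dense[j]
      st <- stats0[[j]]
      ok <- pass0[j] && st$chance <= model$max_chance && st$rc > 0L
      d <- candidate[w]
      while (!ok && d > 1L) {
        d <- d - 1L
        st <- p_at(w, d)
        ok <- st$p <= p_star && st$chance <= model$max_chance && st$rc > 0L
      }
      local[w] <- min(g, max(1L, d))
      window_p[w] <- st$p
    }
    window_q <- rep(NA_real_, n_win)
    window_q[dense] <- p.adjust(window_p[dense], method = "BH")
  } else {
    window_q <- rep(NA_real_, n_win)
  }

  model$windows <- data.frame(
    chrom = win$chrom, start = win$start, end = win$end,
    real_n = real_n, sim_mean = sim_mean_n, fold = fold,
    local_cutoff = as.integer(local), window_p = window_p,
    window_q = window_q, stringsAsFactors = FALSE)
  model$window <- as.numeric(window)
  model$step <- as.numeric(step)
  model
}

#' Local IMD cutoff applicable at genomic positions
#'
#' A position inherits the minimum local cutoff among all (possibly
#' overlapping) windows containing it; positions outside every window, or a
#' model without regional corrections, use the global cutoff.
#'
#' @param model a `threshold_model`.
#' @param chrom,pos vectors of chromosome names and positions.
#' @return integer vector of cutoffs in bp.
#' @export
local_cutoff_at <- function(model, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.numeric(pos), n)
  out <- rep(model$global_cutoff, n)
  w <- model$windows
  if (is.null(w) || nrow(w) == 0L) return(out)
  for (i in seq_len(nrow(w))) {
    hit <- chrom == w$chrom[i] & pos >= w$start[i] & pos <= w$end[i]
    out[hit] <- pmin(out[hit], w$local_cutoff[i])
  }
  out
}
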