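#' Simulate one background catalog
#'
#' Redistributes every substitution of the catalog to a uniformly drawn
#' position carrying the same centred k-mer, the same genic/intergenic
#' status and the same gene-strand class, on the same chromosome; reference
#' and alternate alleles, VAF and CCF travel with the mutation. Indels are
#' re-placed uniformly on their chromosome (no context constraint).
#' Substitutions whose context window runs past a chromosome end are
#' excluded (identically for every simulation). Within one simulated
#' chromosome, colliding positions are redrawn (up to 100 rounds) so
#' positions stay strictly increasing.
#'
#' Empty postings trigger a logged fallback ladder: drop the strand class,
#' then the region class, then shrink the context to the central 3-mer.
#' More than 1\% fallbacks raises a warning (expected only on very small or
#' sparsely indexed genomes).
#'
#' @param catalog a `mutation_catalog`.
#' @param index a `context_index` built on the catalog's genome.
#' @param seed integer seed; the result is a pure function of
#'   (catalog, index, seed).
#' @return a simulated `mutation_catalog` with attribute `"fallbacks"`
#'   (integer count of posting relaxations).
#' @export
simulate_catalog <- function(catalog, index, seed) {
  set.seed(as.integer(seed))
  genome <- index$genome
  rec <- catalog$records
  k <- index$k
  flank <- (k - 1L) %/% 2L

  sbs <- which(rec$class == "SBS")
  ctx <- extract_context(genome, rec$chrom[sbs], rec$pos[sbs], k = k)
  usable <- !is.na(ctx) & !grepl("N", ctx, fixed = TRUE)
  if (any(!usable))
    mc_message(sum(!usable), " substitution(s) lack usable context; ",
               "excluded from the simulated catalogs")
  sbs_keep <- sbs[usable]
  ctx <- ctx[usable]
  cls <- if (length(index$classes) > 1L)
    position_region_class(rec$chrom[sbs_keep], rec$pos[sbs_keep],
                          index$annotation)
  else rep("all", length(sbs_keep))

  new_pos <- integer(nrow(rec))
  new_pos[] <- NA_integer_
  fallbacks <- 0L

  key <- paste(rec$chrom[sbs_keep], cls, ctx, sep = "\r")
  groups <- split(seq_along(sbs_keep), key)
  postings <- vector("list", length(groups))
  names(postings) <- names(groups)
  for (gk in sort(names(groups))) {
    parts <- strsplit(gk, "\r", fixed = TRUE)[[1]]
    lp <- lookup_posting(index, parts[1], parts[2], parts[3])
    if (lp$level > 0L) fallbacks <- fallbacks + length(groups[[gk]])
    if (!length(lp$positions))
      stop("no candidate positions for context ", parts[3], " on ", parts[1])
    postings[[gk]] <- lp$positions
    ii <- groups[[gk]]
    draw <- lp$positions[sample.int(length(lp$positions), length(ii),
                                    replace = TRUE)]
    new_pos[sbs_keep[ii]] <- draw
  }

  # indels: chromosome-uniform over non-N positions
  ind <- which(rec$class == "INDEL")
  for (chr in unique(rec$chrom[ind])) {
    ii <- ind[rec$chrom[ind] == chr]
    len <- genome$lengths[[chr]]
    draw <- sample.int(len, length(ii), replace = TRUE)
    for (r in 1:100) {
      bases <- extract_context(genome, chr, draw, k = 1L)
      bad <- is.na(bases) | bases == "N"
      if (!any(bad)) break
      draw[bad] <- sample.int(len, sum(bad), replace = TRUE)
    }
    new_pos[ii] <- draw
  }

  keep <- which(!is.na(new_pos))
  # resolve within-chromosome collisions by redrawing from the same posting
  group_of <- integer(nrow(rec)); group_of[sbs_keep] <- match(key, names(postings))
  for (chr in unique(rec$chrom[keep])) {
    ii <- keep[rec$chrom[keep] == chr]
    for (r in 1:100) {
      dup <- ii[duplicated(new_pos[ii])]
      if (!length(dup)) break
      if (r == 100L) stop("could not resolve position collisions on ", chr)
      for (j in dup) {
        if (group_of[j] > 0L) {
          p <- postings[[group_of[j]]]
          new_pos[j] <- p[sample.int(length(p), 1L)]
        } else {
          new_pos[j] <- sample.int(genome$lengths[[chr]], 1L)
        }
      }
    }
  }

  frac <- if (length(sbs_keep)) fallbacks / length(sbs_keep) else 0
  if (frac > 0.01)
    warning(sprintf("context-posting fallbacks for %.1f%% of substitutions",
                    100 * frac))

  out <- rec[keep, , drop = FALSE]
  out$pos <- new_pos[keep]
  sim <- suppressMessages(
    mutation_catalog(out, catalog$sample_id, catalog$genome_id))
  if (!is.null(index$annotation))
    sim <- annotate_regions(sim, index$annotation)
  attr(sim, "fallbacks") <- fallbacks
  sim
}

#' Simulate an ensemble of background catalogs
#'
#' Runs [simulate_catalog()] `n_sims` times with seeds `master_seed + i` and
#' caches, per simulation, the sorted substitution positions and
#' nearest-neighbour IMDs per chromosome (the quantities the threshold
#' search consumes).
#'
#' @param catalog a `mutation_catalog`.
#' @param index a `context_index` built on the catalog's genome.
#' @param n_sims number of simulations (default 100; fewer than 100 makes
#'   the default q-value threshold unattainable and raises a warning).
#' @param master_seed integer; simulation i uses seed `master_seed + i`.
#' @param keep_catalogs keep the full simulated catalogs (memory-hungry;
#'   default `FALSE`).
#' @return an object of class `"sim_ensemble"` with elements `n_sims`,
#'   `seeds`, `positions` (per sim, per chromosome, sorted SBS positions),
#'   `imds` (per sim, per chromosome nearest-neighbour IMDs), `pooled_imds`
#'   (per sim, sorted across chromosomes), `catalogs` (optional) and
#'   `sample_id`.
#' @export
simulate_ensemble <- function(catalog, index, n_sims = 100L, master_seed = 1L,
                              keep_catalogs = FALSE) {
  n_sims <- as.integer(n_sims)
  if (n_sims < 2L) stop("n_sims must be at least 2")
  if (n_sims < 100L)
    warning("with n_sims < 100 the minimum attainable empirical p-value ",
            "exceeds the default q-value threshold of 0.01")
  seeds <- as.integer(master_seed) + seq_len(n_sims)
  positions <- vector("list", n_sims)
  imds <- vector("list", n_sims)
  pooled <- vector("list", n_sims)
  catalogs <- if (keep_catalogs) vector("list", n_sims) else NULL
  for (i in seq_len(n_sims)) {
    sim <- suppressMessages(simulate_catalog(catalog, index, seeds[i]))
    rec <- sim$records[sim$records$class == "SBS", , drop = FALSE]
    by_chr <- split(rec$pos, rec$chrom)
    positions[[i]] <- by_chr
    imds[[i]] <- lapply(by_chr, function(p) compute_imds(p)$imd)
    pooled[[i]] <- sort(unlist(imds[[i]], use.names = FALSE))
    if (keep_catalogs) catalogs[[i]] <- sim
  }
  structure(list(n_sims = n_sims, seeds = seeds, positions = positions,
                 imds = imds, pooled_imds = pooled, catalogs = catalogs,
                 sample_id = catalog$sample_id),
            class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat("Simulation ensemble for sample '", x$sample_id, "': ", x$n_sims,
      " simulation(s)\n", sep = "")
  invisible(x)
}
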