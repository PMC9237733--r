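#' Fit the clustered-mutation model to a sample
#'
#' The one-stop fitting interface: annotates the catalog (when an annotation
#' is given), builds the sequence-context index, simulates the background
#' ensemble, derives the sample-dependent global IMD cutoff, corrects it
#' regionally in sliding windows, and chains and subclassifies clustered
#' events.
#'
#' @param catalog a `mutation_catalog` (see [read_catalog()] and
#'   [mutation_catalog()]).
#' @param genome the matching `reference_genome`.
#' @param annotation optional `gene_annotation` enabling genic/intergenic
#'   and transcriptional-strand preservation in the background model.
#' @param n_sims number of background simulations (default 100).
#' @param seed master seed; simulation i uses `seed + i`.
#' @param k context width preserved by the simulation (default 5).
#' @param cap maximum global IMD cutoff in bp (default 10000).
#' @param max_chance maximum tolerated fraction of sub-cutoff mutations
#'   expected by chance (default 0.10).
#' @param q_alpha q-value threshold (default 0.01).
#' @param window,step regional-correction window width and step in bp
#'   (defaults 1 Mb and half the width).
#' @param tol_vaf,tol_ccf adjacent VAF/CCF consistency tolerances (defaults
#'   0.10 and 0.25).
#' @param keep_sims keep full simulated catalogs inside the returned object.
#' @return an object of class `"mutclust"`: list with `call`, `catalog`
#'   (annotated), `thresholds` (a `threshold_model`), `events`,
#'   `nonclustered`, `summary` (counts per subclass), `ensemble`, `index`
#'   and `params`. When no cutoff satisfies the criterion, `events` is
#'   empty and every mutation is non-clustered.
#' @seealso [plot.mutclust()], [simulate.mutclust()], [write_partitions()]
#' @export
mutclust <- function(catalog, genome, annotation = NULL, n_sims = 100L,
                     seed = 1L, k = 5L, cap = 10000L, max_chance = 0.10,
                     q_alpha = 0.01, window = 1e6, step = window / 2,
                     tol_vaf = 0.10, tol_ccf = 0.25, keep_sims = FALSE) {
  cl <- match.call()
  if (!inherits(catalog, "mutation_catalog")) stop("catalog must be a mutation_catalog")
  if (!inherits(genome, "reference_genome")) stop("genome must be a reference_genome")
  if (!is.null(annotation)) catalog <- annotate_regions(catalog, annotation)

  sbs <- catalog$records$class == "SBS"
  kmers <- unique(stats::na.omit(extract_context(
    genome, catalog$records$chrom[sbs], catalog$records$pos[sbs], k = k)))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  index <- build_context_index(genome, annotation, k = k, kmers = kmers)
  ensemble <- simulate_ensemble(catalog, index, n_sims = n_sims,
                                master_seed = seed,
                                keep_catalogs = keep_sims)
  thresholds <- find_global_cutoff(catalog, ensemble, cap = cap,
                                   max_chance = max_chance,
                                   q_alpha = q_alpha)
  if (!is.na(thresholds$global_cutoff))
    thresholds <- regional_correction(catalog, ensemble, thresholds,
                                      window = window, step = step,
                                      genome = genome)
  if (!is.na(thresholds$global_cutoff)) {
    res <- classify_catalog(catalog, thresholds, tol_vaf = tol_vaf,
                            tol_ccf = tol_ccf)
  } else {
    res <- list(events = empty_events(),
                nonclustered = seq_len(nrow(catalog$records)),
                summary = table(factor(character(), levels = SUBCLASSES)))
  }
  structure(list(call = cl, sample_id = catalog$sample_id,
                 catalog = catalog, genome = genome,
                 thresholds = thresholds, events = res$events,
                 nonclustered = res$nonclustered, summary = res$summary,
                 ensemble = ensemble, index = index,
                 params = list(n_sims = n_sims, seed = seed, k = k,
                               cap = cap, max_chance = max_chance,
                               q_alpha = q_alpha, window = window,
                               step = step, tol_vaf = tol_vaf,
                               tol_ccf = tol_ccf)),
            class = "mutclust")
}

#' @export
print.mutclust <- function(x, ...) {
  cat("Clustered-mutation fit for sample '", x$sample_id, "'\n", sep = "")
  print(x$thresholds)
  n <- nrow(x$catalog$records)
  ncl <- n - length(x$nonclustered)
  cat(sprintf("  %d / %d mutation(s) clustered in %d event(s)\n",
              ncl, n, nrow(x$events)))
  if (nrow(x$events)) print(x$summary)
  invisible(x)
}

#' @export
summary.mutclust <- function(object, ...) {
  structure(list(fit = object), class = "summary.mutclust")
}

#' @export
print.summary.mutclust <- function(x, ...) {
  f <- x$fit
  print(f)
  w <- f$thresholds$windows
  if (!is.null(w) && nrow(w)) {
    corr <- w[w$local_cutoff < f$thresholds$global_cutoff, , drop = FALSE]
    if (nrow(corr)) {
      cat("\nRegionally corrected windows:\n")
      print(corr[, c("chrom", "start", "end", "real_n", "sim_mean",
                     "fold", "local_cutoff")], row.names = FALSE)
    }
  }
  if (nrow(f$events)) {
    cat("\nEvents:\n")
    print(f$events[, c("event_id", "subclass", "chrom", "start", "end",
                       "size", "min_gap", "max_gap")], row.names = FALSE)
  }
  invisible(x)
}

#' Cutoffs of a fitted clustered-mutation model
#'
#' @param object a `mutclust` fit.
#' @param ... unused.
#' @return named numeric vector: the global cutoff followed by the local
#'   cutoff of every regionally corrected window.
#' @export
coef.mutclust <- function(object, ...) {
  out <- c(global = as.numeric(object$thresholds$global_cutoff))
  w <- object$thresholds$windows
  if (!is.null(w) && nrow(w)) {
    corr <- w[w$local_cutoff < object$thresholds$global_cutoff, ,
              drop = FALSE]
    if (nrow(corr))
      out <- c(out, setNames(as.numeric(corr$local_cutoff),
                             sprintf("%s:%d-%d", corr$chrom, corr$start,
                                     corr$end)))
  }
  out
}

#' Plot a fitted clustered-mutation model
#'
#' @param x a `mutclust` fit.
#' @param type `"rainfall"` or `"summary"` (the multi-panel spectra/IMD
#'   figure).
#' @param out optional image path (`.png`/`.pdf`); plots to the active
#'   device when `NULL`.
#' @param ... unused.
#' @return invisibly, the plotted data series.
#' @export
plot.mutclust <- function(x, type = c("rainfall", "summary"), out = NULL,
                          ...) {
  type <- match.arg(type)
  if (type == "rainfall")
    plot_rainfall(x$catalog, x$events, x$thresholds, x$genome, out = out)
  else
    summary_panel(x$catalog, x$events, x$ensemble, x$thresholds, x$genome,
                  out = out)
}

#' Draw new simulated background catalogs from a fitted model
#'
#' @param object a `mutclust` fit.
#' @param nsim number of catalogs.
#' @param seed integer seed (default: the fit's master seed offset past the
#'   ensemble's seeds).
#' @param ... unused.
#' @return list of simulated `mutation_catalog`s.
#' @export
simulate.mutclust <- function(object, nsim = 1, seed = NULL, ...) {
  base <- if (is.null(seed))
    object$params$seed + object$ensemble$n_sims else as.integer(seed)
  lapply(seq_len(nsim), function(i)
    simulate_catalog(object$catalog, object$index, base + i))
}

#' Classify a catalog under an already-fitted threshold model
#'
#' Applies the fitted global and local cutoffs to `newdata` without
#' re-simulating. Meaningful only for catalogs on the same genome with a
#' comparable mutational burden; refitting is preferable otherwise.
#'
#' @param object a `mutclust` fit.
#' @param newdata a `mutation_catalog` (default: the fitted catalog).
#' @param ... unused.
#' @return as [classify_catalog()].
#' @export
predict.mutclust <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$catalog
  if (is.na(object$thresholds$global_cutoff))
    return(list(events = empty_events(),
                nonclustered = seq_len(nrow(newdata$records)),
                summary = table(factor(character(), levels = SUBCLASSES))))
  classify_catalog(newdata, object$thresholds,
                   tol_vaf = object$params$tol_vaf,
                   tol_ccf = object$params$tol_ccf)
}
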