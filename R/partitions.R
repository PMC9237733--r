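#' Write partitioned VCF outputs, events table and threshold sidecar
#'
#' Creates `nonClustered/<sample>.vcf`, one
#' `clustered/<sample>_<subclass>.vcf` per subclass present, the per-event
#' summary TSV and a JSON sidecar with the fitted thresholds and
#' parameters. Clustered records carry `SUBCLASS` and `IMD` INFO tags (IMD:
#' the record's nearest-neighbour distance within its event, i.e. the
#' minimum flanking internal gap). Every mutation appears in exactly one
#' partition.
#'
#' @param fit a `mutclust` fit.
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_partitions <- function(fit, outdir) {
  catalog <- fit$catalog; events <- fit$events
  ok <- dir.create(file.path(outdir, "nonClustered"), recursive = TRUE,
                   showWarnings = FALSE)
  dir.create(file.path(outdir, "clustered"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(file.path(outdir, "nonClustered")))
    stop_stage("output", "cannot create output directory ", outdir)
  written <- character(0)

  nc_path <- file.path(outdir, "nonClustered",
                       paste0(catalog$sample_id, ".vcf"))
  write_catalog_vcf(catalog, nc_path, which = fit$nonclustered)
  written["nonClustered"] <- nc_path

  if (nrow(events)) {
    for (sub in unique(events$subclass)) {
      rows <- which(events$subclass == sub)
      idx <- integer(0); info <- character(0)
      for (i in rows) {
        m <- events$members[[i]]
        gaps <- diff(catalog$records$pos[m])
        imd <- pmin(c(Inf, gaps), c(gaps, Inf))
        idx <- c(idx, m)
        info <- c(info, sprintf("SUBCLASS=%s;IMD=%d", sub,
                                as.integer(imd)))
      }
      p <- file.path(outdir, "clustered",
                     paste0(catalog$sample_id, "_", sub, ".vcf"))
      write_catalog_vcf(catalog, p, which = idx, info = info)
      written[paste0("clustered_", sub)] <- p
    }
  }

  ev_path <- file.path(outdir, paste0(catalog$sample_id, "_events.tsv"))
  write_events_tsv(events, ev_path)
  written["events"] <- ev_path

  sidecar <- file.path(outdir, paste0(catalog$sample_id, "_thresholds.json"))
  write_threshold_json(fit, sidecar)
  written["thresholds"] <- sidecar
  invisible(written)
}

#' Serialize a fit's threshold model and parameters to JSON
#'
#' @param fit a `mutclust` fit (or a bare `threshold_model`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(fit, path) {
  model <- if (inherits(fit, "mutclust")) fit$thresholds else fit
  payload <- list(
    sample_id = if (inherits(fit, "mutclust")) fit$sample_id else NULL,
    global_cutoff = if (is.na(model$global_cutoff)) NULL
    else model$global_cutoff,
    cap = model$cap,
    chance_fraction_at_cutoff = model$chance_fraction_at_cutoff,
    qvalue_at_cutoff = model$qvalue_at_cutoff,
    n_sims = model$n_sims, max_chance = model$max_chance,
    q_alpha = model$q_alpha, window = model$window, step = model$step,
    windows = model$windows,
    seeds = if (inherits(fit, "mutclust")) fit$ensemble$seeds else NULL,
    params = if (inherits(fit, "mutclust")) fit$params else NULL)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
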