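SBS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide channel labels, COSMIC order
#' @return character vector like `"A[C>A]A"`.
#' @export
sbs96_labels <- function() {
  unlist(lapply(SBS6, function(s)
    as.vector(t(outer(DNA_BASES, DNA_BASES, function(p, q)
      paste0(p, "[", s, "]", q))))))
}

#' SBS-96 mutational spectrum
#'
#' Bins substitutions by pyrimidine-centred substitution type and flanking
#' bases; purine-reference mutations are reverse-complemented into the
#' pyrimidine frame. Records without a usable trinucleotide context
#' (chromosome ends, Ns) are skipped with a message.
#'
#' @param catalog a `mutation_catalog` (only SBS records contribute).
#' @param genome the matching `reference_genome`.
#' @param which optional integer record indices restricting the spectrum
#'   (e.g. the members of clustered events).
#' @return an object of class `"sbs96"`: a named integer vector of length 96
#'   whose sum equals the number of contributing substitutions.
#' @export
sbs96_spectrum <- function(catalog, genome, which = NULL) {
  rec <- catalog$records
  if (!is.null(which)) rec <- rec[which, , drop = FALSE]
  rec <- rec[rec$class == "SBS", , drop = FALSE]
  labels <- sbs96_labels()
  counts <- setNames(integer(96), labels)
  if (nrow(rec)) {
    ctx <- extract_context(genome, rec$chrom, rec$pos, k = 3L)
    bad <- is.na(ctx) | grepl("N", ctx, fixed = TRUE)
    if (any(bad))
      mc_message(sum(bad), " substitution(s) without trinucleotide context ",
                 "skipped in the spectrum")
    rec <- rec[!bad, , drop = FALSE]; ctx <- ctx[!bad]
    if (nrow(rec)) {
      ref <- rec$ref; alt <- rec$alt
      flip <- ref %in% PURINES
      ctx[flip] <- revcomp(ctx[flip])
      ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
      alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
      lab <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                    substr(ctx, 3, 3))
      tab <- table(factor(lab, levels = labels))
      counts <- counts + as.integer(tab)
      names(counts) <- labels
    }
  }
  structure(counts, class = "sbs96")
}

#' @export
print.sbs96 <- function(x, ...) {
  cat("SBS-96 spectrum: ", sum(x), " substitution(s)\n", sep = "")
  by6 <- tapply(unclass(x), rep(SBS6, each = 16), sum)[SBS6]
  print(by6)
  invisible(x)
}

#' Barplot of an SBS-96 spectrum
#' @param height an `sbs96` spectrum.
#' @param main plot title.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
barplot.sbs96 <- function(height, main = "SBS-96 spectrum", ...) {
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63",
                "#EBC5C3"), each = 16)
  graphics::barplot(unclass(height), col = cols, border = NA, las = 2,
                    cex.names = 0.3, main = main, ylab = "count", ...)
}

#' Rainfall data series
#'
#' One row per mutation on chromosomes carrying at least two mutations:
#' cumulative genomic coordinate (chromosomes concatenated in reference
#' order), nearest-neighbour IMD and the subclass of the clustered event the
#' mutation belongs to (`"non-clustered"` otherwise). Substitutions and
#' indels both appear; the IMD here is computed over all mutations of the
#' sample, matching the rainfall convention.
#'
#' @param catalog a `mutation_catalog`.
#' @param events the `events` table from [classify_catalog()] (may be empty).
#' @param genome a `reference_genome` fixing chromosome order and offsets.
#' @return a data.frame with columns `chrom`, `pos`, `gpos`, `imd`,
#'   `subclass`.
#' @export
rainfall_data <- function(catalog, events, genome) {
  rec <- catalog$records
  offs <- c(0, cumsum(as.numeric(genome$lengths)))
  names(offs) <- c(names(genome$lengths), "_end")
  sub <- rep("non-clustered", nrow(rec))
  if (!is.null(events) && nrow(events))
    for (i in seq_len(nrow(events)))
      sub[events$members[[i]]] <- events$subclass[i]
  out <- NULL
  for (chr in names(genome$lengths)) {
    idx <- which(rec$chrom == chr)
    if (length(idx) < 2L) next
    imd <- compute_imds(rec$pos[idx])$imd
    out <- rbind(out, data.frame(
      chrom = chr, pos = rec$pos[idx],
      gpos = offs[[chr]] + rec$pos[idx],
      imd = imd, subclass = sub[idx], stringsAsFactors = FALSE))
  }
  out %||% data.frame(chrom = character(), pos = integer(),
                      gpos = numeric(), imd = numeric(),
                      subclass = character(), stringsAsFactors = FALSE)
}

subclass_colors <- function() {
  c("non-clustered" = "grey70", "DBS" = "#E6862C", "MBS" = "#8E44AD",
    "omikli" = "#2E86C1", "kataegis" = "#C0392B",
    "other" = "#27AE60", "clustered_indel" = "#7F8C8D")
}

open_device <- function(out, width = 9, height = 5) {
  ext <- tolower(tools::file_ext(out))
  switch(ext,
         png = grDevices::png(out, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(out, width = width, height = height),
         stop("unsupported image format: ", ext))
}

#' Rainfall plot
#'
#' Scatter of log10 nearest-neighbour IMD against cumulative genomic
#' coordinate, points coloured by clustered subclass, with a horizontal line
#' at the global IMD cutoff and chromosome boundary ticks. The plotted data
#' series is co-written as a TSV next to the image so results can be
#' compared numerically rather than by pixels.
#'
#' @param catalog a `mutation_catalog`.
#' @param events events table from [classify_catalog()] (or `NULL`).
#' @param thresholds a `threshold_model` (or `NULL`: no cutoff line).
#' @param genome a `reference_genome`.
#' @param out image path (`.png` or `.pdf`); the TSV lands at the same path
#'   with extension `.tsv`.
#' @return the rainfall data.frame, invisibly.
#' @export
plot_rainfall <- function(catalog, events, thresholds, genome, out = NULL) {
  rf <- rainfall_data(catalog, events, genome)
  if (!is.null(out)) {
    write.table(rf, sub("\\.[^.]+$", ".tsv", out), sep = "\t",
                quote = FALSE, row.names = FALSE)
    open_device(out)
    on.exit(grDevices::dev.off())
  }
  cols <- subclass_colors()
  if (nrow(rf) == 0L) {
    plot(0, 0, type = "n", xlab = "genomic position", ylab = "log10 IMD",
         main = paste0("Rainfall: ", catalog$sample_id))
    graphics::text(0, 0, "no mutations with defined IMD")
    return(invisible(rf))
  }
  plot(rf$gpos, log10(rf$imd), pch = 16, cex = 0.5,
       col = cols[rf$subclass],
       xlab = "genomic position (bp, chromosomes concatenated)",
       ylab = "log10 nearest-neighbour IMD",
       main = paste0("Rainfall: ", catalog$sample_id))
  graphics::abline(v = cumsum(as.numeric(genome$lengths)), col = "grey85",
                   lty = 3)
  if (!is.null(thresholds) && !is.na(thresholds$global_cutoff))
    graphics::abline(h = log10(thresholds$global_cutoff), col = "red",
                     lty = 2)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.6, bg = "white")
  invisible(rf)
}

#' Multi-panel summary figure
#'
#' Four panels: SBS-96 spectra of all, clustered and non-clustered
#' substitutions, and the distribution of real nearest-neighbour IMDs
#' overlaid with the simulated envelope (2.5--97.5 percentile band across
#' the ensemble), with the global cutoff marked. Panel data are co-written
#' as TSVs (`*_spectra.tsv`, `*_imd.tsv`).
#'
#' @param catalog a `mutation_catalog`.
#' @param events events table (or `NULL`).
#' @param ensemble a `sim_ensemble` (or `NULL`: the IMD panel shows only the
#'   real distribution).
#' @param thresholds a `threshold_model` (or `NULL`).
#' @param genome a `reference_genome`.
#' @param out image path (`.png`/`.pdf`).
#' @return invisibly, a list with the spectra matrix and the IMD histogram
#'   table.
#' @export
summary_panel <- function(catalog, events, ensemble, thresholds, genome,
                          out = NULL) {
  clustered <- if (!is.null(events) && nrow(events))
    unlist(events$members, use.names = FALSE) else integer(0)
  nonclustered <- setdiff(seq_len(nrow(catalog$records)), clustered)
  sp_all <- sbs96_spectrum(catalog, genome)
  sp_cl <- sbs96_spectrum(catalog, genome, which = clustered)
  sp_nc <- sbs96_spectrum(catalog, genome, which = nonclustered)
  spectra <- cbind(all = unclass(sp_all), clustered = unclass(sp_cl),
                   non_clustered = unclass(sp_nc))

  prof <- catalog_imd_profile(catalog)
  real_imd <- prof$pooled
  breaks <- seq(0, 8, by = 0.25)
  clamp <- function(x) pmin(pmax(log10(x), 0), 8)
  real_h <- graphics::hist(clamp(real_imd), breaks = breaks, plot = FALSE)
  imd_tab <- data.frame(log10_imd = real_h$mids, real = real_h$counts)
  if (!is.null(ensemble)) {
    sim_counts <- vapply(ensemble$pooled_imds, function(v)
      graphics::hist(clamp(v), breaks = breaks, plot = FALSE)$counts,
      numeric(length(real_h$mids)))
    imd_tab$sim_lo <- apply(sim_counts, 1, quantile, probs = 0.025)
    imd_tab$sim_median <- apply(sim_counts, 1, stats::median)
    imd_tab$sim_hi <- apply(sim_counts, 1, quantile, probs = 0.975)
  }

  if (!is.null(out)) {
    base <- sub("\\.[^.]+$", "", out)
    write.table(cbind(channel = rownames(spectra), as.data.frame(spectra)),
                paste0(base, "_spectra.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(imd_tab, paste0(base, "_imd.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    open_device(out, width = 10, height = 7)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 2), mar = c(3, 4, 2, 1))
  # restore par before any device opened above is closed
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  barplot.sbs96(sp_all, main = "All mutations")
  if (sum(sp_cl) > 0) barplot.sbs96(sp_cl, main = "Clustered")
  else { plot.new(); graphics::title("Clustered (no mutations)") }
  barplot.sbs96(sp_nc, main = "Non-clustered")
  ylim <- c(0, max(imd_tab$real,
                   if (!is.null(ensemble)) imd_tab$sim_hi else 0, 1))
  plot(imd_tab$log10_imd, imd_tab$real, type = "s", lwd = 2, ylim = ylim,
       xlab = "log10 IMD", ylab = "mutations", main = "IMD distribution")
  if (!is.null(ensemble)) {
    graphics::polygon(c(imd_tab$log10_imd, rev(imd_tab$log10_imd)),
                      c(imd_tab$sim_lo, rev(imd_tab$sim_hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(imd_tab$log10_imd, imd_tab$sim_median,
                    col = "steelblue", lwd = 1.5)
    graphics::lines(imd_tab$log10_imd, imd_tab$real, type = "s", lwd = 2)
  }
  if (!is.null(thresholds) && !is.na(thresholds$global_cutoff))
    graphics::abline(v = log10(thresholds$global_cutoff), col = "red",
                     lty = 2)
  invisible(list(spectra = spectra, imd = imd_tab))
}
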