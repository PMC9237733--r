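SUBCLASSES <- c("DBS", "MBS", "omikli", "kataegis", "other",
                "clustered_indel")

#' Chain sub-cutoff mutations into candidate clustered events
#'
#' A candidate event is a maximal run of consecutive same-chromosome,
#' same-class mutations in which every consecutive gap g is below the local
#' cutoff applicable at the gap's midpoint (the minimum cutoff among sliding
#' windows containing it). Substitutions and indels chain separately.
#'
#' @param catalog a `mutation_catalog`.
#' @param thresholds a `threshold_model` with a non-`NA` global cutoff.
#' @return list of candidates; each is a list with `indices` (row indices
#'   into `catalog$records`), `chrom`, `class`, `gaps` and `local_cutoff`
#'   (minimum cutoff applicable across the run).
#' @export
extract_clusters <- function(catalog, thresholds) {
  if (is.na(thresholds$global_cutoff))
    stop("cluster extraction requires a non-NA global cutoff")
  rec <- catalog$records
  out <- list()
  for (cls in c("SBS", "INDEL")) {
    idx_all <- which(rec$class == cls)
    for (chr in unique(rec$chrom[idx_all])) {
      idx <- idx_all[rec$chrom[idx_all] == chr]
      if (length(idx) < 2L) next
      pos <- rec$pos[idx]
      gaps <- diff(pos)
      mids <- floor((pos[-length(pos)] + pos[-1]) / 2)
      cut_at <- local_cutoff_at(thresholds, chr, mids)
      pass <- gaps < cut_at
      r <- rle(pass)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        gi <- starts[j]:ends[j]           # indices into gaps
        members <- idx[gi[1]:(gi[length(gi)] + 1L)]
        out[[length(out) + 1L]] <- list(
          indices = members, chrom = chr, class = cls,
          gaps = as.numeric(gaps[gi]),
          local_cutoff = min(cut_at[gi]))
      }
    }
  }
  out
}

# pairwise adjacent VAF/CCF consistency with CCF precedence; pairs lacking
# data pass vacuously. Returns list(consistent, informative).
adjacent_consistency <- function(vaf, ccf, tol_vaf, tol_ccf) {
  n <- length(vaf)
  if (n < 2L) return(list(consistent = TRUE, informative = FALSE))
  ok <- logical(n - 1L); informative <- logical(n - 1L)
  for (i in seq_len(n - 1L)) {
    if (!is.na(ccf[i]) && !is.na(ccf[i + 1L])) {
      ok[i] <- abs(ccf[i + 1L] - ccf[i]) <= tol_ccf
      informative[i] <- TRUE
    } else if (!is.na(vaf[i]) && !is.na(vaf[i + 1L])) {
      ok[i] <- abs(vaf[i + 1L] - vaf[i]) <= tol_vaf
      informative[i] <- TRUE
    } else {
      ok[i] <- TRUE
    }
  }
  list(consistent = all(ok), informative = any(informative))
}

empty_events <- function() {
  ev <- data.frame(event_id = character(), sample_id = character(),
                   chrom = character(), start = integer(), end = integer(),
                   span = integer(), size = integer(),
                   subclass = character(), min_gap = numeric(),
                   max_gap = numeric(), vaf_min = numeric(),
                   vaf_max = numeric(), vaf_informative = logical(),
                   local_cutoff = integer(), stringsAsFactors = FALSE)
  ev$members <- list()
  ev
}

#' Subclassify one candidate clustered event
#'
#' Rule table: indel candidates are `clustered_indel` (never subclassified
#' further); substitution candidates with an inconsistent adjacent VAF/CCF
#' pair are `other`; otherwise two mutations at IMD 1 are a doublet-base
#' substitution (`DBS`), three or more mutations all at IMD 1 a multi-base
#' substitution (`MBS`), two or three mutations with at least one IMD
#' greater than 1 are `omikli`, and four or more mutations with at least one
#' IMD greater than 1 are `kataegis`. CCF takes precedence over VAF where
#' both are available; pairs without data pass vacuously.
#'
#' @param gaps numeric vector of the event's internal gaps (length size-1).
#' @param class `"SBS"` or `"INDEL"`.
#' @param vaf,ccf optional numeric vectors (length size) of member VAFs/CCFs.
#' @param tol_vaf,tol_ccf consistency tolerances (defaults 0.10 and 0.25).
#' @return subclass label (character scalar).
#' @examples
#' classify_event(gaps = 1)                              # "DBS"
#' classify_event(gaps = c(1, 1))                        # "MBS"
#' classify_event(gaps = 700)                            # "omikli"
#' classify_event(gaps = c(200, 150, 900))               # "kataegis"
#' classify_event(gaps = c(1, 500), vaf = c(0.40, 0.41, 0.80))  # "other"
#' @export
classify_event <- function(gaps, class = "SBS", vaf = NULL, ccf = NULL,
                           tol_vaf = 0.10, tol_ccf = 0.25) {
  size <- length(gaps) + 1L
  if (size < 2L) stop("an event needs at least 2 members")
  if (class == "INDEL") return("clustered_indel")
  n <- size
  if (is.null(vaf)) vaf <- rep(NA_real_, n)
  if (is.null(ccf)) ccf <- rep(NA_real_, n)
  cons <- adjacent_consistency(vaf, ccf, tol_vaf, tol_ccf)
  if (!cons$consistent) return("other")
  if (all(gaps == 1)) {
    if (size == 2L) "DBS" else "MBS"
  } else {
    if (size <= 3L) "omikli" else "kataegis"
  }
}

#' Partition a catalog into classified clustered events and the rest
#'
#' @param catalog a `mutation_catalog`.
#' @param thresholds a `threshold_model` with a non-`NA` global cutoff.
#' @param tol_vaf,tol_ccf VAF/CCF consistency tolerances.
#' @return list with `events` (data.frame, one row per event: `event_id`,
#'   `sample_id`, `chrom`, `start`, `end`, `span`, `size`, `subclass`,
#'   `min_gap`, `max_gap`, `vaf_min`, `vaf_max`, `vaf_informative`,
#'   `local_cutoff`, and list-column `members` of record indices),
#'   `nonclustered` (integer record indices) and `summary` (named counts per
#'   subclass). Every record lands in exactly one event or in
#'   `nonclustered`.
#' @export
classify_catalog <- function(catalog, thresholds, tol_vaf = 0.10,
                             tol_ccf = 0.25) {
  cands <- extract_clusters(catalog, thresholds)
  rec <- catalog$records
  n <- length(cands)
  if (n == 0L)
    return(list(events = empty_events(), nonclustered = seq_len(nrow(rec)),
                summary = table(factor(character(), levels = SUBCLASSES))))
  rows <- lapply(cands, function(cd) {
    m <- cd$indices
    vaf <- rec$vaf[m]; ccf <- rec$ccf[m]
    sub <- classify_event(cd$gaps, cd$class, vaf, ccf, tol_vaf, tol_ccf)
    cons <- adjacent_consistency(vaf, ccf, tol_vaf, tol_ccf)
    data.frame(
      event_id = sprintf("%s_%s_%d_%d", catalog$sample_id, cd$chrom,
                         rec$pos[m[1]], length(m)),
      sample_id = catalog$sample_id, chrom = cd$chrom,
      start = rec$pos[m[1]], end = rec$pos[m[length(m)]],
      span = rec$pos[m[length(m)]] - rec$pos[m[1]],
      size = length(m), subclass = sub,
      min_gap = min(cd$gaps), max_gap = max(cd$gaps),
      vaf_min = if (all(is.na(vaf))) NA_real_ else min(vaf, na.rm = TRUE),
      vaf_max = if (all(is.na(vaf))) NA_real_ else max(vaf, na.rm = TRUE),
      vaf_informative = cons$informative,
      local_cutoff = cd$local_cutoff, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev$members <- lapply(cands, `[[`, "indices")
  clustered_idx <- unlist(ev$members, use.names = FALSE)
  list(events = ev,
       nonclustered = setdiff(seq_len(nrow(rec)), clustered_idx),
       summary = table(factor(ev$subclass, levels = SUBCLASSES)))
}

#' Write the per-event summary TSV
#'
#' @param events the `events` data.frame from [classify_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- events[, setdiff(names(events), "members"), drop = FALSE]
  out$low_confidence <- !events$vaf_informative
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
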