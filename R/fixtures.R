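#' Generate a random mini-genome
#'
#' Independent draws per base with the requested GC fraction, split evenly
#' across chromosomes named `chr1..chrN`. Deterministic per seed.
#'
#' @param length total genome length in bp (>= 10 kb per chromosome).
#' @param gc GC fraction (default 0.5).
#' @param n_chroms number of chromosomes.
#' @param seed integer seed.
#' @param path optional FASTA output path.
#' @return a `reference_genome` (FASTA written when `path` is given).
#' @export
make_genome <- function(length, gc = 0.5, n_chroms = 1L, seed = 1L,
                        path = NULL) {
  length <- as.numeric(length)
  n_chroms <- as.integer(n_chroms)
  if (length / n_chroms < 1e4) stop("need at least 10 kb per chromosome")
  set.seed(as.integer(seed))
  per <- floor(length / n_chroms)
  lens <- rep(per, n_chroms)
  lens[n_chroms] <- length - per * (n_chroms - 1L)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lens, function(l)
    paste(sample(DNA_BASES, l, replace = TRUE, prob = prob), collapse = ""),
    character(1))
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  g <- reference_genome(seqs, genome_id = sprintf("synthetic_seed%d", seed))
  if (!is.null(path)) write_genome(g, path)
  g
}

#' Specification of a planted clustered event
#'
#' Validates that size and gap range are compatible with the subclass rule
#' table (e.g. a DBS has size 2 and gap 1; omikli/kataegis need gaps greater
#' than 1 so the planted truth is unambiguous).
#'
#' @param subclass one of `"DBS"`, `"MBS"`, `"omikli"`, `"kataegis"`,
#'   `"indel_cluster"`.
#' @param size event size (mutation count).
#' @param gap_range integer min/max of internal gaps in bp.
#' @param vaf VAF assigned to every member.
#' @param count how many such events to plant.
#' @return an object of class `"plant_spec"`.
#' @export
plant_spec <- function(subclass = c("DBS", "MBS", "omikli", "kataegis",
                                    "indel_cluster"),
                       size = 2L, gap_range = c(1L, 1L), vaf = 0.4,
                       count = 1L) {
  subclass <- match.arg(subclass)
  size <- as.integer(size); gap_range <- as.integer(gap_range)
  stopifnot(length(gap_range) == 2L, gap_range[1] >= 1L,
            gap_range[1] <= gap_range[2], count >= 1L)
  ok <- switch(subclass,
               DBS = size == 2L && all(gap_range == 1L),
               MBS = size >= 3L && all(gap_range == 1L),
               omikli = size %in% 2:3 && gap_range[1] >= 2L,
               kataegis = size >= 4L && gap_range[1] >= 2L,
               indel_cluster = size >= 2L)
  if (!ok) stop("size/gap_range incompatible with subclass ", subclass)
  structure(list(subclass = subclass, size = size, gap_range = gap_range,
                 vaf = vaf, count = count), class = "plant_spec")
}

#' Plant a mutation catalog with known clustered events
#'
#' Background substitutions are placed uniformly (rejected within `margin`
#' bp of any planted event so truth labels stay unambiguous); each planted
#' event realises its spec with internal gaps drawn uniformly from
#' `gap_range`. Reference alleles are read from the genome, alternates drawn
#' at random; for indel events each member is a 1-bp deletion. Deterministic
#' per seed.
#'
#' @param genome a `reference_genome`.
#' @param n_background number of background substitutions.
#' @param plants list of [plant_spec()] objects.
#' @param background_vaf VAF assigned to background mutations.
#' @param seed integer seed.
#' @param margin exclusion margin around planted events in bp (default
#'   10000).
#' @param sample_id sample name.
#' @return list with `catalog` (a `mutation_catalog`) and `truth`
#'   (data.frame `chrom`, `pos`, `label`, `event`; label `"NONE"` for
#'   background).
#' @export
plant_catalog <- function(genome, n_background, plants = list(),
                          background_vaf = 0.4, seed = 1L, margin = 10000L,
                          sample_id = "synthetic") {
  set.seed(as.integer(seed))
  chroms <- names(genome$lengths)
  occupied <- lapply(chroms, function(x) cbind(integer(0), integer(0)))
  names(occupied) <- chroms
  rows <- list(); truth <- list(); ev_counter <- 0L

  overlaps <- function(chr, s, e) {
    occ <- occupied[[chr]]
    nrow(occ) > 0L && any(s <= occ[, 2] + margin & e >= occ[, 1] - margin)
  }
  random_alt <- function(ref) {
    vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  }

  for (sp in plants) {
    for (j in seq_len(sp$count)) {
      placed <- FALSE
      for (attempt in 1:1000) {
        chr <- if (length(chroms) == 1L) chroms else sample(chroms, 1L)
        gaps <- if (sp$gap_range[1] == sp$gap_range[2])
          rep(sp$gap_range[1], sp$size - 1L)
        else sample(seq(sp$gap_range[1], sp$gap_range[2]), sp$size - 1L,
                    replace = TRUE)
        span <- sum(gaps)
        len <- genome$lengths[[chr]]
        lo <- 3L; hi <- len - span - 3L
        if (hi <= lo) next
        start <- lo + floor(runif(1) * (hi - lo))
        pos <- start + c(0, cumsum(gaps))
        if (overlaps(chr, pos[1], pos[length(pos)])) next
        ref <- extract_context(genome, chr, pos, k = 1L)
        if (anyNA(ref) || any(ref == "N")) next
        ev_counter <- ev_counter + 1L
        if (sp$subclass == "indel_cluster") {
          ref2 <- extract_context(genome, chr, pos + 1L, k = 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chr, pos = pos, ref = paste0(ref, ref2), alt = ref,
            vaf = sp$vaf, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chr, pos = pos, ref = ref, alt = random_alt(ref),
            vaf = sp$vaf, stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chr, pos = pos, label = sp$subclass,
          event = sprintf("planted_%03d", ev_counter),
          stringsAsFactors = FALSE)
        occupied[[chr]] <- rbind(occupied[[chr]],
                                 c(pos[1], pos[length(pos)]))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place a ", sp$subclass,
             " event: genome too crowded for the requested plants")
    }
  }

  # background: uniform, rejected near planted events and on N bases
  if (n_background > 0L) {
    tot <- sum(as.numeric(genome$lengths))
    got <- 0L; guard <- 0L
    bg_chr <- character(n_background); bg_pos <- integer(n_background)
    while (got < n_background) {
      guard <- guard + 1L
      if (guard > 200L * n_background + 1000L)
        stop("background placement exhausted the genome space")
      chr <- sample(chroms, 1L, prob = as.numeric(genome$lengths) / tot)
      p <- sample.int(genome$lengths[[chr]], 1L)
      if (overlaps(chr, p, p)) next
      b <- extract_context(genome, chr, p, k = 1L)
      if (is.na(b) || b == "N") next
      got <- got + 1L
      bg_chr[got] <- chr; bg_pos[got] <- p
    }
    ref <- extract_context(genome, bg_chr, bg_pos, k = 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = bg_chr, pos = bg_pos, ref = ref, alt = random_alt(ref),
      vaf = background_vaf, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      chrom = bg_chr, pos = bg_pos, label = "NONE", event = NA_character_,
      stringsAsFactors = FALSE)
  }

  rec <- do.call(rbind, rows)
  tru <- do.call(rbind, truth)
  cat <- mutation_catalog(rec, sample_id, genome_id = genome$genome_id,
                          genome = genome)
  # align truth to the deduplicated, sorted catalog
  key <- paste(cat$records$chrom, cat$records$pos)
  tru <- tru[!duplicated(paste(tru$chrom, tru$pos)), , drop = FALSE]
  tru <- tru[match(key, paste(tru$chrom, tru$pos)), , drop = FALSE]
  rownames(tru) <- NULL
  list(catalog = cat, truth = tru)
}

#' Score recovery of planted events
#'
#' A mutation counts as a subclass true positive when it is detected inside
#' an event carrying its true subclass label; clustered-vs-non-clustered
#' recovery ignores the subclass. Precision is `NA` for subclasses never
#' predicted.
#'
#' @param truth truth data.frame from [plant_catalog()].
#' @param events events table from [classify_catalog()].
#' @param catalog the classified `mutation_catalog` (supplies record order).
#' @return data.frame with one row per subclass plus a `clustered` row:
#'   `n_true`, `n_detected`, `tp`, `precision`, `recall`.
#' @export
score_recovery <- function(truth, events, catalog) {
  n <- nrow(catalog$records)
  pred <- rep("NONE", n)
  if (!is.null(events) && nrow(events))
    for (i in seq_len(nrow(events)))
      pred[events$members[[i]]] <- events$subclass[i]
  # indel_cluster plants are detected as clustered_indel
  tru <- truth$label
  tru[tru == "indel_cluster"] <- "clustered_indel"
  levels <- union(setdiff(unique(tru), "NONE"),
                  setdiff(unique(pred), "NONE"))
  per <- lapply(levels, function(l) {
    tp <- sum(tru == l & pred == l)
    data.frame(subclass = l, n_true = sum(tru == l),
               n_detected = sum(pred == l), tp = tp,
               precision = if (sum(pred == l)) tp / sum(pred == l)
               else NA_real_,
               recall = if (sum(tru == l)) tp / sum(tru == l)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  tp_c <- sum(tru != "NONE" & pred != "NONE")
  per[[length(per) + 1L]] <- data.frame(
    subclass = "clustered", n_true = sum(tru != "NONE"),
    n_detected = sum(pred != "NONE"), tp = tp_c,
    precision = if (sum(pred != "NONE")) tp_c / sum(pred != "NONE")
    else NA_real_,
    recall = if (sum(tru != "NONE")) tp_c / sum(tru != "NONE")
    else NA_real_,
    stringsAsFactors = FALSE)
  do.call(rbind, per)
}
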