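#' Build a sequence-context index for background simulation
#'
#' Enumerates, for every requested k-mer, all chromosome positions whose
#' centred reference k-mer equals it (k-mers containing N never match).
#' When an annotation is supplied the positions are further partitioned into
#' region classes: intergenic (`ig`), genic on the plus strand (`g+`), genic
#' on the minus strand (`g-`) and covered by genes on both strands (`g=`).
#' The simulator draws replacement positions from these postings so that
#' each substitution keeps its sequence context, its genic/intergenic status
#' and its transcriptional strand class.
#'
#' @param genome a `reference_genome`.
#' @param annotation optional `gene_annotation`.
#' @param k odd context width (default 5).
#' @param kmers optional character vector restricting the index to these
#'   k-mers (postings for the requested k-mers are identical to a full
#'   index); `NULL` enumerates all `4^k`.
#' @return an object of class `"context_index"`.
#' @examples
#' g <- reference_genome(c(chr1 = "ACGTACGT"), "toy")
#' idx <- build_context_index(g, k = 3)
#' idx$postings[["chr1"]][["all"]][["CGT"]]  # positions 3 and 7
#' @export
build_context_index <- function(genome, annotation = NULL, k = 5L,
                                kmers = NULL) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be a positive odd integer")
  if (is.null(kmers)) kmers <- Biostrings::mkAllStrings(DNA_BASES, k)
  kmers <- sort(unique(toupper(kmers)))
  if (any(nchar(kmers) != k)) stop("kmers must all have width k")
  flank <- (k - 1L) %/% 2L
  classes <- if (is.null(annotation)) "all" else c("ig", "g+", "g-", "g=")

  pd <- Biostrings::PDict(kmers)
  postings <- list()
  for (chr in names(genome$seqs)) {
    seq <- genome$seqs[[chr]]
    m <- Biostrings::matchPDict(pd, seq)
    starts <- Biostrings::startIndex(m)
    centers <- lapply(starts, function(s)
      if (is.null(s)) integer(0) else as.integer(s) + flank)
    names(centers) <- kmers
    if (is.null(annotation)) {
      postings[[chr]] <- list(all = centers)
    } else {
      cls_vec <- chromosome_class_vector(chr, genome$lengths[[chr]], annotation)
      by_class <- lapply(classes, function(cl) {
        lapply(centers, function(p) p[cls_vec[p] == cl])
      })
      names(by_class) <- classes
      postings[[chr]] <- by_class
    }
  }
  structure(list(genome_id = genome$genome_id, k = k, kmers = kmers,
                 classes = classes, postings = postings,
                 genome = genome, annotation = annotation),
            class = "context_index")
}

# region class of every position on a chromosome, as a character vector
chromosome_class_vector <- function(chr, len, annotation) {
  gr <- annotation$gr
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
  plus <- logical(len); minus <- logical(len)
  mark <- function(mask, ranges) {
    for (i in seq_along(ranges)) {
      s <- max(1L, IRanges::start(ranges)[i])
      e <- min(len, IRanges::end(ranges)[i])
      if (s <= e) mask[s:e] <- TRUE
    }
    mask
  }
  plus <- mark(plus, IRanges::ranges(gr[BiocGenerics::strand(gr) == "+"]))
  minus <- mark(minus, IRanges::ranges(gr[BiocGenerics::strand(gr) == "-"]))
  out <- rep("ig", len)
  out[plus & !minus] <- "g+"
  out[minus & !plus] <- "g-"
  out[plus & minus] <- "g="
  out
}

#' @export
print.context_index <- function(x, ...) {
  cat("Context index (k = ", x$k, ") on genome <", x$genome_id, ">: ",
      length(x$postings), " chromosome(s), ", length(x$kmers),
      " k-mer(s), classes: ", paste(x$classes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# posting lookup with the fallback ladder:
#   exact (chrom, class, kmer) -> relax strand (any genic class)
#   -> relax region (all classes) -> shrink context to the central 3-mer.
# Returns list(positions, level) where level 0 means no fallback.
lookup_posting <- function(index, chr, cls, kmer) {
  p <- index$postings[[chr]]
  if (is.null(p)) return(list(positions = integer(0), level = 3L))
  if (length(index$classes) == 1L) cls <- "all"
  exact <- p[[cls]][[kmer]]
  if (length(exact)) return(list(positions = exact, level = 0L))
  if (cls %in% c("g+", "g-", "g=")) {
    genic <- c(p[["g+"]][[kmer]], p[["g-"]][[kmer]], p[["g="]][[kmer]])
    if (length(genic)) return(list(positions = sort(genic), level = 1L))
  }
  all_cls <- sort(unlist(lapply(p, `[[`, kmer), use.names = FALSE))
  if (length(all_cls)) return(list(positions = all_cls, level = 2L))
  # central 3-mer, region-free, matched on the fly
  k <- index$k
  mid <- (k + 1L) %/% 2L
  tri <- substr(kmer, mid - 1L, mid + 1L)
  hits <- Biostrings::start(
    Biostrings::matchPattern(tri, index$genome$seqs[[chr]])) + 1L
  list(positions = as.integer(hits), level = 3L)
}
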