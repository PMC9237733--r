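#' Gene annotation container
#'
#' Stranded genic intervals used for (i) the genic/intergenic bookkeeping of
#' the background simulation and (ii) transcriptional strand annotation of
#' genic substitutions. Internally a [GenomicRanges::GRanges].
#'
#' @param chrom,start,end,strand vectors describing 1-based inclusive
#'   intervals; `strand` in `"+"`/`"-"`.
#' @return an object of class `"gene_annotation"` wrapping a `GRanges`.
#' @export
gene_annotation <- function(chrom, start, end, strand) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(strand))
  if (any(end < start)) stop("interval end < start")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)),
    strand = strand)
  structure(list(gr = gr), class = "gene_annotation")
}

#' Read gene intervals from BED or a 1-based GFF-like TSV
#'
#' BED input is 0-based half-open and converted exactly to the package's
#' 1-based inclusive convention (`start + 1`, `end` unchanged); the GFF-like
#' dialect is a headerless TSV `chrom start end strand` already in 1-based
#' inclusive coordinates (or a full 9-column GFF, from which columns 1, 4, 5
#' and 7 are used).
#'
#' @param path input path.
#' @param format `"bed"` or `"gff"`; `"auto"` decides by extension.
#' @return a `gene_annotation`.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_stage("annotation", "file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "gff"
  }
  tab <- read.table(path, header = FALSE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE)
  if (format == "bed") {
    if (ncol(tab) < 6) stop_stage("annotation",
                                  "BED needs 6 columns (strand in column 6)")
    gene_annotation(tab[[1]], tab[[2]] + 1L, tab[[3]], tab[[6]])
  } else {
    if (ncol(tab) >= 9)
      gene_annotation(tab[[1]], tab[[4]], tab[[5]], tab[[7]])
    else {
      if (ncol(tab) < 4) stop_stage("annotation",
                                    "GFF-like TSV needs chrom start end strand")
      gene_annotation(tab[[1]], tab[[2]], tab[[3]], tab[[4]])
    }
  }
}

# Region class of arbitrary positions: "ig" (intergenic), "g+", "g-" or
# "g=" (covered by genes on both strands). Returns "ig" everywhere when
# annotation is NULL.
position_region_class <- function(chrom, pos, annotation) {
  n <- length(pos)
  if (is.null(annotation)) return(rep("ig", n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  gr <- annotation$gr
  plus <- GenomicRanges::countOverlaps(
    q, gr[BiocGenerics::strand(gr) == "+"], ignore.strand = TRUE) > 0
  minus <- GenomicRanges::countOverlaps(
    q, gr[BiocGenerics::strand(gr) == "-"], ignore.strand = TRUE) > 0
  out <- rep("ig", n)
  out[plus & !minus] <- "g+"
  out[minus & !plus] <- "g-"
  out[plus & minus] <- "g="
  out
}

#' Annotate a catalog with genic/intergenic status and transcriptional strand
#'
#' Every record gains `region` (`GENIC`/`INTERGENIC`); genic substitutions
#' gain `tx_strand`: when the pyrimidine of the mutated base pair lies on the
#' coding (untranscribed) strand of the overlapping gene the mutation is
#' `UNTRANSCRIBED`, otherwise `TRANSCRIBED`. A position covered by genes on
#' both strands is treated as genic but strand-ambiguous (`tx_strand` stays
#' `NA`); with no annotation all records keep region `UNKNOWN`.
#'
#' @param catalog a `mutation_catalog`.
#' @param annotation a `gene_annotation`, or `NULL` (no-op).
#' @return the annotated `mutation_catalog`.
#' @export
annotate_regions <- function(catalog, annotation) {
  if (is.null(annotation)) return(catalog)
  rec <- catalog$records
  if (nrow(rec) == 0L) return(catalog)
  cls <- position_region_class(rec$chrom, rec$pos, annotation)
  rec$region <- ifelse(cls == "ig", "INTERGENIC", "GENIC")
  rec$tx_strand <- NA_character_
  sbs <- rec$class == "SBS"
  # coding strand = the gene's own strand; for a (+) gene the reference base
  # is read directly, for a (-) gene the coding-strand base is its complement
  coding_base <- ifelse(cls == "g+", rec$ref,
                        ifelse(cls == "g-", chartr("ACGT", "TGCA", rec$ref),
                               NA_character_))
  pyr <- coding_base %in% PYRIMIDINES
  rec$tx_strand[sbs & cls %in% c("g+", "g-")] <-
    ifelse(pyr[sbs & cls %in% c("g+", "g-")], "UNTRANSCRIBED", "TRANSCRIBED")
  catalog$records <- rec
  catalog
}
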