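#' Reference genome container
#'
#' A thin wrapper around a [Biostrings::DNAStringSet] holding one entry per
#' chromosome. All coordinates in the package are 1-based and inclusive.
#'
#' @param sequences a named character vector or `DNAStringSet` of chromosome
#'   sequences (alphabet A/C/G/T/N, uppercased on construction).
#' @param genome_id identifier for the assembly (free text).
#' @return an object of class `"reference_genome"` with elements `seqs`
#'   (`DNAStringSet`), `genome_id`, and `lengths` (named integer vector).
#' @examples
#' g <- reference_genome(c(chr1 = "AACGTAA"), "toy")
#' chrom_lengths(g)
#' @export
reference_genome <- function(sequences, genome_id = "custom") {
  if (is.character(sequences)) {
    if (is.null(names(sequences)) || anyNA(names(sequences)))
      stop("chromosome sequences must be named")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (!methods::is(sequences, "DNAStringSet"))
    stop("sequences must be a named character vector or DNAStringSet")
  if (anyDuplicated(names(sequences)))
    stop("duplicated chromosome names")
  structure(
    list(seqs = sequences,
         genome_id = genome_id,
         lengths = stats::setNames(Biostrings::width(sequences),
                                   names(sequences))),
    class = "reference_genome")
}

#' Read a reference genome from FASTA
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @param genome_id assembly identifier; defaults to the file name.
#' @return a `reference_genome`.
#' @export
read_genome <- function(path, genome_id = basename(path)) {
  if (!file.exists(path))
    stop_stage("reference", "FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  reference_genome(seqs, genome_id)
}

#' Write a reference genome to FASTA
#' @param genome a `reference_genome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("Reference genome <", x$genome_id, ">: ", length(x$seqs),
      " chromosome(s), ", sum(as.numeric(x$lengths)), " bp total\n", sep = "")
  invisible(x)
}

#' Chromosome names and lengths
#' @param genome a `reference_genome`.
#' @return named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome) genome$lengths

#' Extract reference sequence context around positions
#'
#' Returns the reference k-mer centred at each position. Positions whose
#' window would run past either chromosome end yield `NA` (the
#' context-unavailable signal); callers must skip or handle those.
#'
#' @param genome a `reference_genome`.
#' @param chromosome character vector (recycled against `position`).
#' @param position integer vector of 1-based positions.
#' @param k odd window width (default 5).
#' @return character vector of k-mers (possibly containing N), `NA` where the
#'   window exceeds the chromosome ends.
#' @examples
#' g <- reference_genome(c(chr1 = "AACGTAA"), "toy")
#' extract_context(g, "chr1", 4, k = 5)  # "ACGTA"
#' extract_context(g, "chr1", 1, k = 5)  # NA: window leaves the chromosome
#' @export
extract_context <- function(genome, chromosome, position, k = 5L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be a positive odd integer")
  n <- max(length(chromosome), length(position))
  chromosome <- rep_len(chromosome, n)
  position <- rep_len(as.integer(position), n)
  flank <- (k - 1L) %/% 2L
  out <- rep(NA_character_, n)
  for (chr in unique(chromosome)) {
    if (!chr %in% names(genome$seqs))
      stop("unknown chromosome: ", chr)
    idx <- which(chromosome == chr)
    len <- genome$lengths[[chr]]
    pos <- position[idx]
    ok <- pos - flank >= 1L & pos + flank <= len
    if (any(ok)) {
      at <- IRanges::IRanges(start = pos[ok] - flank, width = k)
      out[idx[ok]] <- as.character(
        Biostrings::extractAt(genome$seqs[[chr]], at))
    }
  }
  out
}
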