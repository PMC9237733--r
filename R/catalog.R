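#' Construct a per-sample mutation catalog
#'
#' The catalog is the package's central container: a position-sorted table of
#' somatic variants for one sample. Records at a duplicated
#' chromosome+position are resolved by keeping the first occurrence (the
#' remainder are dropped with a message), so positions are strictly
#' increasing within each chromosome.
#'
#' @param records a data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `vaf`, `ccf`. `ref`/`alt` are uppercase DNA strings; a
#'   single-base ref and alt makes the record an SBS, anything else an indel.
#' @param sample_id sample identifier.
#' @param genome_id identifier of the reference assembly the coordinates
#'   refer to.
#' @param genome optional `reference_genome`; when supplied, records on
#'   chromosomes absent from the genome are dropped with a message.
#' @return an object of class `"mutation_catalog"`: a list with `sample_id`,
#'   `genome_id` and `records` (sorted data.frame with columns `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `vaf`, `ccf`, `region`, `tx_strand`).
#' @export
mutation_catalog <- function(records, sample_id, genome_id = "custom",
                             genome = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(records)))
    stop("records must have columns chrom, pos, ref, alt")
  rec <- data.frame(
    chrom = as.character(records$chrom),
    pos = as.integer(records$pos),
    ref = toupper(as.character(records$ref)),
    alt = toupper(as.character(records$alt)),
    stringsAsFactors = FALSE)
  rec$vaf <- if ("vaf" %in% names(records)) as.numeric(records$vaf) else NA_real_
  rec$ccf <- if ("ccf" %in% names(records)) as.numeric(records$ccf) else NA_real_
  rec$region <- if ("region" %in% names(records))
    as.character(records$region) else "UNKNOWN"
  rec$tx_strand <- if ("tx_strand" %in% names(records))
    as.character(records$tx_strand) else NA_character_

  bad <- which(rec$pos < 1L | rec$ref == rec$alt | is.na(rec$pos))
  if (length(bad)) {
    mc_message("dropping ", length(bad), " invalid record(s) (pos < 1 or ref == alt)")
    rec <- rec[-bad, , drop = FALSE]
  }
  if (!is.null(genome)) {
    unknown <- !rec$chrom %in% names(genome$seqs)
    if (any(unknown)) {
      mc_message("dropping ", sum(unknown),
                 " record(s) on chromosomes absent from the reference")
      rec <- rec[!unknown, , drop = FALSE]
    }
  }
  ok <- !is.na(rec$vaf) & (rec$vaf < 0 | rec$vaf > 1)
  if (any(ok)) stop("vaf values must lie in [0, 1]")
  ok <- !is.na(rec$ccf) & (rec$ccf < 0 | rec$ccf > 1)
  if (any(ok)) stop("ccf values must lie in [0, 1]")

  rec$class <- ifelse(nchar(rec$ref) == 1L & nchar(rec$alt) == 1L &
                        rec$ref %in% DNA_BASES & rec$alt %in% DNA_BASES,
                      "SBS", "INDEL")
  # duplicate chromosome+position: keep first occurrence in input order
  dup <- duplicated(rec[, c("chrom", "pos")])
  if (any(dup)) {
    mc_message("dropping ", sum(dup), " duplicate record(s) at repeated positions")
    rec <- rec[!dup, , drop = FALSE]
  }
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 genome_id = genome_id,
                 records = rec),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  n <- nrow(x$records)
  cat("Mutation catalog for sample '", x$sample_id, "' (", x$genome_id, ")\n",
      "  ", n, " record(s): ", sum(x$records$class == "SBS"), " SBS, ",
      sum(x$records$class == "INDEL"), " indel(s) on ",
      length(unique(x$records$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Number of records in a catalog
#' @param catalog a `mutation_catalog`.
#' @return integer count.
#' @export
n_mutations <- function(catalog) nrow(catalog$records)

#' Read a mutation catalog from VCF, MAF or plain text
#'
#' Supported dialects:
#' \describe{
#'   \item{vcf}{VCF 4.x; multi-allelic rows are split into one record per
#'     alternate allele before duplicate resolution. VAF is taken from the
#'     per-sample FORMAT field named by `vaf_field` (default `AF`), falling
#'     back to the INFO field of the same name; CCF analogously via
#'     `ccf_field` (INFO only).}
#'   \item{maf}{tab-separated with columns `Chromosome`, `Start_Position`,
#'     `Reference_Allele`, `Tumor_Seq_Allele2`, `Tumor_Sample_Barcode` and
#'     optional `t_alt_count`/`t_depth`, from which VAF = t_alt_count/t_depth.}
#'   \item{text}{tab-separated with header
#'     `sample chrom pos ref alt [vaf] [ccf]`.}
#' }
#'
#' @param path input file.
#' @param format one of `"auto"`, `"vcf"`, `"maf"`, `"text"`; `"auto"` picks
#'   by file extension.
#' @param sample_id overrides the sample name found in the file.
#' @param genome optional `reference_genome` used to drop records on unknown
#'   chromosomes.
#' @param vaf_field,ccf_field VCF field names supplying VAF and CCF.
#' @return a `mutation_catalog`.
#' @export
read_catalog <- function(path, format = c("auto", "vcf", "maf", "text"),
                         sample_id = NULL, genome = NULL,
                         vaf_field = "AF", ccf_field = "CCF") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_stage("input", "file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, vcf = "vcf", maf = "maf", "text")
  }
  switch(format,
         vcf = read_catalog_vcf(path, sample_id, genome, vaf_field, ccf_field),
         maf = read_catalog_maf(path, sample_id, genome),
         text = read_catalog_text(path, sample_id, genome))
}

read_catalog_vcf <- function(path, sample_id, genome, vaf_field, ccf_field) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    return(mutation_catalog(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      sample_id %||% "sample", genome_id = "unknown", genome = genome))

  # per-sample FORMAT VAF, falling back to INFO
  vaf <- rep(NA_real_, nrow(fix))
  gt <- vcf@gt
  if (!is.null(gt) && ncol(gt) >= 2L) {
    v <- suppressWarnings(
      vcfR::extract.gt(vcf, element = vaf_field, as.numeric = TRUE))
    if (!is.null(v)) vaf <- as.numeric(v[, 1])
    if (is.null(sample_id)) sample_id <- colnames(gt)[2]
  }
  info_num <- function(field) {
    info <- fix[, "INFO"]
    val <- rep(NA_character_, length(info))
    hit <- !is.na(info) & grepl(paste0("(^|;)", field, "="), info)
    val[hit] <- sub(paste0(".*(^|;)", field, "=([^;]*).*"), "\\2", info[hit])
    val
  }
  if (all(is.na(vaf))) {
    iv <- info_num(vaf_field)
    vaf <- suppressWarnings(as.numeric(vapply(
      strsplit(iv, ","), `[`, character(1), 1)))
  }
  ccf_raw <- info_num(ccf_field)
  ccf <- suppressWarnings(as.numeric(vapply(
    strsplit(ccf_raw, ","), `[`, character(1), 1)))

  if (is.null(sample_id))
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))

  # split multi-allelic rows into one record per alternate allele
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  times <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), times)
  rec <- data.frame(chrom = fix[idx, "CHROM"],
                    pos = as.integer(fix[idx, "POS"]),
                    ref = fix[idx, "REF"],
                    alt = unlist(alts),
                    vaf = vaf[idx],
                    ccf = ccf[idx],
                    stringsAsFactors = FALSE)
  mutation_catalog(rec, sample_id, genome_id = "unknown", genome = genome)
}

read_catalog_maf <- function(path, sample_id, genome) {
  maf <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(maf))
  if (length(miss))
    stop_stage("input", "MAF is missing column(s): ",
               paste(miss, collapse = ", "))
  vaf <- NA_real_
  if (all(c("t_alt_count", "t_depth") %in% names(maf)))
    vaf <- maf$t_alt_count / maf$t_depth
  # "-" denotes a missing allele in MAF indel rows
  ref <- ifelse(maf$Reference_Allele == "-", "", maf$Reference_Allele)
  alt <- ifelse(maf$Tumor_Seq_Allele2 == "-", "", maf$Tumor_Seq_Allele2)
  rec <- data.frame(chrom = as.character(maf$Chromosome),
                    pos = maf$Start_Position,
                    ref = ref, alt = alt, vaf = vaf,
                    stringsAsFactors = FALSE)
  mutation_catalog(rec, sample_id %||% maf$Tumor_Sample_Barcode[1],
                   genome_id = "unknown", genome = genome)
}

read_catalog_text <- function(path, sample_id, genome) {
  txt <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(txt))
  if (length(miss))
    stop_stage("input", "text catalog is missing column(s): ",
               paste(miss, collapse = ", "))
  rec <- txt[, intersect(c("chrom", "pos", "ref", "alt", "vaf", "ccf"),
                         names(txt)), drop = FALSE]
  mutation_catalog(rec, sample_id %||% txt$sample[1],
                   genome_id = "unknown", genome = genome)
}

#' Write a catalog (or subset of records) as a minimal single-sample VCF
#'
#' Writes minimum VCF 4.2 columns; clustered records may carry the
#' `SUBCLASS` and `IMD` INFO tags, and VAF/CCF are emitted as `AF`/`CCF`
#' INFO fields when present.
#'
#' @param catalog a `mutation_catalog`.
#' @param path output path.
#' @param which integer indices of records to write (default all).
#' @param info optional character vector (same length as `which`) of extra
#'   INFO content, e.g. `"SUBCLASS=kataegis;IMD=120"`.
#' @return `path`, invisibly.
#' @export
write_catalog_vcf <- function(catalog, path, which = NULL, info = NULL) {
  rec <- catalog$records
  if (is.null(which)) which <- seq_len(nrow(rec))
  rec <- rec[which, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=mutclust"),
           paste0("##reference=", catalog$genome_id),
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "##INFO=<ID=CCF,Number=1,Type=Float,Description=\"Cancer cell fraction\">",
           "##INFO=<ID=SUBCLASS,Number=1,Type=String,Description=\"Clustered event subclass\">",
           "##INFO=<ID=IMD,Number=1,Type=Integer,Description=\"Nearest-neighbour inter-mutational distance (bp)\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  base_info <- character(nrow(rec))
  add <- function(cur, tag, val, keep) {
    ifelse(keep, ifelse(cur == "", paste0(tag, "=", val),
                        paste0(cur, ";", tag, "=", val)), cur)
  }
  base_info <- add(base_info, "AF", rec$vaf, !is.na(rec$vaf))
  base_info <- add(base_info, "CCF", rec$ccf, !is.na(rec$ccf))
  if (!is.null(info)) {
    stopifnot(length(info) == nrow(rec))
    base_info <- ifelse(info == "", base_info,
                        ifelse(base_info == "", info,
                               paste0(base_info, ";", info)))
  }
  base_info[base_info == ""] <- "."
  ref <- ifelse(rec$ref == "", "-", rec$ref)
  alt <- ifelse(rec$alt == "", "-", rec$alt)
  body <- if (nrow(rec)) paste(rec$chrom, rec$pos, ".", ref, alt,
                               ".", "PASS", base_info, sep = "\t")
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
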