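#' @keywords internal
"_PACKAGE"

#' @importFrom stats p.adjust quantile runif setNames simulate predict coef
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics plot plot.new title barplot
NULL

DNA_BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character DNA (alphabet ACGTN).
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

is_pyrimidine <- function(base) base %in% PYRIMIDINES

`%||%` <- function(a, b) if (is.null(a)) b else a

mc_message <- function(...) message("mutclust: ", ...)

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
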