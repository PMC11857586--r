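#' @importFrom stats rbeta rbinom rnbinom rmultinom runif rlnorm median
#'   p.adjust pnorm sd var lm coef na.omit cor.test setNames
#' @importFrom utils read.delim write.table packageVersion
#' @import data.table
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience used throughout the simulator; for large
#' sequences use [Biostrings::reverseComplement()].
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stopf("%s", msg)

#' Geometric mean ignoring non-finite values
#' @keywords internal
geomean <- function(x) exp(mean(log(x[is.finite(log(x))])))
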