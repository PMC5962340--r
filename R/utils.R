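#' @import data.table
#' @importFrom stats pbinom sd cor wilcox.test binom.test median rnorm runif
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised over a character vector; understands IUPAC ambiguity codes
#' (in particular \code{N}).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## internal: assert a data.frame has the given columns
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  invisible(df)
}

## internal: check nucleotide alphabet (ACGT only, no ambiguity)
is_acgt <- function(x) {
  !grepl("[^ACGT]", x)
}

## internal: derive a stream of independent sub-seeds from one user seed,
## kept below 2^31 so they remain valid R integers
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
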