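# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input. `N` complements to `N`.
#'
#' @param x character vector of DNA strings over `A,C,G,T,N`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Slice a sequence using 0-based half-open coordinates.
slice_seq <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

# Fraction of A/T residues (N counts toward the denominator).
at_fraction_of <- function(x) {
  n <- nchar(x)
  at <- nchar(gsub("[^AT]", "", x))
  ifelse(n > 0L, at / n, NA_real_)
}

count_n <- function(x) {
  nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what),
         call. = FALSE)
  }
  invisible(x)
}

# Random DNA with a given AT fraction (A/T and C/G split evenly).
random_dna <- function(n, at_content) {
  p <- c(A = at_content / 2, C = (1 - at_content) / 2,
         G = (1 - at_content) / 2, T = at_content / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Check a genome argument: named character vector of DNA strings with
# unique non-empty ids.
check_genome <- function(genome) {
  stopifnot(is.character(genome))
  ids <- names(genome)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("genome sequences must carry non-empty names", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("genome sequence ids must be unique", call. = FALSE)
  }
  assert_dna(genome, "genome")
  invisible(genome)
}

empty_candidates <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             tsd = character(0), tsd_right = character(0),
             tir_length = integer(0), tir_mismatches = integer(0),
             n_count = integer(0), at_fraction = numeric(0),
             stringsAsFactors = FALSE)
}
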