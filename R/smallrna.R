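# Small-RNA profiling: ungapped mapping of short reads to family
# consensus sequences, length distribution and per-position
# sense/antisense density.

#' Map small-RNA reads to consensus sequences
#'
#' Ungapped end-to-end alignment at every offset of every consensus,
#' on both strands; `N` never matches.  Each read reports all loci
#' achieving its best mismatch count, provided that count is at most
#' `max_mismatch` (default 2, the conventional short-read mapping
#' budget).
#'
#' @param reads named character vector of read sequences (16-30 nt),
#'   or a data.frame with `read_id` and `sequence` columns (as
#'   produced by [generate_small_rna_reads()]).
#' @param consensi named character vector of consensus sequences.
#' @param max_mismatch maximum mismatches (0-3).
#' @return data.frame of hits: `read_id`, `family`, `position`
#'   (0-based on the consensus, leftmost base), `strand` (`sense` /
#'   `antisense`), `mismatches`, `length`, `n_loci` (equal-best loci
#'   for that read, shared by all its rows).
#' @export
map_reads <- function(reads, consensi, max_mismatch = 2L) {
  if (is.data.frame(reads)) {
    reads <- stats::setNames(reads$sequence, reads$read_id)
  }
  stopifnot(!is.null(names(reads)), length(consensi) > 0,
            !is.null(names(consensi)))
  assert_dna(reads, "reads")
  lens <- nchar(reads)
  if (any(lens < 16L | lens > 30L)) {
    stop("read lengths must be within 16-30 nt", call. = FALSE)
  }
  raw <- map_reads_cpp(unname(reads), unname(consensi),
                       as.integer(max_mismatch))
  hits <- data.frame(read_id = names(reads)[raw$read],
                     family = names(consensi)[raw$consensus],
                     position = raw$pos,
                     strand = ifelse(raw$strand == 1L, "sense",
                                     "antisense"),
                     mismatches = raw$mm,
                     length = lens[raw$read],
                     stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    hits$n_loci <- integer(0)
    return(hits)
  }
  # keep equal-best loci per read
  best <- tapply(hits$mismatches, hits$read_id, min)
  hits <- hits[hits$mismatches == best[hits$read_id], , drop = FALSE]
  nl <- table(hits$read_id)
  hits$n_loci <- as.integer(nl[hits$read_id])
  rownames(hits) <- NULL
  hits
}

#' Length distribution of mapped reads
#'
#' Each distinct read is counted once regardless of how many loci it
#' maps to.
#'
#' @param hits data.frame from [map_reads()].
#' @param lengths integer vector of lengths to tabulate (default
#'   16:30).
#' @return named integer vector of read counts per length.
#' @export
length_distribution <- function(hits, lengths = 16:30) {
  firsts <- hits[!duplicated(hits$read_id), , drop = FALSE]
  counts <- table(factor(firsts$length, levels = lengths))
  stats::setNames(as.integer(counts), as.character(lengths))
}

#' Per-position sense/antisense read density on a consensus
#'
#' Every position covered by a hit is incremented on the hit's
#' strand; multi-mapped reads contribute fractionally (1 / number of
#' equal-best loci), so summed density equals summed mapped read
#' length.
#'
#' @param hits data.frame from [map_reads()].
#' @param consensus consensus sequence (or its length).
#' @param family family name to profile (defaults to the only family
#'   present in `hits`).
#' @return list of class `density_profile`: `family`, `sense`,
#'   `antisense` (numeric vectors over consensus positions).
#' @export
positional_density <- function(hits, consensus, family = NULL) {
  L <- if (is.character(consensus)) nchar(consensus) else
    as.integer(consensus)
  family <- family %||% unique(hits$family)
  stopifnot(length(family) == 1L)
  h <- hits[hits$family == family, , drop = FALSE]
  sense <- numeric(L)
  anti <- numeric(L)
  for (i in seq_len(nrow(h))) {
    idx <- (h$position[i] + 1L):(h$position[i] + h$length[i])
    w <- 1 / h$n_loci[i]
    if (h$strand[i] == "sense") {
      sense[idx] <- sense[idx] + w
    } else {
      anti[idx] <- anti[idx] + w
    }
  }
  structure(list(family = family, sense = sense, antisense = anti),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("small-RNA density on %s (%d nt): total sense %.1f, antisense %.1f\n",
              x$family, length(x$sense), sum(x$sense), sum(x$antisense)))
  invisible(x)
}
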