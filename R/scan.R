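# De novo structural detection of MITE candidates.
#
# A candidate is a locus where identical flanking direct repeats (the
# target site duplication, 2-20 bp) enclose a body shorter than
# 1500 bp whose termini form an inverted repeat (5-60 bp, at most one
# mismatch by default).  The body excludes the TSD copies.  The TIR
# recorded for a body is the longest one satisfying the mismatch
# budget, and the TSD the longest identical direct repeat.

candidate_frame <- function(contig, seq, raw) {
  if (length(raw$start) == 0L) return(empty_candidates())
  # prefix sums over the contig make per-candidate N and AT counts
  # O(1) regardless of how many raw candidates there are
  bytes <- charToRaw(seq)
  at_prefix <- c(0L, cumsum(bytes == as.raw(65L) | bytes == as.raw(84L)))
  n_prefix <- c(0L, cumsum(bytes == as.raw(78L)))
  width <- raw$end - raw$start
  data.frame(contig = contig,
             start = raw$start, end = raw$end,
             tsd = substring(seq, raw$start - raw$tsd_len + 1L, raw$start),
             tsd_right = substring(seq, raw$end + 1L, raw$end + raw$tsd_len),
             tir_length = raw$tir_len,
             tir_mismatches = raw$tir_mm,
             n_count = n_prefix[raw$end + 1L] - n_prefix[raw$start + 1L],
             at_fraction = (at_prefix[raw$end + 1L] -
                              at_prefix[raw$start + 1L]) / width,
             stringsAsFactors = FALSE)
}

scan_with <- function(genome, config, engine, resolve) {
  check_genome(genome)
  stopifnot(inherits(config, "pipeline_config"))
  out <- lapply(names(genome), function(ctg) {
    raw <- engine(genome[[ctg]], config$tir_min, config$tir_max,
                  config$tsd_min, config$tsd_max,
                  config$max_element_len, config$max_tir_mismatch)
    raw <- lapply(raw, as.integer)
    if (resolve && length(raw$start) > 0L) {
      keep <- resolve_overlaps_cpp(raw$start, raw$end, raw$tsd_len,
                                   raw$tir_len, raw$tir_mm,
                                   config$max_element_len)
      raw <- lapply(raw, function(v) v[keep])
    }
    candidate_frame(ctg, genome[[ctg]], raw)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a genome for MITE candidates
#'
#' Reports every locus where a 2-20 bp identical direct repeat flanks
#' a sub-1500 bp body whose termini form a 5-60 bp inverted repeat
#' with at most `max_tir_mismatch` mismatches (defaults from
#' [pipeline_config()]).  With `resolve = TRUE` (the default),
#' overlapping candidates are reduced: candidates are ranked by
#' longer TIR, then fewer TIR mismatches, then longer TSD, then
#' leftmost position, and a candidate is dropped when it shares more
#' than half of the shorter span with a better-ranked survivor.
#'
#' @param genome named character vector of contig sequences.
#' @param config a [pipeline_config()].
#' @param resolve whether to apply overlap resolution.
#' @return data.frame of candidates sorted by (contig, start):
#'   `contig`, `start`, `end` (body, 0-based half-open, TSD
#'   excluded), `tsd`, `tsd_right` (the two TSD copies), `tir_length`,
#'   `tir_mismatches`, `n_count` (Ns in the body), `at_fraction`.
#' @export
scan_genome <- function(genome, config = pipeline_config(),
                        resolve = TRUE) {
  scan_with(genome, config, scan_core_cpp, resolve)
}

#' Reference brute-force candidate enumeration
#'
#' Enumerates candidates by direct examination of every body interval,
#' sharing no code path with [scan_genome()]'s run-length scanner.
#' Intended as an independent cross-check on small inputs; it is
#' considerably slower but applies exactly the same structural rules.
#'
#' @inheritParams scan_genome
#' @return data.frame in the same shape as [scan_genome()].
#' @export
scan_genome_bruteforce <- function(genome, config = pipeline_config(),
                                   resolve = TRUE) {
  scan_with(genome, config, scan_naive_cpp, resolve)
}

#' Filter MITE candidates
#'
#' Applies the candidate filters: at most `max_n` ambiguous residues
#' in the body (fewer than three Ns by default) and perfectly
#' matching TSD copies.  Attrition per rule is recorded in the
#' `"attrition"` attribute of the result.
#'
#' @param candidates data.frame from [scan_genome()].
#' @param max_n maximum number of Ns tolerated in the body.
#' @return filtered data.frame, with attribute `attrition` (named
#'   integer vector: removed by N rule, removed by TSD rule).
#' @export
filter_candidates <- function(candidates, max_n = 2L) {
  fail_n <- candidates$n_count > max_n
  fail_tsd <- candidates$tsd != candidates$tsd_right
  out <- candidates[!fail_n & !fail_tsd, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- c(n_rule = sum(fail_n),
                              tsd_rule = sum(fail_tsd & !fail_n))
  out
}

#' Extract element sequences for a set of candidates
#'
#' @param genome named character vector of contigs.
#' @param candidates data.frame with `contig`, `start`, `end` (and
#'   `tsd` when `include_tsd = TRUE`).
#' @param include_tsd extend each sequence by the TSD on both sides.
#' @return named character vector; ids are `contig:start-end`.
#' @export
extract_element_sequences <- function(genome, candidates,
                                      include_tsd = FALSE) {
  check_genome(genome)
  if (nrow(candidates) == 0L) return(stats::setNames(character(0),
                                                     character(0)))
  bad <- !(candidates$contig %in% names(genome))
  if (any(bad)) {
    stop(sprintf("unknown contig '%s'", candidates$contig[bad][1]),
         call. = FALSE)
  }
  clen <- nchar(genome)[candidates$contig]
  start <- candidates$start
  end <- candidates$end
  if (include_tsd) {
    tlen <- nchar(candidates$tsd)
    start <- start - tlen
    end <- end + tlen
  }
  if (any(start < 0L) || any(end > clen)) {
    stop("candidate coordinates out of contig bounds", call. = FALSE)
  }
  seqs <- substring(genome[candidates$contig], start + 1L, end)
  stats::setNames(seqs, sprintf("%s:%d-%d", candidates$contig,
                                candidates$start, candidates$end))
}
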