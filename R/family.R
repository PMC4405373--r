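# Family building: pairwise identity, single-linkage clustering,
# center-star consensus, genome-wide remnant mining, superfamily
# classification and family naming.

# Batched free-end-gap alignment over an explicit list of index
# pairs.  Scoring for identity/clustering: match +1, mismatch -1,
# linear gap -2.  Returns one row per pair with score, identity over
# aligned columns (terminal overhangs excluded), coverage of the
# shorter sequence, and the substitution spectrum.
aln_pairs <- function(seqs, i, j, gap_open = 0, gap_ext = 2,
                      strings = FALSE, band = 0L) {
  align_pairs_cpp(unname(as.character(seqs)), as.integer(i),
                  as.integer(j), 1, 1, gap_open, gap_ext, strings,
                  as.integer(band))
}

# Convenience: align all of `patterns` against one `subject`.
aln_to_subject <- function(patterns, subject, gap_open = 0,
                           gap_ext = 2, strings = FALSE, band = 0L) {
  n <- length(patterns)
  aln_pairs(c(unname(as.character(patterns)), subject), seq_len(n),
            rep(n + 1L, n), gap_open, gap_ext, strings, band)
}

#' Pairwise sequence identity and coverage
#'
#' Global alignment with free end gaps (match +1, mismatch -1, linear
#' gap -2).  Identity is matches over aligned columns, terminal gaps
#' excluded; coverage is the aligned span of the shorter sequence over
#' its length.  Identity is symmetric in its arguments.
#'
#' @param a,b DNA strings.
#' @return list with `identity`, `coverage` and alignment `score`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("pairwise_identity requires non-empty sequences", call. = FALSE)
  }
  assert_dna(c(a, b))
  res <- aln_pairs(c(a, b), 1L, 2L)
  list(identity = res$identity, coverage = res$coverage,
       score = res$score)
}

# Identity/coverage for an explicit list of index pairs.  `coverage`
# is the aligned fraction of the shorter sequence, `coverage_long` of
# the longer one.
pair_identities <- function(seqs, pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(i = integer(0), j = integer(0),
                      identity = numeric(0), coverage = numeric(0),
                      coverage_long = numeric(0)))
  }
  res <- aln_pairs(seqs, pairs[, 1], pairs[, 2])
  len_i <- nchar(seqs[pairs[, 1]])
  len_j <- nchar(seqs[pairs[, 2]])
  long_span <- ifelse(len_i >= len_j, res$span_p, res$span_s)
  data.frame(i = pairs[, 1], j = pairs[, 2],
             identity = res$identity, coverage = res$coverage,
             coverage_long = long_span / pmax(len_i, len_j))
}

#' Cluster candidate elements into families
#'
#' Builds the graph whose edges join candidate pairs with identity at
#' least `identity_threshold` over an alignment spanning at least
#' `min_coverage` of *both* sequences -- similarity must relate two
#' comparable elements, not a fragment to an element, or short
#' TIR-sharing debris chains into families -- and takes single-linkage
#' components, mirroring transitive family assignment by all-vs-all
#' homology search.  Components smaller than `min_family_size` are
#' discarded and logged.
#'
#' For large candidate sets an all-vs-all megablast prefilter proposes
#' the pairs worth aligning (`prefilter = "auto"` switches it on above
#' 300 sequences when BLAST+ is available); every retained edge is
#' still decided by [pairwise_identity()].
#'
#' @param seqs named character vector of candidate sequences.
#' @param identity_threshold minimum identity for an edge.
#' @param min_family_size smallest family retained.
#' @param min_coverage minimum aligned fraction of each sequence for
#'   an edge.
#' @param prefilter `"auto"`, `"blast"` or `"none"`.
#' @param loci optional data.frame (`contig`, `start`, `end`) parallel
#'   to `seqs`; candidate pairs whose genomic intervals overlap are
#'   never linked, since overlapping loci cannot be two distinct
#'   copies of a family.
#' @return list with `families` (list of member-id character vectors,
#'   largest first) and `discarded` (ids in components below the size
#'   cutoff).
#' @export
cluster_families <- function(seqs, identity_threshold = 0.90,
                             min_family_size = 3L, min_coverage = 0.60,
                             prefilter = c("auto", "blast", "none"),
                             loci = NULL) {
  prefilter <- match.arg(prefilter)
  n <- length(seqs)
  if (n == 0L) return(list(families = list(), discarded = character(0)))
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  use_blast <- switch(prefilter,
                      blast = TRUE,
                      none = FALSE,
                      auto = n > 300L && has_blast())
  pairs <- if (use_blast) {
    blast_candidate_pairs(seqs)
  } else {
    if (n < 2L) matrix(integer(0), 0, 2) else t(utils::combn(n, 2L))
  }
  if (!is.null(loci) && nrow(pairs) > 0L) {
    stopifnot(nrow(loci) == n)
    i <- pairs[, 1]; j <- pairs[, 2]
    disjoint <- loci$contig[i] != loci$contig[j] |
      loci$end[i] <= loci$start[j] | loci$end[j] <= loci$start[i]
    pairs <- pairs[disjoint, , drop = FALSE]
  }
  ids <- pair_identities(seqs, pairs)
  edges <- ids[ids$identity >= identity_threshold &
                 ids$coverage >= min_coverage &
                 ids$coverage_long >= min_coverage, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges$i[k]); rj <- find(edges$j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(names(seqs), comp)
  sizes <- lengths(groups)
  keep <- groups[sizes >= min_family_size]
  first_seen <- vapply(keep, function(g) match(g[1], names(seqs)),
                       integer(1))
  ord <- order(-lengths(keep), first_seen)
  list(families = unname(keep[ord]),
       discarded = unlist(groups[sizes < min_family_size],
                          use.names = FALSE) %||% character(0))
}

#' Build a family consensus sequence
#'
#' Center-star multiple alignment: the member with the highest summed
#' alignment score against the others is the star; every member is aligned to it
#' with free end gaps and projected onto the star's coordinates
#' (member insertions relative to the star are ignored).  Each column
#' takes the majority residue over A,C,G,T, ties broken
#' lexicographically; columns where gaps are the majority are
#' dropped.  Deterministic.
#'
#' @param seqs character vector of member sequences (>= 1).
#' @return consensus DNA string.
#' @export
build_consensus <- function(seqs) {
  seqs <- unname(as.character(seqs))
  stopifnot(length(seqs) >= 1L, all(nzchar(seqs)))
  n <- length(seqs)
  if (n == 1L) return(seqs[[1]])
  if (length(unique(seqs)) == 1L) return(seqs[[1]])
  # star = member with the highest summed alignment score against
  # the rest; the score is length-weighted, so a member that aligns
  # well over its full span beats one sharing only a fragment
  pairs <- t(utils::combn(n, 2L))
  res <- aln_pairs(seqs, pairs[, 1], pairs[, 2])
  scsum <- numeric(n)
  for (k in seq_len(nrow(pairs))) {
    scsum[pairs[k, 1]] <- scsum[pairs[k, 1]] + res$score[k]
    scsum[pairs[k, 2]] <- scsum[pairs[k, 2]] + res$score[k]
  }
  star <- which.max(scsum)
  L <- nchar(seqs[[star]])
  M <- matrix("-", n, L)
  M[star, ] <- strsplit(seqs[[star]], "")[[1]]
  others <- setdiff(seq_len(n), star)
  aln <- aln_to_subject(seqs[others], seqs[[star]], strings = TRUE)
  pa <- aln$a_aln
  sa <- aln$b_aln
  s_off <- aln$s_off
  for (k in seq_along(others)) {
    pc <- strsplit(pa[k], "")[[1]]
    sc <- strsplit(sa[k], "")[[1]]
    pos <- s_off[k]
    for (col in seq_along(sc)) {
      if (sc[col] != "-") {
        pos <- pos + 1L
        M[others[k], pos] <- pc[col]
      }
    }
  }
  cons <- character(0)
  for (col in seq_len(L)) {
    counts <- table(factor(M[, col], levels = c("A", "C", "G", "T", "-", "N")))
    base_counts <- counts[c("A", "C", "G", "T")]
    if (counts[["-"]] >= sum(base_counts) + counts[["N"]]) next
    if (sum(base_counts) == 0L) next
    cons <- c(cons, names(base_counts)[which.max(base_counts)])
  }
  paste(cons, collapse = "")
}

#' Mine remnant copies of a family across a genome
#'
#' Searches the family consensus against both strands of the genome
#' (BLAST+ nominates loci), then applies the mining filters: hits are
#' kept when nucleotide identity is at least `remnant_identity` and
#' query coverage at least `remnant_coverage`.  Hits overlapping a
#' better hit by more than half the shorter span are merged away
#' (higher identity, then higher coverage, then leftmost wins).  Each
#' surviving copy is flagged intact when the TIR + TSD structure is
#' re-detected at the locus.
#'
#' @param consensus family consensus DNA string.
#' @param genome named character vector of contigs.
#' @param remnant_identity,remnant_coverage mining filters.
#' @param config [pipeline_config()] used for the intactness re-scan.
#' @return data.frame: `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `identity`, `coverage`, `intact`.
#' @export
mine_remnants <- function(consensus, genome,
                          remnant_identity = 0.90,
                          remnant_coverage = 0.80,
                          config = pipeline_config()) {
  stopifnot(nzchar(consensus))
  check_genome(genome)
  require_blast()
  dir <- tempfile("mine")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  db <- make_blast_db(genome, dir)
  hits <- run_blastn(c(consensus = consensus), db,
                     c("sseqid", "pident", "length", "qstart", "qend",
                       "sstart", "send"),
                     c("-task", "blastn", "-dust", "no",
                       "-evalue", "1e-5", "-max_target_seqs", "5000"))
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      intact = logical(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  qlen <- nchar(consensus)
  out <- data.frame(
    contig = as.character(hits$sseqid),
    start = pmin(hits$sstart, hits$send) - 1L,
    end = pmax(hits$sstart, hits$send),
    strand = ifelse(hits$sstart <= hits$send, "+", "-"),
    identity = hits$pident / 100,
    coverage = (abs(hits$qend - hits$qstart) + 1L) / qlen,
    stringsAsFactors = FALSE)
  out <- out[out$identity >= remnant_identity &
               out$coverage >= remnant_coverage, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  # merge overlapping hits, best first
  out <- out[order(-out$identity, -out$coverage, out$contig, out$start), ,
             drop = FALSE]
  kept <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    sel <- which(kept & out$contig == out$contig[i])
    ov <- pmin(out$end[sel], out$end[i]) - pmax(out$start[sel], out$start[i])
    w <- pmin(out$end[sel] - out$start[sel], out$end[i] - out$start[i])
    kept[i] <- !any(ov > 0 & 2 * ov > w)
  }
  out <- out[kept, , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  # intactness: re-detect TIR+TSD structure at each locus
  pad <- config$tsd_max + 5L
  out$intact <- vapply(seq_len(nrow(out)), function(i) {
    clen <- nchar(genome[[out$contig[i]]])
    s0 <- max(0L, out$start[i] - pad)
    e0 <- min(clen, out$end[i] + pad)
    slice <- stats::setNames(slice_seq(genome[[out$contig[i]]], s0, e0), "w")
    cand <- scan_genome(slice, config)
    any(abs(cand$start + s0 - out$start[i]) <= 10L &
          abs(cand$end + s0 - out$end[i]) <= 10L)
  }, logical(1))
  out
}

SUPERFAMILY_LEVELS <- c("Stowaway-like", "Tourist-like", "hAT-like",
                        "Merlin-like", "Mutator-like", "Unknown")
SUPERFAMILY_CODE <- c("Stowaway-like" = "S", "Tourist-like" = "T",
                      "hAT-like" = "h", "Merlin-like" = "Me",
                      "Mutator-like" = "Mu", "Unknown" = "N")

#' Classify a family into a MITE superfamily
#'
#' Assignment follows TSD and TIR properties: TSD `"TA"` is
#' Stowaway-like; a 3 bp TSD is Tourist-like; an 8 bp TSD with TIR
#' length 24-34 is Merlin-like, other 8 bp TSDs are hAT-like; a 10 bp
#' TSD is Mutator-like; anything else is Unknown.  Families with a
#' 5-6 bp TSD whose TIR begins `TGT` carry the `tgt_start` flag, a
#' recurrent novel-superfamily signature.
#'
#' @param tsd TSD sequence (string) or TSD length (integer).
#' @param tir_length TIR length in bp.
#' @param tir_sequence optional TIR sequence (used for `tgt_start`).
#' @return list with `superfamily` and `tgt_start`.
#' @export
classify_superfamily <- function(tsd, tir_length, tir_sequence = "") {
  tsd_len <- if (is.character(tsd)) nchar(tsd) else as.integer(tsd)
  is_ta <- is.character(tsd) && toupper(tsd) == "TA"
  superfamily <-
    if (is_ta) "Stowaway-like"
    else if (tsd_len == 3L) "Tourist-like"
    else if (tsd_len == 8L && tir_length >= 24L && tir_length <= 34L)
      "Merlin-like"
    else if (tsd_len == 8L) "hAT-like"
    else if (tsd_len == 10L) "Mutator-like"
    else "Unknown"
  list(superfamily = superfamily,
       tgt_start = tsd_len %in% c(5L, 6L) &&
         startsWith(toupper(tir_sequence), "TGT"))
}

#' Assign systematic family names
#'
#' Names follow the `NxY#` convention: `N` plus a species letter, a
#' superfamily code (`S` Stowaway-like, `T` Tourist-like, `h`
#' hAT-like, `Me` Merlin-like, `Mu` Mutator-like, `N` others) and a
#' number assigned within each superfamily by decreasing member count,
#' ties by discovery order.
#'
#' @param families list of `mite_family` objects (see
#'   [new_mite_family()]).
#' @param species_letter single letter identifying the species.
#' @return the families, each with `$name` set, in the input order.
#' @export
name_families <- function(families, species_letter) {
  stopifnot(is.character(species_letter), nchar(species_letter) >= 1L)
  sf <- vapply(families, function(f) f$superfamily, character(1))
  sizes <- vapply(families, function(f) nrow(f$members), integer(1))
  for (s in unique(sf)) {
    idx <- which(sf == s)
    idx <- idx[order(-sizes[idx], idx)]
    for (k in seq_along(idx)) {
      families[[idx[k]]]$name <- sprintf("N%s%s%d", species_letter,
                                         SUPERFAMILY_CODE[[s]], k)
    }
  }
  names(families) <- vapply(families, function(f) f$name, character(1))
  families
}

#' Construct a MITE family object
#'
#' @param members data.frame of member copies (`contig`, `start`,
#'   `end`, `intact`, `identity_to_consensus`,
#'   `coverage_of_consensus`, ...).
#' @param consensus consensus DNA string.
#' @param tsd_pattern TSD sequence (if shared) or length.
#' @param tir_length representative TIR length (bp).
#' @param name family name (set by [name_families()]).
#' @return object of class `mite_family`.
#' @export
new_mite_family <- function(members, consensus, tsd_pattern, tir_length,
                            name = NA_character_) {
  tir_seq <- substring(consensus, 1L, tir_length)
  cls <- classify_superfamily(tsd_pattern, tir_length, tir_seq)
  structure(list(name = name, members = members, consensus = consensus,
                 superfamily = cls$superfamily,
                 tsd_pattern = tsd_pattern, tir_length = tir_length,
                 tgt_start = cls$tgt_start),
            class = "mite_family")
}

#' @export
print.mite_family <- function(x, ...) {
  pat <- if (is.character(x$tsd_pattern)) x$tsd_pattern else
    sprintf("%d bp", x$tsd_pattern)
  cat(sprintf("MITE family %s (%s): %d copies (%d intact), TSD %s, TIR %d bp, consensus %d bp\n",
              x$name %||% "<unnamed>", x$superfamily, nrow(x$members),
              sum(x$members$intact), pat, x$tir_length,
              nchar(x$consensus)))
  invisible(x)
}
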