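# Genomic context: gene-association statistics with a Monte-Carlo
# placement null, chi-square bias test, translation-initiation-site
# re-annotation, reciprocal best hits and MITE insertion polymorphism
# candidates.

#' Associate elements with gene regions
#'
#' An element is associated with genes when its span intersects any
#' CDS extended by `flank_bp` on both sides (`[cds_start - flank,
#' cds_end + flank)`); with `flank_bp = 0` association means overlap
#' with the CDS itself.
#'
#' @param elements data.frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param genes data.frame of gene models (see
#'   [read_gene_annotations()]).
#' @param flank_bp flank size in bp (300, 200, 100 and 0 are the
#'   conventional choices).
#' @return list of class `association_result`: `flank_bp`,
#'   `n_elements`, `n_associated`, `fraction` and the per-element
#'   logical vector `associated`.
#' @export
associate_with_genes <- function(elements, genes, flank_bp = 300L) {
  stopifnot(flank_bp >= 0L)
  n <- nrow(elements)
  associated <- logical(n)
  if (n > 0L && nrow(genes) > 0L) {
    for (ctg in unique(elements$contig)) {
      ei <- which(elements$contig == ctg)
      g <- genes[genes$contig == ctg, , drop = FALSE]
      if (nrow(g) == 0L) next
      win <- IRanges::IRanges(start = g$cds_start - flank_bp + 1L,
                              end = g$cds_end + flank_bp)
      el <- IRanges::IRanges(start = elements$start[ei] + 1L,
                             end = elements$end[ei])
      associated[ei] <- IRanges::overlapsAny(el, win)
    }
  }
  structure(list(flank_bp = flank_bp, n_elements = n,
                 n_associated = sum(associated),
                 fraction = if (n > 0) sum(associated) / n else NA_real_,
                 associated = associated),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("flank %d bp: %d / %d elements associated with genes (%.1f%%)\n",
              x$flank_bp, x$n_associated, x$n_elements,
              100 * x$fraction))
  invisible(x)
}

# Place m intervals of the given lengths uniformly at random without
# overlap on the genome; returns a data.frame(contig, start, end).
place_random_elements <- function(contig_lengths, element_lengths) {
  k <- length(element_lengths)
  out_ci <- integer(k)
  out_start <- integer(k)
  occ_s <- lapply(contig_lengths, function(x) integer(0))
  occ_e <- lapply(contig_lengths, function(x) integer(0))
  for (i in seq_len(k)) {
    w <- element_lengths[i]
    placed <- FALSE
    for (try in seq_len(5000L)) {
      ci <- sample.int(length(contig_lengths), 1, prob = contig_lengths)
      if (contig_lengths[ci] <= w + 1L) next
      st <- sample.int(contig_lengths[ci] - w, 1) - 1L
      s <- occ_s[[ci]]
      if (length(s) == 0L || all(st + w <= s | st >= occ_e[[ci]])) {
        occ_s[[ci]] <- c(s, st)
        occ_e[[ci]] <- c(occ_e[[ci]], st + w)
        out_ci[i] <- ci
        out_start[i] <- st
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("random placement infeasible: elements do not fit",
           call. = FALSE)
    }
  }
  data.frame(contig = names(contig_lengths)[out_ci], start = out_start,
             end = out_start + as.integer(element_lengths),
             stringsAsFactors = FALSE)
}

#' Null distribution of gene association under random placement
#'
#' Monte-Carlo negative control: in each replicate, elements of the
#' observed lengths are placed uniformly at random without overlap
#' and the associated fraction is recorded.
#'
#' @param genome named character vector of contigs, or a named integer
#'   vector of contig lengths.
#' @param genes gene models.
#' @param element_lengths integer vector of observed element lengths.
#' @param flank_bp flank size.
#' @param replicates number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @return numeric vector of null associated fractions (one per
#'   replicate), with attribute `mean`.
#' @export
simulate_association_null <- function(genome, genes, element_lengths,
                                      flank_bp = 300L, replicates = 1000L,
                                      seed = 1L) {
  stopifnot(replicates >= 1L)
  contig_lengths <- if (is.character(genome)) nchar(genome) else
    stats::setNames(as.integer(genome), names(genome))
  stopifnot(!is.null(names(contig_lengths)))
  set.seed(seed)
  fractions <- vapply(seq_len(replicates), function(r) {
    placed <- place_random_elements(contig_lengths, element_lengths)
    if (length(element_lengths) == 0L) return(0)
    associate_with_genes(placed, genes, flank_bp)$fraction
  }, numeric(1))
  attr(fractions, "mean") <- mean(fractions)
  fractions
}

#' Pearson chi-square test of insertion bias
#'
#' Pearson statistic `sum((O - E)^2 / E)` without continuity
#' correction, upper-tail p-value.  Two usages:
#'
#' * two-way contingency table (r x c matrix with r, c >= 2):
#'   `expected` defaults to the margin products and
#'   `df = (r - 1)(c - 1)`;
#' * goodness of fit against null-model counts (a vector, or a
#'   one-row/one-column matrix, with `expected` supplied, e.g. cell
#'   counts expected under the Monte-Carlo placement null):
#'   `df = cells - 1`.
#'
#' @param observed observed counts (matrix or vector).
#' @param expected expected counts (all > 0); required for the
#'   goodness-of-fit usage.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_bias_test <- function(observed, expected = NULL) {
  observed <- as.matrix(observed)
  two_way <- nrow(observed) >= 2L && ncol(observed) >= 2L
  if (is.null(expected)) {
    if (!two_way) {
      stop("expected counts are required for a one-way comparison",
           call. = FALSE)
    }
    expected <- outer(rowSums(observed), colSums(observed)) /
      sum(observed)
  }
  expected <- as.matrix(expected)
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0)) {
    stop("zero expected cell counts: pool sparse categories first",
         call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- if (two_way) {
    (nrow(observed) - 1L) * (ncol(observed) - 1L)
  } else {
    length(observed) - 1L
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

# Strand-aware sequence fetch: window [pos, pos + len) in reading
# direction for '+', reverse complement of the matching window for
# '-'; pos is in reading-direction coordinates from the gene's start.
read_oriented <- function(seq, strand, from, to) {
  # from/to are 0-based half-open on the oriented strand where
  # position 0 is the first base of the contig read 5'->3' on that
  # strand
  n <- nchar(seq)
  if (strand == "+") slice_seq(seq, from, to)
  else revcomp(slice_seq(seq, n - to, n - from))
}

#' Revise translation initiation sites
#'
#' Re-annotation of start codons driven by transcription-signal
#' motifs: a start codon is accepted when the 10 nt immediately
#' upstream contain a CCC-like or GGG-like motif (by default any `CC`
#' or `GG` dinucleotide, the degenerate-triplet reading of those
#' motifs) and the 30 nt upstream are more than 80\% AT.  Genes whose
#' annotated ATG already satisfies both criteria are left unchanged;
#' otherwise in-frame alternative ATGs within 30 nt (downstream
#' first, then upstream) are examined and the first one satisfying
#' both criteria becomes the revised start.  Because a revised start
#' satisfies the acceptance criteria, the operation is idempotent.
#'
#' @param genes gene models (0-based half-open, `strand`).
#' @param genome named character vector of contigs.
#' @param motif regular expression the 10 nt upstream context must
#'   match (default `"CC|GG"`).
#' @param at_threshold minimum AT fraction (exclusive) of the 30 nt
#'   upstream window.
#' @param window_nt search radius around the annotated start (nt,
#'   multiple of 3).
#' @param context_nt length of the motif context window (nt).
#' @return list with `genes` (revised models) and `log` (data.frame of
#'   revisions: gene, old and new start offset).  Genes not starting
#'   with ATG are skipped with a warning.
#' @export
reannotate_tis <- function(genes, genome, motif = "CC|GG",
                           at_threshold = 0.80, window_nt = 30L,
                           context_nt = 10L) {
  check_genome(genome)
  log <- list()
  out <- genes
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    seq <- genome[[g$contig]]
    n <- nchar(seq)
    # oriented start position: offset of the first CDS base on the
    # reading strand
    ostart <- if (g$strand == "+") g$cds_start else n - g$cds_end
    olen <- g$cds_end - g$cds_start
    codon_at <- function(o) read_oriented(seq, g$strand, o, o + 3L)
    if (codon_at(ostart) != "ATG") {
      warning(sprintf("gene %s does not start with ATG; skipped",
                      g$gene_id))
      next
    }
    qualifies <- function(o) {
      if (o < context_nt || o + 3L > n) return(FALSE)
      if (codon_at(o) != "ATG") return(FALSE)
      ctx <- read_oriented(seq, g$strand, o - context_nt, o)
      if (!grepl(motif, ctx)) return(FALSE)
      wfrom <- max(0L, o - window_nt)
      win <- read_oriented(seq, g$strand, wfrom, o)
      at_fraction_of(win) > at_threshold
    }
    if (qualifies(ostart)) next
    offsets <- c(seq(3L, window_nt, by = 3L),
                 -seq(3L, window_nt, by = 3L))
    for (off in offsets) {
      o <- ostart + off
      if (off >= olen - 3L) next # keep a non-empty CDS
      if (o < 0L || o + 3L > n) next
      if (qualifies(o)) {
        if (g$strand == "+") {
          out$cds_start[i] <- g$cds_start + off
        } else {
          out$cds_end[i] <- g$cds_end - off
        }
        log[[length(log) + 1L]] <- data.frame(
          gene_id = g$gene_id, offset = off,
          old_start = g$cds_start, old_end = g$cds_end,
          new_start = out$cds_start[i], new_end = out$cds_end[i],
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  list(genes = out,
       log = if (length(log) > 0) do.call(rbind, log) else
         data.frame(gene_id = character(0), offset = integer(0),
                    old_start = integer(0), old_end = integer(0),
                    new_start = integer(0), new_end = integer(0),
                    stringsAsFactors = FALSE))
}

# Local protein alignment scores of all of `a` against one subject.
protein_scores <- function(a, subject) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5))
}

#' Reciprocal best hits between two protein sets
#'
#' A pair `(a, b)` is reported when `b` is `a`'s unique best-scoring
#' match and `a` is `b`'s, under local protein alignment (BLOSUM62,
#' gap open 10 / extend 0.5).  Ties yield no pair.
#'
#' @param a,b named character vectors of protein sequences.
#' @return data.frame with columns `a`, `b`, `score`.
#' @export
reciprocal_best_hits <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0,
            !is.null(names(a)), !is.null(names(b)))
  scores <- matrix(NA_real_, length(a), length(b),
                   dimnames = list(names(a), names(b)))
  for (j in seq_along(b)) {
    scores[, j] <- protein_scores(a, b[[j]])
  }
  unique_best <- function(v) {
    m <- max(v)
    idx <- which(v == m)
    if (length(idx) == 1L) idx else NA_integer_
  }
  best_for_a <- apply(scores, 1, unique_best)
  best_for_b <- apply(scores, 2, unique_best)
  pairs <- list()
  for (i in seq_along(a)) {
    j <- best_for_a[i]
    if (!is.na(j) && !is.na(best_for_b[j]) && best_for_b[j] == i) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = names(a)[i], b = names(b)[j], score = scores[i, j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, pairs)
}

# 5'-flank window of a gene in 0-based half-open contig coordinates.
five_prime_flank <- function(gene, flank_bp) {
  if (gene$strand == "+") {
    c(max(0L, gene$cds_start - flank_bp), gene$cds_start)
  } else {
    c(gene$cds_end, gene$cds_end + flank_bp)
  }
}

overlaps_any <- function(window, intervals, contig) {
  same <- intervals$contig == contig
  any(same & intervals$start < window[2] & intervals$end > window[1])
}

#' Find MITE insertion polymorphism candidates between two species
#'
#' Syntenic blocks are maximal runs of at least `min_block` ortholog
#' pairs in collinear order (consistent direction) on both genomes.
#' Within a block, a candidate is emitted when a MITE lies in the
#' 5'-flank of the species-A gene while no MITE intersects the
#' homologous species-B flank.
#'
#' @param orthologs data.frame with columns `a`, `b` (gene ids, e.g.
#'   from [reciprocal_best_hits()]).
#' @param genes_a,genes_b gene models for the two species.
#' @param mites_a,mites_b element tables (`contig`, `start`, `end`).
#' @param flank_bp 5'-flank size (bp).
#' @param min_block minimum ortholog pairs per syntenic block.
#' @return data.frame of candidates: gene pair, both flank regions and
#'   the number of collinear neighbors in the supporting block.
#' @export
find_mip_candidates <- function(orthologs, genes_a, genes_b,
                                mites_a, mites_b, flank_bp = 300L,
                                min_block = 3L) {
  ga <- genes_a[match(orthologs$a, genes_a$gene_id), , drop = FALSE]
  gb <- genes_b[match(orthologs$b, genes_b$gene_id), , drop = FALSE]
  ok <- !is.na(ga$gene_id) & !is.na(gb$gene_id)
  ga <- ga[ok, , drop = FALSE]; gb <- gb[ok, , drop = FALSE]
  if (nrow(ga) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      contig_a = character(0), flank_start_a = integer(0),
                      flank_end_a = integer(0), contig_b = character(0),
                      flank_start_b = integer(0), flank_end_b = integer(0),
                      collinear_neighbors = integer(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(ga$contig, ga$cds_start)
  ga <- ga[ord, , drop = FALSE]; gb <- gb[ord, , drop = FALSE]
  # rank of each B partner along its own genome
  rank_b <- order(order(gb$contig, gb$cds_start))
  m <- nrow(ga)
  block_id <- integer(m)
  cur <- 1L
  block_id[1] <- cur
  if (m > 1L) {
    for (k in 2:m) {
      contiguous <- ga$contig[k] == ga$contig[k - 1L] &&
        gb$contig[k] == gb$contig[k - 1L] &&
        abs(rank_b[k] - rank_b[k - 1L]) == 1L
      if (contiguous && k > 2L && block_id[k - 2L] == cur &&
          ga$contig[k - 2L] == ga$contig[k - 1L]) {
        # direction within the block must stay consistent
        prev_dir <- sign(rank_b[k - 1L] - rank_b[k - 2L])
        contiguous <- sign(rank_b[k] - rank_b[k - 1L]) == prev_dir
      }
      if (!contiguous) cur <- cur + 1L
      block_id[k] <- cur
    }
  }
  out <- list()
  for (blk in unique(block_id)) {
    idx <- which(block_id == blk)
    if (length(idx) < min_block) next
    for (k in idx) {
      fa <- five_prime_flank(ga[k, ], flank_bp)
      fb <- five_prime_flank(gb[k, ], flank_bp)
      if (overlaps_any(fa, mites_a, ga$contig[k]) &&
          !overlaps_any(fb, mites_b, gb$contig[k])) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = ga$gene_id[k], gene_b = gb$gene_id[k],
          contig_a = ga$contig[k], flank_start_a = fa[1],
          flank_end_a = fa[2], contig_b = gb$contig[k],
          flank_start_b = fb[1], flank_end_b = fb[2],
          collinear_neighbors = length(idx) - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      contig_a = character(0), flank_start_a = integer(0),
                      flank_end_a = integer(0), contig_b = character(0),
                      flank_start_b = integer(0), flank_end_b = integer(0),
                      collinear_neighbors = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
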