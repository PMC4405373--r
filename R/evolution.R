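# Family history: Kimura two-parameter distances, divergence
# histograms with amplification-burst peaks, identical-copy grouping
# and neighbor-joining trees.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Align two sequences and summarise substitution proportions
#'
#' Aligns globally with free end gaps and affine gap costs (first gap
#' -4, each extension -1), then computes the transition proportion
#' `P`, transversion proportion `Q` and the number of comparable
#' sites under pairwise deletion (columns containing a gap or `N` are
#' excluded).
#'
#' @param a,b DNA strings.
#' @return list of class `aligned_pair`: `P`, `Q`, `comparable_sites`,
#'   plus the two gapped aligned strings.
#' @export
align_pair <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- aln_pairs(c(a, b), 1L, 2L, gap_open = 3, gap_ext = 1,
                   strings = TRUE)
  aligned_pair_stats(aln$a_aln, aln$b_aln)
}

#' Substitution proportions from two pre-aligned sequences
#'
#' @param a_aln,b_aln equal-length gapped strings (`-` for gaps).
#' @return list of class `aligned_pair` (see [align_pair()]).
#' @export
aligned_pair_stats <- function(a_aln, b_aln) {
  stopifnot(nchar(a_aln) == nchar(b_aln))
  x <- strsplit(a_aln, "")[[1]]
  y <- strsplit(b_aln, "")[[1]]
  usable <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[usable]; y <- y[usable]
  n <- length(x)
  diff <- x != y
  transition <- diff & ((x %in% PURINES & y %in% PURINES) |
                          (x %in% PYRIMIDINES & y %in% PYRIMIDINES))
  structure(list(P = if (n > 0) sum(transition) / n else NA_real_,
                 Q = if (n > 0) sum(diff & !transition) / n else NA_real_,
                 comparable_sites = n,
                 a_aln = a_aln, b_aln = b_aln),
            class = "aligned_pair")
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` the
#' transition and `Q` the transversion proportion.  Saturated pairs
#' (log domain violated) return `NA` with a warning and carry the
#' attribute `saturated = TRUE`.
#'
#' @param pair an `aligned_pair` from [align_pair()], or the
#'   transition proportion `P` given directly.
#' @param Q transversion proportion when `pair` is numeric.
#' @return the distance (numeric scalar), `NA` if saturated.
#' @export
k2p_distance <- function(pair, Q = NULL) {
  if (inherits(pair, "aligned_pair")) {
    if (pair$comparable_sites == 0L) {
      stop("no comparable sites", call. = FALSE)
    }
    P <- pair$P
    Q <- pair$Q
  } else {
    P <- pair
    stopifnot(is.numeric(P), is.numeric(Q))
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("saturated pair: Kimura two-parameter distance undefined")
    return(structure(NA_real_, saturated = TRUE))
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix for family members
#'
#' Members are pairwise aligned (global, free end gaps) with pairwise
#' deletion of gap/N columns.  Saturated pairs are excluded from the
#' matrix (entries `NA`) and listed in the `"saturated"` attribute.
#'
#' @param seqs named character vector of member sequences (>= 2).
#' @param band alignment band width: the dynamic program is restricted
#'   to a corridor of this many columns around the diagonal (widened
#'   by each pair's length difference).  The default, 50, is exact
#'   for copies diverged by substitutions and short indels; use 0 for
#'   the unrestricted alignment.
#' @return symmetric numeric matrix of distances with `NA` for
#'   saturated pairs; attribute `saturated` is a 2-column matrix of
#'   the offending pair names.
#' @export
family_distance_matrix <- function(seqs, band = 50L) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  ids <- names(seqs) %||% sprintf("seq%d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- list()
  pairs <- t(utils::combn(n, 2L))
  res <- aln_pairs(seqs, pairs[, 1], pairs[, 2], gap_open = 3,
                   gap_ext = 1, band = band)
  pair_stats <- function(k) {
    if (res$comparable[k] == 0L) {
      return(c(NA_real_, NA_real_))
    }
    c(res$transitions[k] / res$comparable[k],
      res$transversions[k] / res$comparable[k])
  }
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    pq <- pair_stats(k)
    dij <- if (anyNA(pq)) NA_real_ else
      suppressWarnings(k2p_distance(pq[1], pq[2]))
    # a saturated or barely-overlapping banded alignment usually means
    # the homologous region lies outside the band corridor (e.g. a
    # fragment embedded off-center); retry that pair unrestricted
    retry <- band > 0 &&
      (is.na(dij) ||
         res$comparable[k] < 0.5 * min(nchar(seqs[[i]]),
                                       nchar(seqs[[j]])))
    if (retry) {
      res1 <- aln_pairs(seqs[c(i, j)], 1L, 2L, gap_open = 3,
                        gap_ext = 1, band = 0L)
      dij <- if (res1$comparable == 0L) NA_real_ else
        suppressWarnings(k2p_distance(res1$transitions / res1$comparable,
                                      res1$transversions / res1$comparable))
    }
    if (is.na(dij)) {
      warning("pair ", ids[i], " / ", ids[j],
              " is saturated; excluded from the matrix")
      sat[[length(sat) + 1L]] <- c(ids[i], ids[j])
    }
    d[i, j] <- d[j, i] <- as.numeric(dij)
  }
  if (all(is.na(d[upper.tri(d)]))) {
    stop("all pairs saturated: no usable distances", call. = FALSE)
  }
  attr(d, "saturated") <- if (length(sat) > 0) do.call(rbind, sat) else
    matrix(character(0), 0, 2)
  d
}

# Topographic prominence of local maxima in a count vector.  For each
# local maximum, walk outward on both sides recording the minimum
# until terrain higher than the peak is met; the key saddle is the
# larger of the two minima over sides that reach higher ground, and
# the prominence is height minus key saddle (full height for the
# global maximum).
peak_prominences <- function(counts) {
  n <- length(counts)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) counts[i - 1L] else -Inf
    right <- if (i < n) counts[i + 1L] else -Inf
    counts[i] > left && counts[i] >= right
  }, logical(1))
  peaks <- which(is_peak & counts > 0)
  prom <- vapply(peaks, function(i) {
    saddles <- numeric(0)
    for (dir in c(-1L, 1L)) {
      j <- i + dir
      m <- Inf
      found_higher <- FALSE
      while (j >= 1L && j <= n) {
        if (counts[j] > counts[i]) { found_higher <- TRUE; break }
        m <- min(m, counts[j])
        j <- j + dir
      }
      if (found_higher) saddles <- c(saddles, m)
    }
    if (length(saddles) == 0) counts[i] else counts[i] - max(saddles)
  }, numeric(1))
  data.frame(index = peaks, height = counts[peaks], prominence = prom)
}

#' Divergence histogram with amplification-burst peaks
#'
#' Bins the upper-triangle pairwise distances of a family and detects
#' peaks: local maxima whose topographic prominence is at least
#' `prominence_frac` of the total pair count.  Each peak is read as
#' one round of amplification.
#'
#' @param d distance matrix from [family_distance_matrix()] (or a
#'   numeric vector of pairwise distances).
#' @param bin_width histogram bin width (default 0.02).
#' @param prominence_frac minimum prominence as a fraction of total
#'   pairs (default 0.10).
#' @return object of class `burst_profile`: `bin_edges`, `counts`,
#'   `peaks` (data.frame with bin `center` and `prominence`).
#' @export
burst_histogram <- function(d, bin_width = 0.02, prominence_frac = 0.10) {
  vals <- if (is.matrix(d)) d[upper.tri(d)] else as.numeric(d)
  vals <- vals[!is.na(vals)]
  stopifnot(length(vals) > 0, all(vals >= 0))
  nbins <- max(1L, ceiling((max(vals) + 1e-9) / bin_width))
  edges <- seq(0, nbins * bin_width, by = bin_width)
  idx <- pmin(nbins, floor(vals / bin_width) + 1L)
  counts <- tabulate(idx, nbins)
  pk <- peak_prominences(counts)
  pk <- pk[pk$prominence >= prominence_frac * length(vals), , drop = FALSE]
  structure(list(bin_edges = edges, counts = counts,
                 peaks = data.frame(
                   center = (pk$index - 0.5) * bin_width,
                   prominence = pk$prominence)),
            class = "burst_profile")
}

#' @export
print.burst_profile <- function(x, ...) {
  cat(sprintf("divergence histogram: %d pairs in %d bins of %.3g; %d peak(s)",
              sum(x$counts), length(x$counts),
              x$bin_edges[2] - x$bin_edges[1], nrow(x$peaks)), "\n")
  if (nrow(x$peaks) > 0) {
    cat(sprintf("  peak at %.3f (prominence %g)\n",
                x$peaks$center, x$peaks$prominence), sep = "")
  }
  invisible(x)
}

#' Group sequences by exact identity
#'
#' Partitions a sequence set into groups of 100\% identical members,
#' ordered by decreasing size and then first occurrence.
#'
#' @param seqs named character vector.
#' @return list of character vectors of member ids.
#' @export
identity_groups <- function(seqs) {
  stopifnot(length(seqs) > 0)
  ids <- names(seqs) %||% sprintf("seq%d", seq_along(seqs))
  groups <- split(ids, factor(seqs, levels = unique(seqs)))
  ord <- order(-lengths(groups), vapply(groups, function(g)
    match(g[1], ids), integer(1)))
  unname(groups[ord])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining with deterministic
#' tie-breaking (lowest index pair wins).  Negative branch lengths
#' are clamped to zero with the deficit moved to the sister edge.
#'
#' @param d symmetric distance matrix with finite entries.
#' @return a `phylo` tree (see the ape package).
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  if (any(is.na(d)) || any(!is.finite(d))) {
    stop("distance matrix must be finite", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(d) %||% sprintf("t%d", seq_len(nrow(d)))
  labels <- gsub("[,():; \t]", "_", labels)
  nodes <- as.list(labels) # newick fragment per active node
  dm <- d
  n <- nrow(dm)
  while (n > 3L) {
    r <- rowSums(dm)
    q <- (n - 2) * dm - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- dm[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dm[i, j] - li
    if (li < 0) { lj <- dm[i, j]; li <- 0 }
    if (lj < 0) { li <- dm[i, j]; lj <- 0 }
    newd <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], li,
                      nodes[[j]], lj)
    keep <- setdiff(seq_len(n), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    nodes <- c(nodes[keep], merged)
    n <- n - 1L
  }
  newick <- if (n == 2L) {
    half <- dm[1, 2] / 2
    sprintf("(%s:%.10g,%s:%.10g);", nodes[[1]], half, nodes[[2]], half)
  } else {
    la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
    lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
    lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
    lens <- pmax(c(la, lb, lc), 0)
    sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
            nodes[[1]], lens[1], nodes[[2]], lens[2], nodes[[3]], lens[3])
  }
  ape::read.tree(text = newick)
}
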