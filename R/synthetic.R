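# Synthetic genomes with planted MITE families.
#
# The generator emulates the statistical structure the analysis
# assumes: small AT-rich genomes, element families with a defined TSD
# and TIR, copy bursts at one or more divergence levels, degraded
# remnant copies, CDS annotations and terminal-biased small-RNA reads.
# Every planted copy is recorded in a ground-truth table so recall can
# be measured exactly.
#
# Burst model.  A family descends from a founder element through a
# master lineage.  Each divergence level l_k represents one
# amplification episode of age proportional to l_k: the episode
# ancestor sits at distance l_k / 2 from the founder along the master
# lineage, and every copy of the episode accumulates its own l_k / 2
# (plus a small per-copy "within-burst" term) after insertion.  A
# copy's distance to the founder is therefore l_k in expectation,
# while the distance between two copies from episodes k and l is
# max(l_k, l_l): all pairs involving an episode collapse onto that
# episode's level, so a family simulated with k levels shows exactly
# k modes in its pairwise-distance histogram, located at the levels
# themselves -- the signature amplification-burst detection is meant
# to recover.
#
# Mutations are substitutions only, with a 2:1 transition:transversion
# ratio, so a requested Kimura two-parameter (K2P) distance maps to a
# per-site substitution probability analytically.  Substitutions are
# confined to the internal region (TIRs and TSDs stay intact on
# non-remnant copies) and the per-site rate is scaled up so that the
# distance over the whole element body hits the requested level.

#' Specify a synthetic MITE family
#'
#' @param name family label used in truth records.
#' @param tsd either the literal string `"TA"` (a fixed dinucleotide
#'   TSD, as in Stowaway-like elements) or an integer TSD length
#'   (2-20); length-specified TSDs are drawn independently per copy,
#'   mimicking duplication of the host target site.
#' @param tir terminal inverted repeat: a DNA string (5-60 bp) or an
#'   integer length to be drawn randomly when the genome is built.
#' @param internal_length length of the internal region (bp).
#' @param copy_number total planted copies.
#' @param divergence_levels list of `c(distance, fraction)` pairs: the
#'   K2P distance of each amplification episode from the founder and
#'   the fraction of copies it contributes.  Fractions must sum to 1.
#' @param remnant_fraction fraction of copies planted as truncated
#'   remnants (one terminus lost, 40-95\% of the body retained, no
#'   TSD).
#' @param within_burst per-copy K2P divergence from the episode
#'   ancestor (default 0.005).
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(name, tsd = "TA", tir = 15L,
                        internal_length = 200L, copy_number = 10L,
                        divergence_levels = list(c(0.02, 1)),
                        remnant_fraction = 0,
                        within_burst = 0.005) {
  stopifnot(is.character(name), nzchar(name))
  if (is.character(tsd)) {
    assert_dna(tsd, "tsd")
    stopifnot(nchar(tsd) >= 2L, nchar(tsd) <= 20L)
  } else {
    tsd <- as.integer(tsd)
    stopifnot(tsd >= 2L, tsd <= 20L)
  }
  if (is.character(tir)) {
    assert_dna(tir, "tir")
    tir_len <- nchar(tir)
  } else {
    tir_len <- as.integer(tir)
    tir <- tir_len
  }
  stopifnot(tir_len >= 5L, tir_len <= 60L)
  internal_length <- as.integer(internal_length)
  stopifnot(internal_length >= 10L)
  if (2L * tir_len + internal_length >= 1500L) {
    stop("total element length (2*TIR + internal) must be < 1500 bp",
         call. = FALSE)
  }
  if (is.matrix(divergence_levels)) {
    divergence_levels <- lapply(seq_len(nrow(divergence_levels)),
                                function(i) divergence_levels[i, ])
  }
  lev <- vapply(divergence_levels, function(x) x[1], numeric(1))
  frac <- vapply(divergence_levels, function(x) x[2], numeric(1))
  stopifnot(all(lev >= 0), all(frac > 0))
  if (abs(sum(frac) - 1) > 1e-8) {
    stop("divergence level fractions must sum to 1", call. = FALSE)
  }
  ord <- order(lev)
  stopifnot(remnant_fraction >= 0, remnant_fraction < 1,
            within_burst >= 0, within_burst < 0.1)
  structure(list(name = name, tsd = tsd, tir = tir,
                 internal_length = internal_length,
                 copy_number = as.integer(copy_number),
                 levels = lev[ord], fractions = frac[ord],
                 remnant_fraction = remnant_fraction,
                 within_burst = within_burst),
            class = "family_spec")
}

# Per-site substitution probability m such that a single round of
# substitutions applied to `n_mut` of `n_total` sites yields, in
# expectation, a K2P distance of `d` over all n_total sites.  With a
# 2:1 ts:tv ratio the expected observed proportions after one round
# are P = (2/3) m rho and Q = (1/3) m rho, rho = n_mut / n_total.
solve_subst_prob <- function(d, n_mut, n_total) {
  if (d <= 0) return(0)
  rho <- n_mut / n_total
  k2p_of <- function(m) {
    P <- (2 / 3) * m * rho
    Q <- (1 / 3) * m * rho
    -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  }
  # log-domain bound: 1 - 2P - Q = 1 - (5/3) m rho must stay positive
  upper <- min(0.999, 0.999 * 0.6 / rho)
  if (k2p_of(upper) < d) {
    stop(sprintf("divergence target %.3f not reachable by substitutions on %d/%d sites",
                 d, n_mut, n_total), call. = FALSE)
  }
  uniroot(function(m) k2p_of(m) - d, c(0, upper), tol = 1e-10)$root
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Draw a per-copy TSD whose terminal bases do not pair with each
# other.  When the duplication's ends complement (TSD[t] with TSD[1],
# or TSD[t-1] with TSD[2]), the element's inverted repeat chains
# outward through the duplication and the element boundary becomes
# structurally ambiguous -- the palindromic TA duplication is the
# extreme case.  Length-specified TSDs avoid such draws so that
# planted coordinates stay identifiable; fixed-motif TSDs (e.g. "TA")
# are used verbatim.
draw_tsd <- function(t, at_content) {
  repeat {
    tsd <- random_dna(t, at_content)
    x <- strsplit(tsd, "")[[1]]
    c1 <- x[t] == COMPLEMENT[[x[1]]]
    c2 <- t >= 3L && x[t - 1L] == COMPLEMENT[[x[2]]]
    if (!c1 && !c2) return(tsd)
  }
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

# One round of random substitutions at per-site probability m,
# transitions twice as likely as transversions.
mutate_dna <- function(seq, m) {
  if (m <= 0 || nchar(seq) == 0L) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(x)) < m & x != "N")
  for (i in hit) {
    if (runif(1) < 2 / 3) {
      x[i] <- TRANSITION[[x[i]]]
    } else {
      x[i] <- sample(TRANSVERSIONS[[x[i]]], 1)
    }
  }
  paste(x, collapse = "")
}

# Largest-remainder apportionment of n copies to level fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic genome with planted MITE families
#'
#' The background is i.i.d. with the requested AT fraction.  Each
#' intact planted copy is `TSD + TIR + internal + revcomp(TIR) + TSD`
#' with substitutions confined to the internal region; remnant copies
#' lose one terminus (including the TSD).  Planting replaces
#' background slices, so the genome length is exactly `length`.
#'
#' @param length total genome length (bp).
#' @param at_content background AT fraction, in `[0.4, 0.85]`.
#' @param family_specs list of [family_spec()] objects.
#' @param seed integer seed; identical seeds give identical output.
#' @param n_contigs number of contigs (length split evenly).
#' @param min_gap minimum spacing between planted copies (bp).
#' @return list with components `genome` (named character vector),
#'   `truth` (data.frame: family, contig, start, end, intact, level,
#'   tsd -- body coordinates, 0-based half-open, TSD excluded) and
#'   `founders` (named character vector of founder element bodies).
#' @export
generate_genome <- function(length, at_content, family_specs, seed,
                            n_contigs = 1L, min_gap = 30L) {
  stopifnot(at_content >= 0.4, at_content <= 0.85, length > 0)
  if (inherits(family_specs, "family_spec")) family_specs <- list(family_specs)
  stopifnot(all(vapply(family_specs, inherits, logical(1), "family_spec")))
  set.seed(seed)
  contig_len <- rep(length %/% n_contigs, n_contigs)
  contig_len[n_contigs] <- contig_len[n_contigs] + length %% n_contigs
  genome <- stats::setNames(
    vapply(contig_len, random_dna, character(1), at_content = at_content),
    sprintf("contig_%d", seq_len(n_contigs)))

  founders <- character(0)
  truth <- list()
  occupied <- lapply(contig_len, function(x) cbind(start = integer(0),
                                                   end = integer(0)))

  place <- function(width) {
    # returns c(contig index, start) for a free slot, or errors
    for (try in seq_len(5000L)) {
      ci <- sample.int(length(contig_len), 1, prob = contig_len)
      if (contig_len[ci] < width + 2L) next
      st <- sample.int(contig_len[ci] - width - 1L, 1)
      occ <- occupied[[ci]]
      if (nrow(occ) == 0L ||
          all(st + width + min_gap <= occ[, 1] | st >= occ[, 2] + min_gap)) {
        occupied[[ci]] <<- rbind(occ, c(st, st + width))
        return(c(ci, st))
      }
    }
    stop("requested copies do not fit in the genome", call. = FALSE)
  }

  for (spec in family_specs) {
    tir <- if (is.character(spec$tir)) spec$tir else
      random_dna(spec$tir, at_content)
    internal0 <- random_dna(spec$internal_length, at_content)
    body_len <- 2L * nchar(tir) + spec$internal_length
    founder <- paste0(tir, internal0, revcomp(tir))
    founders[spec$name] <- founder

    counts <- apportion(spec$copy_number, spec$fractions)
    n_remnant <- round(spec$remnant_fraction * spec$copy_number)
    remnant_idx <- if (n_remnant > 0)
      sample.int(spec$copy_number, n_remnant) else integer(0)

    # episode ancestors along the master lineage, at half the level
    # distance from the founder; each copy then accumulates the other
    # half plus the within-burst term
    anc_internal <- internal0
    prev_level <- 0
    copy_no <- 0L
    for (k in seq_along(spec$levels)) {
      inc <- (spec$levels[k] - prev_level) / 2
      if (inc > 0) {
        m <- solve_subst_prob(inc, spec$internal_length, body_len)
        anc_internal <- mutate_dna(anc_internal, m)
      }
      prev_level <- spec$levels[k]
      m_wb <- solve_subst_prob(spec$levels[k] / 2 + spec$within_burst,
                               spec$internal_length, body_len)
      for (j in seq_len(counts[k])) {
        copy_no <- copy_no + 1L
        internal_j <- mutate_dna(anc_internal, m_wb)
        body <- paste0(tir, internal_j, revcomp(tir))
        if (copy_no %in% remnant_idx) {
          keep <- runif(1, 0.4, 0.95)
          keep_len <- max(10L, round(keep * body_len))
          body_part <- if (runif(1) < 0.5)
            substring(body, 1L, keep_len)
          else
            substring(body, nchar(body) - keep_len + 1L, nchar(body))
          slot <- place(nchar(body_part))
          ci <- slot[1]; st <- slot[2]
          substr(genome[ci], st + 1L, st + nchar(body_part)) <- body_part
          truth[[length(truth) + 1L]] <- data.frame(
            family = spec$name, contig = names(genome)[ci],
            start = st, end = st + nchar(body_part),
            intact = FALSE, level = spec$levels[k], tsd = NA_character_,
            stringsAsFactors = FALSE)
        } else {
          tsd <- if (is.character(spec$tsd)) spec$tsd else
            draw_tsd(spec$tsd, at_content)
          insert <- paste0(tsd, body, tsd)
          slot <- place(nchar(insert))
          ci <- slot[1]; st <- slot[2]
          substr(genome[ci], st + 1L, st + nchar(insert)) <- insert
          truth[[length(truth) + 1L]] <- data.frame(
            family = spec$name, contig = names(genome)[ci],
            start = st + nchar(tsd), end = st + nchar(tsd) + nchar(body),
            intact = TRUE, level = spec$levels[k], tsd = tsd,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(family = character(0), contig = character(0),
               start = integer(0), end = integer(0), intact = logical(0),
               level = numeric(0), tsd = character(0),
               stringsAsFactors = FALSE)
  list(genome = genome, truth = truth, founders = founders)
}

#' Generate non-overlapping CDS annotations on a synthetic genome
#'
#' @param genome named character vector of contigs.
#' @param n_genes number of genes to place.
#' @param mean_cds_len mean CDS length (bp); lengths are log-normal
#'   around this mean, rounded to codons, minimum 150 bp.
#' @param seed integer seed.
#' @param truth optional truth table from [generate_genome()]; when
#'   given, each gene is tagged with whether a planted element lies
#'   within `flank_bp` of its CDS.
#' @param flank_bp flank used for the tag (default 300).
#' @return data.frame of gene models (`gene_id`, `contig`, `strand`,
#'   `cds_start`, `cds_end`, and `mite_within_flank` when `truth` is
#'   supplied).
#' @export
generate_gene_annotations <- function(genome, n_genes, mean_cds_len = 500L,
                                      seed = 1L, truth = NULL,
                                      flank_bp = 300L) {
  check_genome(genome)
  if (length(genome) == 0L || all(nchar(genome) == 0L)) {
    stop("empty genome", call. = FALSE)
  }
  set.seed(seed)
  contig_len <- nchar(genome)
  occupied <- lapply(seq_along(genome), function(i) cbind(integer(0),
                                                          integer(0)))
  lens <- pmax(150L, as.integer(round(mean_cds_len *
                                        exp(rnorm(n_genes, 0, 0.25)))))
  lens <- (lens %/% 3L) * 3L
  genes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      ci <- sample.int(length(genome), 1, prob = contig_len)
      if (contig_len[ci] <= lens[i] + 2L) next
      st <- sample.int(contig_len[ci] - lens[i] - 1L, 1)
      occ <- occupied[[ci]]
      if (nrow(occ) == 0L ||
          all(st + lens[i] <= occ[, 1] | st >= occ[, 2])) {
        occupied[[ci]] <- rbind(occ, c(st, st + lens[i]))
        genes[[i]] <- data.frame(gene_id = sprintf("g%04d", i),
                                 contig = names(genome)[ci],
                                 strand = sample(c("+", "-"), 1),
                                 cds_start = st, cds_end = st + lens[i],
                                 stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("genes do not fit in the genome", call. = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes <- genes[order(genes$contig, genes$cds_start), , drop = FALSE]
  rownames(genes) <- NULL
  if (!is.null(truth)) {
    genes$mite_within_flank <- vapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      same <- truth$contig == g$contig
      any(same &
            truth$start < g$cds_end + flank_bp &
            truth$end > g$cds_start - flank_bp)
    }, logical(1))
  }
  genes
}

default_length_weights <- function(lengths) {
  w <- stats::dnorm(lengths, mean = 24.4, sd = 2.0)
  w / sum(w)
}

#' Generate small-RNA reads from family consensus sequences
#'
#' Read lengths follow a unimodal distribution peaked at 24-25 nt;
#' start positions are biased toward the element termini: a fraction
#' `terminal_bias` of reads starts inside the outer 20\% of the
#' consensus (either end), the rest uniformly.  Strand is drawn
#' 50/50; the stored truth keeps the generating family, start and
#' strand.
#'
#' @param consensi named character vector of consensus sequences.
#' @param n_reads number of reads.
#' @param terminal_bias fraction of reads drawn from terminal windows.
#' @param length_range integer range of read lengths (within 16-30).
#' @param seed integer seed.
#' @param length_weights optional weights over `length_range`.
#' @return data.frame: `read_id`, `sequence`, `length`, `family`,
#'   `start` (0-based on the consensus), `strand`.
#' @export
generate_small_rna_reads <- function(consensi, n_reads,
                                     terminal_bias = 0.7,
                                     length_range = c(18L, 29L),
                                     seed = 1L, length_weights = NULL) {
  check_genome(consensi)
  stopifnot(length_range[1] >= 16L, length_range[2] <= 30L,
            length_range[1] <= length_range[2],
            terminal_bias >= 0, terminal_bias <= 1)
  lens <- seq(length_range[1], length_range[2])
  maxlen <- max(lens)
  short <- nchar(consensi) <= maxlen
  if (any(short)) {
    stop(sprintf("consensus '%s' is shorter than the maximum read length",
                 names(consensi)[short][1]), call. = FALSE)
  }
  set.seed(seed)
  w <- length_weights %||% default_length_weights(lens)
  fam <- sample(names(consensi), n_reads, replace = TRUE)
  rlen <- sample(lens, n_reads, replace = TRUE, prob = w)
  strand <- sample(c("sense", "antisense"), n_reads, replace = TRUE)
  terminal <- runif(n_reads) < terminal_bias
  start <- integer(n_reads)
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    L <- nchar(consensi[[fam[i]]])
    last <- L - rlen[i]
    if (terminal[i]) {
      wlen <- max(1L, as.integer(floor(0.2 * L)))
      left <- seq(0L, min(wlen - 1L, last))
      right <- seq(max(0L, last - wlen + 1L), last)
      start[i] <- sample(c(left, right), 1)
    } else {
      start[i] <- sample(seq(0L, last), 1)
    }
    s <- slice_seq(consensi[[fam[i]]], start[i], start[i] + rlen[i])
    seqs[i] <- if (strand[i] == "sense") s else revcomp(s)
  }
  data.frame(read_id = sprintf("r%06d", seq_len(n_reads)),
             sequence = seqs, length = rlen, family = fam,
             start = start, strand = strand, stringsAsFactors = FALSE)
}
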