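# Shared fixtures and independent mini-oracles used across the suite.

# Random DNA with an AT-rich composition, independent of the package's
# internal generator.
fixture_dna <- function(n, at = 0.65) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Reverse complement written independently of the package helper.
fixture_rc <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Substitute exactly k positions of a sequence (guaranteed changes),
# used to construct pairs with exact identity values.
fixture_substitute <- function(seq, positions) {
  x <- strsplit(seq, "")[[1]]
  for (i in positions) {
    x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[sample.int(3, 1)]
  }
  paste(x, collapse = "")
}

# Independent linear-gap free-end-gap alignment score (match +1,
# mismatch -1, gap -2), the brute-force oracle for pairwise_identity.
fixture_dp_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (A[i] == B[j] && A[i] != "N") 1 else -1
      H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] - 2, H[i + 1, j] - 2)
    }
  }
  max(H[m + 1, ], H[, n + 1])
}

# Element planted in an AC-repeat background: the AC alphabet contains
# no Watson-Crick pair, so the background can form direct repeats but
# never inverted repeats, making the planted candidate the only
# TIR-bearing locus and its coordinates unambiguous.
fixture_planted_genome <- function(tsd = "TA", tir = "ACGGTTCAGACCTGAATGCA",
                                   internal = NULL, flank = 400L,
                                   seed = 1L) {
  set.seed(seed)
  if (is.null(internal)) internal <- fixture_dna(150)
  ac <- function(n) paste(rep(c("A", "C"), length.out = n), collapse = "")
  body <- paste0(tir, internal, fixture_rc(tir))
  genome <- c(chr = paste0(ac(flank), tsd, body, tsd, ac(flank)))
  list(genome = genome,
       start = flank + nchar(tsd),
       end = flank + nchar(tsd) + nchar(body),
       body = body, tsd = tsd, tir = tir)
}

# Study conditions for the planted-family recovery experiment: five
# families spanning the superfamily spectrum, 20 copies each, half
# undiverged and half at divergence 0.05, 10% remnants, copies spaced
# more than an element length apart so inter-copy artifacts cannot
# shadow other insertions.
recovery_specs <- function() {
  list(
    family_spec("hat", tsd = 8L, tir = 16L, internal_length = 220L,
                copy_number = 20L,
                divergence_levels = list(c(0, 0.5), c(0.05, 0.5)),
                remnant_fraction = 0.1),
    family_spec("merlin", tsd = 8L, tir = 28L, internal_length = 320L,
                copy_number = 20L,
                divergence_levels = list(c(0, 0.5), c(0.05, 0.5)),
                remnant_fraction = 0.1),
    family_spec("mutator", tsd = 10L, tir = 20L, internal_length = 260L,
                copy_number = 20L,
                divergence_levels = list(c(0, 0.5), c(0.05, 0.5)),
                remnant_fraction = 0.1),
    family_spec("tourist", tsd = 3L, tir = 22L, internal_length = 180L,
                copy_number = 20L,
                divergence_levels = list(c(0, 0.5), c(0.05, 0.5)),
                remnant_fraction = 0.1),
    family_spec("novel_tgt", tsd = 5L,
                tir = "TGTACGTTGGCAAGTCCTAGG", internal_length = 400L,
                copy_number = 20L,
                divergence_levels = list(c(0, 0.5), c(0.05, 0.5)),
                remnant_fraction = 0.1))
}

# Simulate one family's copies and return their sequences, for
# divergence/burst experiments.
simulate_family_copies <- function(levels, fractions, n_copies, seed,
                                   internal = 1200L, tir = 25L,
                                   tsd = 8L) {
  spec <- family_spec("fam", tsd = tsd, tir = tir,
                      internal_length = internal,
                      copy_number = n_copies,
                      divergence_levels = Map(c, levels, fractions))
  sim <- generate_genome(as.integer(n_copies * (internal + 150) * 2.2),
                         0.65, list(spec), seed = seed, min_gap = 60L)
  tr <- sim$truth
  seqs <- substring(sim$genome[tr$contig], tr$start + 1L, tr$end)
  names(seqs) <- sprintf("c%03d", seq_along(seqs))
  list(seqs = seqs, truth = tr, founder = sim$founders[[1]])
}
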