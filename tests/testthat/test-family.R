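test_that("pairwise identity handles the forced cases", {
  set.seed(1)
  a <- fixture_dna(100)
  expect_equal(pairwise_identity(a, a),
               list(identity = 1, coverage = 1, score = 100))
  b <- fixture_substitute(a, sample(10:90, 5))
  expect_equal(pairwise_identity(a, b)$identity, 0.95)
  # symmetry
  c2 <- fixture_dna(80)
  expect_equal(pairwise_identity(a, c2)$identity,
               pairwise_identity(c2, a)$identity)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("alignment scores equal the independent dynamic-programming oracle", {
  set.seed(2)
  for (r in 1:25) {
    a <- fixture_dna(sample(40:200, 1))
    b <- if (r %% 2 == 0) {
      fixture_dna(sample(40:200, 1))
    } else {
      # a mutated, possibly deleted copy
      x <- fixture_substitute(a, sample(nchar(a), 8))
      if (r %% 4 == 1) {
        ch <- strsplit(x, "")[[1]]
        x <- paste(ch[-sample(length(ch), 5)], collapse = "")
      }
      x
    }
    expect_equal(pairwise_identity(a, b)$score, fixture_dp_score(a, b))
  }
})

test_that("alignment scores also match the Biostrings aligner", {
  submat <- matrix(-1, 5, 5,
                   dimnames = list(c("A", "C", "G", "T", "N"),
                                   c("A", "C", "G", "T", "N")))
  diag(submat) <- 1
  submat["N", "N"] <- -1
  set.seed(3)
  for (r in 1:10) {
    a <- fixture_dna(150)
    ch <- strsplit(fixture_substitute(a, sample(150, 10)), "")[[1]]
    b <- paste(ch[-sample(150, 4)], collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "overlap", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)
    expect_equal(pairwise_identity(a, b)$score, Biostrings::score(ref))
  }
})

test_that("single-linkage clustering groups and discards as specified", {
  set.seed(4)
  base <- fixture_dna(200)
  near <- vapply(1:5, function(i) fixture_substitute(base, sample(200, 4)),
                 character(1))
  names(near) <- sprintf("m%d", 1:5)
  out <- cluster_families(near, 0.90, 3L, prefilter = "none")
  expect_length(out$families, 1L)
  expect_setequal(out$families[[1]], names(near))

  # a pair below the family-size floor is discarded
  pair <- near[1:2]
  out2 <- cluster_families(pair, 0.90, 3L, prefilter = "none")
  expect_length(out2$families, 0L)
  expect_setequal(out2$discarded, names(pair))
})

test_that("single linkage joins chains whose ends fall below threshold", {
  set.seed(5)
  a <- fixture_dna(200)
  b <- fixture_substitute(a, 50:65)       # a~b 92%
  c2 <- fixture_substitute(b, 100:117)    # b~c 91%, a~c 83%
  seqs <- c(A = a, B = b, C = c2)
  expect_lt(pairwise_identity(a, c2)$identity, 0.90)
  expect_gte(pairwise_identity(a, b)$identity, 0.90)
  expect_gte(pairwise_identity(b, c2)$identity, 0.90)
  out <- cluster_families(seqs, 0.90, 3L, prefilter = "none")
  expect_length(out$families, 1L)
  expect_setequal(out$families[[1]], c("A", "B", "C"))
})

test_that("consensus building follows majority and tie rules", {
  s <- "ACGTACGTAC"
  expect_identical(build_consensus(c(s, s, s)), s)
  # column majority: A,A,G -> A
  v1 <- "AACGT"
  v2 <- "AACGT"
  v3 <- "GACGT"
  expect_identical(build_consensus(c(v1, v2, v3)), "AACGT")
  # tie A vs G -> lexicographic A
  expect_identical(build_consensus(c("AACGTACG", "GACGTACG")), "AACGTACG")
})

test_that("remnant mining applies identity and coverage filters", {
  set.seed(6)
  spec <- family_spec("f", tsd = 8L, tir = 20L, internal_length = 260L,
                      copy_number = 10L,
                      divergence_levels = list(c(0.04, 1)),
                      within_burst = 0)
  sim <- generate_genome(120000, 0.62, list(spec), seed = 21,
                         min_gap = 1600L)
  founder <- sim$founders[[1]]
  body_len <- nchar(founder)
  # plant one truncated copy above both thresholds (85% of the body)
  # and one below the coverage threshold (60%) on a separate contig of
  # AC-repeat filler (no inverted-repeat structure of its own)
  keep85 <- substring(founder, 1, round(0.85 * body_len))
  keep60 <- substring(founder, round(0.4 * body_len), body_len)
  ac <- function(n) paste(rep(c("A", "C"), length.out = n), collapse = "")
  pos1 <- 300L
  pos2 <- pos1 + nchar(keep85) + 500L
  genome <- c(sim$genome,
              frags = paste0(ac(300), keep85, ac(500), keep60, ac(300)))
  hits <- mine_remnants(founder, genome)
  hits_frag <- hits[hits$contig == "frags", ]
  hits <- hits
  # the 85% fragment is reported, the 60% fragment is not
  expect_true(any(abs(hits_frag$start - pos1) <= 5))
  expect_false(any(abs(hits_frag$start - pos2) <= 5))
  # 10 planted intact + 1 passing fragment, intactness flagged
  expect_identical(nrow(hits), 11L)
  expect_identical(sum(hits$intact), 10L)
  frag <- hits_frag[abs(hits_frag$start - pos1) <= 5, ]
  expect_false(frag$intact)
  expect_gte(frag$coverage, 0.80)
  expect_gte(frag$identity, 0.90)
})

test_that("superfamily classification follows the TSD/TIR key", {
  expect_identical(classify_superfamily("TA", 12)$superfamily,
                   "Stowaway-like")
  expect_identical(classify_superfamily("TAA", 8)$superfamily,
                   "Tourist-like")
  expect_identical(classify_superfamily(8L, 28)$superfamily,
                   "Merlin-like")
  expect_identical(classify_superfamily(8L, 12)$superfamily,
                   "hAT-like")
  expect_identical(classify_superfamily(10L, 5)$superfamily,
                   "Mutator-like")
  novel <- classify_superfamily(5L, 10, "TGTAAGGTCA")
  expect_identical(novel$superfamily, "Unknown")
  expect_true(novel$tgt_start)
  expect_false(classify_superfamily(8L, 12, "TGTAA")$tgt_start)
  expect_identical(classify_superfamily(4L, 12)$superfamily, "Unknown")
  # TA written as a length (not the literal motif) is not Stowaway
  expect_identical(classify_superfamily(2L, 12)$superfamily, "Unknown")
})

test_that("family naming uses species letter, superfamily code and size order", {
  mk <- function(sf, n) {
    members <- data.frame(contig = "c", start = seq_len(n) * 1000L,
                          end = seq_len(n) * 1000L + 150L, intact = TRUE)
    f <- list(members = members, superfamily = sf, consensus = "ACGT",
              tsd_pattern = "TA", tir_length = 10L, tgt_start = FALSE)
    class(f) <- "mite_family"
    f
  }
  fams <- list(mk("hAT-like", 20), mk("Stowaway-like", 7),
               mk("hAT-like", 40), mk("Unknown", 4))
  named <- name_families(fams, "b")
  expect_identical(names(named)[2], "NbS1")
  expect_identical(names(named)[4], "NbN1")
  # larger hAT family takes number 1
  expect_identical(named[["Nbh1"]]$members$start,
                   mk("hAT-like", 40)$members$start)
  expect_identical(nrow(named[["Nbh2"]]$members), 20L)
})
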