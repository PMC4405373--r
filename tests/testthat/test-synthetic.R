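test_that("genome generation is deterministic and truth-complete", {
  specs <- list(family_spec("f1", tsd = 8L, tir = 18L,
                            internal_length = 150L, copy_number = 8L,
                            divergence_levels = list(c(0, 1))),
                family_spec("f2", tsd = "TA", tir = 15L,
                            internal_length = 120L, copy_number = 5L))
  a <- generate_genome(60000, 0.65, specs, seed = 42)
  b <- generate_genome(60000, 0.65, specs, seed = 42)
  expect_identical(a, b)
  expect_identical(nrow(a$truth), 13L)
  expect_identical(sum(nchar(a$genome)), 60000L)

  c2 <- generate_genome(60000, 0.65, specs, seed = 43)
  expect_false(identical(a$genome, c2$genome))
})

test_that("background AT content matches the request", {
  g <- generate_genome(200000, 0.75, list(), seed = 7)$genome
  at <- nchar(gsub("[^AT]", "", g)) / nchar(g)
  # binomial concentration: SE ~ 0.001 at this length
  expect_lt(abs(at - 0.75), 0.01)
})

test_that("undiverged planted copies contain the TIR and its reverse complement", {
  tir <- "ACGGTTCAGACCTGAA"
  spec <- family_spec("f", tsd = 8L, tir = tir, internal_length = 100L,
                      copy_number = 10L,
                      divergence_levels = list(c(0, 1)),
                      within_burst = 0)
  sim <- generate_genome(50000, 0.6, list(spec), seed = 3)
  expect_identical(nrow(sim$truth), 10L)
  for (i in seq_len(10)) {
    body <- substring(sim$genome[[sim$truth$contig[i]]],
                      sim$truth$start[i] + 1L, sim$truth$end[i])
    expect_identical(substring(body, 1, nchar(tir)), tir)
    expect_identical(substring(body, nchar(body) - nchar(tir) + 1),
                     fixture_rc(tir))
    # identical flanking TSD copies
    tsd <- sim$truth$tsd[i]
    left <- substring(sim$genome[[sim$truth$contig[i]]],
                      sim$truth$start[i] - nchar(tsd) + 1L,
                      sim$truth$start[i])
    right <- substring(sim$genome[[sim$truth$contig[i]]],
                       sim$truth$end[i] + 1L,
                       sim$truth$end[i] + nchar(tsd))
    expect_identical(left, tsd)
    expect_identical(right, tsd)
  }
})

test_that("per-copy divergence to the founder recovers the requested levels", {
  fam <- simulate_family_copies(levels = c(0.02, 0.10),
                                fractions = c(0.5, 0.5),
                                n_copies = 30L, seed = 11,
                                internal = 900L)
  d_to_founder <- vapply(fam$seqs, function(s) {
    k2p_distance(align_pair(s, fam$founder))
  }, numeric(1))
  for (lev in c(0.02, 0.10)) {
    got <- mean(d_to_founder[fam$truth$level == lev])
    expect_lt(abs(got - lev), 0.015 + lev * 0.15)
  }
})

test_that("overfull genomes are rejected rather than silently truncated", {
  spec <- family_spec("f", tsd = 8L, tir = 20L, internal_length = 400L,
                      copy_number = 50L)
  expect_error(generate_genome(5000, 0.6, list(spec), seed = 1),
               "do not fit")
})

test_that("small-RNA reads honour terminal bias, lengths and determinism", {
  set.seed(2)
  cons <- c(f1 = fixture_dna(300), f2 = fixture_dna(250))
  reads <- generate_small_rna_reads(cons, 1000, terminal_bias = 1,
                                    seed = 5)
  expect_identical(generate_small_rna_reads(cons, 1000, terminal_bias = 1,
                                            seed = 5), reads)
  L <- nchar(cons)[reads$family]
  in_outer <- reads$start < 0.2 * L | reads$start + reads$length > 0.8 * L
  expect_true(all(in_outer))
  expect_true(all(reads$length >= 18 & reads$length <= 29))
  # multinomial mode of the default length distribution
  tab <- table(reads$length)
  expect_true(names(tab)[which.max(tab)] %in% c("24", "25"))
  # reads are substrings of the stated strand
  i <- which(reads$strand == "sense")[1]
  expect_identical(reads$sequence[i],
                   substring(cons[[reads$family[i]]], reads$start[i] + 1,
                             reads$start[i] + reads$length[i]))
  j <- which(reads$strand == "antisense")[1]
  expect_identical(fixture_rc(reads$sequence[j]),
                   substring(cons[[reads$family[j]]], reads$start[j] + 1,
                             reads$start[j] + reads$length[j]))

  expect_error(generate_small_rna_reads(c(f = "ACGTACGTACGT"), 10, 0.5),
               "shorter than the maximum read length")
})

test_that("gene annotation generation places and tags genes correctly", {
  sim <- generate_genome(200000, 0.65,
                         list(family_spec("f", tsd = 8L, tir = 18L,
                                          internal_length = 150L,
                                          copy_number = 10L)), seed = 9)
  genes <- generate_gene_annotations(sim$genome, 50L, seed = 4,
                                     truth = sim$truth, flank_bp = 300L)
  expect_identical(nrow(genes), 50L)
  # non-overlapping within each contig
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, ]
    g <- g[order(g$cds_start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$cds_start[-1] >= g$cds_end[-nrow(g)]))
    }
  }
  # tagging arithmetic: a gene 250 bp from an element is associated at
  # flank 300 but not at flank 200
  tr <- data.frame(family = "f", contig = names(sim$genome)[1],
                   start = 1000L, end = 1200L, intact = TRUE,
                   level = 0, tsd = "AA", stringsAsFactors = FALSE)
  gene <- data.frame(gene_id = "g", contig = names(sim$genome)[1],
                     strand = "+", cds_start = 1450L, cds_end = 2050L,
                     stringsAsFactors = FALSE)
  expect_true(associate_with_genes(tr, gene, 300L)$associated)
  expect_false(associate_with_genes(tr, gene, 200L)$associated)

  expect_error(generate_gene_annotations(character(0), 5L, seed = 1),
               "genome")
})
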