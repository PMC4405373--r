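test_that("K2P distance matches the closed form and its bounds", {
  expect_identical(k2p_distance(0, 0), 0)
  # direct evaluation of -1/2 log((1-2P-Q) sqrt(1-2Q))
  expect_lt(abs(k2p_distance(0.10, 0.05) - 0.17018), 1e-4)
  # correction never shrinks the raw proportion of differences
  set.seed(1)
  for (r in 1:200) {
    P <- runif(1, 0, 0.3)
    Q <- runif(1, 0, min(0.3, (1 - 2 * P) * 0.9))
    if (1 - 2 * P - Q <= 0) next
    expect_gte(k2p_distance(P, Q), P + Q - 1e-12)
  }
  expect_warning(d <- k2p_distance(0.5, 0.2), "saturated")
  expect_true(is.na(d))
})

test_that("aligned-pair statistics use pairwise deletion of gaps and Ns", {
  st <- aligned_pair_stats("ACG-TANA", "GCGCTA-A")
  # columns 4 (gap) and 7 (N/gap) are excluded -> 6 comparable sites
  expect_identical(st$comparable_sites, 6L)
  expect_equal(st$P, 1 / 6) # A<->G at column 1
  expect_equal(st$Q, 0)
  d <- k2p_distance(st)
  expect_gt(d, 0)
})

test_that("identical members give a zero distance matrix", {
  s <- fixture_dna(120)
  d <- family_distance_matrix(c(a = s, b = s, c = s))
  expect_true(all(d == 0))
  expect_identical(dim(d), c(3L, 3L))
})

test_that("star-simulated members have pairwise distance twice the radius", {
  # independent star-topology simulation: each member mutated from the
  # founder at ~0.1 expected K2P, with a 2:1 ts:tv spectrum
  set.seed(2)
  founder <- fixture_dna(2000)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  mutate_star <- function(s, m) {
    x <- strsplit(s, "")[[1]]
    hit <- which(runif(length(x)) < m)
    for (i in hit) {
      x[i] <- if (runif(1) < 2 / 3) transition[[x[i]]] else
        sample(setdiff(setdiff(c("A", "C", "G", "T"), x[i]),
                       transition[[x[i]]]), 1)
    }
    paste(x, collapse = "")
  }
  # per-site substitution probability giving K2P ~ 0.1
  members <- vapply(1:8, function(i) mutate_star(founder, 0.094),
                    character(1))
  names(members) <- sprintf("m%d", 1:8)
  d <- family_distance_matrix(members)
  expect_lt(abs(mean(d[upper.tri(d)]) - 0.2), 0.02)
})

test_that("the distance matrix equals scalar recomputation per pair", {
  fam <- simulate_family_copies(levels = c(0, 0.08),
                                fractions = c(0.5, 0.5),
                                n_copies = 8L, seed = 3,
                                internal = 300L)
  d <- family_distance_matrix(fam$seqs)
  ids <- names(fam$seqs)
  for (i in 1:(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      scalar <- k2p_distance(align_pair(fam$seqs[[i]], fam$seqs[[j]]))
      expect_equal(d[i, j], scalar)
      expect_identical(d[i, j], d[j, i])
    }
  }
})

test_that("burst histograms count pairs and find planted amplification modes", {
  # degenerate: all distances near zero -> one peak in the first bin
  h0 <- burst_histogram(rep(0.001, 45), bin_width = 0.02)
  expect_identical(nrow(h0$peaks), 1L)
  expect_equal(h0$peaks$center[1], 0.01)

  fam2 <- simulate_family_copies(levels = c(0, 0.12),
                                 fractions = c(0.5, 0.5),
                                 n_copies = 30L, seed = 4)
  d2 <- family_distance_matrix(fam2$seqs)
  h2 <- burst_histogram(d2, 0.02)
  expect_identical(sum(h2$counts), as.integer(choose(30, 2)))
  expect_identical(nrow(h2$peaks), 2L)

  fam3 <- simulate_family_copies(levels = c(0, 0.12, 0.24),
                                 fractions = c(0.45, 0.30, 0.25),
                                 n_copies = 33L, seed = 5)
  h3 <- burst_histogram(family_distance_matrix(fam3$seqs), 0.02)
  expect_identical(nrow(h3$peaks), 3L)
})

test_that("identity groups partition by exact sequence equality", {
  seqs <- c(a = "ACGT", b = "ACGT", c = "ACGT", d = "TTTT", e = "TTTT")
  g <- identity_groups(seqs)
  expect_identical(lengths(g), c(3L, 2L))
  expect_setequal(g[[1]], c("a", "b", "c"))

  distinct <- stats::setNames(vapply(1:6, function(i) fixture_dna(30),
                                     character(1)), letters[1:6])
  expect_identical(lengths(identity_groups(distinct)), rep(1L, 6))

  # the intact-copy structure of a heavily amplified family: 24 groups
  # led by 38 and 29 identical elements (112 copies total)
  sizes <- c(38L, 29L, rep(3L, 9), rep(2L, 5), rep(1L, 8))
  expect_identical(sum(sizes), 112L)
  expect_length(sizes, 24L)
  set.seed(6)
  reps <- vapply(seq_along(sizes), function(i) fixture_dna(80),
                 character(1))
  pool <- rep(reps, times = sizes)
  names(pool) <- sprintf("e%03d", seq_along(pool))
  pool <- pool[sample(length(pool))]
  g24 <- identity_groups(pool)
  expect_length(g24, 24L)
  expect_identical(lengths(g24)[1:2], c(38L, 29L))
})

test_that("neighbor joining solves small cases exactly", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5),
               tolerance = 1e-12)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2)), "finite")
})

test_that("neighbor joining recovers additive topologies and matches ape", {
  set.seed(7)
  for (r in 1:20) {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    D <- D[order(rownames(D)), order(colnames(D))]
    mine <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(mine))), 0)
    ref <- ape::nj(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref),
                                           ape::unroot(mine))), 0)
  }
})

test_that("copies from two amplification episodes form two clades", {
  ok <- 0L
  for (seed in 1:5) {
    fam <- simulate_family_copies(levels = c(0, 0.12),
                                  fractions = c(0.5, 0.5),
                                  n_copies = 16L, seed = seed,
                                  internal = 600L)
    d <- family_distance_matrix(fam$seqs)
    tree <- nj_tree(d)
    young <- names(fam$seqs)[fam$truth$level == 0]
    old <- names(fam$seqs)[fam$truth$level > 0]
    mono <- ape::is.monophyletic(tree, young) ||
      ape::is.monophyletic(tree, old)
    if (mono) ok <- ok + 1L
  }
  expect_identical(ok, 5L)
})
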