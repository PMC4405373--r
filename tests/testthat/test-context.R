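test_that("gene association uses flank-extended CDS windows", {
  gene <- data.frame(gene_id = "g", contig = "c1", strand = "+",
                     cds_start = 5000L, cds_end = 5600L,
                     stringsAsFactors = FALSE)
  # element ending exactly 250 bp upstream of the CDS
  el <- data.frame(contig = "c1", start = 4550L, end = 4750L,
                   stringsAsFactors = FALSE)
  expect_true(associate_with_genes(el, gene, 300L)$associated)
  expect_false(associate_with_genes(el, gene, 200L)$associated)
  # flank 0: only overlap with the CDS itself counts
  expect_false(associate_with_genes(el, gene, 0L)$associated)
  inside <- data.frame(contig = "c1", start = 5100L, end = 5200L)
  expect_true(associate_with_genes(inside, gene, 0L)$associated)
  # touching the CDS boundary without overlap does not count at flank 0
  touching <- data.frame(contig = "c1", start = 4900L, end = 5000L)
  expect_false(associate_with_genes(touching, gene, 0L)$associated)
  expect_true(associate_with_genes(touching, gene, 100L)$associated)
})

test_that("association counts are monotone in the flank size", {
  set.seed(1)
  genes <- data.frame(gene_id = sprintf("g%d", 1:30), contig = "c1",
                      strand = "+",
                      cds_start = sort(sample(seq(0, 95000, 500), 30)))
  genes$cds_end <- genes$cds_start + 600L
  els <- data.frame(contig = "c1",
                    start = sort(sample(seq(0, 99000, 250), 80)))
  els$end <- els$start + 150L
  counts <- vapply(c(0L, 100L, 200L, 300L), function(f)
    associate_with_genes(els, genes, f)$n_associated, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the placement null matches its binomial expectation", {
  # single gene window; length-1 elements hit it with probability
  # exactly window / placeable positions
  gene <- data.frame(gene_id = "g", contig = "c1", strand = "+",
                     cds_start = 40000L, cds_end = 42000L,
                     stringsAsFactors = FALSE)
  L <- 100000L
  flank <- 300L
  reps <- 400L
  fr <- simulate_association_null(c(c1 = L), gene,
                                  element_lengths = rep(1L, 20),
                                  flank_bp = flank, replicates = reps,
                                  seed = 7)
  p_hit <- (2000 + 2 * flank) / L
  se <- sqrt(p_hit * (1 - p_hit) / (20 * reps))
  expect_lt(abs(attr(fr, "mean") - p_hit), 3 * se + 1e-3)
  # determinism and degenerate cases
  expect_identical(simulate_association_null(c(c1 = L), gene, rep(1L, 20),
                                             flank, 3L, seed = 7),
                   simulate_association_null(c(c1 = L), gene, rep(1L, 20),
                                             flank, 3L, seed = 7))
  none <- simulate_association_null(c(c1 = L), gene[0, ], rep(50L, 10),
                                    300L, 5L, seed = 1)
  expect_identical(as.numeric(none), rep(0, 5))
  expect_error(simulate_association_null(c(c1 = 100L), gene,
                                         rep(90L, 5), 0L, 1L, seed = 1),
               "infeasible")
})

test_that("the chi-square statistic matches closed forms and chisq.test", {
  res <- chi_square_bias_test(rbind(c(30, 70), c(20, 80)))
  # closed form n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  expect_equal(res$statistic, 200 * (30 * 80 - 70 * 20)^2 /
                 (100 * 100 * 50 * 150))
  expect_equal(res$statistic, 2.6667, tolerance = 1e-4)
  expect_identical(res$df, 1L)

  eq <- chi_square_bias_test(rbind(c(25, 25), c(25, 25)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  set.seed(2)
  for (r in 1:20) {
    tab <- matrix(sample(20:90, 4), 2)
    mine <- chi_square_bias_test(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, unname(ref$p.value))
  }

  # goodness-of-fit usage against null-model expectations
  gof <- chi_square_bias_test(c(30, 70), expected = c(25, 75))
  expect_identical(gof$df, 1L)
  expect_equal(gof$statistic, 25 / 25 + 25 / 75)
  expect_error(chi_square_bias_test(c(30, 70)), "expected")
  expect_error(chi_square_bias_test(rbind(c(1, 1), c(1, 1)),
                                    expected = rbind(c(0, 2), c(2, 2))),
               "pool")
})

make_tis_fixture <- function() {
  at30 <- paste(rep("AT", 20), collapse = "")
  ctx_bad <- "ATATATATAT" # current start context lacks CC/GG
  core <- paste0(ctx_bad, "ATG", "AAACCCTTT", "ATG")
  seqA <- paste0(at30, core, paste(rep("AT", 15), collapse = ""), "TAG")
  genome <- c(c1 = seqA)
  genes <- data.frame(gene_id = "g1", contig = "c1", strand = "+",
                      cds_start = 50L, cds_end = 50L + 39L,
                      stringsAsFactors = FALSE)
  list(genome = genome, genes = genes)
}

test_that("start codons are revised only with motif and AT support", {
  fx <- make_tis_fixture()
  r <- reannotate_tis(fx$genes, fx$genome)
  expect_identical(nrow(r$log), 1L)
  expect_identical(r$log$offset, 12L)
  expect_identical(r$genes$cds_start, 62L)
  # idempotent: the revised annotation is a fixed point
  r2 <- reannotate_tis(r$genes, fx$genome)
  expect_identical(nrow(r2$log), 0L)
  expect_identical(r2$genes, r$genes)

  # same gene on the minus strand
  L <- nchar(fx$genome)
  rc_genome <- c(c1 = revcomp(fx$genome[[1]]))
  rc_genes <- data.frame(gene_id = "g1", contig = "c1", strand = "-",
                         cds_start = L - fx$genes$cds_end,
                         cds_end = L - fx$genes$cds_start,
                         stringsAsFactors = FALSE)
  rr <- reannotate_tis(rc_genes, rc_genome)
  expect_identical(rr$log$offset, 12L)
  expect_identical(rr$genes$cds_end, rc_genes$cds_end - 12L)

  # no motif anywhere: annotation unchanged
  plain <- c(c1 = paste0(paste(rep("AT", 30), collapse = ""), "ATG",
                         paste(rep("AT", 30), collapse = "")))
  g <- data.frame(gene_id = "g", contig = "c1", strand = "+",
                  cds_start = 60L, cds_end = 99L,
                  stringsAsFactors = FALSE)
  expect_identical(nrow(reannotate_tis(g, plain)$log), 0L)

  # motif present but GC-rich context: unchanged
  gc_fx <- fx
  gc_genome <- c(c1 = paste0(paste(rep("GC", 20), collapse = ""),
                             substring(fx$genome[[1]], 41)))
  expect_identical(nrow(reannotate_tis(fx$genes, gc_genome)$log), 0L)

  # a gene not starting with ATG is skipped with a warning
  bad <- transform(fx$genes, cds_start = 51L)
  expect_warning(rb <- reannotate_tis(bad, fx$genome), "ATG")
  expect_identical(rb$genes$cds_start, 51L)
})

test_that("reciprocal best hits require mutual unique best scores", {
  set.seed(3)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  rnd_aa <- function(n) paste(sample(aas, n, TRUE), collapse = "")
  mut_aa <- function(s, p) {
    x <- strsplit(s, "")[[1]]
    i <- which(runif(length(x)) < p)
    x[i] <- sample(aas, length(i), TRUE)
    paste(x, collapse = "")
  }
  A <- stats::setNames(replicate(12, rnd_aa(100)), sprintf("a%02d", 1:12))
  expect_identical(reciprocal_best_hits(A, stats::setNames(A, sub("a", "b", names(A))))$a,
                   names(A))
  # orthologs at 10% divergence plus diverged paralogs: all true pairs
  # recovered, paralogs never pair
  B <- stats::setNames(vapply(A, mut_aa, "", p = 0.10),
                       sub("a", "b", names(A)))
  B <- c(B, stats::setNames(vapply(A[1:2], mut_aa, "", p = 0.25),
                            c("par1", "par2")))
  rb <- reciprocal_best_hits(A, B)
  expect_gte(sum(rb$b == sub("a", "b", rb$a)), round(0.95 * length(A)))
  expect_false(any(c("par1", "par2") %in% rb$b))
  # reciprocity: a2 is an exact copy of b1, so b1's best is a2 and a1
  # goes unpaired
  A2 <- c(a1 = A[[1]], a2 = mut_aa(A[[1]], 0.10))
  B2 <- c(b1 = A2[["a2"]])
  rb2 <- reciprocal_best_hits(A2, B2)
  expect_identical(rb2$a, "a2")
  expect_false("a1" %in% rb2$a)
})

make_synteny_fixture <- function(n_genes = 20L, n_insertions = 18L) {
  ga <- data.frame(gene_id = sprintf("ga%02d", seq_len(n_genes)),
                   contig = "cA", strand = "+",
                   cds_start = seq_len(n_genes) * 5000L,
                   stringsAsFactors = FALSE)
  ga$cds_end <- ga$cds_start + 900L
  gb <- ga
  gb$gene_id <- sub("ga", "gb", ga$gene_id)
  gb$contig <- "cB"
  orth <- data.frame(a = ga$gene_id, b = gb$gene_id,
                     stringsAsFactors = FALSE)
  with_mite <- seq_len(n_insertions)
  mites_a <- data.frame(contig = "cA",
                        start = ga$cds_start[with_mite] - 250L,
                        end = ga$cds_start[with_mite] - 100L,
                        stringsAsFactors = FALSE)
  list(ga = ga, gb = gb, orth = orth, mites_a = mites_a,
       no_mites = data.frame(contig = character(0), start = integer(0),
                             end = integer(0), stringsAsFactors = FALSE))
}

test_that("MIP candidates require a one-sided insertion in a syntenic block", {
  fx <- make_synteny_fixture()
  mip <- find_mip_candidates(fx$orth, fx$ga, fx$gb, fx$mites_a,
                             fx$no_mites, 300L)
  expect_identical(nrow(mip), 18L)
  expect_true(all(mip$collinear_neighbors >= 2L))

  # the same MITE present in both species' flanks yields no candidate
  mites_b <- fx$mites_a
  mites_b$contig <- "cB"
  both <- find_mip_candidates(fx$orth, fx$ga, fx$gb, fx$mites_a,
                              mites_b, 300L)
  expect_identical(nrow(both), 0L)

  # blocks below the collinearity floor are not used
  tiny <- find_mip_candidates(fx$orth[1:2, ], fx$ga, fx$gb, fx$mites_a,
                              fx$no_mites, 300L)
  expect_identical(nrow(tiny), 0L)
})
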