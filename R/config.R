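#' Pipeline configuration
#'
#' Bundles every tunable threshold of the discovery pipeline.  The
#' defaults reproduce the structural scanner parameterisation used for
#' microsporidian genomes (TIR 5-60 bp, TSD 2-20 bp, element length
#' under 1500 bp, at most one TIR mismatch), the 90\% family-identity
#' clustering rule with discard of families under three members, the
#' remnant-mining filters (identity >= 90\%, query coverage >= 80\%),
#' the 300 bp gene-flank window, and a 0.02 divergence histogram bin.
#'
#' @param tir_min,tir_max allowed terminal inverted repeat length (bp).
#' @param tsd_min,tsd_max allowed target site duplication length (bp).
#' @param max_element_len elements must be shorter than this (bp,
#'   exclusive; applies to the element body, TSD copies excluded).
#' @param max_tir_mismatch maximum Hamming mismatches between the 5'
#'   TIR and the reverse complement of the 3' TIR.
#' @param family_identity minimum pairwise identity for two candidates
#'   to join the same family (single linkage).
#' @param min_family_size families with fewer members are discarded.
#' @param remnant_identity,remnant_coverage filters applied to
#'   consensus-vs-genome hits when mining remnant copies.
#' @param flank_bp default gene flank for the association analysis.
#' @param histogram_bin bin width for divergence histograms.
#' @param rng_seed seed for the pipeline's stochastic stages.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(tir_min = 5L, tir_max = 60L,
                            tsd_min = 2L, tsd_max = 20L,
                            max_element_len = 1500L,
                            max_tir_mismatch = 1L,
                            family_identity = 0.90,
                            min_family_size = 3L,
                            remnant_identity = 0.90,
                            remnant_coverage = 0.80,
                            flank_bp = 300L,
                            histogram_bin = 0.02,
                            rng_seed = 1234L) {
  cfg <- list(tir_min = as.integer(tir_min), tir_max = as.integer(tir_max),
              tsd_min = as.integer(tsd_min), tsd_max = as.integer(tsd_max),
              max_element_len = as.integer(max_element_len),
              max_tir_mismatch = as.integer(max_tir_mismatch),
              family_identity = family_identity,
              min_family_size = as.integer(min_family_size),
              remnant_identity = remnant_identity,
              remnant_coverage = remnant_coverage,
              flank_bp = as.integer(flank_bp),
              histogram_bin = histogram_bin,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(tir_min >= 1L, tir_min <= tir_max,
              tsd_min >= 1L, tsd_min <= tsd_max,
              max_element_len > 2L * tir_min,
              max_tir_mismatch >= 0L,
              family_identity >= 0, family_identity <= 1,
              min_family_size >= 1L,
              remnant_identity >= 0, remnant_identity <= 1,
              remnant_coverage >= 0, remnant_coverage <= 1,
              flank_bp >= 0L, histogram_bin > 0)
  })
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("MITE pipeline configuration\n")
  cat(sprintf("  TIR %d-%d bp (<= %d mismatch), TSD %d-%d bp, length < %d bp\n",
              x$tir_min, x$tir_max, x$max_tir_mismatch,
              x$tsd_min, x$tsd_max, x$max_element_len))
  cat(sprintf("  family identity >= %.2f, min size %d\n",
              x$family_identity, x$min_family_size))
  cat(sprintf("  remnant identity >= %.2f, coverage >= %.2f\n",
              x$remnant_identity, x$remnant_coverage))
  cat(sprintf("  gene flank %d bp, histogram bin %.3f, seed %d\n",
              x$flank_bp, x$histogram_bin, x$rng_seed))
  invisible(x)
}
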