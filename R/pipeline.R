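# End-to-end discovery pipeline: scan -> filter -> cluster ->
# consensus -> mine -> classify -> name -> divergence -> association,
# with a reproducible run report and optional artifact directory.

member_sequences <- function(genome, members) {
  seqs <- substring(genome[members$contig], members$start + 1L,
                    members$end)
  minus <- !is.null(members$strand) & members$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  stats::setNames(seqs, sprintf("%s:%d-%d", members$contig,
                                members$start, members$end))
}

# Assemble one family from clustered structural members plus mined
# copies; returns NULL when the family shrinks below min_family_size.
assemble_family <- function(member_ids, filtered, seqs, genome, config,
                            mine = TRUE) {
  rows <- filtered[match(member_ids, names(seqs)), , drop = FALSE]
  consensus <- build_consensus(seqs[member_ids])
  members <- data.frame(contig = rows$contig, start = rows$start,
                        end = rows$end, strand = "+",
                        intact = TRUE, stringsAsFactors = FALSE)
  add_idcov <- function(m) {
    mseqs <- member_sequences(genome, m)
    idcov <- aln_to_subject(mseqs, consensus)
    m$identity_to_consensus <- idcov$identity
    m$coverage_of_consensus <- idcov$span_s / nchar(consensus)
    m
  }
  # the mining filters applied uniformly: members must match the
  # consensus at >= remnant_identity over >= remnant_coverage of it.
  # Structural members are vetted before mined hits are merged so a
  # rejected structural candidate cannot shadow a genuine remnant.
  members <- add_idcov(members)
  members <- members[members$identity_to_consensus >= config$remnant_identity &
                       members$coverage_of_consensus >= config$remnant_coverage, ,
                     drop = FALSE]
  if (mine) {
    mined <- mine_remnants(consensus, genome, config$remnant_identity,
                           config$remnant_coverage, config)
    if (nrow(mined) > 0L) {
      new_hit <- vapply(seq_len(nrow(mined)), function(i) {
        same <- members$contig == mined$contig[i]
        ov <- pmin(members$end[same], mined$end[i]) -
          pmax(members$start[same], mined$start[i])
        w <- pmin(members$end[same] - members$start[same],
                  mined$end[i] - mined$start[i])
        !any(ov > 0 & 2 * ov > w)
      }, logical(1))
      if (any(new_hit)) {
        add <- add_idcov(mined[new_hit, c("contig", "start", "end",
                                          "strand", "intact"),
                               drop = FALSE])
        add <- add[add$identity_to_consensus >= config$remnant_identity &
                     add$coverage_of_consensus >= config$remnant_coverage, ,
                   drop = FALSE]
        members <- rbind(members, add)
      }
    }
  }
  members <- members[order(members$contig, members$start), , drop = FALSE]
  rownames(members) <- NULL
  if (nrow(members) < config$min_family_size) return(NULL)
  # shared TSD motif when most members agree (e.g. the "TA" of
  # Stowaway-like families, allowing a minority of chance-extended
  # TSDs), otherwise the modal TSD length
  tsds <- rows$tsd
  tsd_tab <- sort(table(tsds), decreasing = TRUE)
  tsd_pattern <- if (tsd_tab[1] >= length(tsds) / 2) {
    names(tsd_tab)[1]
  } else {
    lens <- nchar(tsds)
    as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  }
  tirs <- rows$tir_length
  tir_length <- as.integer(names(sort(table(tirs), decreasing = TRUE))[1])
  new_mite_family(members, consensus, tsd_pattern, tir_length)
}

#' Summarise families by superfamily
#'
#' One row per superfamily with the family count, total element count
#' and summed element length, plus a totals row -- the conventional
#' per-genome MITE summary table.
#'
#' @param families list of `mite_family` objects.
#' @param genome named character vector of contigs (used for the
#'   `genome_fraction` attribute).
#' @return data.frame with attribute `genome_fraction` (summed element
#'   length over genome length).
#' @export
summarize_superfamilies <- function(families, genome = NULL) {
  sf <- vapply(families, function(f) f$superfamily, character(1))
  rows <- lapply(SUPERFAMILY_LEVELS, function(s) {
    fams <- families[sf == s]
    if (length(fams) == 0L) return(NULL)
    data.frame(superfamily = s, families = length(fams),
               elements = sum(vapply(fams, function(f)
                 nrow(f$members), integer(1))),
               total_bp = sum(vapply(fams, function(f)
                 sum(f$members$end - f$members$start), integer(1))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(superfamily = character(0), families = integer(0),
                      elements = integer(0), total_bp = integer(0),
                      stringsAsFactors = FALSE)
  }
  total <- data.frame(superfamily = "Total",
                      families = sum(out$families),
                      elements = sum(out$elements),
                      total_bp = sum(out$total_bp),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  if (!is.null(genome)) {
    attr(out, "genome_fraction") <- total$total_bp / sum(nchar(genome))
  }
  out
}

#' Run the full MITE discovery pipeline
#'
#' Executes scan, candidate filtering, family clustering, consensus
#' building, remnant mining, superfamily classification, family
#' naming, per-family divergence analysis (distance matrix, burst
#' histogram, neighbor-joining tree) and, when gene models are
#' supplied, the gene-association analysis with its Monte-Carlo null
#' and chi-square bias test.  The run is a pure function of (inputs,
#' config): rerunning with the same seed reproduces the report
#' exactly.
#'
#' @param genome named character vector of contigs.
#' @param genes optional gene models (see
#'   [read_gene_annotations()]).
#' @param config a [pipeline_config()].
#' @param species_letter letter used in family names.
#' @param outdir optional directory for artifacts (report, element
#'   table, consensus FASTA, histograms, trees, log).
#' @param mine whether to mine remnant copies (requires BLAST+).
#' @param divergence_min_copies minimum intact copies for the
#'   divergence analysis of a family.
#' @param association_flanks flank sizes (bp) for the association
#'   analysis.
#' @param null_replicates Monte-Carlo replicates for the placement
#'   null.
#' @return object of class `mite_run_report`.
#' @export
run_pipeline <- function(genome, genes = NULL,
                         config = pipeline_config(),
                         species_letter = "x", outdir = NULL,
                         mine = TRUE, divergence_min_copies = 10L,
                         association_flanks = c(300L, 200L, 100L, 0L),
                         null_replicates = 200L) {
  check_genome(genome)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  candidates <- scan_genome(genome, config)
  note("scan: %d candidates", nrow(candidates))
  filtered <- filter_candidates(candidates)
  att <- attr(filtered, "attrition")
  note("filter: %d candidates retained (removed %d by N rule, %d by TSD rule)",
       nrow(filtered), att[["n_rule"]], att[["tsd_rule"]])
  seqs <- extract_element_sequences(genome, filtered)
  cl <- cluster_families(seqs, config$family_identity,
                         config$min_family_size, loci = filtered)
  note("cluster: %d families, %d candidates discarded in small components",
       length(cl$families), length(cl$discarded))
  families <- list()
  for (member_ids in cl$families) {
    fam <- assemble_family(member_ids, filtered, seqs, genome, config,
                           mine = mine)
    if (!is.null(fam)) families[[length(families) + 1L]] <- fam
  }
  families <- name_families(families, species_letter)
  note("families: %d after consensus/mining, %d copies total",
       length(families),
       sum(vapply(families, function(f) nrow(f$members), integer(1))))

  profiles <- list()
  for (fam in families) {
    intact <- fam$members[fam$members$intact, , drop = FALSE]
    if (nrow(intact) < divergence_min_copies) next
    mseqs <- member_sequences(genome, intact)
    names(mseqs) <- sprintf("%s_%d", fam$name, seq_along(mseqs))
    dmat <- suppressWarnings(family_distance_matrix(mseqs))
    # members with saturated pairs cannot be placed on the tree; drop
    # the worst offenders until the matrix is complete
    dropped <- character(0)
    while (anyNA(dmat) && nrow(dmat) > 2L) {
      worst <- which.max(rowSums(is.na(dmat)))
      dropped <- c(dropped, rownames(dmat)[worst])
      dmat <- dmat[-worst, -worst, drop = FALSE]
    }
    if (length(dropped) > 0L) {
      note("divergence: %s: %d member(s) with saturated distances excluded",
           fam$name, length(dropped))
    }
    if (nrow(dmat) < 2L || anyNA(dmat)) next
    profiles[[fam$name]] <- list(
      distance_matrix = dmat,
      histogram = burst_histogram(dmat, config$histogram_bin),
      tree = nj_tree(dmat))
  }
  note("divergence: %d families profiled", length(profiles))

  copies <- if (length(families) == 0L) {
    data.frame(contig = character(0), start = integer(0),
               end = integer(0), intact = logical(0),
               family = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(lapply(families, function(f) {
      cbind(f$members[, c("contig", "start", "end", "intact")],
            family = f$name, stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  }

  association <- NULL
  if (!is.null(genes) && nrow(copies) > 0L) {
    association <- lapply(seq_along(association_flanks), function(k) {
      flank <- association_flanks[k]
      obs <- associate_with_genes(copies, genes, flank)
      nulls <- simulate_association_null(
        genome, genes, copies$end - copies$start, flank,
        replicates = null_replicates,
        seed = config$rng_seed + k)
      pbar <- attr(nulls, "mean")
      n <- obs$n_elements
      test <- chi_square_bias_test(
        c(associated = obs$n_associated,
          not_associated = n - obs$n_associated),
        expected = c(n * pbar, n * (1 - pbar)))
      data.frame(flank_bp = flank, n_elements = n,
                 n_associated = obs$n_associated,
                 fraction = obs$fraction, null_mean_fraction = pbar,
                 null_replicates = null_replicates,
                 chi_square = test$statistic, p_value = test$p_value,
                 stringsAsFactors = FALSE)
    })
    association <- do.call(rbind, association)
    note("association: flanks %s analysed",
         paste(association_flanks, collapse = "/"))
  }

  summary <- summarize_superfamilies(families, genome)
  report <- structure(list(
    counts = list(candidates = nrow(candidates),
                  filtered = nrow(filtered),
                  families = length(families),
                  copies = nrow(copies),
                  intact_copies = sum(copies$intact)),
    superfamily_summary = summary,
    genome_fraction = attr(summary, "genome_fraction"),
    association = association,
    families = families,
    profiles = profiles,
    copies = copies,
    log = log_lines,
    fingerprint = list(package = "mitescope",
                       version = as.character(utils::packageVersion("mitescope")),
                       config = unclass(config),
                       seed = config$rng_seed)),
    class = "mite_run_report")
  if (!is.null(outdir)) write_run_artifacts(report, outdir)
  report
}

#' @export
print.mite_run_report <- function(x, ...) {
  cat("MITE discovery run\n")
  cat(sprintf("  candidates %d -> filtered %d -> families %d (%d copies, %d intact)\n",
              x$counts$candidates, x$counts$filtered, x$counts$families,
              x$counts$copies, x$counts$intact_copies))
  cat(sprintf("  genome fraction occupied: %.4f\n",
              x$genome_fraction %||% 0))
  print(x$superfamily_summary)
  if (!is.null(x$association)) {
    cat("  gene association:\n")
    print(x$association, row.names = FALSE)
  }
  invisible(x)
}

write_run_artifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sub <- function(...) {
    p <- file.path(outdir, ...)
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    p
  }
  write.table(report$superfamily_summary, sub("report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  copies <- report$copies
  if (nrow(copies) > 0L) {
    copies$tsd <- "."
    copies$tir_length <- NA_integer_
    for (fam in report$families) {
      sel <- copies$family == fam$name
      copies$tsd[sel] <- if (is.character(fam$tsd_pattern))
        fam$tsd_pattern else "."
      copies$tir_length[sel] <- fam$tir_length
    }
    write_element_table(copies, sub("copies.bed"))
  }
  if (length(report$families) > 0L) {
    write_fasta(vapply(report$families, function(f) f$consensus,
                       character(1)), sub("consensus.fa"))
  }
  for (nm in names(report$profiles)) {
    pr <- report$profiles[[nm]]
    h <- pr$histogram
    write.table(data.frame(bin_start = h$bin_edges[-length(h$bin_edges)],
                           bin_end = h$bin_edges[-1],
                           count = h$counts),
                sub("histograms", paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ape::write.tree(pr$tree, sub("trees", paste0(nm, ".nwk")))
  }
  if (!is.null(report$association)) {
    write.table(report$association, sub("association.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cfg <- report$fingerprint$config
  writeLines(c(sprintf("package=%s %s", report$fingerprint$package,
                       report$fingerprint$version),
               sprintf("%s=%s", names(cfg),
                       vapply(cfg, format, character(1)))),
             sub("config.snapshot.txt"))
  writeLines(report$log, sub("logs", "run.log"))
  invisible(outdir)
}
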