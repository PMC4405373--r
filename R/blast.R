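# Thin wrappers around NCBI BLAST+ used for homology search: the
# all-vs-all prefilter that proposes candidate pairs for family
# clustering, and consensus-vs-genome search for remnant mining.
# BLAST only nominates loci/pairs; all accept/reject decisions are
# made by the package's own identity and coverage computations.

has_blast <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

require_blast <- function() {
  if (!has_blast()) {
    stop("NCBI BLAST+ (blastn, makeblastdb) not found on PATH",
         call. = FALSE)
  }
}

make_blast_db <- function(seqs, dir) {
  db_fa <- file.path(dir, "db.fa")
  write_fasta(seqs, db_fa)
  out <- system2("makeblastdb",
                 c("-in", db_fa, "-dbtype", "nucl", "-out",
                   file.path(dir, "db")),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("makeblastdb failed: ", paste(out, collapse = "\n"),
         call. = FALSE)
  }
  file.path(dir, "db")
}

run_blastn <- function(query, db, fields, extra = character(0)) {
  dir <- dirname(db)
  q_fa <- file.path(dir, "query.fa")
  write_fasta(query, q_fa)
  out_tsv <- file.path(dir, "hits.tsv")
  out <- system2("blastn",
                 c("-query", q_fa, "-db", db,
                   "-outfmt", shQuote(paste(c("6", fields), collapse = " ")),
                   "-out", out_tsv, extra),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("blastn failed: ", paste(out, collapse = "\n"), call. = FALSE)
  }
  if (file.size(out_tsv) == 0L) {
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(fields))), fields))
  }
  stats::setNames(read.delim(out_tsv, header = FALSE,
                             stringsAsFactors = FALSE), fields)
}

# Unordered candidate pairs (i < j, integer indices into seqs) whose
# members share a megablast hit.
blast_candidate_pairs <- function(seqs) {
  require_blast()
  dir <- tempfile("blastall")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  ids <- sprintf("s%08d", seq_along(seqs))
  db <- make_blast_db(stats::setNames(seqs, ids), dir)
  hits <- run_blastn(stats::setNames(seqs, ids), db,
                     c("qseqid", "sseqid"),
                     c("-evalue", "1e-5", "-max_target_seqs", "500"))
  qi <- as.integer(sub("^s", "", hits$qseqid))
  si <- as.integer(sub("^s", "", hits$sseqid))
  keep <- qi != si
  pairs <- unique(cbind(pmin(qi[keep], si[keep]),
                        pmax(qi[keep], si[keep])))
  pairs
}
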