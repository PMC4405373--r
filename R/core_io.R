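# Readers and writers for the standard formats the pipeline touches.
#
# Coordinate conventions: every internal table uses 0-based half-open
# coordinates.  GFF-like input/output is 1-based inclusive; BED-style
# element tables are 0-based half-open.  All conversion happens in
# this file and nowhere else.

#' Read a FASTA file of DNA sequences
#'
#' Residues are uppercased; only `A,C,G,T,N` are accepted.  Parse
#' problems are reported with the offending line number.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) == 0L || !hdr[1]) {
    stop(sprintf("%s: line 1: expected FASTA header", path), call. = FALSE)
  }
  ids <- character(0)
  seqs <- character(0)
  buf <- character(0)
  start_line <- 0L
  flush <- function(line_no) {
    s <- paste(buf, collapse = "")
    if (!nzchar(s)) {
      stop(sprintf("%s: line %d: empty sequence for record '%s'",
                   path, start_line, ids[length(ids)]), call. = FALSE)
    }
    seqs[[length(seqs) + 1L]] <<- s
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^>", ln)) {
      if (length(ids) > 0L) flush(i)
      id <- sub("^>\\s*", "", ln)
      id <- sub("\\s.*$", "", id)
      if (!nzchar(id)) {
        stop(sprintf("%s: line %d: empty FASTA header", path, i),
             call. = FALSE)
      }
      ids <- c(ids, id)
      buf <- character(0)
      start_line <- i
    } else {
      s <- toupper(gsub("\\s", "", ln))
      if (grepl("[^ACGTN]", s)) {
        stop(sprintf("%s: line %d: illegal character in sequence", path, i),
             call. = FALSE)
      }
      buf <- c(buf, s)
    }
  }
  flush(length(lines) + 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate sequence id '%s'", path,
                 ids[anyDuplicated(ids)]), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  check_genome(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene annotations from a GFF-like tab-separated file
#'
#' Expects the GFF dialect: `seqid source type start end score strand
#' frame [attributes]` with 1-based inclusive coordinates.  The
#' attributes column, when present, is used as the gene id; otherwise
#' ids are generated.  Coordinates are converted to the package's
#' 0-based half-open convention.
#'
#' @param path path to the annotation file.
#' @param contig_lengths optional named integer vector used to check
#'   that records fall within their contig.
#' @return data.frame with columns `gene_id`, `contig`, `strand`,
#'   `cds_start`, `cds_end` (0-based half-open).
#' @export
read_gene_annotations <- function(path, contig_lengths = NULL) {
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 8L) {
    stop(sprintf("%s: expected at least 8 tab-separated columns", path),
         call. = FALSE)
  }
  start1 <- as.integer(raw[[4]])
  end1 <- as.integer(raw[[5]])
  strand <- as.character(raw[[7]])
  if (any(is.na(start1)) || any(is.na(end1))) {
    stop(sprintf("%s: non-numeric coordinates", path), call. = FALSE)
  }
  if (any(start1 > end1)) {
    stop(sprintf("%s: record %d: start > end", path,
                 which(start1 > end1)[1]), call. = FALSE)
  }
  if (any(start1 < 1L)) {
    stop(sprintf("%s: record %d: start < 1", path,
                 which(start1 < 1L)[1]), call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) {
    stop(sprintf("%s: record %d: strand must be '+' or '-'", path,
                 which(!strand %in% c("+", "-"))[1]), call. = FALSE)
  }
  ids <- if (ncol(raw) >= 9L) as.character(raw[[9]]) else
    sprintf("gene_%d", seq_len(nrow(raw)))
  genes <- data.frame(gene_id = ids,
                      contig = as.character(raw[[1]]),
                      strand = strand,
                      cds_start = start1 - 1L,
                      cds_end = end1,
                      stringsAsFactors = FALSE)
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(genes$contig, names(contig_lengths))
    if (length(unknown) > 0L) {
      stop(sprintf("%s: unknown contig '%s'", path, unknown[1]),
           call. = FALSE)
    }
    over <- genes$cds_end > contig_lengths[genes$contig]
    if (any(over)) {
      stop(sprintf("%s: record %d: end beyond contig length", path,
                   which(over)[1]), call. = FALSE)
    }
  }
  genes
}

#' Write gene annotations as GFF-like TSV
#'
#' Inverse of [read_gene_annotations()]: converts back to 1-based
#' inclusive coordinates.
#'
#' @param genes data.frame as returned by [read_gene_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(genes, path) {
  out <- data.frame(genes$contig, ".", "CDS",
                    genes$cds_start + 1L, genes$cds_end,
                    ".", genes$strand, ".", genes$gene_id,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

ELEMENT_TABLE_COLS <- c("contig", "start", "end", "family", "tsd",
                        "tir_length")

#' Write an element table (BED-compatible TSV)
#'
#' First three columns are `contig`, `start`, `end` in 0-based
#' half-open coordinates, so the file doubles as a BED interval file;
#' the remaining columns carry element attributes.  Any extra columns
#' present in `elements` are preserved.  Writes a header line.
#'
#' @param elements data.frame with at least the columns `contig`,
#'   `start`, `end`, `family`, `tsd`, `tir_length`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_element_table <- function(elements, path) {
  missing_cols <- setdiff(ELEMENT_TABLE_COLS, names(elements))
  if (length(missing_cols) > 0L) {
    stop(sprintf("element table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ord <- c(ELEMENT_TABLE_COLS, setdiff(names(elements), ELEMENT_TABLE_COLS))
  write.table(elements[, ord, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an element table written by [write_element_table()]
#'
#' @param path path to the TSV file.
#' @return data.frame with the element columns.
#' @export
read_element_table <- function(path) {
  out <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ELEMENT_TABLE_COLS, names(out))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: not an element table (missing %s)", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$family <- as.character(out$family)
  out$tsd <- as.character(out$tsd)
  out
}
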