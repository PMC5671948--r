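#' Read a FASTA file
#'
#' Multi-record, line-wrapped FASTA; sequence is uppercased. Lines starting
#' with `;` (old-style comments, as in some reference distributions) are
#' skipped.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, ";")]
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  x <- Biostrings::readDNAStringSet(tmp)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences, or a single
#'   [circular_genome()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "circular_genome")) {
    seqs <- stats::setNames(seqs$sequence, seqs$name)
  }
  x <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read regions from a BED file
#'
#' BED is 0-based, half-open; coordinates are converted to the package's
#' 1-based, end-exclusive convention (`start = bed_start + 1`,
#' `end = bed_end + 1`), which preserves lengths exactly.
#'
#' @param path Path to a BED file (3-6 columns, tab-separated).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]],
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]) + 1L,
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  out$strand <- if (ncol(df) >= 6) as.character(df[[6]]) else "+"
  out
}

#' Write regions to a BED file
#'
#' Inverse of [read_bed()]: internal 1-based end-exclusive coordinates are
#' converted back to BED's 0-based half-open convention.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  name <- if ("name" %in% names(regions)) regions$name else "."
  strand <- if ("strand" %in% names(regions)) regions$strand else "+"
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end - 1L,
                   name, 0L, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write paired reads as FASTQ (Phred+33)
#'
#' Read names carry the simulation truth in a colon-separated tag
#' (`id:start:fraglen:bisulfite_strand:topology`); downstream alignment
#' ignores the tag.
#'
#' @param reads A read-pair data.frame from [generate_reads()].
#' @param prefix Output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  hdr <- paste0("@", reads$read_id)
  writeLines(as.vector(rbind(hdr, reads$read1, "+", reads$qual1)), p1)
  writeLines(as.vector(rbind(hdr, reads$read2, "+", reads$qual2)), p2)
  invisible(c(p1, p2))
}

#' Read paired FASTQ files written by [write_fastq()]
#'
#' @param path_r1,path_r2 Paths to the two mate files.
#' @return A read-pair data.frame with columns `read_id`, `read1`, `qual1`,
#'   `read2`, `qual2`.
#' @export
read_fastq <- function(path_r1, path_r2) {
  parse1 <- function(p) {
    x <- readLines(p, warn = FALSE)
    stopifnot(length(x) %% 4L == 0L)
    i <- seq(1L, length(x), by = 4L)
    list(id = sub("^@", "", x[i]), seq = x[i + 1L], qual = x[i + 3L])
  }
  a <- parse1(path_r1); b <- parse1(path_r2)
  stopifnot(identical(a$id, b$id))
  data.frame(read_id = a$id, read1 = a$seq, qual1 = a$qual,
             read2 = b$seq, qual2 = b$qual, stringsAsFactors = FALSE)
}

#' Write a per-cytosine report (CX cytosine-report dialect)
#'
#' Tab-separated, no header, column order: chromosome, position, strand,
#' count methylated, count unmethylated, context, trinucleotide.
#'
#' @param records Cytosine-report data.frame from [call_methylation()].
#' @param path Output path.
#' @export
write_cytosine_report <- function(records, path) {
  utils::write.table(
    records[, c("chrom", "position", "strand", "count_methylated",
                "count_unmethylated", "context", "trinucleotide")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-cytosine report
#'
#' Accepts the dialect written by [write_cytosine_report()] (and external
#' cytosine reports in the same column order), so diagnostics can run on
#' reports produced outside this package.
#'
#' @param path Path to a tab-separated cytosine report.
#' @return Cytosine-report data.frame with a `coverage` and
#'   `methylation_percent` column added.
#' @export
read_cytosine_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "position", "strand",
                                        "count_methylated",
                                        "count_unmethylated",
                                        "context", "trinucleotide"))
  add_methylation_percent(df)
}

#' Add coverage and methylation percentage columns to a cytosine report
#'
#' `methylation_percent = 100 * C / (C + T)`, `NA` where coverage is zero.
#'
#' @param records Cytosine-report data.frame.
#' @return The data.frame with `coverage` and `methylation_percent` columns.
#' @export
add_methylation_percent <- function(records) {
  cov <- records$count_methylated + records$count_unmethylated
  records$coverage <- cov
  records$methylation_percent <-
    ifelse(cov > 0, 100 * records$count_methylated / cov, NA_real_)
  records
}
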