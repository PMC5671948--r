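#' Circular (or linear) genome object
#'
#' Container for a reference sequence with explicit topology. All coordinates
#' in the package are 1-based with end-exclusive intervals, so an interval
#' start..end has length `end - start`. On circular genomes, coordinate
#' accessors wrap across the origin; on linear genomes wrapping is an error.
#'
#' @param name Sequence name (single string).
#' @param sequence DNA string over A, C, G, T, N (case-insensitive; stored
#'   uppercase).
#' @param circular Logical; is the molecule circular?
#' @return An object of class `circular_genome` with fields `name`,
#'   `sequence`, `circular` and `length`.
#' @export
circular_genome <- function(name, sequence, circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L, is.logical(circular), length(circular) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  structure(
    list(name = name, sequence = sequence, circular = circular,
         length = nchar(sequence)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Genomic interval (1-based, end-exclusive)
#'
#' The interval start..end covers positions `start, ..., end - 1` and has
#' length `end - start`. `end` may exceed the genome length only on circular
#' genomes, in which case the interval wraps across the origin. Strand is
#' `"+"` (heavy) or `"-"` (light).
#'
#' @param start 1-based start position.
#' @param end End position, exclusive; must be greater than `start`.
#' @param strand `"+"` or `"-"`.
#' @param name Optional interval name.
#' @return A `genomic_interval` object.
#' @export
genomic_interval <- function(start, end, strand = "+", name = NA_character_) {
  stopifnot(length(start) == 1L, length(end) == 1L, start >= 1)
  if (end <= start) stop("empty interval: end must exceed start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(name = name, start = as.integer(start), end = as.integer(end),
                 strand = strand),
            class = "genomic_interval")
}

#' Interval length in bp
#' @param interval A [genomic_interval()].
#' @return Integer length `end - start`.
#' @export
interval_length <- function(interval) interval$end - interval$start

#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (non-degenerate, ACGT only,
#'   at least 4 bp).
#' @param cut_offset Cut position within the recognition site, in
#'   `[0, nchar(recognition)]`; fragments start at site start + offset.
#' @return A `restriction_enzyme` object.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) stop("recognition sequence must be >= 4 bp")
  if (grepl("[^ACGT]", recognition))
    stop("degenerate or invalid bases in recognition sequence")
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset outside recognition site")
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' BamHI (G/GATCC), the enzyme that linearizes human mtDNA
#' @return A `restriction_enzyme`.
#' @export
bamhi <- function() restriction_enzyme("BamHI", "GGATCC", 1L)

#' BglII (A/GATCT), used for mouse mtDNA
#' @return A `restriction_enzyme`.
#' @export
bglii <- function() restriction_enzyme("BglII", "AGATCT", 1L)

#' Reverse complement of a DNA string
#'
#' N complements to N. Vectorised over `seq`.
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a subsequence, wrapping across the origin when circular
#'
#' @param genome A [circular_genome()].
#' @param start 1-based start position in `1..length`.
#' @param length Number of bases to extract (`<=` genome length).
#' @param strand `"+"` returns the top strand left-to-right; `"-"` returns
#'   the reverse complement.
#' @return A DNA string of exactly `length` bases.
#' @export
circular_subseq <- function(genome, start, length, strand = "+") {
  L <- genome$length
  if (length > L) stop("requested length exceeds genome length")
  if (start < 1 || start > L) stop("start outside genome")
  end <- start + length - 1L
  if (end <= L) {
    s <- substr(genome$sequence, start, end)
  } else {
    if (!genome$circular) stop("interval runs off the end of a linear genome")
    s <- paste0(substr(genome$sequence, start, L),
                substr(genome$sequence, 1L, end - L))
  }
  if (strand == "-") s <- reverse_complement(s) else s
}

#' Find restriction sites on the forward strand
#'
#' Scans for exact occurrences of the recognition sequence, crossing the
#' origin when the genome is circular (a site spanning the origin is reported
#' at its true start near the end of the sequence, once).
#'
#' @param genome A [circular_genome()].
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of 1-based site start positions.
#' @export
find_sites <- function(genome, enzyme) {
  rec <- enzyme$recognition
  k <- nchar(rec)
  seq <- genome$sequence
  subject <- if (genome$circular && genome$length >= k) {
    paste0(seq, substr(seq, 1L, k - 1L))
  } else {
    seq
  }
  m <- gregexpr(rec, subject, fixed = TRUE)[[1]]
  pos <- as.integer(m[m > 0])
  pos <- pos[pos <= genome$length]   # wrap copies map back to the same site
  sort(unique(pos))
}

#' Digest a genome with a restriction enzyme
#'
#' Complete digestion: a circular genome with `k >= 1` sites yields exactly
#' `k` linear fragments (one full-length fragment when `k == 1`); a linear
#' genome with `k` sites yields `k + 1` fragments. Fragment boundaries sit at
#' site start + `cut_offset`. With zero sites the molecule is returned
#' unchanged and `was_linearized` is `FALSE`.
#'
#' @param genome A [circular_genome()].
#' @param enzyme A [restriction_enzyme()].
#' @return A `digest_product`: list with `fragments` (character vector of
#'   linear sequences, in genome order starting from the first cut),
#'   `site_positions` (1-based recognition-site starts) and `was_linearized`.
#' @export
digest <- function(genome, enzyme) {
  sites <- find_sites(genome, enzyme)
  L <- genome$length
  if (length(sites) == 0L) {
    return(structure(list(fragments = genome$sequence,
                          site_positions = integer(0),
                          was_linearized = FALSE),
                     class = "digest_product"))
  }
  cuts <- ((sites + enzyme$cut_offset - 1L) %% L) + 1L  # first base of fragment
  cuts <- sort(unique(cuts))
  if (genome$circular) {
    frags <- vapply(seq_along(cuts), function(i) {
      from <- cuts[i]
      to <- if (i < length(cuts)) cuts[i + 1L] else cuts[1L] + L
      circular_subseq(genome, from, to - from)
    }, character(1))
    linearized <- TRUE
  } else {
    bounds <- c(1L, cuts[cuts > 1L & cuts <= L], L + 1L)
    bounds <- unique(bounds)
    frags <- vapply(seq_len(length(bounds) - 1L), function(i) {
      substr(genome$sequence, bounds[i], bounds[i + 1L] - 1L)
    }, character(1))
    linearized <- FALSE   # already linear; digestion does not change topology
  }
  structure(list(fragments = frags, site_positions = sites,
                 was_linearized = linearized),
            class = "digest_product")
}

#' Extract an amplicon sequence for an interval
#'
#' Returns exactly `end - start` bases; intervals on the light strand
#' (`"-"`) return the reverse complement, as a bisulfite amplicon targeting
#' that strand would.
#'
#' @param genome A [circular_genome()].
#' @param interval A [genomic_interval()].
#' @return DNA string of length `interval_length(interval)`.
#' @export
extract_amplicon <- function(genome, interval) {
  len <- interval_length(interval)
  if (len <= 0) stop("empty amplicon: end must exceed start")
  circular_subseq(genome, interval$start, len, strand = interval$strand)
}

#' Rotate the sequence origin of a circular genome
#'
#' Utility for topology-invariance checks: the rotated genome starts at
#' position `offset + 1` of the original.
#'
#' @param genome A circular [circular_genome()].
#' @param offset Number of bases to rotate by (0..length-1).
#' @return A new `circular_genome`.
#' @export
rotate_genome <- function(genome, offset) {
  stopifnot(genome$circular)
  offset <- offset %% genome$length
  if (offset == 0) return(genome)
  circular_genome(genome$name,
                  circular_subseq(genome, offset + 1L, genome$length),
                  circular = TRUE)
}
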