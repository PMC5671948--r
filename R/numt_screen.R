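#' Enumerate all fixed-length reads from a NUMT sequence
#'
#' One read per start offset (step 1) per strand per state. The
#' "methylated" state is the sequence unchanged (every cytosine retained —
#' the worst case for confusability with mtDNA); the "unmethylated" state is
#' full bisulfite conversion of the read's strand (every C to T). Count =
#' `max(0, L - read_len + 1) * n_strands * n_states`.
#'
#' @param numt_sequence The NUMT sequence as planted in the nuclear genome.
#' @param read_len Read length, default 300 (`>= 30`).
#' @param states Subset of `c("methylated", "unmethylated")`.
#' @param strands `"both"` (default) or `"top"`/`"bottom"`.
#' @return data.frame with `seq`, `state`, `strand`, `offset` (1-based
#'   start within the NUMT, on the enumerated strand).
#' @export
enumerate_numt_reads <- function(numt_sequence, read_len = 300L,
                                 states = c("methylated", "unmethylated"),
                                 strands = "both") {
  if (read_len < 30) stop("read_len must be >= 30")
  states <- match.arg(states, c("methylated", "unmethylated"),
                      several.ok = TRUE)
  strand_set <- switch(strands, both = c("top", "bottom"),
                       top = "top", bottom = "bottom",
                       stop("strands must be 'both', 'top' or 'bottom'"))
  L <- nchar(numt_sequence)
  n_off <- max(0L, L - read_len + 1L)
  if (n_off == 0L)
    return(data.frame(seq = character(0), state = character(0),
                      strand = character(0), offset = integer(0)))
  out <- list()
  for (strand in strand_set) {
    template <- if (strand == "top") numt_sequence
                else reverse_complement(numt_sequence)
    for (state in states) {
      s <- if (state == "unmethylated") chartr("C", "T", template)
           else template
      reads <- substring(s, 1:n_off, read_len:(read_len + n_off - 1L))
      out[[length(out) + 1L]] <- data.frame(
        seq = reads, state = state, strand = strand, offset = seq_len(n_off),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' NUMT contamination screen
#'
#' The contamination null experiment: enumerate every possible fixed-length
#' read from each planted NUMT (methylated and unmethylated copies, both
#' strands), realign them against the combined mitochondrial + nuclear
#' reference with the pipeline's unique-best-hit rule, and count where they
#' go. NUMT-derived reads assigned to the mitochondrial genome would
#' masquerade as mtDNA methylation; `mt_assigned == 0` is the pass
#' condition. Deterministic — no randomness anywhere.
#'
#' @param numts NUMT record data.frame from [plant_numts()].
#' @param mt_genome The mitochondrial [circular_genome()].
#' @param nuclear_genome The nuclear decoy [circular_genome()].
#' @param read_len Read length, default 300.
#' @param max_mismatches Aligner mismatch cap, default 5.
#' @return A `screen_report`: `total_reads`, `mt_assigned`,
#'   `nuclear_assigned`, `unmapped_or_ambiguous`, and `per_numt` breakdown.
#' @export
numt_screen <- function(numts, mt_genome, nuclear_genome, read_len = 300L,
                        max_mismatches = 5L) {
  index <- build_bisulfite_index(list(mt_genome, nuclear_genome),
                                 wrap = read_len + 10L)
  per <- lapply(seq_len(nrow(numts)), function(i) {
    numt_seq <- substr(nuclear_genome$sequence, numts$nuclear_start[i],
                       numts$nuclear_end[i] - 1L)
    reads <- enumerate_numt_reads(numt_seq, read_len)
    if (nrow(reads) == 0L)
      return(data.frame(name = numts$name[i], total = 0L, mt = 0L,
                        nuclear = 0L, other = 0L, stringsAsFactors = FALSE))
    assign <- vapply(reads$seq, function(s) {
      a <- align_single_core(s, index, max_mismatches)
      if (is.null(a) || !a$unique) "unmapped_or_ambiguous"
      else if (a$ref == mt_genome$name) "mt" else "nuclear"
    }, character(1), USE.NAMES = FALSE)
    data.frame(name = numts$name[i], total = nrow(reads),
               mt = sum(assign == "mt"), nuclear = sum(assign == "nuclear"),
               other = sum(assign == "unmapped_or_ambiguous"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(total_reads = sum(per$total), mt_assigned = sum(per$mt),
                 nuclear_assigned = sum(per$nuclear),
                 unmapped_or_ambiguous = sum(per$other), per_numt = per,
                 read_len = read_len),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf(
    "<screen_report> %d reads of %d bp: %d to mtDNA, %d to nuclear, %d unmapped/ambiguous\n",
    x$total_reads, x$read_len, x$mt_assigned, x$nuclear_assigned,
    x$unmapped_or_ambiguous))
  invisible(x)
}

#' In-silico PCR on a (bisulfite-converted) genome
#'
#' Checks primer specificity the way bisulfite primer design does: the
#' genome is fully converted per strand (`converted = TRUE`; every C to T on
#' the strand being primed), then products are reported wherever the
#' forward primer and the reverse primer hybridise convergently within
#' `max_product` bases, each with at most `max_mismatches` mismatches.
#'
#' @param primer_fwd,primer_rev Primer sequences, 5'->3', at least 15 nt.
#' @param genome A [circular_genome()].
#' @param converted Match against the bisulfite-converted genome (default
#'   TRUE).
#' @param max_mismatches Per-primer Hamming tolerance, default 0.
#' @param max_product Maximum product length, default 2000.
#' @return data.frame with `strand` (template strand primed by the forward
#'   primer), `start` (1-based position of the product on that template's
#'   coordinates, top-strand for `+`), `product_length`.
#' @export
insilico_pcr <- function(primer_fwd, primer_rev, genome, converted = TRUE,
                         max_mismatches = 0L, max_product = 2000L) {
  if (nchar(primer_fwd) < 15 || nchar(primer_rev) < 15)
    stop("primers must be >= 15 nt")
  primer_fwd <- toupper(primer_fwd); primer_rev <- toupper(primer_rev)
  hits <- list()
  for (strand in c("+", "-")) {
    template <- if (strand == "+") genome$sequence
                else reverse_complement(genome$sequence)
    if (converted) template <- chartr("C", "T", template)
    ext <- if (genome$circular)
      paste0(template, substr(template, 1L, max_product)) else template
    fpos <- hamming_matches(primer_fwd, ext, max_mismatches)
    rsite <- reverse_complement(primer_rev)
    rpos <- hamming_matches(rsite, ext, max_mismatches)
    if (!length(fpos) || !length(rpos)) next
    for (f in fpos) {
      if (f > nchar(template)) next   # wrap duplicate
      ends <- rpos + nchar(rsite) - 1L
      ok <- ends > f & (ends - f + 1L) <= max_product
      for (e in ends[ok]) {
        hits[[length(hits) + 1L]] <- data.frame(
          strand = strand, start = f, product_length = e - f + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(strand = character(0), start = integer(0),
                      product_length = integer(0)))
  out <- unique(do.call(rbind, hits))
  rownames(out) <- NULL
  out
}

# All 1-based start positions where `pattern` matches `subject` with at
# most `max_mm` mismatches.
hamming_matches <- function(pattern, subject, max_mm = 0L) {
  if (max_mm == 0L) {
    m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
    return(as.integer(m[m > 0]))
  }
  pr <- charToRaw(pattern)
  sr <- charToRaw(subject)
  n <- length(pr)
  if (length(sr) < n) return(integer(0))
  which(vapply(seq_len(length(sr) - n + 1L), function(p)
    sum(sr[p:(p + n - 1L)] != pr) <= max_mm, logical(1)))
}
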