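# Three-letter bisulfite mini-aligner for small (<= ~1 Mb) references.
#
# A read is compared to the reference in four collapsed "spaces", one per
# bisulfite read strand:
#   OT   : C->T(read)  vs C->T(reference, forward)
#   OB   : C->T(read)  vs C->T(reverse complement of reference)
#   CTOT : G->A(read)  vs G->A(reverse complement of reference)
#   CTOB : G->A(read)  vs G->A(reference, forward)
# Candidates come from exact k-mer seeding (k = 20, three seed offsets) in
# the collapsed space, verified by full Hamming distance; the unique best
# hit (margin >= 1 mismatch over the runner-up) is reported, else the read
# is unmapped/ambiguous. OT/CTOT alignments interrogate top-strand
# cytosines, OB/CTOB bottom-strand cytosines.

collapse_ct <- function(s) chartr("C", "T", s)
collapse_ga <- function(s) chartr("G", "A", s)

MAX_REFERENCE_BP <- 1e6

#' Build a bisulfite alignment index over small references
#'
#' @param genomes A [circular_genome()], or a list of them (e.g.
#'   mitochondrial plus a nuclear decoy). Total length must not exceed
#'   1 Mb; this is a desk-scale mini-aligner — use an external bisulfite
#'   mapper for full genomes.
#' @param k Seed k-mer length (collapsed space), default 20.
#' @param wrap Extra wrap-around bases indexed for circular references;
#'   must cover the longest expected read. Default 200.
#' @return A `bs_index` object.
#' @export
build_bisulfite_index <- function(genomes, k = 20L, wrap = 200L) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  total <- sum(vapply(genomes, function(g) g$length, numeric(1)))
  if (total > MAX_REFERENCE_BP)
    stop("combined reference exceeds the mini-aligner's 1 Mb limit; ",
         "use an external bisulfite mapper for large genomes")
  refs <- lapply(genomes, function(g) {
    L <- g$length
    W <- if (g$circular) min(wrap, L - 1L) else 0L
    fwd <- if (W > 0) paste0(g$sequence, substr(g$sequence, 1L, W)) else g$sequence
    rc0 <- reverse_complement(g$sequence)
    rev <- if (W > 0) paste0(rc0, substr(rc0, 1L, W)) else rc0
    spaces <- list(
      OT   = collapse_ct(fwd),   # read CT vs fwd CT
      CTOB = collapse_ga(fwd),   # read GA vs fwd GA
      OB   = collapse_ct(rev),   # read CT vs rev CT
      CTOT = collapse_ga(rev)    # read GA vs rev GA
    )
    idx <- lapply(spaces, function(s) {
      n <- nchar(s)
      if (n < k) return(new.env(parent = emptyenv()))
      kmers <- substring(s, 1:(n - k + 1L), k:n)
      list2env(split(seq_len(n - k + 1L), kmers), parent = emptyenv())
    })
    raws <- lapply(spaces, charToRaw)
    list(name = g$name, length = L, circular = g$circular, wrap = W,
         idx = idx, raws = raws, sequence = g$sequence)
  })
  names(refs) <- vapply(refs, `[[`, character(1), "name")
  structure(list(refs = refs, k = k), class = "bs_index")
}

# Align one read in one space of one reference; returns hits as a list of
# parallel vectors (pos, mism), or NULL. pos is 1-based in the (possibly
# wrap-extended) space string.
space_hits <- function(read_collapsed, read_raw, ref, space, k, max_mm) {
  env <- ref$idx[[space]]
  n <- length(read_raw)
  if (n < k) return(NULL)
  offs <- c(1L, 1L + k, 1L + 2L * k)
  offs <- unique(offs[offs <= n - k + 1L])
  if (!length(offs)) offs <- n - k + 1L
  cand <- integer(0)
  for (o in offs) {
    seed <- substr(read_collapsed, o, o + k - 1L)
    hit <- get0(seed, envir = env, ifnotfound = NULL)
    if (!is.null(hit)) cand <- c(cand, hit - o + 1L)
  }
  if (!length(cand)) return(NULL)
  cand <- unique.default(cand[cand >= 1L])
  sref <- ref$raws[[space]]
  cand <- cand[cand + n - 1L <= length(sref)]
  if (!length(cand)) return(NULL)
  mm <- integer(length(cand))
  for (j in seq_along(cand)) {
    p <- cand[j]
    mm[j] <- sum(sref[p:(p + n - 1L)] != read_raw)
  }
  ok <- mm <= max_mm
  if (!any(ok)) return(NULL)
  list(pos = cand[ok], mism = mm[ok])
}

# Map a space position to the top-strand start of the covered segment.
space_to_genome <- function(pos_space, read_len, space, ref) {
  L <- ref$length
  if (space %in% c("OT", "CTOB")) {
    s <- ((pos_space - 1L) %% L) + 1L
  } else {
    # position in reverse-complement coordinates; covered rc segment
    # [p, p+n) maps to forward segment starting at L - p - n + 2
    p <- ((pos_space - 1L) %% L) + 1L
    s <- L - p - read_len + 2L
    s <- ((s - 1L) %% L) + 1L
  }
  s
}

#' Align a single read (all four bisulfite spaces, all references)
#'
#' @param seq Read sequence.
#' @param index A [build_bisulfite_index()].
#' @param max_mismatches Maximum collapsed-space mismatches, default 5.
#' @return One-row data.frame: `ref`, `start` (top-strand, 1-based),
#'   `length`, `bs_strand`, `mism`, `unique`, `mapped`. Unmapped or
#'   ambiguous reads have `mapped = FALSE` (`unique = FALSE` when the tie
#'   caused it).
#' @export
align_single <- function(seq, index, max_mismatches = 5L) {
  a <- align_single_core(seq, index, max_mismatches)
  if (is.null(a)) {
    return(data.frame(ref = NA_character_, start = NA_integer_,
                      length = nchar(seq), bs_strand = NA_character_,
                      mism = NA_integer_, unique = FALSE, mapped = FALSE))
  }
  data.frame(ref = a$ref, start = a$start, length = nchar(seq),
             bs_strand = a$space, mism = a$mism, unique = a$unique,
             mapped = a$unique)
}

# Core search; returns NULL when no hit within max_mismatches, else a list
# (ref, start, space, mism, unique). Equal-score hits at the *same* genomic
# locus under different strand interpretations (e.g. a fully unconverted
# read, identical in the OT and CTOB spaces) are position-unique: they are
# reported at that locus with a fixed strand priority (OT, OB, CTOT, CTOB).
# Equal-score hits at different loci make the read ambiguous (not unique).
align_single_core <- function(seq, index, max_mismatches = 5L) {
  n <- nchar(seq)
  read_ct <- collapse_ct(seq)
  read_ga <- collapse_ga(seq)
  raw_ct <- charToRaw(read_ct)
  raw_ga <- charToRaw(read_ga)
  h_ref <- character(0); h_start <- integer(0); h_space <- character(0)
  h_mm <- integer(0)
  for (ref in index$refs) {
    for (space in c("OT", "OB", "CTOT", "CTOB")) {
      ct_space <- space %in% c("OT", "OB")
      h <- space_hits(if (ct_space) read_ct else read_ga,
                      if (ct_space) raw_ct else raw_ga,
                      ref, space, index$k, max_mismatches)
      if (is.null(h)) next
      # collapse wrap duplicates of the same genomic start
      st <- space_to_genome(h$pos, n, space, ref)
      keep <- !duplicated(st)
      st <- st[keep]
      h_ref <- c(h_ref, rep(ref$name, length(st)))
      h_start <- c(h_start, st)
      h_space <- c(h_space, rep(space, length(st)))
      h_mm <- c(h_mm, h$mism[keep])
    }
  }
  if (!length(h_mm)) return(NULL)
  best_mm <- min(h_mm)
  b <- h_mm == best_mm
  loci <- paste(h_ref[b], h_start[b])
  uniq <- length(unique(loci)) == 1L   # integer scores: margin >= 1 implied
  pick <- which(b)[order(match(h_space[b], c("OT", "OB", "CTOT", "CTOB")))][1]
  list(ref = h_ref[pick], start = h_start[pick], space = h_space[pick],
       mism = best_mm, unique = uniq)
}

#' Trim read heads (bias removal)
#'
#' Removes the first `n_head` bases and quality characters from each mate
#' (10 for whole-genome libraries, 2 for targeted amplicons). Pairs in which
#' either mate would fall below `n_head + 20` bases are dropped.
#'
#' @param reads Read-pair data.frame.
#' @param n_head Number of 5' bases to remove (`>= 0`).
#' @return The trimmed read-pair data.frame.
#' @export
trim_heads <- function(reads, n_head) {
  stopifnot(n_head >= 0)
  if (n_head == 0) return(reads)
  keep <- nchar(reads$read1) >= n_head + 20L & nchar(reads$read2) >= n_head + 20L
  reads <- reads[keep, , drop = FALSE]
  reads$read1 <- substring(reads$read1, n_head + 1L)
  reads$read2 <- substring(reads$read2, n_head + 1L)
  reads$qual1 <- substring(reads$qual1, n_head + 1L)
  reads$qual2 <- substring(reads$qual2, n_head + 1L)
  rownames(reads) <- NULL
  reads
}

#' Align read pairs with the bisulfite mini-aligner
#'
#' Mates are aligned independently and must be concordant: same reference,
#' interrogating the same strand (OT pairs with CTOT, OB with CTOB),
#' with a fragment span no longer than `max_insert`. The pair's
#' `bs_strand` is read 1's space.
#'
#' @param reads Read-pair data.frame (post-trimming).
#' @param index A [build_bisulfite_index()].
#' @param max_mismatches Per-mate collapsed-space mismatch cap, default 5.
#' @param max_insert Maximum fragment span, default 1000.
#' @return data.frame with one row per input pair: mate coordinates
#'   (`start1`, `len1`, `space1`, `bases1`, idem mate 2), fragment
#'   coordinates (`fstart`, `fend`), `bs_strand`, `mism`, `unique`,
#'   `mapped` (mapped means both mates unique and concordant).
#' @export
align_bisulfite <- function(reads, index, max_mismatches = 5L,
                            max_insert = 1000L) {
  n <- nrow(reads)
  ref <- character(n); start1 <- integer(n); len1 <- integer(n)
  space1 <- character(n); start2 <- integer(n); len2 <- integer(n)
  space2 <- character(n); mism <- integer(n)
  fstart <- rep(NA_integer_, n); fend <- rep(NA_integer_, n)
  uniq <- logical(n); mapped <- logical(n)
  for (i in seq_len(n)) {
    a1 <- align_single_core(reads$read1[i], index, max_mismatches)
    a2 <- align_single_core(reads$read2[i], index, max_mismatches)
    ref[i] <- if (is.null(a1)) NA_character_ else a1$ref
    start1[i] <- if (is.null(a1)) NA_integer_ else a1$start
    len1[i] <- nchar(reads$read1[i])
    space1[i] <- if (is.null(a1)) NA_character_ else a1$space
    start2[i] <- if (is.null(a2)) NA_integer_ else a2$start
    len2[i] <- nchar(reads$read2[i])
    space2[i] <- if (is.null(a2)) NA_character_ else a2$space
    mism[i] <- if (is.null(a1) || is.null(a2)) NA_integer_ else a1$mism + a2$mism
    uniq[i] <- !is.null(a1) && !is.null(a2) && a1$unique && a2$unique
    if (!is.null(a1) && !is.null(a2) && a1$unique && a2$unique &&
        identical(a1$ref, a2$ref)) {
      g1 <- a1$space %in% c("OT", "CTOT")
      g2 <- a2$space %in% c("OT", "CTOT")
      if (g1 == g2) {
        L <- index$refs[[a1$ref]]$length
        s1 <- a1$start; s2 <- a2$start
        # unwrap: place s2 on the same circular arc as s1
        if (index$refs[[a1$ref]]$circular) {
          if (s2 - s1 > L / 2) s2 <- s2 - L
          if (s1 - s2 > L / 2) s2 <- s2 + L
        }
        fs <- min(s1, s2)
        fe <- max(s1 + len1[i], s2 + len2[i])
        if (fe - fs <= max_insert && fe - fs >= len1[i]) {
          fstart[i] <- ((fs - 1L) %% L) + 1L
          fend[i] <- fstart[i] + (fe - fs)
          mapped[i] <- TRUE
        }
      }
    }
  }
  data.frame(read_id = reads$read_id, ref = ref, start1 = start1,
             len1 = len1, space1 = space1, start2 = start2, len2 = len2,
             space2 = space2, mism = mism, fstart = fstart, fend = fend,
             bs_strand = space1, unique = uniq, mapped = mapped,
             stringsAsFactors = FALSE)
}

#' Remove presumed PCR duplicates
#'
#' Keeps one representative alignment per key (reference, fragment start,
#' fragment end, bisulfite strand). Idempotent. Applied only to
#' whole-genome libraries — amplicon reads are expected to stack.
#'
#' @param alignments Pair-alignment data.frame from [align_bisulfite()]
#'   (unmapped rows are kept as-is).
#' @return De-duplicated alignment data.frame.
#' @export
deduplicate <- function(alignments) {
  mapped <- alignments$mapped
  key <- paste(alignments$ref, alignments$fstart, alignments$fend,
               alignments$bs_strand, sep = ":")
  keep <- !mapped | !duplicated(key)
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
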