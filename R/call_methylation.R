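#' Classify cytosine context (CpG / CHG / CHH)
#'
#' Context is set by the two bases downstream of the cytosine on its own
#' strand: `CG*` is CpG, `C-H-G` is CHG, `C-H-H` is CHH (H = A, C or T).
#' Circular genomes wrap; on linear genomes, missing downstream bases are
#' N-padded and classified CHH.
#'
#' @param genome A [circular_genome()].
#' @param position Integer vector of 1-based positions.
#' @param strand Strand vector (`"+"`/`"-"`), recycled to match positions.
#' @return data.frame with `position`, `strand`, `context`, `trinucleotide`.
#'   Errors if any position is not a cytosine on the stated strand.
#' @export
classify_context <- function(genome, position, strand = "+") {
  n <- max(length(position), length(strand))
  position <- rep_len(position, n)
  strand <- rep_len(strand, n)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  L <- genome$length
  base_at <- function(pos) {
    # downstream offsets may run off linear ends -> N
    ok <- pos >= 1L & pos <= L
    out <- rep("N", length(pos))
    if (genome$circular) {
      out <- chars[((pos - 1L) %% L) + 1L]
    } else {
      out[ok] <- chars[pos[ok]]
    }
    out
  }
  is_top <- strand == "+"
  here <- ifelse(is_top, chars[pmin(position, L)], chars[pmin(position, L)])
  bad <- (is_top & here != "C") | (!is_top & here != "G")
  if (any(bad))
    stop(sprintf("position %d is not a cytosine on strand %s",
                 position[which(bad)[1]], strand[which(bad)[1]]))
  p1 <- ifelse(is_top, position + 1L, position - 1L)
  p2 <- ifelse(is_top, position + 2L, position - 2L)
  b1 <- base_at(p1); b2 <- base_at(p2)
  # on the minus strand, read downstream bases as their complements
  b1[!is_top] <- chartr("ACGTN", "TGCAN", b1[!is_top])
  b2[!is_top] <- chartr("ACGTN", "TGCAN", b2[!is_top])
  context <- ifelse(b1 == "G", "CpG", ifelse(b2 == "G", "CHG", "CHH"))
  data.frame(position = position, strand = strand, context = context,
             trinucleotide = paste0("C", b1, b2), stringsAsFactors = FALSE)
}

#' Call per-cytosine methylation from aligned read pairs
#'
#' For every cytosine of the reference (both strands, all contexts), counts
#' read bases supporting the methylated call (C) and the unmethylated call
#' (T, i.e. converted). OT/CTOT alignments interrogate top-strand
#' cytosines; OB/CTOB alignments interrogate bottom-strand cytosines (read
#' G = methylated, A = converted, in top-strand orientation). Other bases
#' (sequencing error) are ignored. Where mates overlap, only read 1's base
#' is counted. Zero-coverage cytosines are emitted with counts 0/0.
#'
#' @param alignments Pair alignments from [align_bisulfite()] (typically
#'   after [deduplicate()] for whole-genome libraries).
#' @param reads The read-pair data.frame the alignments refer to (matched
#'   by `read_id`).
#' @param genome The reference [circular_genome()].
#' @return Cytosine-report data.frame: `chrom`, `position`, `strand`,
#'   `count_methylated`, `count_unmethylated`, `context`, `trinucleotide`,
#'   plus convenience columns `coverage` and `methylation_percent`.
#' @export
call_methylation <- function(alignments, reads, genome) {
  L <- genome$length
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  is_c <- chars == "C"
  is_g <- chars == "G"
  al <- alignments[alignments$mapped & alignments$ref == genome$name, ,
                   drop = FALSE]
  rd <- reads[match(al$read_id, reads$read_id), , drop = FALSE]

  acc <- list(mt = vector("list", nrow(al)), ut = vector("list", nrow(al)),
              mb = vector("list", nrow(al)), ub = vector("list", nrow(al)))

  mate_calls <- function(seqchars, gstart, space, exclude_pos = NULL) {
    len <- length(seqchars)
    pos <- ((gstart - 1L + 0:(len - 1L)) %% L) + 1L
    full_pos <- pos
    if (!is.null(exclude_pos)) {
      keep <- !(pos %in% exclude_pos)
      pos <- pos[keep]; seqchars <- seqchars[keep]
    }
    if (space %in% c("OT", "CTOT")) {
      sel <- is_c[pos]
      p <- pos[sel]; b <- seqchars[sel]
      list(m = p[b == "C"], u = p[b == "T"], top = TRUE, pos = full_pos)
    } else {
      sel <- is_g[pos]
      p <- pos[sel]; b <- seqchars[sel]
      list(m = p[b == "G"], u = p[b == "A"], top = FALSE, pos = full_pos)
    }
  }

  for (i in seq_len(nrow(al))) {
    # express each mate's bases in top-strand orientation
    c1 <- mate_calls(oriented_bases(rd$read1[i], al$space1[i]),
                     oriented_start(al$start1[i], al$len1[i], al$space1[i]),
                     al$space1[i])
    c2 <- mate_calls(oriented_bases(rd$read2[i], al$space2[i]),
                     oriented_start(al$start2[i], al$len2[i], al$space2[i]),
                     al$space2[i], exclude_pos = c1$pos)
    for (cc in list(c1, c2)) {
      if (cc$top) {
        acc$mt[[i]] <- c(acc$mt[[i]], cc$m); acc$ut[[i]] <- c(acc$ut[[i]], cc$u)
      } else {
        acc$mb[[i]] <- c(acc$mb[[i]], cc$m); acc$ub[[i]] <- c(acc$ub[[i]], cc$u)
      }
    }
  }
  tab0 <- function(v) tabulate(as.integer(unlist(v)), L)
  meth_top <- tab0(acc$mt)
  unmeth_top <- tab0(acc$ut)
  meth_bot <- tab0(acc$mb)
  unmeth_bot <- tab0(acc$ub)

  top_pos <- which(is_c); bot_pos <- which(is_g)
  ctx_top <- if (length(top_pos)) classify_context(genome, top_pos, "+") else NULL
  ctx_bot <- if (length(bot_pos)) classify_context(genome, bot_pos, "-") else NULL
  rec <- rbind(
    if (!is.null(ctx_top)) data.frame(
      chrom = genome$name, position = top_pos, strand = "+",
      count_methylated = meth_top[top_pos],
      count_unmethylated = unmeth_top[top_pos],
      context = ctx_top$context, trinucleotide = ctx_top$trinucleotide,
      stringsAsFactors = FALSE),
    if (!is.null(ctx_bot)) data.frame(
      chrom = genome$name, position = bot_pos, strand = "-",
      count_methylated = meth_bot[bot_pos],
      count_unmethylated = unmeth_bot[bot_pos],
      context = ctx_bot$context, trinucleotide = ctx_bot$trinucleotide,
      stringsAsFactors = FALSE))
  rec <- rec[order(rec$position, rec$strand), , drop = FALSE]
  rownames(rec) <- NULL
  add_methylation_percent(rec)
}

# Bases of a mate in top-strand orientation: reads aligned in the
# reverse-complement spaces (OB, CTOT) are reverse-complemented.
oriented_bases <- function(seq, space) {
  if (space %in% c("OB", "CTOT")) seq <- reverse_complement(seq)
  strsplit(seq, "", fixed = TRUE)[[1]]
}

# `start` reported by the aligner is already the top-strand start of the
# covered segment in every space.
oriented_start <- function(start, len, space) start
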