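#' Bisulfite conversion model
#'
#' Conversion failure probabilities: an unmethylated, unprotected cytosine
#' escapes conversion (reads as C) with probability `epsilon0`; inside an
#' active protected window the failure probability rises to `epsilon_prot`
#' (structure blocks bisulfite access); a methylated cytosine is
#' over-converted (reads as T) with probability `delta`.
#'
#' @param epsilon0 Baseline conversion failure, default 0.01 (a realistic
#'   kit-level unconversion rate; the background signal of digested DNA).
#' @param epsilon_prot Conversion failure inside active protected windows,
#'   default 0.30. Must satisfy `epsilon0 <= epsilon_prot`.
#' @param delta Over-conversion probability of methylated cytosines,
#'   default 0.
#' @param seq_error Uniform sequencing substitution rate applied to final
#'   reads, default 0 (off).
#' @return A `conversion_model` object.
#' @export
conversion_model <- function(epsilon0 = 0.01, epsilon_prot = 0.30,
                             delta = 0, seq_error = 0) {
  stopifnot(epsilon0 >= 0, epsilon_prot <= 1, delta >= 0, delta <= 1,
            seq_error >= 0, seq_error < 1)
  if (epsilon0 > epsilon_prot)
    stop("epsilon_prot must be >= epsilon0 (protection can only hinder conversion)")
  structure(list(epsilon0 = epsilon0, epsilon_prot = epsilon_prot,
                 delta = delta, seq_error = seq_error),
            class = "conversion_model")
}

#' Fragment a molecule population by simulated sonication
#'
#' Candidate fragments are drawn uniformly over molecule coordinates with
#' normally distributed lengths (truncated at `min_len`). A candidate that
#' overlaps any active protected window of its (supercoiled, undigested)
#' parent is released with probability `release_penalty` — shear protection
#' by the supercoiled structure. Circular parents may yield origin-spanning
#' fragments; digested (linear) parents never span the cut.
#'
#' @param population A [make_population()] result.
#' @param target_fragment_count Number of fragments to return (`> 0`).
#' @param mean_len,sd_len Fragment length distribution (bp); defaults 300/60.
#' @param min_len Truncation floor, default 50 bp.
#' @param read_len Configured read length, used only to warn when
#'   `mean_len < 2 * read_len` is not met (mates would always overlap).
#' @param seed Integer seed.
#' @return data.frame of fragments: `molecule`, `topology`, `protected`
#'   (parent carries active windows), `start` (1-based), `length`.
#' @export
fragment_population <- function(population, target_fragment_count,
                                mean_len = 300, sd_len = 60, min_len = 50L,
                                read_len = 150L, seed = 1L) {
  if (target_fragment_count <= 0) stop("target_fragment_count must be > 0")
  if (mean_len < 2 * read_len)
    warning("mean fragment length below twice the read length; mates will overlap")
  L <- population$genome_length
  mol <- population$molecules
  model <- population$model
  mask <- protection_mask(model, L)
  rho <- model$release_penalty
  cut <- population$cut_position
  digested <- population$digested

  out <- vector("list", 0L)
  got <- 0L
  withr_seed(seed, {
    while (got < target_fragment_count) {
      nb <- max(2L * (target_fragment_count - got), 2000L)
      idx <- sample.int(nrow(mol), nb, replace = TRUE)
      len <- pmax(min_len, as.integer(round(stats::rnorm(nb, mean_len, sd_len))))
      len <- pmin(len, L)
      start <- sample.int(L, nb, replace = TRUE)
      keep <- rep(TRUE, nb)
      if (digested && !is.na(cut)) {
        # linearized at `cut`: fragment must not cross the cut point
        rel <- ((start - cut) %% L)
        keep <- keep & (rel + len <= L)
      } else {
        # undigested: all topologies sampled circularly
      }
      prot_parent <- mol$protected[idx]
      if (any(prot_parent) && rho < 1) {
        # vectorised circular overlap via cumulative protection counts
        cm <- cumsum(mask)
        endp <- start + len - 1L
        wraps <- endp > L
        inwin <- integer(nb)
        nw <- !wraps
        inwin[nw] <- cm[endp[nw]] - cm[start[nw]] + mask[start[nw]]
        if (any(wraps)) {
          w <- which(wraps)
          inwin[w] <- (cm[L] - cm[start[w]] + mask[start[w]]) +
            cm[endp[w] - L]
        }
        ov <- prot_parent & keep & inwin > 0L
        drop <- ov & (stats::runif(nb) >= rho)
        keep <- keep & !drop
      }
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          molecule = mol$id[idx[keep]], topology = mol$topology[idx[keep]],
          protected = prot_parent[keep], start = start[keep],
          length = len[keep], stringsAsFactors = FALSE)
        got <- got + sum(keep)
      }
    }
  })
  frags <- do.call(rbind, out)
  frags <- frags[seq_len(target_fragment_count), , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

#' In-silico bisulfite conversion of one double-stranded fragment
#'
#' Converts both strands of a fragment independently. Per cytosine: the
#' methylation state is drawn from its probability; a methylated C reads C
#' with probability `1 - delta`, else T; an unmethylated C reads T with
#' probability `1 - eps` (where `eps` is `epsilon_prot` if the position is
#' protected, else `epsilon0`), else stays C. Gs of the top strand are the
#' Cs of the bottom strand and are handled there. Non-cytosines are never
#' altered and sequence length is preserved.
#'
#' @param sequence Top-strand fragment sequence (5'->3').
#' @param meth_prob_top,meth_prob_bottom Per-base methylation probabilities
#'   aligned to `sequence` positions (top: at C positions; bottom: at G
#'   positions; other entries ignored/NA).
#' @param protected Logical per-base protection flags aligned to `sequence`.
#' @param model A [conversion_model()].
#' @param seed Optional integer seed; when `NULL` (the default) the current
#'   RNG stream is used, as when called from [generate_reads()].
#' @return List with `top` and `bottom` converted strands, both written
#'   5'->3' (`bottom` is the converted reverse complement).
#' @export
bisulfite_convert <- function(sequence, meth_prob_top, meth_prob_bottom,
                              protected, model, seed = NULL) {
  if (!is.null(seed))
    return(withr_seed(seed, bisulfite_convert(sequence, meth_prob_top,
                                              meth_prob_bottom, protected,
                                              model)))
  n <- nchar(sequence)
  stopifnot(length(meth_prob_top) == n, length(meth_prob_bottom) == n,
            length(protected) == n)
  list(top = convert_one_strand(sequence, meth_prob_top, protected, model,
                                top = TRUE),
       bottom = convert_one_strand(sequence, meth_prob_bottom, protected,
                                   model, top = FALSE))
}

#' Generate paired-end reads from converted fragments
#'
#' Directional libraries emit OT/OB pairs (the two original converted
#' strands, each with probability 1/2); non-directional libraries
#' additionally emit their PCR complements CTOT/CTOB, all four with equal
#' probability. Read 1 and read 2 are taken from opposite ends of the
#' converted fragment; fragments shorter than `read_len` yield truncated
#' reads. Qualities are constant Phred 37 (`"F"`).
#'
#' @param fragments Fragment data.frame from [fragment_population()].
#' @param genome The source [circular_genome()].
#' @param methylome A [generate_methylome()] truth object.
#' @param population The [make_population()] the fragments came from (for
#'   the protection mask).
#' @param model A [conversion_model()].
#' @param read_len Read length, default 150 (`>= 30`).
#' @param directional Logical, default `TRUE`.
#' @param duplicate_fraction Fraction of pairs emitted twice as exact
#'   copies (PCR duplicates; used to exercise deduplication). Default 0.
#' @param seed Integer seed.
#' @return Read-pair data.frame: `read_id` (truth tag
#'   `id:start:fraglen:bs:topology`), `read1`, `qual1`, `read2`, `qual2`,
#'   `bs_strand`, plus truth columns `truth_start`, `truth_len`,
#'   `truth_topology`.
#' @export
generate_reads <- function(fragments, genome, methylome, population, model,
                           read_len = 150L, directional = TRUE,
                           duplicate_fraction = 0, seed = 1L) {
  if (read_len < 30) stop("read_len must be >= 30")
  L <- genome$length
  mask <- protection_mask(population$model, L)
  n <- nrow(fragments)
  withr_seed(seed, {
    tags <- if (directional) {
      sample(c("OT", "OB"), n, replace = TRUE)
    } else {
      sample(c("OT", "OB", "CTOT", "CTOB"), n, replace = TRUE)
    }
    r1 <- character(n); r2 <- character(n)
    for (i in seq_len(n)) {
      st <- fragments$start[i]; fl <- fragments$length[i]
      pos <- ((st - 1L + 0:(fl - 1L)) %% L) + 1L
      seq <- circular_subseq(genome, st, fl)
      prot <- if (fragments$protected[i]) mask[pos] else rep(FALSE, fl)
      rl <- min(read_len, fl)
      # convert only the template strand the pair is sequenced from
      top_strand <- tags[i] %in% c("OT", "CTOT")
      template <- convert_one_strand(
        seq, if (top_strand) methylome$top[pos] else methylome$bottom[pos],
        prot, model, top = top_strand)
      first <- substr(template, 1L, rl)
      last_rc <- reverse_complement(substr(template, fl - rl + 1L, fl))
      if (tags[i] %in% c("OT", "OB")) {
        r1[i] <- first; r2[i] <- last_rc
      } else {              # PCR complement: read 1 from the synthesized strand
        r1[i] <- last_rc; r2[i] <- first
      }
    }
    if (model$seq_error > 0) {
      r1 <- apply_seq_error(r1, model$seq_error)
      r2 <- apply_seq_error(r2, model$seq_error)
    }
    reads <- data.frame(
      read_id = sprintf("frag%06d:%d:%d:%s:%s", seq_len(n), fragments$start,
                        fragments$length, tags, fragments$topology),
      read1 = r1, qual1 = strrep("F", nchar(r1)),
      read2 = r2, qual2 = strrep("F", nchar(r2)),
      bs_strand = tags, truth_start = fragments$start,
      truth_len = fragments$length, truth_topology = fragments$topology,
      stringsAsFactors = FALSE)
    if (duplicate_fraction > 0) {
      dup <- which(stats::runif(n) < duplicate_fraction)
      if (length(dup)) reads <- rbind(reads, reads[dup, , drop = FALSE])
    }
  })
  rownames(reads) <- NULL
  reads
}

# Convert one strand of a top-strand fragment sequence; returns the
# converted strand 5'->3' (for top = FALSE, the converted reverse
# complement). Probabilities/protection are indexed in top-strand
# orientation. Uses the current RNG stream.
convert_one_strand <- function(sequence, probs, prot, model, top = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  c_idx <- which(chars == if (top) "C" else "G")
  if (length(c_idx)) {
    pr <- probs[c_idx]
    pr[is.na(pr)] <- 0
    methylated <- stats::runif(length(c_idx)) < pr
    eps <- ifelse(prot[c_idx], model$epsilon_prot, model$epsilon0)
    u <- stats::runif(length(c_idx))
    call <- ifelse(methylated,
                   ifelse(u < model$delta, "T", "C"),
                   ifelse(u < eps, "C", "T"))
  }
  if (top) {
    out <- chars
    if (length(c_idx)) out[c_idx] <- call
    paste0(out, collapse = "")
  } else {
    out <- chartr("ACGTN", "TGCAN", chars)   # complement, top orientation
    if (length(c_idx)) out[c_idx] <- call
    intToUtf8(rev(utf8ToInt(paste0(out, collapse = ""))))
  }
}

# Uniform substitution errors at the given rate.
apply_seq_error <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit))
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' One-call simulator: population to paired reads
#'
#' Convenience wrapper chaining [fragment_population()],
#' [bisulfite_convert()] (per fragment) and [generate_reads()] under a
#' single seed.
#'
#' @inheritParams generate_reads
#' @inheritParams fragment_population
#' @param n_fragments Number of fragments to simulate.
#' @return The read-pair data.frame, with the fragment table attached as
#'   attribute `"fragments"`.
#' @export
simulate_bisulfite_reads <- function(genome, methylome, population, model,
                                     n_fragments, mean_len = 300, sd_len = 60,
                                     read_len = 150L, directional = TRUE,
                                     duplicate_fraction = 0, seed = 1L) {
  frags <- fragment_population(population, n_fragments, mean_len = mean_len,
                               sd_len = sd_len, read_len = read_len,
                               seed = seed)
  reads <- generate_reads(frags, genome, methylome, population, model,
                          read_len = read_len, directional = directional,
                          duplicate_fraction = duplicate_fraction,
                          seed = seed + 1L)
  attr(reads, "fragments") <- frags
  reads
}
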