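#' Generate a random circular genome
#'
#' Bases are drawn i.i.d. with the requested GC fraction (split evenly
#' between G and C, and between A and T), so composition matches
#' `gc_fraction` in expectation.
#'
#' @param length Genome length in bp (`>= 100`).
#' @param gc_fraction GC content in `[0, 1]`; default 0.44, the approximate
#'   GC content of human mtDNA.
#' @param seed Integer seed; generation is bit-reproducible.
#' @param name Sequence name.
#' @param circular Topology flag.
#' @return A [circular_genome()].
#' @export
generate_genome <- function(length, gc_fraction = 0.44, seed = 1L,
                            name = "synthetic_mt", circular = TRUE) {
  if (length < 100) stop("length must be >= 100")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction outside [0,1]")
  withr_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                             gc_fraction / 2, (1 - gc_fraction) / 2))
  })
  circular_genome(name, paste0(bases, collapse = ""), circular = circular)
}

# Run code under a local RNG seed without disturbing the caller's RNG state.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic mtDNA-like genome with a single restriction site
#'
#' A random genome in which every spurious occurrence of the enzyme's
#' recognition sequence is ablated (one base substituted) and one site is
#' planted at `site_position`, mimicking the single BamHI site of human
#' mtDNA used to linearize the molecule.
#'
#' @param length Genome length; default 16,569 bp (human mtDNA length).
#' @param gc_fraction GC content; default 0.44.
#' @param enzyme A [restriction_enzyme()]; default [bamhi()].
#' @param site_position Where to plant the unique site; default 14258, the
#'   rCRS coordinate of the BamHI site.
#' @param seed Integer seed.
#' @return A circular [circular_genome()] with exactly one enzyme site.
#' @export
simulate_mtdna_genome <- function(length = 16569L, gc_fraction = 0.44,
                                  enzyme = bamhi(), site_position = 14258L,
                                  seed = 1L) {
  g <- generate_genome(length, gc_fraction, seed)
  rec <- enzyme$recognition
  k <- nchar(rec)
  if (site_position + k - 1L > length) stop("site_position too close to end")
  seq <- g$sequence
  # plant the site first, then break all other occurrences
  substr(seq, site_position, site_position + k - 1L) <- rec
  mid <- (k %/% 2L) + 1L
  repeat {
    gg <- circular_genome(g$name, seq, circular = TRUE)
    sites <- find_sites(gg, enzyme)
    extra <- setdiff(sites, site_position)
    if (length(extra) == 0L) break
    for (p in extra) {
      pos <- ((p + mid - 2L) %% length) + 1L
      cur <- substr(seq, pos, pos)
      repl <- setdiff(c("A", "T", "G", "C"), c(cur, substr(rec, mid, mid)))[1]
      substr(seq, pos, pos) <- repl
    }
  }
  gg
}

#' True methylome for a genome
#'
#' Per-position, per-strand methylation probabilities, defined exactly at
#' cytosines: top-strand entries where the reference base is C, bottom-strand
#' entries where it is G. Non-cytosine positions are `NA`.
#'
#' @param genome A [circular_genome()].
#' @param mode `"all_zero"` (the default: no true methylation anywhere),
#'   `"uniform"` (constant probability `p` at every cytosine) or
#'   `"site_list"` (zero everywhere except listed sites).
#' @param p Methylation probability for `mode = "uniform"`.
#' @param sites For `mode = "site_list"`: data.frame with columns `position`,
#'   `strand` (`"+"`/`"-"`) and `p`. A listed position that is not a cytosine
#'   on the stated strand is an error.
#' @return A `methylome` object: list with numeric vectors `top` and
#'   `bottom` of genome length.
#' @export
generate_methylome <- function(genome, mode = c("all_zero", "uniform",
                                                "site_list"),
                               p = 0, sites = NULL) {
  mode <- match.arg(mode)
  base <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  top <- ifelse(base == "C", 0, NA_real_)
  bottom <- ifelse(base == "G", 0, NA_real_)
  if (mode == "uniform") {
    if (p < 0 || p > 1) stop("p outside [0,1]")
    top[base == "C"] <- p
    bottom[base == "G"] <- p
  } else if (mode == "site_list") {
    if (is.null(sites)) stop("mode 'site_list' requires a sites data.frame")
    for (i in seq_len(nrow(sites))) {
      pos <- sites$position[i]; str <- sites$strand[i]; pp <- sites$p[i]
      if (pp < 0 || pp > 1) stop("site probability outside [0,1]")
      if (str == "+") {
        if (base[pos] != "C")
          stop(sprintf("position %d is not a C on the + strand", pos))
        top[pos] <- pp
      } else {
        if (base[pos] != "G")
          stop(sprintf("position %d is not a C on the - strand", pos))
        bottom[pos] <- pp
      }
    }
  }
  structure(list(top = top, bottom = bottom, genome_name = genome$name),
            class = "methylome")
}

#' Topology model for a molecule population
#'
#' The causal variable of the artifact: a fraction of genome copies is
#' supercoiled, and supercoiled copies carry protected windows in which
#' bisulfite conversion fails at an elevated rate and from which sonication
#' fragments are released with a penalty.
#'
#' @param supercoiled_fraction Proportion of copies that are supercoiled,
#'   in `[0, 1]`. Default 0.5.
#' @param protected_windows List of [genomic_interval()]s active on
#'   supercoiled copies. Default: one window over the control-region analog
#'   (rCRS-like D-loop coordinates 16024..576, wrapping the origin of a
#'   16,569 bp genome).
#' @param release_penalty Probability (`rho`) that a sonication fragment
#'   overlapping an active protected window is released. Default 0.2.
#' @return A `topology_model` object.
#' @export
topology_model <- function(supercoiled_fraction = 0.5,
                           protected_windows = list(
                             genomic_interval(16024L, 16569L + 577L,
                                              name = "control_region")),
                           release_penalty = 0.2) {
  stopifnot(supercoiled_fraction >= 0, supercoiled_fraction <= 1,
            release_penalty >= 0, release_penalty <= 1)
  if (inherits(protected_windows, "genomic_interval"))
    protected_windows <- list(protected_windows)
  structure(list(supercoiled_fraction = supercoiled_fraction,
                 protected_windows = protected_windows,
                 release_penalty = release_penalty),
            class = "topology_model")
}

# Logical vector over 1..L: inside any protected window (circular wrap).
protection_mask <- function(model, genome_length) {
  mask <- logical(genome_length)
  for (w in model$protected_windows) {
    pos <- ((seq.int(w$start, w$end - 1L) - 1L) %% genome_length) + 1L
    mask[pos] <- TRUE
  }
  mask
}

#' Simulate a population of genome copies with mixed topology
#'
#' Each copy is supercoiled with probability `supercoiled_fraction`,
#' otherwise open-circular or linear (an even split; the two behave
#' identically here since only supercoiling confers protection). Digestion
#' forces every copy linear, cut at the enzyme site, with all protection
#' removed.
#'
#' @param genome A [circular_genome()].
#' @param n_copies Number of molecules (`>= 1`).
#' @param model A [topology_model()].
#' @param digested Logical; has the population been restriction-digested?
#' @param cut_position 1-based cut coordinate used when `digested = TRUE`
#'   (typically `find_sites()` + cut offset).
#' @param seed Integer seed.
#' @return A `molecule_population`: list with `molecules` (data.frame of
#'   `id`, `topology`, `protected`), the model, the digestion state and the
#'   genome name/length.
#' @export
make_population <- function(genome, n_copies, model = topology_model(),
                            digested = FALSE, cut_position = NA_integer_,
                            seed = 1L) {
  stopifnot(n_copies >= 1)
  withr_seed(seed, {
    sc <- stats::runif(n_copies) < model$supercoiled_fraction
    other <- sample(c("open_circular", "linear"), n_copies, replace = TRUE)
  })
  topo <- ifelse(sc, "supercoiled", other)
  protected <- sc
  if (digested) {
    topo <- rep("linear", n_copies)
    protected <- rep(FALSE, n_copies)
  }
  structure(list(
    molecules = data.frame(id = seq_len(n_copies), topology = topo,
                           protected = protected, stringsAsFactors = FALSE),
    model = model, digested = digested, cut_position = cut_position,
    genome_name = genome$name, genome_length = genome$length),
    class = "molecule_population")
}

#' Plant NUMTs into a synthetic nuclear decoy genome
#'
#' Builds a random linear nuclear background and copies mtDNA segments into
#' it with independent per-base substitutions at the requested divergence.
#' The mitochondrial genome itself is never modified.
#'
#' @param mt_genome A mitochondrial [circular_genome()].
#' @param nuclear_length Length of the nuclear decoy (bp).
#' @param numt_specs data.frame with columns `mt_start`, `mt_end`
#'   (1-based end-exclusive interval on the mt genome), `divergence`
#'   (substitution fraction in `[0, 1]`), and optionally `nuclear_start`
#'   (auto-placed evenly when absent). Overlapping placements are an error.
#' @param gc_fraction GC content of the nuclear background.
#' @param seed Integer seed.
#' @return List with `nuclear_genome` (a linear [circular_genome()]) and
#'   `numts`, a data.frame of NUMT records: placement, origin, length,
#'   requested and realized divergence, and `alignment_score`
#'   (+1 match / -1 mismatch over the planted span, so identity scores
#'   `length` and the expectation decreases with divergence).
#' @export
plant_numts <- function(mt_genome, nuclear_length, numt_specs,
                        gc_fraction = 0.41, seed = 1L) {
  ns <- as.data.frame(numt_specs)
  stopifnot(all(c("mt_start", "mt_end", "divergence") %in% names(ns)))
  ns$mt_start <- as.integer(ns$mt_start)
  ns$mt_end <- as.integer(ns$mt_end)
  if (!is.null(ns$nuclear_start)) ns$nuclear_start <- as.integer(ns$nuclear_start)
  if (any(ns$divergence < 0 | ns$divergence > 1))
    stop("divergence outside [0,1]")
  lens <- ns$mt_end - ns$mt_start
  if (any(lens <= 0)) stop("empty mt_origin interval")
  n <- nrow(ns)
  if (is.null(ns$nuclear_start) || all(is.na(ns$nuclear_start))) {
    gap <- (nuclear_length - sum(lens)) %/% (n + 1L)
    if (gap < 1) stop("specs do not fit within nuclear_length")
    gap <- as.integer(gap)
    starts <- integer(n); at <- gap + 1L
    for (i in seq_len(n)) { starts[i] <- at; at <- at + lens[i] + gap }
    ns$nuclear_start <- as.integer(starts)
  }
  ns$nuclear_end <- ns$nuclear_start + lens
  if (any(ns$nuclear_end - 1L > nuclear_length | ns$nuclear_start < 1))
    stop("specs do not fit within nuclear_length")
  o <- order(ns$nuclear_start)
  if (n > 1 && any(ns$nuclear_end[o][-n] > ns$nuclear_start[o][-1]))
    stop("overlapping NUMT placements")

  nuc <- generate_genome(nuclear_length, gc_fraction, seed = seed + 101L,
                         name = "nuclear_decoy", circular = FALSE)
  nuc_seq <- nuc$sequence
  recs <- ns
  recs$length <- lens
  recs$realized_divergence <- NA_real_
  recs$alignment_score <- NA_integer_
  withr_seed(seed, {
    for (i in seq_len(n)) {
      seg <- strsplit(circular_subseq(mt_genome, ns$mt_start[i], lens[i]),
                      "", fixed = TRUE)[[1]]
      hit <- stats::runif(lens[i]) < ns$divergence[i]
      if (any(hit)) {
        seg[hit] <- vapply(seg[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      }
      n_sub <- sum(hit)
      substr(nuc_seq, ns$nuclear_start[i], ns$nuclear_end[i] - 1L) <-
        paste0(seg, collapse = "")
      recs$realized_divergence[i] <- n_sub / lens[i]
      recs$alignment_score[i] <- as.integer((lens[i] - n_sub) - n_sub)
    }
  })
  recs$name <- sprintf("NUMT_%02d", seq_len(n))
  list(nuclear_genome = circular_genome("nuclear_decoy", nuc_seq,
                                        circular = FALSE),
       numts = recs[, c("name", "nuclear_start", "nuclear_end", "mt_start",
                        "mt_end", "length", "divergence",
                        "realized_divergence", "alignment_score")])
}

#' Write/read the synthetic-data tables (tab-separated, round-trippable)
#'
#' `write_methylome()` stores one row per cytosine (position, strand,
#' probability); `write_numt_table()` and `write_population_table()` store
#' the corresponding record data.frames with a header.
#'
#' @param methylome A `methylome` object.
#' @param path Output path.
#' @name synthetic_tables
#' @export
write_methylome <- function(methylome, path) {
  top_i <- which(!is.na(methylome$top))
  bot_i <- which(!is.na(methylome$bottom))
  df <- data.frame(
    position = c(top_i, bot_i),
    strand = c(rep("+", length(top_i)), rep("-", length(bot_i))),
    probability = c(methylome$top[top_i], methylome$bottom[bot_i]))
  df <- df[order(df$position, df$strand), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_tables
#' @param genome The genome the methylome belongs to.
#' @export
read_methylome <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- generate_methylome(genome, "all_zero")
  top <- df$strand == "+"
  m$top[df$position[top]] <- df$probability[top]
  m$bottom[df$position[!top]] <- df$probability[!top]
  m
}

#' @rdname synthetic_tables
#' @param numts NUMT record data.frame from [plant_numts()].
#' @export
write_numt_table <- function(numts, path) {
  utils::write.table(numts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_tables
#' @export
read_numt_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname synthetic_tables
#' @param population A `molecule_population`.
#' @export
write_population_table <- function(population, path) {
  utils::write.table(population$molecules, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_tables
#' @export
read_population_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
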