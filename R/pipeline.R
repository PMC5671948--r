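#' Default targeted regions (Table-layout analog)
#'
#' Six amplicons mirroring the canonical targeted design on human mtDNA —
#' same lengths and relative placement, applied to the synthetic genome:
#' two D-loop amplicons, tRNA-F+12S, 16S, ND5 and CYTB. D-loop, tRNA-F+12S
#' and ND5 target the heavy (+) strand; 16S and CYTB the light (-) strand.
#'
#' @return data.frame with `name`, `start`, `end` (1-based end-exclusive)
#'   and `strand`.
#' @export
default_regions <- function() {
  data.frame(
    name = c("D-Loop_1", "D-Loop_2", "tRNA-F_12S", "16S", "ND5", "CYTB"),
    start = c(6L, 279L, 577L, 2763L, 12687L, 15091L),
    end = c(298L, 458L, 765L, 2873L, 12856L, 15243L),
    strand = c("+", "+", "+", "-", "+", "-"),
    stringsAsFactors = FALSE)
}

#' Experiment configuration
#'
#' Bundles every tunable of the two in-silico experiments with validated
#' defaults. All probabilities must lie in `[0, 1]`; the seed is recorded in
#' every output manifest.
#'
#' @param genome_length,gc_fraction Synthetic genome parameters.
#' @param site_position Coordinate of the planted unique restriction site.
#' @param methylome_mode,methylome_p,methylome_sites True methylome (see
#'   [generate_methylome()]); the default is the all-zero methylome.
#' @param supercoiled_fraction,protected_windows,release_penalty Topology
#'   model (see [topology_model()]); `protected_windows = NULL` uses the
#'   control-region default.
#' @param epsilon0,epsilon_prot,delta,seq_error Conversion model (see
#'   [conversion_model()]).
#' @param n_copies Molecules per simulated population.
#' @param n_fragments Whole-genome fragments per run. Default 60000, about
#'   450x per-strand coverage at 150 bp paired reads on a 16.6 kb genome —
#'   deep enough that the methylation-greater-than-zero filter has no
#'   selection effect under an artifact-free null (see the methods
#'   vignette).
#' @param mean_fragment_len,sd_fragment_len Sonication length model.
#' @param read_len Read length (default 150).
#' @param directional Library directionality (default TRUE).
#' @param trim_wmgbs,trim_targeted Head-trim lengths: 10 for whole-genome
#'   reads, 2 for targeted reads.
#' @param regions Targeted regions data.frame (default [default_regions()]).
#' @param amplicons_per_region Sampled template molecules per amplicon and
#'   arm in the targeted experiment (default 400).
#' @param enzyme Restriction enzyme (default [bamhi()]).
#' @param max_mismatches,max_insert Aligner settings.
#' @return A validated `experiment_config` list.
#' @export
experiment_config <- function(genome_length = 16569L, gc_fraction = 0.44,
                              site_position = 14258L,
                              methylome_mode = "all_zero", methylome_p = 0,
                              methylome_sites = NULL,
                              supercoiled_fraction = 0.5,
                              protected_windows = NULL,
                              release_penalty = 0.2,
                              epsilon0 = 0.01, epsilon_prot = 0.30,
                              delta = 0, seq_error = 0,
                              n_copies = 5000L, n_fragments = 60000L,
                              mean_fragment_len = 300, sd_fragment_len = 60,
                              read_len = 150L, directional = TRUE,
                              trim_wmgbs = 10L, trim_targeted = 2L,
                              regions = default_regions(),
                              amplicons_per_region = 400L,
                              enzyme = bamhi(),
                              max_mismatches = 5L, max_insert = 1000L) {
  cfg <- as.list(environment())
  probs <- c(gc_fraction = gc_fraction, methylome_p = methylome_p,
             supercoiled_fraction = supercoiled_fraction,
             release_penalty = release_penalty, epsilon0 = epsilon0,
             epsilon_prot = epsilon_prot, delta = delta,
             seq_error = seq_error)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0,1]: ", paste(names(probs)[bad],
                                                collapse = ", "))
  if (epsilon0 > epsilon_prot)
    stop("epsilon_prot must be >= epsilon0")
  if (n_fragments <= 0 || n_copies <= 0 || amplicons_per_region <= 0)
    stop("counts must be positive")
  if (read_len < 30) stop("read_len must be >= 30")
  stopifnot(all(c("name", "start", "end", "strand") %in% names(regions)))
  if (any(regions$end <= regions$start))
    stop("region end must exceed start")
  class(cfg) <- "experiment_config"
  cfg
}

config_topology <- function(config) {
  if (is.null(config$protected_windows)) {
    topology_model(config$supercoiled_fraction,
                   release_penalty = config$release_penalty)
  } else {
    topology_model(config$supercoiled_fraction, config$protected_windows,
                   config$release_penalty)
  }
}

config_conversion <- function(config) {
  conversion_model(config$epsilon0, config$epsilon_prot, config$delta,
                   config$seq_error)
}

config_genome <- function(config, seed) {
  simulate_mtdna_genome(config$genome_length, config$gc_fraction,
                        config$enzyme, config$site_position, seed = seed)
}

config_methylome <- function(config, genome) {
  generate_methylome(genome, config$methylome_mode, p = config$methylome_p,
                     sites = config$methylome_sites)
}

write_manifest <- function(path, config, seed, stage_counts) {
  flat <- config
  flat$regions <- paste(apply(config$regions, 1, paste, collapse = ","),
                        collapse = ";")
  flat$enzyme <- paste0(config$enzyme$name, ":", config$enzyme$recognition)
  flat$protected_windows <- if (is.null(config$protected_windows)) "default"
    else paste(vapply(config$protected_windows, function(w)
      sprintf("%d-%d", w$start, w$end), character(1)), collapse = ";")
  flat$methylome_sites <- NULL
  lines <- c(sprintf("seed\t%d", seed),
             sprintf("package_version\t%s",
                     as.character(utils::packageVersion("mtbsim"))),
             vapply(names(flat), function(k)
               sprintf("%s\t%s", k, paste(format(flat[[k]]), collapse = ",")),
               character(1)),
             vapply(names(stage_counts), function(k)
               sprintf("count_%s\t%d", k, stage_counts[[k]]), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Run the whole-genome bisulfite artifact experiment
#'
#' Simulates an undigested molecule population over a synthetic mtDNA-like
#' genome, fragments it with topology-dependent release, converts with
#' structure-dependent failure, generates paired 150 bp reads, trims 10
#' head bases, aligns with the three-letter mini-aligner, de-duplicates,
#' calls per-cytosine methylation, and computes the depth-methylation
#' log-log correlation. Deterministic given `seed`.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed.
#' @param outdir Optional output directory: persists the cytosine report,
#'   smoothed profile, correlation table and a reproducibility manifest.
#' @return List with `report` (cytosine report), `correlation`
#'   (`correlation_result`), `profile` (smoothed), `counts` (per-stage
#'   record counts) and `genome`.
#' @export
run_wmgbs <- function(config, seed = 1L, outdir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  genome <- config_genome(config, seed)
  methylome <- config_methylome(config, genome)
  topo <- config_topology(config)
  conv <- config_conversion(config)
  pop <- make_population(genome, config$n_copies, topo, digested = FALSE,
                         seed = seed + 1L)
  reads <- simulate_bisulfite_reads(
    genome, methylome, pop, conv, config$n_fragments,
    mean_len = config$mean_fragment_len, sd_len = config$sd_fragment_len,
    read_len = config$read_len, directional = config$directional,
    seed = seed + 2L)
  trimmed <- trim_heads(reads, config$trim_wmgbs)
  index <- build_bisulfite_index(genome, wrap = config$read_len + 50L)
  aln <- align_bisulfite(trimmed, index, config$max_mismatches,
                         config$max_insert)
  mapped <- aln[aln$mapped, , drop = FALSE]
  deduped <- deduplicate(mapped)
  report <- call_methylation(deduped, trimmed, genome)
  correlation <- depth_methylation_correlation(report)
  profile <- smooth_profile(report)
  counts <- list(reads_simulated = nrow(reads), reads_trimmed = nrow(trimmed),
                 pairs_mapped = nrow(mapped), pairs_deduped = nrow(deduped),
                 cytosines = nrow(report))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cytosine_report(report, file.path(outdir, "cytosine_report.tsv"))
    utils::write.table(profile, file.path(outdir, "smoothed_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(r = correlation$r, p_value = correlation$p_value,
                 n = correlation$n),
      file.path(outdir, "depth_methylation_correlation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(file.path(outdir, "manifest.tsv"), config, seed, counts)
  }
  list(report = report, correlation = correlation, profile = profile,
       counts = counts, genome = genome)
}

# Simulate one targeted (amplicon) arm: per region, sample template
# molecules, bisulfite-convert the amplicon, sequence from both ends, trim,
# align, and call. No deduplication (amplicon reads legitimately stack).
run_targeted_arm <- function(config, genome, methylome, pop, conv, index,
                             seed) {
  L <- genome$length
  mask <- protection_mask(pop$model, L)
  regions <- config$regions
  all_reads <- list()
  withr_seed(seed, {
    for (r in seq_len(nrow(regions))) {
      len <- regions$end[r] - regions$start[r]
      idx <- sample.int(nrow(pop$molecules), config$amplicons_per_region,
                        replace = TRUE)
      prot_parent <- pop$molecules$protected[idx]
      pos <- ((regions$start[r] - 1L + 0:(len - 1L)) %% L) + 1L
      seq <- circular_subseq(genome, regions$start[r], len)
      rl <- min(config$read_len, len)
      r1 <- character(length(idx)); r2 <- character(length(idx))
      tag <- character(length(idx))
      top_strand <- regions$strand[r] == "+"
      probs <- if (top_strand) methylome$top[pos] else methylome$bottom[pos]
      for (i in seq_along(idx)) {
        prot <- if (prot_parent[i]) mask[pos] else rep(FALSE, len)
        # amplicon interrogates the design strand only
        template <- convert_one_strand(seq, probs, prot, conv,
                                       top = top_strand)
        tag[i] <- if (top_strand) "OT" else "OB"
        r1[i] <- substr(template, 1L, rl)
        r2[i] <- reverse_complement(substr(template, len - rl + 1L, len))
      }
      all_reads[[r]] <- data.frame(
        read_id = sprintf("%s_amp%04d:%d:%d:%s:amplicon", regions$name[r],
                          seq_along(idx), regions$start[r], len, tag),
        read1 = r1, qual1 = strrep("F", nchar(r1)),
        read2 = r2, qual2 = strrep("F", nchar(r2)),
        bs_strand = tag, truth_start = regions$start[r], truth_len = len,
        truth_topology = pop$molecules$topology[idx],
        region = regions$name[r], stringsAsFactors = FALSE)
    }
  })
  reads <- do.call(rbind, all_reads)
  trimmed <- trim_heads(reads, config$trim_targeted)
  aln <- align_bisulfite(trimmed, index, config$max_mismatches,
                         config$max_insert)
  mapped <- aln[aln$mapped, , drop = FALSE]
  report <- call_methylation(mapped, trimmed, genome)
  list(report = report, n_reads = nrow(reads), n_mapped = nrow(mapped))
}

#' Run the targeted digested-vs-undigested experiment
#'
#' Two arms over the same genome and methylome: an undigested population
#' (mixed topology, protected windows active on supercoiled copies) and a
#' BamHI-digested population (all linear, protection removed). Each arm is
#' amplicon-sequenced over the configured regions (no deduplication), and
#' per region the two arms are compared by a min-max summary and a paired
#' per-cytosine sign test, Bonferroni-corrected over the family of regions.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed.
#' @param outdir Optional output directory for the two cytosine reports,
#'   the summary/sign-test tables and the manifest.
#' @return List with `summaries` (per region x arm min-max data.frame),
#'   `sign_tests` (per region: counts and p-values), `report_undigested`,
#'   `report_digested`, `genome`, `counts`.
#' @export
run_targeted <- function(config, seed = 1L, outdir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  genome <- config_genome(config, seed)
  methylome <- config_methylome(config, genome)
  topo <- config_topology(config)
  conv <- config_conversion(config)
  sites <- find_sites(genome, config$enzyme)
  if (length(sites) == 0)
    warning("no restriction site in genome; digested arm equals undigested")
  cut <- if (length(sites)) ((sites[1] + config$enzyme$cut_offset - 1L) %%
                               genome$length) + 1L else NA_integer_
  pop_u <- make_population(genome, config$n_copies, topo, digested = FALSE,
                           seed = seed + 1L)
  pop_d <- make_population(genome, config$n_copies, topo, digested = TRUE,
                           cut_position = cut, seed = seed + 1L)
  index <- build_bisulfite_index(genome, wrap = config$read_len + 50L)
  arm_u <- run_targeted_arm(config, genome, methylome, pop_u, conv, index,
                            seed + 10L)
  arm_d <- run_targeted_arm(config, genome, methylome, pop_d, conv, index,
                            seed + 20L)

  regions <- config$regions
  m_tests <- nrow(regions)
  summaries <- list(); tests <- list()
  for (r in seq_len(nrow(regions))) {
    iv <- genomic_interval(regions$start[r], regions$end[r],
                           strand = regions$strand[r], name = regions$name[r])
    su <- region_summary(arm_u$report, iv, genome_length = genome$length)
    sd_ <- region_summary(arm_d$report, iv, genome_length = genome$length)
    su$arm <- "undigested"; sd_$arm <- "digested"
    summaries[[r]] <- rbind(su, sd_)
    pos <- ((seq.int(iv$start, iv$end - 1L) - 1L) %% genome$length) + 1L
    pick <- function(rep) {
      s <- rep[rep$position %in% pos & rep$strand == iv$strand &
                 rep$coverage > 0, c("position", "methylation_percent")]
      s
    }
    pu <- pick(arm_u$report); pd <- pick(arm_d$report)
    common <- intersect(pu$position, pd$position)
    st <- sign_test(pu$methylation_percent[match(common, pu$position)],
                    pd$methylation_percent[match(common, pd$position)],
                    m_tests = m_tests)
    tests[[r]] <- data.frame(
      region = regions$name[r], n_cytosines = length(common),
      n_pos = st$n_pos, n_neg = st$n_neg, n_ties = st$n_ties,
      p_raw = st$p_raw, p_adjusted = st$p_adjusted,
      degenerate = st$degenerate, stringsAsFactors = FALSE)
  }
  summaries <- do.call(rbind, summaries)
  tests <- do.call(rbind, tests)
  counts <- list(reads_undigested = arm_u$n_reads,
                 pairs_mapped_undigested = arm_u$n_mapped,
                 reads_digested = arm_d$n_reads,
                 pairs_mapped_digested = arm_d$n_mapped)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cytosine_report(arm_u$report,
                          file.path(outdir, "cytosine_report_undigested.tsv"))
    write_cytosine_report(arm_d$report,
                          file.path(outdir, "cytosine_report_digested.tsv"))
    utils::write.table(summaries, file.path(outdir, "region_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tests, file.path(outdir, "sign_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(file.path(outdir, "manifest.tsv"), config, seed, counts)
  }
  list(summaries = summaries, sign_tests = tests,
       report_undigested = arm_u$report, report_digested = arm_d$report,
       genome = genome, counts = counts)
}
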