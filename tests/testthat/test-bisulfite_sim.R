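make_sim <- function(len = 4000L, seed = 1L, supercoiled = 0.5,
                     window = genomic_interval(1000L, 2000L), rho = 0.2,
                     n_copies = 400L) {
  g <- generate_genome(len, 0.5, seed = seed, name = "simtoy")
  tm <- topology_model(supercoiled, list(window), rho)
  pop <- make_population(g, n_copies, tm, seed = seed + 1L)
  list(genome = g, methylome = generate_methylome(g, "all_zero"),
       pop = pop, model = tm)
}

test_that("conversion follows the per-cytosine failure model", {
  s <- paste0(rep(c("A", "C", "G", "T"), 250), collapse = "")
  n <- nchar(s)
  # fully methylated, no over-conversion: sequence unchanged
  out <- bisulfite_convert(s, rep(1, n), rep(1, n), rep(FALSE, n),
                           conversion_model(0, 0, delta = 0), seed = 1)
  expect_identical(out$top, s)
  expect_identical(out$bottom, reverse_complement(s))

  # fully unmethylated, perfect conversion: all C -> T on each strand
  out0 <- bisulfite_convert(s, rep(0, n), rep(0, n), rep(FALSE, n),
                            conversion_model(0, 0), seed = 1)
  expect_identical(out0$top, chartr("C", "T", s))
  expect_identical(out0$bottom, chartr("C", "T", reverse_complement(s)))

  # epsilon0 = 0.01 over 10,000 cytosines: escapes within 3 binomial sd
  s2 <- strrep("CA", 10000)
  n2 <- nchar(s2)
  out2 <- bisulfite_convert(s2, rep(0, n2), rep(0, n2), rep(FALSE, n2),
                            conversion_model(0.01, 0.01), seed = 5)
  escapes <- sum(strsplit(out2$top, "")[[1]] == "C")
  expect_lt(abs(escapes - 100), 3 * sqrt(10000 * 0.01 * 0.99))

  # conversion never touches A/T and never changes length
  for (seed in 1:5) {
    ss <- generate_genome(200, 0.5, seed = seed)$sequence
    oo <- bisulfite_convert(ss, runif(200), runif(200),
                            sample(c(TRUE, FALSE), 200, TRUE),
                            conversion_model(0.1, 0.5, delta = 0.2),
                            seed = seed)
    expect_identical(nchar(oo$top), 200L)
    cc <- strsplit(ss, "")[[1]]; tt <- strsplit(oo$top, "")[[1]]
    expect_identical(tt[cc == "A"], cc[cc == "A"])
    expect_identical(tt[cc == "T"], cc[cc == "T"])
    expect_identical(tt[cc == "G"], cc[cc == "G"])  # top strand keeps Gs
  }
})

test_that("protected cytosines escape conversion at epsilon_prot", {
  s2 <- strrep("CA", 5000)
  n2 <- nchar(s2)
  out <- bisulfite_convert(s2, rep(0, n2), rep(0, n2), rep(TRUE, n2),
                           conversion_model(0.01, 0.30), seed = 6)
  escapes <- sum(strsplit(out$top, "")[[1]] == "C")
  expect_lt(abs(escapes - 1500), 3 * sqrt(5000 * 0.30 * 0.70))
})

test_that("fragmentation is uniform without protection", {
  sim <- make_sim(supercoiled = 0, rho = 1)
  frags <- fragment_population(sim$pop, 50000, mean_len = 160, sd_len = 20,
                               read_len = 80, seed = 2)
  L <- sim$genome$length
  # fragment starts are the independent uniform draws; bin them 100 ways
  bins <- tabulate(((frags$start - 1L) %/% (L %/% 100L)) + 1L, 100L)
  p <- suppressWarnings(chisq.test(bins)$p.value)
  expect_gt(p, 0.001)
  # and mean per-base coverage inside vs outside an arbitrary window agrees
  cov <- integer(L)
  for (i in seq_len(nrow(frags))) {
    pos <- ((frags$start[i] - 1L + 0:(frags$length[i] - 1L)) %% L) + 1L
    cov[pos] <- cov[pos] + 1L
  }
  expect_lt(abs(mean(cov[1000:2000]) / mean(cov[c(100:900, 2100:3900)]) - 1),
            0.05)
})

test_that("release penalty thins protected-window coverage by about rho", {
  sim <- make_sim(supercoiled = 1, rho = 0.2,
                  window = genomic_interval(1000L, 2000L))
  frags <- fragment_population(sim$pop, 30000, mean_len = 150, sd_len = 15,
                               read_len = 70, seed = 3)
  L <- sim$genome$length
  cov <- integer(L)
  for (i in seq_len(nrow(frags))) {
    pos <- ((frags$start[i] - 1L + 0:(frags$length[i] - 1L)) %% L) + 1L
    cov[pos] <- cov[pos] + 1L
  }
  # compare deep inside the window to far outside (edges are intermediate)
  inside <- mean(cov[1200:1800])
  outside <- mean(cov[c(2500:3800, 100:800)])
  expect_lt(abs(inside / outside - 0.2), 0.05)
})

test_that("origin-spanning fragments carry the wrap-around sequence", {
  sim <- make_sim(len = 500L)
  g <- sim$genome
  frag_seq <- circular_subseq(g, 480, 60)
  expect_identical(frag_seq, oracle_circular_subseq(g$sequence, 480, 60))
  # simulate unconverted reads from a forced origin-spanning fragment
  frags <- data.frame(molecule = 1L, topology = "linear", protected = FALSE,
                      start = 480L, length = 60L)
  reads <- generate_reads(frags, g, sim$methylome, sim$pop,
                          conversion_model(1, 1),  # every C escapes: raw read
                          read_len = 30L, seed = 4)
  expect_true(reads$read1 %in% c(substr(frag_seq, 1, 30),
                                 reverse_complement(substr(frag_seq, 31, 60))))
})

test_that("read geometry tiles the fragment and respects truncation", {
  sim <- make_sim(len = 1000L)
  g <- sim$genome
  frags <- data.frame(molecule = 1:2, topology = "linear", protected = FALSE,
                      start = c(101L, 301L), length = c(120L, 40L))
  cmodel <- conversion_model(1, 1)   # identity conversion for geometry checks
  reads <- generate_reads(frags, g, sim$methylome, sim$pop, cmodel,
                          read_len = 60L, seed = 8)
  f1 <- circular_subseq(g, 101, 120)
  r1 <- reads[1, ]
  if (r1$bs_strand == "OT") {
    expect_identical(r1$read1, substr(f1, 1, 60))
    expect_identical(r1$read2, reverse_complement(substr(f1, 61, 120)))
  } else {
    bot <- reverse_complement(f1)
    expect_identical(r1$read1, substr(bot, 1, 60))
    expect_identical(r1$read2, reverse_complement(substr(bot, 61, 120)))
  }
  # fragment shorter than read length: truncated reads
  expect_identical(nchar(reads$read1[2]), 40L)
  expect_identical(nchar(reads$read2[2]), 40L)
})

test_that("unconverted error-free reads are exact genome substrings", {
  sim <- make_sim(len = 2000L)
  g <- sim$genome
  doubled <- paste0(g$sequence, g$sequence)
  reads <- simulate_bisulfite_reads(g, sim$methylome, sim$pop,
                                    conversion_model(1, 1), 200,
                                    mean_len = 200, sd_len = 20,
                                    read_len = 80, seed = 9)
  hits <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads$read1[i]
    grepl(r, doubled, fixed = TRUE) ||
      grepl(reverse_complement(r), doubled, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
})

test_that("non-directional libraries emit all four strand tags at 25%", {
  sim <- make_sim(len = 2000L)
  frags <- fragment_population(sim$pop, 8000, mean_len = 160, sd_len = 10,
                               read_len = 70, seed = 10)
  reads <- generate_reads(frags, sim$genome, sim$methylome, sim$pop,
                          conversion_model(0.01, 0.3), read_len = 70L,
                          directional = FALSE, seed = 11)
  tab <- table(reads$bs_strand)
  expect_setequal(names(tab), c("OT", "OB", "CTOT", "CTOB"))
  sd3 <- 3 * sqrt(8000 * 0.25 * 0.75)
  expect_true(all(abs(tab - 2000) < sd3))
  # directional mode emits only the two original strands
  rd <- generate_reads(frags[1:200, ], sim$genome, sim$methylome, sim$pop,
                       conversion_model(0.01, 0.3), read_len = 70L,
                       directional = TRUE, seed = 12)
  expect_setequal(unique(rd$bs_strand), c("OT", "OB"))
})

test_that("topology has no conversion effect when epsilon_prot equals epsilon0", {
  # same seeds, window protection on vs off: with eps_prot == eps0 the
  # apparent-methylation distribution inside the window must match
  esc_rate <- function(supercoiled) {
    sim <- make_sim(len = 3000L, supercoiled = supercoiled, rho = 1,
                    window = genomic_interval(1L, 3001L))
    reads <- simulate_bisulfite_reads(sim$genome, sim$methylome, sim$pop,
                                      conversion_model(0.02, 0.02), 3000,
                                      mean_len = 160, sd_len = 10,
                                      read_len = 70, seed = 13)
    ch <- strsplit(reads$read1[reads$bs_strand == "OT"], "")
    n_c <- sum(vapply(ch, function(x) sum(x == "C"), numeric(1)))
    n_t <- sum(vapply(ch, function(x) sum(x == "T"), numeric(1)))
    n_c / (n_c + n_t)
  }
  r1 <- esc_rate(1); r0 <- esc_rate(0)
  # both are binomial estimates of the same 2% escape rate
  expect_lt(abs(r1 - r0), 3 * sqrt(2 * 0.02 * 0.98 / 40000))
})

test_that("FASTQ round-trips with truth tags intact", {
  sim <- make_sim(len = 1000L)
  reads <- simulate_bisulfite_reads(sim$genome, sim$methylome, sim$pop,
                                    conversion_model(0.01, 0.3), 50,
                                    mean_len = 160, sd_len = 10,
                                    read_len = 70, seed = 14)
  pre <- tempfile()
  write_fastq(reads, pre)
  back <- read_fastq(paste0(pre, "_R1.fastq"), paste0(pre, "_R2.fastq"))
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$read1, reads$read1)
  expect_identical(back$read2, reads$read2)
  expect_identical(back$qual2, reads$qual2)
  expect_identical(nchar(reads$qual1), nchar(reads$read1))
})
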