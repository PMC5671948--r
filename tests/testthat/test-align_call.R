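test_that("head trimming removes bases and drops short pairs", {
  reads <- data.frame(
    read_id = c("a", "b"),
    read1 = c(strrep("ACGT", 38), strrep("AC", 12)),   # 152 bp and 24 bp
    qual1 = c(strrep("F", 152), strrep("F", 24)),
    read2 = c(strrep("TGCA", 38), strrep("GT", 12)),
    qual2 = c(strrep("F", 152), strrep("F", 24)),
    stringsAsFactors = FALSE)
  t10 <- trim_heads(reads, 10)
  expect_identical(nrow(t10), 1L)                      # 24 < 10 + 20: dropped
  expect_identical(nchar(t10$read1), 142L)
  expect_identical(t10$read1, substring(reads$read1[1], 11))
  expect_identical(nchar(t10$qual2), 142L)
  expect_identical(trim_heads(reads, 0), reads)        # identity at n = 0
})

test_that("identity and fully converted reads align at their origin", {
  g <- toy_genome(2000, seed = 21)
  idx <- build_bisulfite_index(g, wrap = 120)
  for (p in c(1L, 487L, 1990L)) {          # includes an origin-spanning read
    seg <- circular_subseq(g, p, 80)
    a <- align_single(seg, idx)
    expect_true(a$mapped)
    expect_identical(a$start, p)
    expect_identical(a$mism, 0L)
    # full bisulfite conversion of the top strand still maps at p
    conv <- chartr("C", "T", seg)
    a2 <- align_single(conv, idx)
    expect_identical(a2$start, p)
    expect_identical(a2$bs_strand, "OT")
    orc <- oracle_align(conv, g)
    expect_identical(a2$start, orc$start)
    expect_identical(a2$mism, orc$mism)
    # bottom strand: converted reverse complement maps as OB at p
    conv_b <- chartr("C", "T", reverse_complement(seg))
    a3 <- align_single(conv_b, idx)
    expect_identical(a3$start, p)
    expect_identical(a3$bs_strand, "OB")
  }
})

test_that("reads equidistant from duplicated loci are flagged ambiguous", {
  base <- generate_genome(1500, 0.5, seed = 22)$sequence
  dup <- substr(base, 201, 320)
  substr(base, 1001, 1120) <- dup                # plant an exact duplicate
  g <- circular_genome("dup", base)
  idx <- build_bisulfite_index(g, wrap = 120)
  read <- substr(dup, 1, 80)
  a <- align_single(read, idx)
  expect_false(a$mapped)
  expect_false(a$unique)
  orc <- oracle_align(read, g)
  expect_false(orc$unique)
})

test_that("mini-aligner agrees with the exhaustive Hamming oracle", {
  g <- toy_genome(1200, seed = 23)
  idx <- build_bisulfite_index(g, wrap = 100)
  m <- generate_methylome(g, "uniform", p = 0.3)
  pop <- make_population(g, 50, topology_model(0.5,
                                               list(genomic_interval(1, 300)),
                                               1), seed = 1)
  reads <- simulate_bisulfite_reads(g, m, pop, conversion_model(0.05, 0.4),
                                    100, mean_len = 170, sd_len = 15,
                                    read_len = 75, seed = 24)
  singles <- c(reads$read1, reads$read2)
  for (s in singles) {
    a <- align_single(s, idx)
    orc <- oracle_align(s, g)
    expect_identical(a$mapped, orc$unique)
    if (a$mapped) {
      expect_identical(a$start, orc$start)
      expect_identical(a$mism, orc$mism)
      expect_identical(a$bs_strand, orc$space)
    }
  }
})

test_that("uniquely mapped error-free pairs recover their true fragment", {
  g <- toy_genome(3000, seed = 25)
  m <- generate_methylome(g, "all_zero")
  pop <- make_population(g, 100, topology_model(0.5), seed = 2)
  reads <- simulate_bisulfite_reads(g, m, pop, conversion_model(0.01, 0.3),
                                    400, mean_len = 180, sd_len = 15,
                                    read_len = 80, seed = 26)
  idx <- build_bisulfite_index(g, wrap = 120)
  al <- align_bisulfite(reads, idx)
  mapped <- al$mapped
  expect_gt(mean(mapped), 0.98)
  agree <- al$fstart[mapped] == reads$truth_start[mapped] &
    (al$fend - al$fstart)[mapped] == reads$truth_len[mapped]
  expect_gte(mean(agree), 0.99)
})

test_that("deduplication keeps one representative per fragment key", {
  al <- data.frame(
    read_id = sprintf("r%d", 1:8),
    ref = "g", fstart = c(10L, 10L, 10L, 10L, 10L, 50L, 60L, 70L),
    fend = c(200L, 200L, 200L, 200L, 200L, 240L, 250L, 260L),
    bs_strand = c("OT", "OT", "OT", "OT", "OB", "OT", "OT", "OT"),
    mapped = TRUE, stringsAsFactors = FALSE)
  d <- deduplicate(al)
  # 5 identical-key alignments collapse to 1; different bs_strand retained
  expect_identical(nrow(d), 5L)
  expect_true(any(d$bs_strand == "OB" & d$fstart == 10))
  expect_identical(deduplicate(d), d)          # idempotent
  al2 <- al[c(6, 7, 8), ]
  expect_identical(nrow(deduplicate(al2)), 3L) # all-distinct: unchanged
})

test_that("pileup counting computes methylation percent per record", {
  # constructed pileup: one CpG cytosine covered by 10 OT reads, 3 C + 7 T
  g <- circular_genome("pile", paste0(strrep("A", 49), "CGT",
                                      strrep("A", 48)), circular = FALSE)
  reads <- data.frame(
    read_id = sprintf("r%d", 1:10),
    read1 = c(rep(paste0(strrep("A", 9), "CG"), 3),
              rep(paste0(strrep("A", 9), "TG"), 7)),
    qual1 = strrep("F", 11),
    read2 = rep(paste0("TG", strrep("A", 9)), 10),   # same fragment other end
    qual2 = strrep("F", 11), stringsAsFactors = FALSE)
  al <- data.frame(
    read_id = reads$read_id, ref = "pile",
    start1 = 41L, len1 = 11L, space1 = "OT",
    start2 = 49L, len2 = 11L, space2 = "CTOT",
    mism = 0L, fstart = 41L, fend = 60L, bs_strand = "OT",
    unique = TRUE, mapped = TRUE, stringsAsFactors = FALSE)
  rep_ <- call_methylation(al, reads, g)
  rec <- rep_[rep_$position == 50 & rep_$strand == "+", ]
  expect_identical(rec$count_methylated, 3L)
  expect_identical(rec$count_unmethylated, 7L)
  expect_equal(rec$methylation_percent, 30.0)
  expect_identical(rec$context, "CpG")
  # zero-coverage cytosines are present with 0/0 and NA percent
  zero <- rep_[rep_$position == 51 & rep_$strand == "-", ]
  expect_identical(zero$coverage, 0L)
  expect_true(is.na(zero$methylation_percent))
})

test_that("mate overlap is not double-counted", {
  g <- circular_genome("ov", paste0(strrep("A", 20), "C", strrep("A", 19)),
                       circular = FALSE)
  # both mates fully overlap position 21; read1 says C, read2 says T
  reads <- data.frame(
    read_id = "p1",
    read1 = paste0(strrep("A", 10), "C", strrep("A", 9)),
    qual1 = strrep("F", 20),
    read2 = reverse_complement(paste0(strrep("A", 10), "T", strrep("A", 9))),
    qual2 = strrep("F", 20), stringsAsFactors = FALSE)
  al <- data.frame(read_id = "p1", ref = "ov",
                   start1 = 11L, len1 = 20L, space1 = "OT",
                   start2 = 11L, len2 = 20L, space2 = "CTOT",
                   mism = 0L, fstart = 11L, fend = 31L, bs_strand = "OT",
                   unique = TRUE, mapped = TRUE, stringsAsFactors = FALSE)
  rep_ <- call_methylation(al, reads, g)
  rec <- rep_[rep_$position == 21 & rep_$strand == "+", ]
  expect_identical(rec$coverage, 1L)           # read 1 wins the overlap
  expect_identical(rec$count_methylated, 1L)
})

test_that("context classification partitions all cytosines and wraps", {
  g <- circular_genome("ctx", "ACGTACAGTAC")  # circular: wrap matters
  chars <- strsplit(g$sequence, "")[[1]]
  top <- which(chars == "C"); bot <- which(chars == "G")
  ctx_top <- classify_context(g, top, "+")
  ctx_bot <- classify_context(g, bot, "-")
  expect_identical(nrow(ctx_top) + nrow(ctx_bot), length(top) + length(bot))
  expect_true(all(c(ctx_top$context, ctx_bot$context) %in%
                    c("CpG", "CHG", "CHH")))
  # "AC|GT": C followed by G is CpG; "ACA|GT": C,A,G is CHG
  expect_identical(ctx_top$context[ctx_top$position == 2], "CpG")
  expect_identical(ctx_top$context[ctx_top$position == 6], "CHG")
  # wrap: final-position C with G at position 1 is CpG
  g2 <- circular_genome("wrapctx", "GTTTTTTTTC")
  expect_identical(classify_context(g2, 10, "+")$context, "CpG")
  # linear end: insufficient downstream bases pads with N, classified CHH
  g3 <- circular_genome("linctx", "GTTTTTTTTC", circular = FALSE)
  cc <- classify_context(g3, 10, "+")
  expect_identical(cc$context, "CHH")
  expect_identical(cc$trinucleotide, "CNN")
  expect_error(classify_context(g2, 2, "+"), "not a cytosine")
})

test_that("context classes partition the cytosines of a random genome", {
  g <- generate_genome(3000, 0.5, seed = 27)
  chars <- strsplit(g$sequence, "")[[1]]
  n_c <- sum(chars == "C") + sum(chars == "G")
  rep_ <- call_methylation(
    data.frame(read_id = character(0), ref = character(0),
               start1 = integer(0), len1 = integer(0), space1 = character(0),
               start2 = integer(0), len2 = integer(0), space2 = character(0),
               mism = integer(0), fstart = integer(0), fend = integer(0),
               bs_strand = character(0), unique = logical(0),
               mapped = logical(0)),
    data.frame(read_id = character(0), read1 = character(0),
               read2 = character(0)), g)
  expect_identical(nrow(rep_), n_c)
  expect_identical(sum(table(rep_$context)), n_c)
})

test_that("end-to-end with all-zero methylome and perfect conversion is 0% everywhere", {
  g <- toy_genome(2500, seed = 28)
  m <- generate_methylome(g, "all_zero")
  pop <- make_population(g, 100, topology_model(0.5), seed = 3)
  reads <- simulate_bisulfite_reads(g, m, pop, conversion_model(0, 0),
                                    600, mean_len = 180, sd_len = 15,
                                    read_len = 80, seed = 29)
  idx <- build_bisulfite_index(g, wrap = 120)
  al <- align_bisulfite(reads, idx)
  rep_ <- call_methylation(deduplicate(al[al$mapped, ]), reads, g)
  covered <- rep_[rep_$coverage > 0, ]
  expect_gt(nrow(covered), 1000)
  expect_identical(sum(covered$count_methylated), 0L)
  expect_true(all(covered$methylation_percent == 0))
})

test_that("truth tags confirm >= 99% of unique mappings hit their origin", {
  g <- toy_genome(4000, seed = 30)
  m <- generate_methylome(g, "all_zero")
  pop <- make_population(g, 200, topology_model(0.5), seed = 4)
  reads <- simulate_bisulfite_reads(g, m, pop, conversion_model(0.01, 0.3),
                                    500, mean_len = 180, sd_len = 15,
                                    read_len = 80, seed = 31)
  idx <- build_bisulfite_index(g, wrap = 120)
  al <- align_bisulfite(reads, idx)
  uq <- al$mapped
  expect_gte(mean(al$fstart[uq] == reads$truth_start[uq]), 0.99)
})

test_that("oversized references are rejected with guidance", {
  g <- circular_genome("big", strrep("ACGT", 100), circular = FALSE)
  g$length <- 2e6   # pretend: avoid allocating 2 Mb in-test
  expect_error(build_bisulfite_index(g), "1 Mb")
})
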