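#!/usr/bin/env Rscript
# Builds and persists every synthetic input of the study: the mtDNA-like
# circular genome with its single BamHI site, the all-zero true methylome,
# a mixed-topology molecule population, and a NUMT-bearing nuclear decoy.
# Everything downstream (02-04) regenerates these from the same seed, so
# this script exists to inspect the inputs, not to feed the pipeline.

suppressMessages(library(mtbsim))
seed <- 1L
outdir <- "results/inputs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- simulate_mtdna_genome(seed = seed)
write_fasta(genome, file.path(outdir, "synthetic_mtdna.fasta"))
cat(sprintf("genome: %d bp, BamHI site(s) at %s\n", genome$length,
            paste(find_sites(genome, bamhi()), collapse = ", ")))

methylome <- generate_methylome(genome, "all_zero")
write_methylome(methylome, file.path(outdir, "methylome_truth.tsv"))
cat("methylome: all-zero (no true methylation anywhere)\n")

topo <- topology_model()   # 50% supercoiled, control-region window, rho 0.2
pop <- make_population(genome, 5000, topo, seed = seed + 1L)
write_population_table(pop, file.path(outdir, "population_topology.tsv"))
cat(sprintf("population: %d molecules, %.1f%% supercoiled\n",
            nrow(pop$molecules), 100 * mean(pop$molecules$protected)))

planted <- plant_numts(genome, 60000,
                       data.frame(mt_start = c(501L, 5001L, 11001L),
                                  mt_end = c(1501L, 6501L, 11801L),
                                  divergence = c(0.03, 0.05, 0.10)),
                       seed = seed + 2L)
write_fasta(planted$nuclear_genome, file.path(outdir, "nuclear_decoy.fasta"))
write_numt_table(planted$numts, file.path(outdir, "numt_records.tsv"))
cat(sprintf("nuclear decoy: %d bp with %d planted NUMTs\n",
            planted$nuclear_genome$length, nrow(planted$numts)))
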