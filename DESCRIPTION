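Package: mtbsim
Title: Bisulfite Sequencing Simulation and Artifact Diagnostics for
    Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-genome and targeted bisulfite sequencing over
    circular mitochondrial-like genomes in which supercoiled secondary
    structure blocks both bisulfite conversion and fragment release, and
    provides the diagnostic statistics that expose the resulting
    false-positive methylation signal: the depth-methylation log-log
    Pearson correlation, paired sign tests comparing restriction-digested
    against undigested DNA with Bonferroni correction, min-max region
    summaries, and an exhaustive NUMT (nuclear-mitochondrial segment)
    contamination screen. Includes a self-contained three-letter bisulfite
    mini-aligner and a per-cytosine methylation caller emitting
    CX-style cytosine reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
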