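---
title: "Simulating the mitochondrial bisulfite-sequencing artifact"
author: "mtbsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the mitochondrial bisulfite-sequencing artifact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbsim)
```

## The problem

Bisulfite sequencing estimates cytosine methylation by chemically
deaminating unmethylated cytosines to uracil (read as thymine), while
methylated cytosines resist conversion and are still read as cytosine. The
apparent methylation at a position is therefore the *unconversion rate*:
the fraction of reads still carrying a C. Anything that lets an
unmethylated cytosine escape conversion inflates that estimate.

Mitochondrial DNA is a small circular genome that exists in several
topological states — linear, open-circular and supercoiled (and catenated)
forms. Two properties of the supercoiled state can corrupt a bisulfite
assay:

1. the compact structure can block access of sodium bisulfite, so
   unmethylated cytosines inside structured regions escape deamination;
2. the same structure protects DNA from shear, so sonication releases
   structured regions less efficiently and they are under-represented in
   the library.

The combination produces a characteristic signature: positions with *low*
sequencing depth carry *high* apparent methylation, so apparent methylation
and depth are negatively correlated on the log–log scale, even when the
true methylome is exactly zero. Linearizing the molecule with a
single-cutter restriction enzyme (BamHI for human mtDNA, whose G/GATCC
site occurs exactly once) removes the secondary structure, and the
apparent methylation collapses to the chemistry's background failure rate.

This package simulates that entire mechanism end to end with a known
ground truth, and implements the diagnostics that expose it.

## The generative model

**Genome.** A random circular genome (default 16,569 bp, GC 0.44 — the
length and composition of human mtDNA) with exactly one BamHI site planted
at position 14258 and all spurious sites ablated
(`simulate_mtdna_genome()`). All coordinates are 1-based with
end-exclusive intervals, so an interval `start..end` has length
`end - start`; this makes every amplicon in the canonical targeted design
(e.g. 6–298 → 292 bp) come out exactly.

**True methylome.** Per-cytosine, per-strand methylation *probabilities*.
The default is all-zero: under the model's conclusion the mitochondrial
genome carries no cytosine methylation, so everything the caller reports
is artifact plus chemistry noise. Uniform and site-list methylomes are
available for power studies.

**Topology.** Each of `n_copies` genome copies is supercoiled with
probability `supercoiled_fraction` (default 0.5 — topological state
mixtures vary by tissue and no census is available; an even split makes
both subpopulations well sampled). Supercoiled copies carry one or more
*protected windows*; the default is a single window over the
control-region analog (16024 to 576, wrapping the origin), the region
where regulatory protein binding and triple-stranded structure make
protection most plausible. Open-circular and linear copies behave
identically (only supercoiling confers protection), so the simulator
collapses them into one unprotected class.

**Conversion.** An unmethylated cytosine escapes conversion with
probability `epsilon0` outside protected windows (default 0.01, a typical
kit-level unconversion rate and the background level reported for
linearized templates) and `epsilon_prot` inside an active window (default
0.30 — no direct measurement exists; the value is chosen so an undigested
control region shows the double-digit apparent methylation seen in
structured templates at desk scale). A methylated cytosine over-converts
with probability `delta` (default 0). `epsilon0 <= epsilon_prot` is
enforced: protection can only hinder conversion.

**Release.** Sonication fragments are drawn uniformly with normal lengths
(mean 300, sd 60, truncated at 50 bp; sonication settings do not pin down
a length distribution, so a unimodal shape around twice the read length is
assumed). A candidate fragment overlapping an active protected window of
its parent is released with probability `release_penalty` (default 0.2),
the shear-protection mechanism. Both couplings — conversion failure and
release penalty — can be disabled independently, because the relative
contribution of the two mechanisms is unknown; the package exposes them as
parameters rather than asserting a split.

**Reads.** 150 bp paired-end reads from opposite ends of each converted
fragment. Directional libraries emit the two original strands (OT/OB);
non-directional (post-bisulfite random-primed) libraries also emit their
PCR complements (CTOT/CTOB) at equal probability. Qualities are constant
Phred 37 — no downstream step uses them. Sequencing error is off by
default (the artifact under study is chemical, not instrumental) but a
uniform substitution rate is available. Read names carry the simulation
truth (origin, fragment length, strand, parent topology) for evaluation;
the aligner never looks at them.

## Alignment and calling

The bundled three-letter mini-aligner makes the pipeline self-contained at
desk scale (references up to 1 Mb; it refuses larger input and points to
external bisulfite mappers). A read is collapsed C→T and G→A and compared
against the correspondingly collapsed forward and reverse-complement
reference, giving the four bisulfite read strands; candidates come from
exact 20-mer seeding at three offsets, verified by full Hamming distance,
with a 5-mismatch cap and a unique-best-hit rule (any equal-scoring hit at
a *different* locus makes the read ambiguous). Equal-scoring hits at the
*same* locus under different strand interpretations — e.g. a fully
unconverted read, identical in the OT and CTOB spaces — are
position-unique; they are kept and assigned a strand by fixed priority.
Mates must be concordant (same reference, same strand family, fragment
span within `max_insert`).

Head trimming removes 10 bases from whole-genome reads and 2 from targeted
reads before alignment (position-within-read bias is handled by trimming,
with the trim lengths as configuration inputs). Whole-genome libraries are
de-duplicated on (reference, fragment start, fragment end, bisulfite
strand); amplicon libraries are not, since their reads legitimately stack.

The caller emits a record for *every* reference cytosine on both strands —
including zero-coverage ones — with methylated (C) and unmethylated (T)
counts, context (CpG/CHG/CHH from the two downstream bases on the
cytosine's own strand, wrapping on circular genomes) and the trinucleotide,
in the CX cytosine-report column order, so externally produced reports can
be fed straight into the diagnostics. Where mates overlap, only read 1 is
counted; bases other than C/T at a cytosine column are ignored rather than
miscounted as unmethylated.

## Diagnostics

**Depth–methylation correlation.** Cytosines with coverage ≥ 1 and
apparent methylation strictly greater than zero enter a Pearson
correlation of log coverage against log methylation percent. The natural
logarithm is used; Pearson correlation is invariant to the base (an
affine map in both coordinates), which the tests verify directly. Pooling
samples is concatenating their filtered records. Coverage is counted after
de-duplication. Note the statistic deliberately conditions on
apparent-positive sites — it measures the artifact among positions that
*look* methylated, which is exactly the set a naive analysis would report.

**Sign test.** Paired per-cytosine comparison of the undigested and
digested arms: ties dropped, exact two-sided binomial tail
`min(1, 2 * sum_{i<=k} C(n,i) / 2^n)` with `k` the minority count, then
Bonferroni multiplication by the family size. The family size is a
configuration input; `run_targeted()` uses the number of regions tested in
the session, since no canonical family is defined elsewhere. The
implementation is cross-checked in the tests against full enumeration for
every outcome with n ≤ 12 and against the stock exact binomial test.

**Region summaries.** Min–max apparent methylation over covered cytosines
in a region, optionally split CpG vs non-CpG, restricted to the region's
target strand (amplicons interrogate one strand). A region with no covered
cytosines is reported "not determined" rather than zero. Replicate arms
are pooled before summarising.

**Background envelope.** The digested arm should fall to chemistry
background. A literal "mean + 3 sd" bound on the *maximum* of ~70
per-cytosine binomial proportions is exceeded by chance alone in a
substantial fraction of clean runs, so the package defines the envelope as
the multiplicity-adjusted binomial upper quantile
`qbinom(1 - alpha / n_cytosines, coverage, epsilon0) / coverage` (alpha
0.01), `background_envelope()`.

**Smoothing.** Coverage and methylation tracks are smoothed with a
centred, circularly wrapping sliding-window mean whose window is a
fraction of the positions (default 0.2). This is a transparent stand-in
for a generalized-additive smoother at comparable span: profile-level
behaviour (constants preserved, full-window limit equal to the global
mean, step transitions one window wide) is what the diagnostics need, and
figure-level equivalence with any particular smoother is not claimed.

**NUMT screen.** Nuclear copies of mitochondrial sequence (NUMTs) are the
other candidate explanation for spurious mtDNA methylation. The screen
enumerates *every* read of the protocol's length (default 300 bp, the
fragment size chosen precisely because known human NUMTs have no
300 bp span of perfect mtDNA identity) from each planted NUMT — methylated
copies modelled as fully unconverted, the worst case for confusability —
and realigns them against the combined reference under the pipeline's
unique-best-hit rule. The pass condition is zero mtDNA-assigned reads.
Full-genome screens require external tooling; the desk-scale screen uses
the package aligner on synthetic references.

## Study scale and numerical choices

The default whole-genome run simulates 60,000 fragments (~450× per-strand
coverage). The depth matters for the *control*, not the artifact: the
greater-than-zero filter conditions each site on at least one unconverted
read, and when the expected escape count per site (`epsilon0 ×
coverage`) is small this conditioning alone manufactures a negative
depth–methylation correlation in artifact-free data. At `epsilon0 = 0.01`
the selection effect is gone by ~450× — mirroring the observation that the
inverse relationship disappears in deeply sequenced regions — so at this
depth a negative correlation is evidence of the artifact, not of the
filter. Correspondingly, the artifact-off control is judged one-sidedly
(no significant *negative* correlation): with thousands of cytosines, a
two-sided test detects harmless sub-0.02 curvature of the binomial log
mean.

The targeted experiment samples 400 template molecules per amplicon and
arm (~400× coverage, comparable to deep amplicon sequencing), over six
amplicons mirroring the canonical design's lengths, placement and strand
targeting. Two of them (the D-loop amplicons at 6–298 and 279–458) fall
inside the default protected window; the other four act as within-run
negative controls. Replication uses independent seeds.

Determinism: every generator takes an explicit seed and restores the
caller's RNG state; rerunning any experiment with the same configuration
and seed reproduces its outputs byte-identically, and each run writes a
manifest (configuration, seed, package version, per-stage record counts).

Degenerate inputs: empty intervals, non-cytosine methylome sites,
probability parameters outside [0, 1], oversized references and
all-ties sign tests are rejected or flagged rather than silently handled.

## What the simulation does and does not show

The simulator reproduces the *mechanism* — structure-dependent conversion
failure and release bias on a circular genome — with a known zero ground
truth, so passing tests show that the pipeline's statistics detect the
artifact when it is present and stay silent when it is absent. It does not
model real mtDNA sequence (only length and GC), catenanes, protein
occupancy footprints, PCR amplification bias, or quality-dependent
sequencing error; the published real-data effect sizes (pooled r near
−0.9, sign-test p-values at the 10^-41 scale, per-region percentages from
particular cell lines) depend on unreleased reads and are reference points,
not reproduction targets. The mouse situation — a long nuclear segment
with perfect mtDNA identity that erases mapping over part of the genome —
is noted but not emulated, as it requires the real nuclear assembly.

The worked human example uses the mitochondrial reference shipped with the
seqinr package (NC_001807.4), whose unique BamHI site falls at 14259 in
that assembly's numbering; the rCRS (NC_012920.1) numbering of the same
site is 14258, the two references differing by upstream indels.
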