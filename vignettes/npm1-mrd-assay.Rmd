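---
title: "Ultradeep amplicon sequencing MRD for NPM1-mutated AML: models and methods"
author: "npm1mrd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultradeep amplicon sequencing MRD for NPM1-mutated AML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npm1mrd)
```

## The assay

Acute myeloid leukemia with mutated *NPM1* carries recurrent 4-nt
insertions in exon 12 of the gene. Because these insertions are specific to
the leukemic blast compartment, the fraction of sequencing reads carrying
an insertion — the variant allele frequency (VAF) — is a direct measure of
measurable residual disease (MRD) after therapy. `npm1mrd` implements the
complete computational side of an ultradeep, dual-indexed amplicon
sequencing assay for this purpose:

1. **Read simulation** (`simulateSample()`, `simulateRun()`) — seeded
   synthetic paired-end reads with known truth, standing in for cell-line
   dilutions and patient libraries.
2. **Dual-index demultiplexing** (`demultiplex()`) — joint 10-nt i7/i5
   barcode matching with quarantine of index-hopping conflicts.
3. **Pair self-assembly** (`mergePairs()`) — overlap-based consensus of
   each 150 bp read pair into one full-length amplicon read.
4. **Targeted insertion calling** (`callSample()`) — banded glocal
   alignment to the amplicon, left-normalized insertion grouping, the
   two-supporting-read pass rule, and VAF estimation.
5. **Assay validation** (`limitOfBlank()`, `limitOfDetection()`,
   `monitorPrecision()`) — the designed limit-of-blank, limit-of-detection
   and precision-control experiments.
6. **MRD classification** (`logReduction()`, `classifyMRD()`,
   `youdenCutoff()`) — the patient-level log-reduction rule between
   post-induction (PI) and post-consolidation (PC) time points.

A run-level *bioinformatics control* — reads carrying a fixed 20-nt
insertion on a reserved index pair — travels through every simulated run;
recovering it end to end (`verifyBioinfControl()`) is the gate for
reporting anything else from that run.

## Coordinates, the reference and the catalog

All internal coordinates are 0-based and half-open; an insertion is a gap
position `position0` plus the inserted bases (insertion between
`position0 - 1` and `position0`). HGVS-style `c.` coordinates appear only
at the parse/format boundary (`parseHgvs()` / `hgvs()`), connected to
amplicon coordinates through a single integer `codingOffset`.

The packaged reference (`npm1Amplicon()`) is a **synthetic 250-nt
stand-in** for the exon-12 amplicon: the assay's true primer and amplicon
coordinates are not public, and every function in the package is
parameterized by an `AmpliconReference`, so a laboratory's real amplicon
drops in via `readAmpliconReference()` without code changes. The synthetic
sequence was generated once under a fixed seed with two constraints — no
homopolymer of length 4 and no adjacent repeated 4-mer near the hotspot —
so that the packaged catalog entries are fixed points of left
normalization and remain distinct. One consequence of the synthetic
context is that the "type A" entry is *not* literally a tandem
duplication of its left flank, as it is in the real *NPM1* exon-12
sequence; in real data the duplication ambiguity is exactly what left
normalization resolves, and the normalization tests exercise that case on
a repeat-bearing test amplicon.

The catalog (`npm1Catalog()`) ships 12 4-nt insertion types: types A, B
and D use the literature insert sequences (TCTG, CATG, CCTG), one entry is
the published novel insertion `c.873_874insGCCA`, and the remaining eight
are synthetic fixture entries (`fixture-01` … `fixture-08`) that make the
breadth of a 12-type catalog testable. Equivalent insertion
representations are grouped by VCF-style left alignment
(`leftNormalize()`): shift the gap left while the last inserted base
equals the reference base left of the gap, rotating the inserted string.
Normalization is idempotent and preserves the implied mutant haplotype;
both properties are tested.

## What the simulator emulates — and what it does not

Each simulated fragment spans the full amplicon (amplicon sequencing, not
shotgun); a fragment is mutant with per-fragment probability equal to the
configured mutant fraction, so true mutant counts are binomial. Read 1 is
the first `read_length` bases, read 2 the reverse complement of the last
`read_length` bases (150 bp paired-end chemistry by default). The error
model is deliberately minimal:

* independent per-base substitutions at a uniform rate
  (default $10^{-3}$), never reproducing the original base;
* rare 1-nt indel errors at a per-base rate of $10^{-6}$ by default —
  the process that makes the limit of blank non-trivial;
* quality scores equal to the Phred equivalent of the substitution rate
  (capped at Q41), so quality-aware consensus behaves sensibly.

Index hopping is modeled at the run level: a hopped read has one of its
two indices replaced by the corresponding index of another sample, which
is precisely the signature dual indexing quarantines. Per-base error
positions are drawn independently (a repeated position re-randomizes the
same base; at these rates the effect is negligible).

Not modeled: PCR duplicates and jackpot amplification, quality decay by
cycle, UMI chemistry, index sequencing errors, or any position-dependent
error profile. Passing tests on these simulations therefore demonstrate
the *pipeline's* correctness — conservation, inversion of the generative
process, exact counting, threshold behavior — not robustness to every
artifact of real sequencers. The sequencer error profile of the original
assay is unpublished; all rates here are configurable stand-ins.

Seeding: every sample carries its own seed; cohort builders
(`simulateBlankCohort()`, `simulateDilutionSeries()`) derive per-sample
seeds deterministically from a master seed via `sample.int()` after
`set.seed(master)`, so cohorts are reproducible sample by sample and runs
are byte-identical under a fixed seed.

## Merging and alignment: contracts and numerical choices

**Merging.** For each pair, every overlap length of at least
`min_overlap = 20` is scored as matches − mismatches; the best-scoring
overlap wins, ties broken toward the longer overlap. Consensus bases in
the overlap: agreement keeps the base with quality `min(q1 + q2, 41)`;
disagreement takes the higher-quality base with quality
`higher − lower`, an exact tie keeping the read-1 base (deterministic).
Pairs are *rejected*, not errored, when the best overlap is shorter than
`min_overlap` or its mismatch fraction exceeds `max_mismatch_frac = 0.25`;
amplicon design guarantees overlap, so unmergeable pairs are suspect and
are only counted in QC. This is a simplified, fully specified equivalent
of the probabilistic PANDAseq-style assemblers typically used on
amplicon data.

**Alignment.** Merged reads are aligned to the single amplicon directly —
for a single-locus assay this carries the same information as genome-wide
mapping while removing two external tools. The aligner is a banded global
(Gotoh, affine-gap) dynamic program: match +1, mismatch −2, gap open −6,
gap extend −1 (a gap of length $L$ costs $6 + L$), band half-width 32
around the length-difference diagonal, so any insertion the assay can
produce (including the 20-nt control) is inside the band. Reads with more
than 20% of reference positions mismatched are unalignable and excluded
from depth. Tie-breaks are deterministic (state preference in the DP), and
reported insertions are left-normalized afterwards, collapsing co-optimal
gap placements to one canonical call.

Two performance shortcuts are used, both bit-identical to the full DP and
property-tested as such: reads exactly equal to the reference or to a
known mutant haplotype skip alignment via hash lookup, and equal-length
reads with at most 4 mismatches take an ungapped path (any gapped
alignment of equal-length strings pays two gap runs, at least −14, while
4 mismatches cost only −12 — so the ungapped alignment is provably
optimal there). Identical read pairs and identical merged sequences are
processed once and fanned back out. These shortcuts are what keep
$5 \times 10^5$-read samples at interactive speed.

**Calling.** Identical normalized insertions are grouped across reads;
depth is the number of alignable hotspot-spanning reads (with full-length
amplicon reads and a global alignment, every alignable read spans the
hotspot with ample flank, and the 10-nt flank requirement is checked
structurally); VAF = supporting / depth. A call **passes** iff it has at
least `min_mutant_reads = 2` supporting reads — the assay's published
decision rule, configurable. Only insertions whose normalized position
lies in the hotspot window are reported as calls; indel artifacts
elsewhere in the amplicon still count in depth. Multiple distinct
insertions in one sample are all reported, which is what permits
surveillance for a clonal switch of the mutation type.

## Validation statistics

**Limit of blank.** Nonparametric, in the style of clinical-assay
guidance: the background VAF of each mutation-free sample (the largest
hotspot-insertion VAF it shows, 0 if none) is collected over the blank
cohort (the design uses 30 blanks), and LOB is the empirical
$(1-\alpha)$ quantile at rank $0.5 + n(1-\alpha)$ with interpolation,
clamped to $[1, n]$. All-zero blanks give LOB = 0; $\alpha = 0$ gives the
maximum.

**Limit of detection.** The smallest dilution fraction whose detection
proportion (pass call of the spiked mutation) reaches
`required_hit_rate = 0.95` *and* whose detected replicates' VAFs all
exceed the LOB. Undetected replicates already count against the hit rate,
so the VAF condition is applied to detected replicates. With no indel
errors, detection at a level is governed purely by Poisson sampling of
mutant fragments against the 2-read rule, which the tests exploit as an
oracle: at $5\times10^5$ reads per level the expected mutant count at
fraction $10^{-5}$ is 5, and $P(\ge 2) \approx 0.96$, so the assay's
0.001% sensitivity claim is reproduced. Replicates per level default
to 3 (the original replicate count is unpublished); no parametric
(probit) LOD fit is attempted.

**Precision controls.** Every run carries a high (0.2% VAF) and a low
(0.02% VAF) control emulating a mutant cell line diluted in normal DNA
(`controlConfig()`, 50,000 fragments). Monitoring is Levey-Jennings with
Westgard-style rules: the first 5 runs establish fixed control limits
(mean ± SD) and later runs warn beyond 2 SD and fail beyond 3 SD or on
the second of two consecutive same-side warnings. Fixed baseline limits
were chosen over an expanding window deliberately: a first warning
inflates a running SD and would mask the repeat-warn rule. If all
baseline values are identical (zero SD), any departure from them fails.

## MRD classification

For a patient with PI and PC VAFs, the log reduction is
$\log_{10}(\mathrm{VAF}_{PI}/\mathrm{VAF}_{PC})$, and the patient is
NGS-MRD **positive** iff it is below the cutoff (default 1 log). Zero
VAFs need sentinels, and only one rule is inherited from the assay
definition (both zero ⇒ negative); the rest follow the direction of
effect: PC = 0 with PI > 0 is maximal clearance ($+\infty$, negative);
PI = 0 with PC > 0 is $-\infty$ (rising from nothing, positive).
Classification is monotone in the cutoff.

`youdenCutoff()` re-derives a cutoff on a cohort with binary outcome
labels: candidate thresholds are midpoints between consecutive distinct
finite log reductions plus sentinels just outside the finite range and
$\pm\infty$ (so every achievable classification, including
"-∞ patients only", is in the candidate set); the threshold maximizing
Youden's $J = \text{sensitivity} + \text{specificity} - 1$ is returned
with ties broken toward higher sensitivity and then the lower threshold,
alongside the full ROC table for audit. The outcome label is supplied by
the user; survival modeling itself is out of scope. Whether the original
ROC analysis handled zero-VAF sentinels is unknown — the procedure, not
the cohort value it produced, is the contract here, and the tests pin the
procedure to an exhaustive brute-force scan and an independent ROC
implementation.

## A worked example

```{r example}
ref <- npm1Amplicon()
cat12 <- npm1Catalog(ref)
typeA <- parseHgvs("c.863_864insTCTG", ref)

cfg <- SimConfig("patient_PI", seed = 42, n_fragments = 20000,
                 mutant_fraction = 0.02, mutation = typeA)
run <- simulateRun(list(cfg), ref, include_bioinf_control = TRUE, seed = 42)
pr <- processRun(run$reads, run$sheet, ref, cat12)
pr$qc
sampleCalls(pr$results$patient_PI)
```

```{r mrd}
pts <- data.frame(patient_id = c("p1", "p2", "p3"),
                  vaf_pi = c(0.031, 0.024, 0),
                  vaf_pc = c(0.012, 0.0004, 0))
classifyMRD(pts, cutoff = 1)
```

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script size the experiments to the
validation design itself: the dilution series runs four levels at
$5\times10^5$ merged reads per level, the precision controls at 50,000
reads, the catalog breadth check at 10,000 reads per entry, and the blank
cohort at 30 samples; the deduplicating fast paths make these sizes
routine on a single core. Degenerate inputs are defined, not accidental:
empty samples and fully unalignable samples return a `"no coverage"`
result with no calls; a missing control fails run QC with
`"control missing"`; fewer than 2 blanks, fewer than 2 dilution levels,
or a single-class outcome vector are errors.

## Known limitations

* The packaged amplicon and eight of the twelve catalog entries are
  synthetic fixtures; results on them validate the pipeline, not the
  biology of a particular laboratory's amplicon.
* The error model excludes PCR jackpots and position-dependent error,
  so real-world LOB is expected to be less favorable than simulated LOB.
* Insertions only: substitutions and deletions at the locus are out of
  scope by design, as is any non-*NPM1* marker.
* The Youden cutoff is only as good as the outcome labels supplied;
  the package does not model survival.
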