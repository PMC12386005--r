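---
title: "Typing HLA-B*58:01 from Sanger consensus sequences: models and design"
author: "hlaB5801 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing HLA-B*58:01 from Sanger consensus sequences: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaB5801)
```

## Scope and model

HLA-B\*58:01 confers a codominant risk of severe cutaneous adverse
reactions under allopurinol: one copy is enough, so the clinically
relevant quantity is *carriage*, not phase. The package types carriage
from short Sanger amplicon consensus sequences by a two-stage diagnostic
screen, types the candidate surrogate SNP rs9263726 from a third
amplicon, and computes the cohort-level statistics that a screening study
reports. Input is always the already-called consensus string; chromatogram
interpretation and base calling are upstream of this package.

The diploid consensus model is simple: at any position where a subject's
two alleles disagree, a Sanger trace shows both bases and the consensus
records the IUPAC two-base code (R = A/G, Y = C/T, S = C/G, W = A/T,
K = G/T, M = A/C). `N` and the three-base codes mean the position could
not be read. This is the entire observation model — there is no
quality-score or error-rate layer, because the consensus is taken at face
value (a deliberate limitation, see below).

## The diagnostic panel

A *diagnostic position* is an alignment column where the target allele's
base separates it from other alleles. The packaged panel is the
eight-position set in the sequenced-fragment coordinate frame — exon-3
amplicon 353T, 355A, 368A, 379C, 387C; exon-2 amplicon 209A, 285G, 319C.
Fragment coordinates are used (position 387 exceeds the genomic exon-3
length); per-amplicon frame offsets are configurable for consensus
strings trimmed differently.

`findDiagnosticPositions()` re-derives such panels from any allele
alignment. One definitional subtlety is resolved deliberately: at
positions 368 and 209 the *reference* allele (HLA00132.1) shares the
target base, yet they belong to the panel — they still discriminate
against other alleles. Per-position uniqueness is therefore assessed
against all non-reference, non-target alleles; columns where only the
reference shares the target base are retained but flagged
`zygosity_informative = FALSE`, because against a reference partner they
carry no heterozygosity signal. `verifyPanel()` stays strict: it
brute-force checks that **no** non-target allele, reference included,
matches the target base at every panel position jointly, and the
discovery function refuses any panel that fails it. The greedy
`minimal_joint` mode is a set cover with lowest-position tie-breaks; it
is deterministic but not guaranteed minimum-cardinality, so tests flag
(rather than fail on) redundant positions.

## Calling rules and tie-breaks

Stage 1 reads the five exon-3 positions. Any position whose observed base
set excludes the target base short-circuits to \*X/\*X — exon 2 is never
consulted, mirroring the two-stage laboratory workflow where exon 2 is
only sequenced for screen-positive samples. A stage-1-positive sample
without exon-2 data is `candidate_unconfirmed`, never a carrier call.

Zygosity is resolved only from the informative positions: homozygous
\*58:01/\*58:01 requires *all* of them homozygous for the target base;
any heterozygous informative position gives \*X/\*58:01. A mixed pattern
(some informative positions homozygous, some heterozygous) cannot arise
from a reference partner; it can arise from a partner allele sharing part
of the diagnostic pattern, so it is still called \*X/\*58:01 — carriage
is what matters — but flagged `pattern_inconsistent` for review. `N` at a
panel position yields `indeterminate`: missing data must never silently
become an \*X call. All parsing is case-insensitive.

rs9263726 is read at amplicon position 110: G → GG, R → GA, A → AA,
anything else `indeterminate`. Two coordinate conventions exist for this
SNP (a transcript frame and the amplicon frame); the position is a plain
argument, defaulting to the amplicon frame.

## Statistical methods

**Frequencies.** Allele counts use gene counting (2·hom + 1·het over 2N).
Percentages are rounded half away from zero (`roundHalfUp()`) at 2
decimals (1 decimal where the conventional report prints 1); raw
proportions are always retained alongside. Wilson intervals are used for
frequencies and Clopper–Pearson (via `binom.test`) for the surrogate
metrics, because the carrier counts involved are small (tens, not
hundreds). Frequencies are always computed from the genotype counts, not
copied from any printed allele count, which sidesteps transcription
errors in source tables.

**Surrogate performance.** Test-positive = carries ≥ 1 A allele,
condition-positive = carries ≥ 1 \*58:01 allele; sensitivity,
specificity, PPV and NPV follow from the joint table margins. A zero
margin reports `NA` with a reason rather than a number.

**EM haplotype frequencies and LD.** With genotypes unphased, only the
double heterozygote (\*X/\*58:01 × GA) is ambiguous between coupling
(58:01·A / X·G) and repulsion (58:01·G / X·A). The EM starts at linkage
equilibrium, splits the double heterozygotes by the current odds
p₁₁p₂₂/(p₁₁p₂₂ + p₁₂p₂₁) in the E-step, and re-estimates haplotype
frequencies by counting in the M-step. This preserves the observed allele
margins at every iteration and the log-likelihood is monotone. The
default tolerance is 1e-8 on the largest frequency update with a
1000-iteration cap (convergence takes ~10 iterations on cohort-sized
tables). D′ uses D_max = min(p₅₈p_G, p_Xp_A) for D > 0 and the symmetric
form for D < 0; a monomorphic locus reports D = D′ = r² = 0 with a
`"monomorphic"` note rather than NaN. The test suite checks the EM
against an independent grid-search maximum-likelihood oracle over the
one free parameter p(58:01·A).

**Hardy–Weinberg.** The exact conditional test enumerates all
heterozygote counts compatible with the observed allele counts and sums
the probabilities not exceeding the observed configuration's (with a
1e-12 relative tie tolerance), computed via log-factorials for stability.

**Clinical associations.** Pearson r with the t-distribution p-value on
n−2 df, pairwise-complete; strata under 3 complete pairs are flagged with
no p. Group comparisons default to Student's equal-variance t (the
convention of the SPSS workflows this mirrors, which rarely name the
method) with Welch always co-reported, listwise within each comparison.
No multiple-testing correction is applied anywhere — deliberately, to
match how such screening cohorts are conventionally reported; a
correction would be trivial to add downstream of the returned tables.
p-values everywhere are two-sided.

## The synthetic-data generator

The generator's defaults are the emulated study conditions, fixed once:

* a 133-subject cohort in roster mode with joint genotype counts
  (XX·GG 106, XX·GA 11, X58·GG 6, X58·GA 10), or sample mode drawing two
  haplotypes per subject from configurable frequencies;
* 93.2% male (exact count), male ages N(51.44, 14.59²), female
  N(70.33, 10.64²) truncated at 18 and rounded to years; carriers are
  placed among males by default, since the emulated cohort had no female
  carriers;
* amplicon lengths 613 / 495 / 265 bp (exon 2, exon 3, PSORS1C1), 20
  decoy alleles at 2% divergence from the reference;
* paraclinical means/SDs from the non-carrier group of the emulated
  cohort, each variable's correlation with uric acid as the target
  correlation structure (e.g. PLT 0.174, Cre 0.195), and a +2.702
  ×10⁹/L WBC shift in carriers.

Decoy alleles are constructed to differ from the target at *every* panel
position (keeping the reference base with probability 0.7, otherwise a
third base) plus random substitutions elsewhere. This encodes the premise
of the diagnostic panel — that no other allele shows the target bases at
those positions — and makes the printed panel the exact per-position
discovery result on the synthetic database. Correlated paraclinical
variables come from a multivariate normal whose correlation matrix is
nearest-PD-adjusted (`Matrix::nearPD`) if a user configuration is not
positive definite; genotype effects are additive mean shifts. One master
seed drives every stage through deterministically derived sub-seeds, so a
config+seed pair yields byte-identical FASTA/CSV output.

What the generator does *not* emulate: sequencing noise and failed reads
(a noise hook would sit in `synthesizeSequences`; default is noise-free),
indels (the panel positions are substitutions), more than two alleles per
subject, chromatogram-level artifacts, and non-normal paraclinical
distributions. Green round-trip tests therefore demonstrate the
correctness of the calling logic under clean consensus input, not
robustness to dirty traces; real-data use should treat `indeterminate`
and `pattern_inconsistent` outputs as the signal to re-examine traces.

## Numerical and design choices

* Percent rounding half-away-from-zero with a 1e-9 relative nudge, so
  decimal .5 values stored just below .5 in binary still round up.
* EM vs grid oracle comparisons are absolute (the parameter lives near
  0.05, where relative tolerances mislead).
* Greedy tie-break: lowest position index, for determinism.
* The truth roster is written separately from the pipeline inputs so a
  round-trip test cannot accidentally leak truth into the caller.
* Config files for the CLI wrapper are JSON; R-level configuration is a
  plain list built by `simulationConfig()`.

## Problem sizes used in the test suite

The suite exercises the cohort scale directly (133 subjects end to end),
100 random rosters of 10–200 subjects for the round-trip property, EM
recovery at n = 5,000 over 200 replicates, and 1,000-replicate null
calibrations of the correlation and t tests at the study's stratum sizes
(124; 117 vs 16). These sizes give the property checks sampling error
well under their tolerances (±0.01 for haplotype recovery, ±0.02 for
type-I error, ±0.03 for correlation recovery) while keeping the whole
suite in the low minutes on a single core.

## Known limitations

Typing is binary (target allele vs anything else): other alleles sharing
part of the diagnostic pattern are never identified by name, and a
partner allele identical to the target over both amplicons would be
indistinguishable from homozygosity. The panel is only as good as the
allele alignment it was verified against; new database releases can add
alleles that collide with an old panel, which is exactly what
`verifyPanel()` re-checks. The clinical module reproduces the *structure*
of a screening study's tables; its numerical outputs on synthetic cohorts
are validated against the generator's ground truth, not against any real
patient dataset.
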