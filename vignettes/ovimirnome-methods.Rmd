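---
title: "Methods: cross-species miRNome assembly and age-group differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species miRNome assembly and age-group differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovimirnome)
```

## Scope and model

`ovimirnome` implements a small-RNA sequencing analysis for species whose
own miRNA catalogs are sparse, as is the case for sheep: mature miRNA
sequences cloned in *any* species (plus recently published
species-specific candidates, the `PC-` entries) are mapped exactly onto
the study genome, collapsed to a non-overlapping locus set (the
"miRNome"), and used as the annotation over which small-RNA reads are
counted.  Age-group expression shifts are then tested per tissue with
moderated t-statistics, and candidate shifts are validated by
delta-delta-Ct qRT-PCR.  The package is built around a four-tissue
(lung, pulmonary artery, left and right ventricle), three-age-group
(preterm fetus PT, near-term fetus NT, neonate Neo) cardiopulmonary
design with 3 sequencing and 4 qPCR animals per cell, but every layout
parameter is configurable through `sim_design()` and the sample sheet.

## Pipeline stages and their parameters

**Trimming** (`trim_reads`, `size_select`).  Reads are processed in a
fixed cascade: the leading run of N's is stripped; the 5' adapter is
removed from the read prefix; the 3' adapter from the suffix; both steps
are repeated with the reverse-complemented adapters.  A match must span
at least `min_overlap = 5` bases and may contain
`floor(max_error_rate * span)` mismatches (`max_error_rate = 0.1`); the
longest within-budget match is removed.  Size selection keeps reads of
15–32 nt inclusive — the bounds are read literally from the common
mature-miRNA length range, and reads of exactly 15 or 32 nt are kept.
Adapter sequences are configuration, never hard-coded: library kits
differ.  Internal N's are retained (only the 5' run is stripped) and
no quality trimming is attempted.

**Alignment** (`build_index`, `align_sequence`, `align_batch`).  A
desk-scale ungapped seed-and-extend aligner: with mismatch budget
`max_mm`, seeds of length `k` are taken from `max_mm + 1` disjoint query
segments, so by pigeonhole every placement within budget contains an
exact seed and the hit set provably equals an exhaustive Hamming scan
(property-tested against exactly that oracle).  The seed length defaults
to `k = 5`, the largest value for which the guarantee holds for a 15-nt
query at two mismatches (`(max_mm + 1) * k <= L`).  Only placements
tying the minimal mismatch count are reported; among equal-best
placements `align_batch` retains the lexicographically smallest
(chrom, start, strand) and flags the read non-unique, with
`policy = "unique"` available to discard multi-mapped reads instead.
N positions always count as mismatches.  Indels, quality-aware scoring
and genome-scale indexing are out of scope: at 15–32 nt, ungapped
mismatch-budget semantics match the behaviour of the short-read mappers
used for miRNA data.

**miRNome assembly** (`map_catalog`, `consolidate_loci`,
`census_prefixes`).  Catalog sequences are converted U→T and mapped with
a zero-mismatch budget, one placement per entry under the aligner tie
policy.  Redundancy removal is greedy: candidates sorted by
species-prefix priority, then descending length, then entry id, accepted
iff they overlap no accepted locus on the same (chrom, strand).  The
priority order (`oar > PC > none > bta > hsa > mmu > others
alphabetical`) is a design choice — same-species names should win when
several catalogs report the same locus — and is fully configurable; no
published rule exists for this resolution, only the requirement that the
result be non-overlapping.  Overlap is strand-aware by default because
mature miRNAs are strand-specific; `strand_aware = FALSE` reproduces a
strand-blind merge.  Variant-suffix notation in entry names (`_R+1`,
`_L+1R-1`, `1ss6CG`) is treated as opaque text.  The census parses the
token before the first hyphen: `PC-` entries count as PC, bare
`miR-`/`let-` names as NONE (conserved across species), three-letter
tokens as species codes, anything else as OTHER with a warning.

**Quantification** (`assign_counts`, `compute_cpm`, `filter_expressed`).
A read increments a locus iff it overlaps it by at least one base,
strand-blind by default (the convention of the standard read-summarization
tools); reads overlapping two loci — possible only across strands — are
ambiguous and unassigned, as are non-unique alignments unless
`count_multi = TRUE`.  Library sizes default to total assigned counts per
sample, since the cpm scale is defined within the miRNA analysis.  The
expression filter keeps miRNAs with cpm ≥ 1 in ≥ 3 samples, counted over
*all* samples regardless of tissue or group: "at least three samples" is
read as any three, the literal reading; with three replicates per cell
this also guarantees a miRNA expressed in one full condition survives.
Filtering does not recompute library sizes, so cpm values are unchanged.

**Differential expression** (`tmm_factors`, `voom_logcpm`,
`fit_moderated_t`, `bh_adjust`, `call_significant`, `run_de`).
Normalization factors use the trimmed mean of M-values: against a
reference sample (closest cpm upper quartile to the mean), gene-wise
M and A values over genes positive in both samples, 30% of M and 5% of A
trimmed from each tail, inverse-variance-weighted mean of the remaining
M, factors rescaled to geometric mean 1.  Log-cpm is
`log2((count + 0.5) / (libsize * factor + 1) * 1e6)`; note the offsets
make the transform only asymptotically invariant to joint count/library
doubling.  Cyclic pairwise loess (span 0.5, `stats::lowess`) removes
residual intensity-dependent differences.  Precision weights come from a
mean–variance trend: the square root of each gene's residual standard
deviation under the cell-means model is smoothed against average log
count, and each observation's weight is the predicted standard deviation
to the power −4, floored at a small positive value so weights stay
strictly positive; with fewer than 10 genes the trend is unreliable and
unit weights are used with a warning.  Testing is per tissue: a weighted
least-squares group-means fit, residual variances shrunk by empirical
Bayes with prior degrees of freedom `d0` and prior variance `s0_sq`
estimated by moment matching the log residual variances (Newton
inversion of the trigamma function), and a t-statistic on
`d0 + residual df` degrees of freedom for each consecutive-group
contrast (NT−PT, Neo−NT).  `d0_override = 0` recovers the ordinary
two-sample t; `d0_override = Inf` the normal-like large-prior limit —
both are pinned by tests.  The `robust` option trims 10% of extreme
variances before moment matching; it is an approximation to outlier-robust
hyperparameter estimation, off by default.  BH adjustment is applied per
(tissue, contrast) family, reproducing per-tissue FDR columns; the call
rule is strict: FDR < 0.15 *and* average log2-cpm > 1, results sorted by
FDR within tissue.  Average log expression is computed across the
tissue's samples (the analyses are tissue-separate; recorded here because
the alternative — across all samples — is also defensible).

**qPCR** (`select_reference_mirnas`, `compute_delta_ct`,
`compute_fold_change`, `group_tests`, `run_qpcr`).  Reference miRNAs are
the two rows with the smallest log2-cpm standard deviation across all
sequencing samples (ties broken by id).  Technical replicates are
collapsed by arithmetic mean before any difference is formed (the
collapse rule is unstated in common protocols; the mean is the
convention).  ΔCt subtracts the average of the two reference means per
sample; ΔΔCt is the difference of group means of per-animal ΔCt — not of
pooled Cts — matching a per-animal design; fold change is 2^−ΔΔCt.
Group tests are one-way ANOVA plus unpaired pooled-variance t-tests with
Bonferroni factor m = 3 (all group pairs, the convention of the usual
desktop statistics programs; configurable since only two contrasts are
planned).  ANOVA is reported alongside the t-tests, never used as a
gatekeeper.  Amplification-efficiency correction and well outlier
rejection are out of scope.

**Reporting** (`percent_change`, `concordance`, `export_table2`).
Percent changes round half away from zero, which reproduces published
percent phrasings of three-decimal fold changes.  Concordance joins
sequencing and qPCR calls on (miRNA, tissue, contrast) after optional
assay-name aliasing (qPCR assays are often named for the homologous
human/cattle miRNA); a change is confirmed iff significant on both sides
(FDR < 0.15, adjusted p < 0.05) with agreeing direction.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known
ground truth: a uniform-random genome; planted non-overlapping 18–25 nt
loci on either strand emitted as an RNA-alphabet catalog whose prefix mix
defaults to the composition typical of a cross-species cardiopulmonary
catalog (weights 504 PC : 288 none : 236 bta : 130 hsa : 80 oar : 62
other) plus a configurable decoy fraction (default 0.1) absent from the
genome; adapter-flanked Q30 reads with negative-binomial per-locus
counts (variance μ + μ²φ, φ = 0.1 by default), 10% random-sequence
background (the published pipelines filter other small-RNA species but
report no proportion; 10% exercises the annotation filter), a 5% leading-N
fraction, and a configurable per-base error rate defaulting to 0 so exact
alignment checks are deterministic; direct count matrices with two
designated reference miRNAs of near-zero dispersion; and Ct tables
following `baseline − log2(abundance) + N(0, sd)` with triplicate wells
(sd = 0.2 by default, a realistic technical scatter).  Planted effects
apply to the later group of their contrast and all subsequent groups, so
each effect is visible in exactly one consecutive contrast.  Library-size
imbalance between tissues is configurable and defaults to 1 (heart
libraries are often smaller than lung libraries in practice, but no
magnitude is established).  Every generator is a pure function of its
arguments and the design seed.

What the generator does *not* emulate — realistic base-quality profiles,
hairpin precursors and isomiR structure, ligation bias, biological
covariance between miRNAs — bounds what green tests mean: they establish
that the implementation computes the intended statistics and recovers
planted signals under the stated noise model, not that the pipeline's
operating characteristics transfer to any particular real library.

## Numerical choices and problem sizes

Local regressions use span 0.5 throughout and are deterministic given the
data.  Ties in reference selection and consolidation are broken
lexicographically, which together with the priority sort makes miRNome
assembly invariant to catalog order (property-tested).  Degenerate
inputs: empty mapped sets give an empty miRNome; zero-variance t-tests
fall back to a 0/1 p-value with a warning; zero libraries, missing
references and singular designs raise errors naming the offender.

The shipped validation suite runs the aligner–oracle comparison on 1000
random instances (genomes ≤ 6 kb), miRNome invariants on 500 random
catalogs, type-I calibration on 200 null simulations of 200 miRNAs at
3 vs 3, sensitivity on 50 simulations with planted two-fold effects, and
one full FASTQ-to-calls run at 60 loci and nine samples of 30 000 reads —
sizes chosen so the whole suite completes in minutes on a laptop while
keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

The aligner is deliberately desk-scale (hash index, ungapped); running
against a full mammalian genome is out of scope.  Exact numerical
equality with the established normalization/EB packages is not a goal —
they serve as cross-check oracles at loose tolerances in the test suite —
and the robust EB variant is a trimmed approximation, not a replication
of any package's estimator.  The expression filter's "any three samples"
reading and the per-tissue average-log-expression convention are
documented choices; both have defensible alternatives and are isolated
behind function arguments or small code paths.
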