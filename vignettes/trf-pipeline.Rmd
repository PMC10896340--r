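---
title: "Classifying and quantifying tRNA-derived fragments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and quantifying tRNA-derived fragments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(trfkit)
```

## The problem

RNA polymerase III (Pol III) synthesizes tRNAs and other small
non-coding RNAs. A nascent pre-tRNA carries a 5'-leader, sometimes an
intron, and a 3'-trailer that ends in the oligo(U) run templated by the
oligo(T) terminator of the gene. Processing releases three classes of
small fragments that a small-RNA-seq library will sample:

* **tRF-5** — from the mature 5' end;
* **tRF-3** — from the mature 3' end, including the
  post-transcriptionally added CCA;
* **tRF-1** — the 3'-trailer itself, released by RNase Z/ELAC2 cleavage
  at the discriminator and Pol III termination at the first oligo(T)
  tract (the *T1 terminator*, defined as the leftmost run of ≥4 Ts
  downstream of the gene).

Because tRF-1s derive from nascent transcripts and are stabilized by La
protein binding to their 3'-UUU-OH ends, their abundance relative to
mature-tRNA-derived tRF-3s from the *same gene* indexes the balance
between Pol III output and La availability. Under Pol III deficiency the
profile shifts — tRF-1s up, tRF-5/tRF-3 down — which makes per-gene
tRF-1/tRF-3 ratios candidate deficiency biomarkers. trfkit implements
the full quantification route from reads to that metric, plus the decay
kinetics used to separate transcriptional from post-transcriptional
effects.

A generic genome aligner handles this badly: a tRF-3 read ends in a CCA
that is absent from the genome, mature and pre-tRNA sequences overlap,
and tRF-1s live downstream of the annotated gene. The pipeline therefore
maps against purpose-built references.

## Reference construction

From a set of tRNA gene models (genomic body, optional intron with
0-based half-open coordinates, up to 150 nt of downstream sequence) two
reference layouts are built:

* **Set 1 (cascade)** — stage 1: mature miRNAs plus other ncRNAs
  (absorbs background); stage 2: mature tRNAs (introns excised, `CCA`
  appended — always appended, even if the genomic 3' end happens to read
  CCA, so record lengths are reproducible); stage 3: pre-tRNAs (intron
  retained, body + 150-nt downstream window, no 5'-leader).
* **Set 2 (concatenated)** — one stage holding the class-defining
  windows: tRF-5 = first 35 nt of each mature tRNA, tRF-3 = 3'-most
  30 nt including CCA, tRF-1 = the 150-nt downstream window, plus
  optional snaR-A/VtRNA-style records split into 5'/3' halves (odd
  lengths give the 5' half the extra base; the convention is arbitrary
  and documented rather than load-bearing).

All coordinates in the package are 0-based half-open. Duplicate
sequences across isodecoders are kept as separate records so per-gene
attribution survives; multi-mapping is resolved by the mapper's
deterministic tie-break below.

The terminator scanner returns the leftmost maximal run of ≥4
consecutive Ts in a downstream window; runs are never merged across
non-T bases, a run of exactly 4 is class `fourT`, longer runs
`fivePlusT`. An empty window or no qualifying run yields `found =
FALSE`, not an error, since chromosome-end truncation is legitimate
input.

## The alignment cascade

Reads are first length-filtered (default ≥18 nt; libraries are
size-selected for 15–50 nt inserts, and shorter inserts are too
ambiguous to map usefully). Each stage then maps reads end-to-end,
ungapped, sense or antisense, with at most 2 substitutions and no
indels; only reads unmapped at stage *k* proceed to stage *k* + 1, so a
read is counted exactly once, at the first reference able to explain
it. That ordering is a modelling decision, not a convenience: a tRF-5
read is also a perfect prefix of its pre-tRNA, and the cascade is what
assigns it to the mature reference rather than splitting counts.

The matching contract replaces a general-purpose aligner deliberately.
For 15–50-nt reads against references this small, end-to-end ungapped
matching with a substitution budget is behaviour-equivalent on
error-free data and — unlike a heuristic seed-and-extend tool — exactly
testable: the test suite checks the mapper against an exhaustive
all-positions scan oracle. Internally, exact occurrences are found by
hashing every reference substring of each read width, and mismatched
occurrences by a pigeonhole search (a read with ≤2 substitutions has at
least one of three disjoint segments exact; candidates from the segment
index are verified by direct comparison). The best hit is the one with
fewest mismatches; ties break deterministically by sense strand first,
then category order, lexicographic record id, leftmost position.
Additional hits are counted (capped at 10 alternates), but only the
primary record is quantified. Antisense hits are recorded and excluded
from tRF counting by default, since tRFs are sense fragments.

## Classification and quantification

On set-2 references, class membership is the owning category. On set-1,
position decides: a pre-tRNA read starting at or after the body end is a
tRF-1, a read straddling the body/downstream junction is an unprocessed
pre-tRNA fragment (`pre_other`), and mature-reference reads within 2 nt
of the 5' start or 3' end are tRF-5/tRF-3 (the 2-nt tolerance absorbs
exonucleolytic raggedness; set-2 membership needs no tolerance). A
tRF-1 whose 3' end extends *strictly* beyond the last T of its gene's
T1 terminator is flagged as terminator readthrough; a read ending
exactly at the last T is not readthrough.

Counts are tallied per (gene, class, sample) and normalized to CPM with
the per-sample total of primary mapped reads across **all** categories
as the library size; both reference sets share this denominator
definition within a run. Downstream:

* **Expression filter** — keep a locus when the 75th percentile of its
  per-sample CPMs is ≥20 (linear interpolation between order
  statistics, `quantile()` type 7). A high percentile rather than a
  mean keeps loci that are silent in one condition but high in another
  — exactly the loci a differential analysis cares about. The filter
  operates on CPM; the threshold's unit is CPM, so filtering raw counts
  against it would not be well defined. It is idempotent.
* **MA statistics** — loci below a 50-CPM cross-group mean are
  excluded; log2 fold changes use a 0.5-CPM pseudocount (an
  edgeR-flavoured stabilizer; the intragenic biomarker below uses *no*
  pseudocount because its candidates are pre-screened for abundance and
  a silently-zero denominator should be an error, not a zero).
* **Read-length histograms and positional coverage maps** provide the
  standard per-class quality views (coverage in body-anchored
  coordinates, with pre-tRNA positions annotated body vs downstream).

## The intragenic tRF-1/tRF-3 biomarker

For a gene with both classes quantified, the metric is the ratio of
tRF-1 to tRF-3 mean CPM within each group (means of replicate CPMs, at
least two replicates per group), and the *ratio of ratios* between case
and control. Because numerator and denominator come from the same
library, library size cancels: the metric is invariant to sequencing
depth, and `ratio_of_ratios(case, control) ×
ratio_of_ratios(control, case) = 1` exactly. The candidate screen
demands both classes above a CPM floor (default 50, mirroring the MA
cutoff — "substantially above background" has no canonical threshold)
in every sample, and ranks by the worst-case (minimum over controls)
ratio of ratios.

Group-level summaries (`class_ratio_summary()`) report per-gene
tRF1/(tRF3+tRF5), tRF1/tRF3 and tRF1/tRF5 distributions with median,
quartile and 5th–95th percentile boxes. The group-comparison test is a
pluggable hook defaulting to a Mann–Whitney test per pair: a two-way
ANOVA with Tukey correction is the classical choice for the
ratio-type × group layout, but its factor structure is ambiguous for
unbalanced per-gene ratio sets, so the package ships the
distribution-free default and lets the analyst supply the parametric
test where its assumptions are known to hold.

## Decay kinetics

Actinomycin-D time courses are normalized per replicate to the loading
control and to the t = 0 sample (untreated cells), then averaged. The
half-life is *the time at which 50% of the t = 0 RNA remains*; the
default estimator is log-linear interpolation between the two
timepoints bracketing the crossing,

$$ t_{1/2} = t_a + (t_b - t_a)\,\frac{\ln(v_a/50)}{\ln(v_a/v_b)}, $$

which reproduces the graphical dashed-rectangle read-off from a decay
plot and is exact on single-exponential data. A least-squares
single-exponential fit (`method = "exp_fit"`, linear least squares on
the log scale) is offered as the labelled alternative; both agree to
machine precision on noiseless data. Non-monotone series use the first
downward crossing; a series that never reaches 50% in the observed
window sets `not_reached` rather than extrapolating.

`attribute_difference()` formalizes the steady-state-vs-half-life
argument: if only stability differed between two cell states, the
steady-state ratio would match the half-life ratio; the *discrepancy*
(steady-state ratio / half-life ratio, both case/control) is the fold
difference left for transcription to explain. Classification works on
fold magnitudes `m(x) = max(x, 1/x)` with a declared 2-fold threshold:
`transcription_dominant` when the discrepancy reaches the threshold
while the half-life ratio does not, `stability_dominant` in the
opposite case, `mixed` when both or neither do. The magnitude form is
what makes the rule direction-agnostic and exactly symmetric under
case/control swap (the discrepancy inverts); a one-sided rule on the
raw ratio would classify an 8-fold *decrease* differently from an
8-fold increase of the same biology. The original argument is
qualitative; the 2-fold threshold is this package's declared constant.

Two bench utilities round this out: `probe_tm_ti()` evaluates the oligo
probe formula `Tm = 16.6 log10(M) + 0.41 Pgc + 81.5 − 675/L − 0.65`
(M molar salt, default 0.5; Pgc percent G+C; L length; the trailing
−0.65 is applied verbatim) with the hybridization/wash temperature Ti
fixed at Tm − 15 °C; and `decay_correct_signal()` rescales
radioactive-probe signal by `2^(elapsed/half-life)` with the 32P
half-life (14.3 days) as the documented default.

## What the simulator emulates — and what it does not

The synthetic-data module is first-class, tested code: every
quantitative claim the test suite makes is a recovery of parameters the
generator planted. Its defaults are chosen once as the study
conditions:

| parameter | default | why |
|---|---|---|
| `n_genes` | 60 | enough loci for stable medians at desk scale |
| `frac_4T` | 0.7 | ~70% of high-confidence human tRNA genes end in exactly 4 Ts |
| `frac_intron` | 0.065 | 28 of 429 high-confidence genes carry introns |
| `trailer_length_range` | 17–36 nt | keeps tRF-1 reads (trailer + terminator, incl. readthrough) inside the 15–50-nt insert window |
| `read_length_range` | 15–50 nt | the library size-selection window |
| `reads_per_sample` | 200,000 | typical desk-scale small-RNA library |
| `dispersion` | 0.1 | negative-binomial overdispersion of biological replicates |
| `class_weights` | tRF5 .25, tRF3 .25, tRF1 .20, miRNA .30 | miRNA-rich background with all three tRF classes well sampled |
| deficient condition | tRF-1 ×3, tRF-5 ×0.5, tRF-3 ×0.7, miRNA ×1.25 | tRF-1 up and tRF-5 more depleted than tRF-3, miRNAs mildly up |
| `la_kd_trf1_factor` | 0.5 | La knockdown halves tRF-1 accumulation |
| `readthrough_frac` | 0.1 | a minor readthrough population per gene |

Negative-binomial locus abundances were chosen because downstream
differential analysis assumes overdispersed counts; per-gene,
per-class baseline shares are drawn log-normally *once per gene set*,
so re-sequencing the same genes under different conditions or seeds
keeps locus identity — that is what makes per-gene ratio-of-ratios
recovery a fair test. Reads are error-free by default (ground truth
stays exact); an optional uniform substitution rate exercises the
mapper's mismatch budget. Each gene gets one intron at most, at the
canonical insertion point after body position 37. The planted T1
terminator is the only ≥4T run upstream of itself in the window, with
non-T flanks, so scanner recovery is unambiguous.

Real libraries differ in ways the generator deliberately does not
model: adapter remnants and UMIs, ragged 5' ends from partial
processing, position-dependent sequencing error, internal tRFs and
tRNA halves, modification-induced reverse-transcription stops, and
genes sharing identical windows (isodecoder collapse). Passing tests
therefore demonstrate that the *pipeline logic* is correct under known
ground truth — not that any particular biological library will be free
of those artefacts.

## Numerical choices and degenerate inputs

* Percentiles: `quantile()` type 7 (linear interpolation), stated
  because filter boundary behaviour depends on it.
* CPM after filtering is *not* recomputed; library size remains that of
  the full library, which is what keeps the filter idempotent.
* Tie-breaks in the mapper and the candidate screen are lexicographic
  and deterministic; permuting cascade stage order legitimately changes
  ambiguous assignments and is tested as such.
* Zero mapped reads in a declared sample is an error naming the sample;
  an undefined biomarker ratio is an error, not a zero; an absent T1
  terminator makes readthrough `NA`, not `FALSE`.
* A tRF-1 read request longer than its source window, or a trailer
  range whose T run would cross position 150, fails loudly at
  generation time.
* All randomness flows through explicit integer seeds; FASTQ output is
  byte-identical under a fixed seed.

## Problem sizes

The shipped tests run the full cascade on one 200,000-read library
(the conservation and source-stage-assignment checks), 20 independent
20,000-read simulations for the directional condition claims,
triplicate 200,000-read libraries per condition for biomarker
recovery, 10,000 random windows for the terminator-scanner oracle, and
50 stochastic triplicate time courses for half-life recovery — sizes
chosen so the whole suite completes in about a minute on a laptop
while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The ≤2-substitution ungapped contract is a stand-in for the original
  heuristic aligner's behaviour; it is validated on synthetic data
  only, and an external SAM-producing aligner can be substituted
  upstream of `assign_classes()` if indel tolerance is needed.
* Histidine G-1 addition and other post-transcriptional edits are not
  modelled in mature references.
* The half-life interpolation estimator is undefined (flagged) when
  the 50% crossing lies outside the sampled window; it does not
  extrapolate.
* Reads straddling the discriminator junction are classed `pre_other`;
  whether such fragments should count toward pre-tRNA totals or be
  discarded is a judgement call, and the class is kept separate so
  either convention can be applied downstream.
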