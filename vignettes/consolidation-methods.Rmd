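---
title: "Methods: clone-level VDJ consolidation and its scoring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-level VDJ consolidation and its scoring model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
design is the way it is: the processing model and its assumptions, the
parameters that matter, what the simulator does and does not emulate, the
numerical conventions, and the known limitations.

## The processing model

The package assumes the plate-multiplexed amplicon architecture used for
clonal BCR/TCR sequencing: every merged read reconstructs

```
[well barcode] [TSO] [leader + variable domain + constant stub] [constant primer]
```

Cleaning proceeds in the order merge → demultiplex → primer/chain → TSO →
N-filter → 3′ quality trim → length filter. The order matters: the barcode is
read off the intact 5′ end before anything is excised, the chain label is
derived from the 3′ constant primer before the TSO is removed, and the 385 bp
minimum-length filter runs last so it measures the retained insert, not the
raw merged read. Every stage emits a `(reads_in, reads_out, reads_discarded)`
triple and the suite asserts exact conservation at each stage and end to end.

Ambiguity is always resolved by discarding, never by guessing: a read tied
between two barcodes at the best distance goes to the unassigned pool, and a
read matching a light- and a heavy-chain primer equally well is dropped.
Downstream scoring assumes clean well and chain assignment; a silently
mis-assigned read would corrupt two wells at once, which is far worse than
losing one read. For the same reason the default tolerances differ: 0
mismatches for barcodes (they carry sample identity), 2 for primers and the
TSO (they only gate chain identity and are long enough to tolerate errors).

### Pair merging

The merger scans every ungapped placement of the reverse-complemented mate
against the forward read, scores each as `matches − mismatches`, and accepts
the best placement with overlap ≥ 20 and mismatch rate ≤ 0.1. Within the
overlap the higher-quality base wins and keeps its quality. The exhaustive
scan is implemented in a small C++ kernel; with 300 nt mates it is the only
stage whose cost would otherwise be visible.

### Denoising

ASVs are produced by exact dereplication followed by a greedy collapse: in
decreasing abundance, a sequence within Hamming distance 2 of an
already-retained ASV *and* with at most 0.1 times that ASV's dereplicated
count is absorbed into it (the most abundant qualifying parent wins; counts
are summed afterwards). Sequences of unequal length are never compared —
with a substitutions-only error model, equal-length comparison is exactly
what the data can produce, and it keeps the collapse well-posed. The ratio
test uses the parent's *dereplicated* count, not its running total, so the
result does not depend on absorption order beyond the abundance sort. The
suite checks the greedy output against an independently written brute-force
absorption on small inputs.

The denoiser sits behind a plain data-frame interface (`derep` output in,
ASV table out) precisely so that a heavier error-model-learning caller can
be substituted without touching anything downstream.

### Annotation and numbering

Segmentation into FR1–FR4/CDR1–CDR3 is delegated to a pluggable annotator:

* the **table backend** recognises a variable domain by exact amino-acid
  match against a region table (the simulator's ground truth, or any table
  of known chains) — this is the reference backend for all quantitative
  tests;
* the **motif backend** anchors on the conserved FR1 cysteine (≈ position
  23), the FR3 cysteine preceding CDR3, and the `[FW]G.G` J-motif opening
  FR4, then fills the interior with canonical splits, adjusting CDR1/CDR2
  widths until FR3 fits its numbering window. It never mistakes the chain
  class on clean chains but pins interior boundaries only approximately; it
  exists for data without a region table and is tested for aggregate hit
  rates, not exact boundaries.

Numbering uses fixed integer windows emulating the IMGT convention
(FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104 end-anchored at the
conserved Cys 104, CDR3 105–117, FR4 end-anchored at 127 for light-type and
128 for heavy-type chains). Insertion codes are deliberately not modelled;
consequently CDR3 lengths are limited to 13 residues and the simulator draws
5–13. This trades a corner of biological realism (very long heavy CDR3s) for
integer positions everywhere, which keeps span extraction and its tests
exact. The reported nucleotide span covers the annotated positions within
1–127/128; missing leading or trailing positions narrow the span and are
never padded.

Chains with any zero-length region are discarded; ASVs with identical
region-concatenated amino-acid sequences are binned (counts summed, the most
abundant member supplying the representative nucleotide sequence, ties
broken lexicographically); bins below 10% of their well+chain reads are
eliminated. The 10% threshold is inclusive ("minimum" semantics) and is
applied per chain per well, with the denominator equal to all cleaned reads
assigned to that chain's primer in the well — the same denominator the ASV
score uses.

## The star rating

For a chain bin observed in a replicate group (all samples sharing
project and parent):

* `asv = reads per sequence / reads per primer well` ∈ [0, 1];
* `match = (BR + ν·TR) − (1 − (BR + TR)/Total)`, where BR counts distinct
  subclones supporting the sequence, TR counts additional samples of
  already-counted subclones, and Total is the group size. The penalty term
  uses unweighted counts: ν controls only the reward, so at ν = 0 a
  technical replicate still shrinks the coverage penalty but earns nothing;
* `total = clamp(ln(match), 0, λ) + μ·asv` with defaults μ = 2, λ = 3.

Two published constraints on the total score — that λ is a *ceiling* on the
match component and that the score lives in (0, 5) — are incompatible with
reading its closed form `max(λ, ln(match))` literally, which would floor the
component at λ and force every total ≥ 3. The package resolves the conflict
in favour of the constraints: the default mode clamps `ln(match)` into
[0, λ], and the literal `max()` form is preserved behind
`scoring_params(literal_max = TRUE)` for auditability. Similarly, the match
formula can yield non-positive values for a lone hit in a large group
despite its stated (0, ∞) range; non-positive match maps to component 0
rather than erroring.

Conventions worth stating once: sample IDs `Project/Parent.subclone` split
on the first `/` and the last `.`; samples without a subclone part count as
one shared (empty) subclone, so two of them are TRs of each other;
percentiles are computed within chain class across the run with the
strictly-below convention (a singleton sits at percentile 0); the aberrant
light-chain rule flags light-type amino-acid sequences present in strictly
more than 50% of the run's samples (heavy chains never); complexity is the
product of distinct light and heavy sequence counts after flag removal.

High-confidence pairs require both chains strictly above 4 (or a
verified-by-cloning mark), take the maximum-scoring chain when several
qualify (ties: higher ASV score, then lexicographic nucleotide sequence),
and must be unique across *parent lines* — subclones of one parent
legitimately share their true chains, so uniqueness is enforced between
distinct parent groups rather than between raw samples. With the default
parameters a pair needs `ln(match) > 2`, i.e. match > e² ≈ 7.4, to clear the
threshold even at full read support: high confidence deliberately demands
broad replicate support, and small three-replicate designs cannot reach it.

## The pairing classifier

Positives are the selected high-confidence pairs; negatives rewire heavy
chains by a seeded derangement. The derangement is built from disjoint
transpositions over a seeded shuffle (one 3-cycle absorbs an odd leftover)
rather than drawn uniformly: a uniform derangement typically has only
O(log n) cycles, and since grouped cross-validation must keep every chain
sequence inside one fold, a few giant cycles would collapse all candidates
into one or two groups and make leakage-free 5-fold splitting degenerate.
Transpositions give ~n/2 small chain-sharing components, which are then
packed onto folds largest-first.

Features are fixed-order and order-stable: both CDR3 lengths, all 14 region
lengths, chain-class indicators, a germline-similarity stub (identity to the
nearest member of a supplied germline pool, via edit distance), and length
differences. The booster is xgboost with fixed hyperparameters (depth 3,
η = 0.3, 60 rounds, single thread) and a recorded seed; there is no tuning
loop. Metrics come from pooled held-out predictions; ROC-AUC uses the exact
rank (Mann–Whitney) formula, cross-checked against an independent ROC
implementation in the tests.

Held-out AUC under shuffled labels is estimated as the mean over several
independent shuffles: a single small-sample grouped-CV run under the null is
noticeably pessimistic (boosted trees overfit label noise, pushing held-out
AUC below 0.5), and averaging restores an unbiased view of chance-level
behaviour without touching the 0.5 ± 0.1 acceptance band.

## What the simulator emulates — and what it does not

`generate_clone` builds each chain from random non-stop codons with the two
conserved cysteines and an FR4 J-motif planted, wrapped in a random leader
and constant stub so the insert is always ≥ 385 nt (total amplicon ≈ 450–515
nt with barcode, TSO and primer). Reads are 300 nt from each amplicon end,
so the merge overlap is ≈ 85–150 nt and merged inserts straddle the length
filter's regime. Qualities follow a flat Q37 profile decaying linearly to Q8
over the last 30 cycles — enough to exercise the 3′ trim rule — and errors
are uniform substitutions (0.002/base by default, the right order for a
modern short-read run). Barcodes are 8-mers kept ≥ 3 substitutions apart.
Wells default to 200 read pairs: deep enough that the abundance-ratio
absorption behaves as it would at production depth, small enough that a full
24-sample, 2-plate run processes in seconds. The aberrant light chain is
spiked as a secondary VL into ⌈prevalence × samples⌉ samples at 30% of the
well's light-chain reads, spread across parents.

Deliberately not emulated: real germline sequences (annotation is
table-driven, so biological realism buys nothing for correctness tests),
indels and quality-correlated errors, PCR chimeras, UMIs (the protocol has
none), and length variation of FR4. Passing tests therefore demonstrate the
*bookkeeping and scoring machinery* — demultiplexing, denoising,
binning, replicate logic, flagging — not robustness to indel-heavy
platforms or to annotator failure modes on real germlines, where an
HMM-based external annotator should replace the motif heuristic.

## Numerical choices and degenerate inputs

* All thresholds that read "minimum"/"maximum" are inclusive on the retained
  side; the two strict inequalities are the aberrant prevalence (> 50%) and
  the high-confidence threshold (> 4), as published.
* Ties: dereplication sorts by count then lexicographic sequence; bin
  representatives and pair selection break ties the same way; ambiguous
  barcode/primer matches discard.
* Empty inputs flow through: empty wells produce empty ASV tables, an empty
  run exports a valid empty SQLite schema, a fully low-quality read trims to
  length 0 and is removed by the length filter.
* Seeds: every stochastic component (clone draw, plate simulation, error
  placement, derangement, fold assignment, booster) takes an explicit seed
  and restores the caller's RNG state; identical seeds give byte-identical
  FASTQ and identical scored tables.
* Problem sizes in the shipped tests: the deterministic suite uses an
  error-free 6-well run; the realistic suite uses 2 plates × 12 wells at 200
  read pairs/well and 0.2% error; classifier checks use 100 synthetic pairs
  under grouped 5-fold CV. These sizes keep the whole suite under a minute
  while leaving every rule's boundary exercised at its exact value.

## Limitations

* The greedy collapse is not an error-model learner; at very low depth
  (≲ 50 reads per well and chain) singleton errors stop being absorbed
  because the 0.1 abundance ratio cannot be satisfied.
* Integer-only IMGT numbering caps CDR3 at 13 residues; long heavy CDR3s
  need insertion-code support and an external annotator.
* The aberrant-chain rule is run-global; a contaminant present in exactly
  half the samples is retained by design.
* The pairing classifier harness reproduces the *training-set construction
  procedure*, not any production model's weights; its shipped metrics are
  sanity bars on synthetic features, not biological performance claims.
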