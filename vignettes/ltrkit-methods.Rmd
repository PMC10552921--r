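---
title: "Methods: structural LTR retrotransposon annotation with ltrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural LTR retrotransposon annotation with ltrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrkit)
```

## The problem

Long terminal repeat retrotransposons (LTR-RTs) dominate many plant
genomes. An intact element has a characteristic architecture: a short
target-site duplication (TSD, typically 4–6 bp of host sequence repeated on
both flanks), two near-identical LTRs beginning with `TG` and ending with
`CA`, a primer binding site (PBS) complementary to the 3′ tail of a host
tRNA just inside the 5′ LTR, an internal coding region (GAG and the Pol
domains — protease, integrase, reverse transcriptase, RNase H), and a
polypurine tract (PPT) just upstream of the 3′ LTR. Because the two LTRs
are identical at insertion time, their present-day divergence dates the
insertion.

`ltrkit` implements this whole analysis as a desk-scale, fully testable
toolkit: structural detection of intact candidates, PBS/PPT annotation,
rule-based classification (autonomous/non-autonomous Gypsy and Copia, plus
the LARD, TRIM, TR-GAG and BARE-2 structural classes), Kimura
two-parameter insertion dating, gene-context calling, redundant and
non-redundant library construction, nucleotide-level benchmarking, and a
synthetic-genome simulator that provides ground truth for all of it.
Protein-domain discovery itself is out of scope: domain hits are consumed
as an external table (the format produced by HMM-based TE scanners),
never inferred from sequence.

## Coordinate conventions

Every interval the package stores is 0-based half-open `[start, end)`;
every GFF3 byte written is 1-based inclusive, and the conversion functions
`to_gff_coords()` / `from_gff_coords()` are exact inverses. Element spans
exclude the TSDs — the duplication is host sequence flanking the element,
not part of it. Softmasked input is uppercased on reading; IUPAC ambiguity
codes collapse to `N`, and `N` never counts as a match in any seed or
alignment.

## Structural detection

Detection proceeds in three stages.

**Seeding.** Exact forward repeats of length ≥ `M` (default 20 bp, the
minimum exact-match length) whose separation lies within the configured
distance bounds `[d, D]` (defaults 1 000–15 000 bp between LTR starts) are
found with a collision-free 2-bit packing of every window into a double,
and merged along diagonals into maximal exact matches.

**Extension.** Seeds sharing a diagonal are pooled per putative element
and extended outward with X-drop scoring (match +2, mismatch −3, drop-off
20). The extension never leaves the seed diagonal: the package's
divergence model for LTR pairs is substitution-only (as is the dating
model), so a banded gapped extension would buy nothing here — this is a
deliberate design choice, and the final acceptance decision still uses a
full affine-gap global alignment (`Biostrings::pairwiseAlignment`, gap
open 5, extend 2) to compute the LTR pair identity. Candidates must have
an LTR length within `[l, L]` (defaults 100–7 000 bp) and identity ≥ `S`
(default 0.85).

**Structural filtering.** X-drop extension systematically overshoots
boundaries by a few bases (a positive-scoring random-walk excursion into
the flanks), so boundaries are polished the way dedicated filtering tools
do it: within a ±20 bp window the filter searches for the closest boundary
pair flanked by identical direct repeats of 4–6 bp (the TSD, longest
first) that also carries the `TG…CA` terminal motif. The wiggle of 20 bp
covers the overshoot tail of the score random walk; a spurious
TSD-plus-motif match at a wrong offset requires roughly a one-in-a-million
coincidence per offset pair and is negligible at this scale. The motif
check can be disabled (`motif_check = FALSE`) since some genuine elements
carry non-canonical termini. When a candidate is rejected, the reason code
(`ltr_length`, `similarity`, `tsd`, `motif`) reflects the candidate's own
boundaries; overlapping accepted candidates are resolved by similarity,
then length, then leftmost position.

On the simulator's default scenario (one 2 Mb sequence, 50 implants,
exact LTR copies) this recovers every implant with exact boundaries and no
false detections on the i.i.d. background; at 5% LTR divergence recall
stays at or near 100% with boundary errors within a few bases. The
acceptance tests and `scripts/acceptance.R` recompute these numbers.

## PBS and PPT

The PBS search takes the 3′-terminal 18 nt of each tRNA, reverse
complements it, and looks for the longest ungapped match (≤ 1 mismatch,
min 12 nt) in a 30 bp window downstream of the 5′ LTR; ties go to the
smallest offset, then the lexicographically smallest tRNA id. The PPT
search scans a 50 bp window upstream of the 3′ LTR for the window with the
most purines among those at least 10 bp long, purine fraction ≥ 0.8, and
beginning and ending on a purine (the canonical trimmed form — this
closes the tie/extension ambiguity deterministically); ties go to the
rightmost, then the longer window. Window sizes follow common
LTR-annotation practice; all thresholds are explicit configuration.
Minus-strand elements are scanned on the reverse complement so both
features stay adjacent to their biological LTR.

## Classification

The order of core domains along the element separates the two
superfamilies: integrase *after* RNase H is the Gypsy arrangement
(GAG–PROT–RT–RH–INT), integrase *before* the reverse transcriptase the
Copia arrangement (GAG–PROT–INT–RT–RH). The cascade — first match wins,
every step recorded in a replayable rule trace — is:

1. Gypsy order + PBS + PPT → autonomous Gypsy
2. Copia order + PBS + PPT → autonomous Copia
3. GAG plus at least one of INT/RT/RH, but not 1–2 → non-autonomous;
   superfamily by majority of the hits' labels, ties broken by the INT
   position, otherwise unknown
4. a Pol domain but no GAG → BARE-2
5. GAG alone → TR-GAG
6. no domains and total length ≤ 1 000 bp → TRIM
7. no domains and internal region ≥ 3 500 bp → LARD
8. otherwise unknown

The size thresholds for the two non-coding classes are not fixed anywhere
authoritative; 1 000 bp for "miniature" and 3 500 bp of internal sequence
for "large" follow common usage and are configurable. Whether autonomy
should require the PBS and PPT in addition to the full domain complement
is genuinely open; the default requires them (the complete structural
template), and `autonomy_requires_pbs_ppt = FALSE` relaxes the call to
domains only. The cascade is total: an exhaustive sweep over all 326
domain orders × PBS/PPT presence × three size regimes assigns exactly one
category each, and only the two canonical orders are ever autonomous.
Clade is the majority clade label of the hits (pass-through aggregation,
never inferred from sequence).

## Insertion age

The 5′ and 3′ LTR of each element are aligned end-to-end with affine gaps;
columns containing a gap or `N` in either row are excluded (complete
deletion — the convention has to be chosen somewhere, and excluding
half-informative columns is the conservative choice). Transitions
(A↔G, C↔T) and transversions are counted, and the Kimura two-parameter
distance is

$$K = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

with `P` and `Q` the transition and transversion proportions. When
`1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0` the pair is saturated: `K` is undefined,
the element is flagged, and no age is reported — never a zero. The
insertion age is `T = K / (2r)`, where `r` is the neutral substitution
rate per site per year. `r` has no default: rates differ by an order of
magnitude across species, so the user must supply one (common plant
values are around 1.3×10⁻⁸ substitutions/site/year). The estimator is
validated three ways: against a literal per-column classifier plus the
closed form (to 10⁻¹²), against `ape::dist.dna(model = "K80")`, and by
parameter recovery — simulated LTR pairs at true K ∈ {0.01, 0.05, 0.1,
0.2} are re-estimated with mean error within 10% at every level.

## Gene context

An element's relation to every gene on the same sequence is decided by
interval algebra: containment either way (`WITHIN_GENE` is checked before
`CONTAINS_GENE`, so a gene exactly coinciding with an element counts as
hosting it), partial overlap, or nearest-edge distance within `U` bp
upstream / `X` bp downstream (defaults 500 bp). Upstream and downstream
are relative to the element's genomic orientation, not the gene's strand
— the distances asked about are distances from the element. All
qualifying genes are reported; an element with none gets a single
`INTERGENIC` record. The chimera report defaults to any overlap, with a
strict containment-only mode available; `CONTAINS_GENE` is reported as
its own relation so either reading of "within the coordinates of the
gene" is recoverable. The implementation is verified to be exactly
equivalent to a brute-force all-pairs scan on randomized fixtures.

## Libraries and clustering

The redundant library holds every element's genomic sequence (reverse
complemented for minus-strand elements) under a reparseable header
carrying the id, classification string and locus. The non-redundant
library uses greedy length-sorted centroid clustering: longest first, each
sequence joins the first centroid reaching identity ≥ `S`, else founds a
new cluster. Identity is matches divided by alignment columns with gaps
counted — one of several defensible definitions, fixed here and stated.
No word-matching acceleration heuristics are used; every comparison is a
full global alignment (a length-ratio screen skips pairs that cannot
mathematically reach `S`, which changes nothing in the result). The
clustering threshold defaults to the detector's `S` but is independently
settable. Permuting equal-length inputs can change which sequence becomes
a centroid, but never the invariant that every member realigns to its
centroid at ≥ `S` — this is tested.

## Benchmarking

Annotation quality is measured at the nucleotide level by direct interval
algebra: both annotations are merged per sequence, every base is
classified TP/FP/FN/TN, and the six standard metrics follow (sensitivity,
specificity, accuracy, precision, FDR = 1 − precision, F1 =
2TP/(2TP+FP+FN)). This replaces homology-based masking with an exact,
self-contained computation; the trade-off is that homology-masking
artefacts are out of scope. TN covers every unannotated base of the whole
genome, strand is ignored, and a metric whose denominator is zero is
reported as undefined rather than coerced to 0. The counting routine is
verified against a literal per-base loop.

## The simulator

`simulate_genome()` is the package's ground-truth factory, and its
defaults are the package's reference study conditions: one 2 Mb sequence
of i.i.d. background at GC 0.4, 50 implants cycling over seven templates,
exact LTR copies unless a divergence is requested, 5 bp TSDs, a PBS and
PPT in every implant, and genes placed both at random (5 per Mb) and in
controlled relation to elements. Implant geometries follow the templates
(LTRs of 120–300 bp, internals from 400 bp for TRIM to 5.2 kb for
BARE-2). Three constructions deserve explanation:

* **TRIM is absent from the default mixture.** A TRIM element is at most
  1 kb in total, which puts its LTR separation below the default minimum
  distance `d` = 1 000 bp — under the reference detection settings such
  an element is undetectable by construction (mirroring the common
  experience that these miniature elements go unreported in standard
  runs). TRIM stays a first-class template for targeted tests with a
  smaller `d`.
* **LTR termini are exempt from mutation.** The 3′ LTR copy is mutated
  under exact K2P column probabilities (ts/tv = 2), except its first and
  last dinucleotides: the `TG…CA` motif is conserved in real elements
  precisely because it is functionally required, and mutating it would
  make the simulator eject a fixed fraction of its own truth through the
  motif filter.
* **The PPT sits in a pyrimidine pad.** The purine tract is flanked by
  pyrimidines filling its whole search window, so the implanted span is
  the unique maximal tract and feature recovery can be asserted exactly.

These choices mean the simulator validates the machinery, not the
messiness of real genomes: no nested insertions, no solo LTRs, no indels
between LTR copies, no repeat-rich background (a low-complexity spike-in
exists for stress tests). Passing tests demonstrate correctness of the
algorithms under the stated model; sensitivity on real genomes with
degenerate, nested and truncated elements will necessarily be lower.

Randomness is controlled by a single seed set once per simulation; every
`ltr_sim` records it, and `mutate_k2p()` is deterministic under a given
seed.

## Pipeline and determinism

`run_pipeline()` chains detection → features → (classification, ageing) →
gene context → libraries → statistics, writing GFF3, TSVs, FASTA
libraries and a JSON manifest (configuration snapshot, input checksums,
stage timings, outputs). Detection is parallelised one sequence per task
(`parallel::mclapply`), and results are merged in `(seq_id, start)` order
with ids assigned after the merge, so the analysis outputs are
byte-identical for any thread count — the determinism contract covers
every analysis file; the manifest records wall-clock provenance and is
the one file expected to differ between runs. Missing optional inputs
(gene annotation, tRNA library, domain table, substitution rate) skip
their stages gracefully and are recorded in the manifest. The
`exec/ltrkit` script exposes `run`, `simulate` and `bench` subcommands
over these functions with the conventional single-letter flags
(`-l -L -d -D -S -M -U -X -W -R -N -t`); unrecognised flags in a YAML
config are retained as pass-through so invocations written for the larger
ecosystem do not hard-fail.

## Problem sizes used in the test suite

The shipped tests run the complete default scenario (2 Mb, 50 implants)
for detector recall and for the two-thread-count determinism check, 200
replicates per level for K2P recovery, 1 000 random pairs for the
divergence-count oracle, 100 random fixtures each for the benchmark and
gene-context oracles, and 20-sequence planted-group fixtures for
clustering. These sizes were chosen so the whole suite exercises every
contract at full fidelity while remaining comfortable on a single CPU.

## Known limitations

* No nested-insertion resolution and no solo-LTR recovery; overlapping
  candidates are resolved greedily, so heavily nested regions will
  under-report.
* LTR pairs that have accumulated indels are handled by the final affine
  alignment but not by the diagonal extension; grossly indel-riddled
  pairs may be missed at the extension stage.
* Clade assignment is an aggregation of supplied labels; without an
  external domain table, classification is structural only and
  superfamily calls require domain positions.
* The benchmark measures interval agreement, not the downstream effect of
  a library on homology masking.
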