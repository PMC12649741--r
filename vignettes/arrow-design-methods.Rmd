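---
title: "Allele-specific guide design with intentional mismatches: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific guide design with intentional mismatches: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrowdesign)
```

## The design model

SpCas9 recognises a 20-nt protospacer flanked by an NGG PAM, and its guide
RNA tolerates single mismatches against the DNA target — enough that a guide
perfectly matched to a point-mutant allele (EGFR L858R, KRAS G12V) still
cleaves the wild-type allele one base away. The ARROW strategy turns this
tolerance into a design variable: starting from the mutant-matched guide,
one deliberate substitution is introduced at a selected position, giving a
guide with one mismatch to the mutant allele and two to the wild-type
allele. Since Cas9 activity drops sharply between one and two mismatches,
this asymmetry produces allele-selective editing.

All positions are expressed in PAM-indexed coordinates (`p = 21 - i` for a
20-nt spacer written 5'→3'; position 1 is PAM-proximal). The EGFR L858R
variant falls at PAM index 12 of its guide, KRAS G12V at PAM index 1 —
`worked_examples()` carries both pairs, with the published spacer sequences
rendered as RNA.

Two rules are enforced rather than merely documented:

* **The 1-vs-2 contract.** `design_arrow_guides()` recomputes, for every
  candidate, the Hamming distance to the mutant and wild-type protospacers
  extracted from the allele contexts at the site's coordinates, and refuses
  to emit a guide that does not satisfy `mm_vs_mut == 1 && mm_vs_wt == 2`.
* **The forbidden position.** An intentional mismatch at the variant's own
  PAM index would overwrite the only allele-discriminating base, so it is
  rejected (an `allow_variant_position` override exists for exploration, and
  its outputs are exempt from the contract check).

### Position sets

Mismatch tolerance is screened at three seed positions {1, 3, 6} and three
non-seed positions {9, 12, 15}. For design we keep this six-position set,
adjusted for the variant: a variant at PAM index 12 (EGFR L858R) swaps
position 12 for the neighbouring 11, keeping six design positions; a variant
anywhere else in the set is simply dropped (KRAS G12V at index 1 leaves five
design positions). This reproduces the position sets used in the EGFR and
KRAS designs while keeping `default_design_positions()` total and
deterministic. Sources differ on whether the sixth EGFR position is called
11 or 12; we treat 12 as the variant position and 11 as the design position,
and `position_preset("design6")` makes the substituted set available
explicitly.

### Tolerance tables and H/L labels

Which base to substitute at a position is an empirical question — mismatch
tolerance depends on position, base identity and locus. The package
therefore takes tolerance as *input*: a TSV of measured indel rates per
(position, substituted base). `classify_tolerance()` labels, per position,
the argmax rate as H (highly tolerant) and the argmin as L (low tolerant);
ties are broken alphabetically (A<C<G<T) and flagged, since a tie carries no
information about which substitution to prefer. The tables shipped under
`inst/extdata/` are synthetic illustrations of the format, not measured
data, and are labelled as such in their `source` column. The screening
itself enumerates substitutions exhaustively (3 per position, 60 for a full
guide) rather than sampling randomly: enumeration is cheap in software and
reproducible, whereas random draws only made sense for wet-lab economy.

## Off-target enumeration

`find_offtargets()` re-implements the accepted desk-top search contract for
this design space: report every NGG-adjacent site that differs from the
guide by at most 8 mismatches without a bulge, or by at most 2 mismatches
with a single contiguous 1–5 nt bulge — a DNA bulge (extra bases in the
genomic site, gap in the guide) or an RNA bulge (extra guide bases, gap in
the site). These defaults are the `search_budget()` constructor's defaults
and every one of them is configurable.

The algorithm is a PAM-anchored scan: locate NGG (and CCN for the minus
strand) on each contig, read the adjacent sequence PAM-proximal→distal, and
score each bulge class by splitting the guide at each possible bulge
placement. We chose scanning over an FM-index or seed-and-extend scheme
deliberately: the package targets amplicons, reporter constructs and
kilobase-scale regions, where an exhaustive scan is fast, trivially correct,
and directly comparable to a naive oracle in tests (the test suite asserts
exact hit-set equality against an independently coded all-windows scan on
seeded planted genomes, 20 genomes of 2–3 kb in the default run).

Determinism conventions, applied identically in the implementation and the
test oracle:

* one hit per (location, strand, bulge kind); bulge-free and bulged
  representations of the same locus are distinct records;
* within a kind: the smallest budget-satisfying bulge, then the fewest
  mismatches, then the most PAM-distal bulge placement;
* bulges adjacent to the PAM (between the PAM and guide position 1) are
  disallowed by default — they are biophysically implausible and create PAM
  ambiguity — and terminal bulges at the distal end are never considered,
  since an unflanked bulge is indistinguishable from a shorter site;
* `N` in the genome mismatches every guide base (conservative), and
  opposite-strand overlapping sites are reported independently.

`compare_burden()` then re-aligns a designed guide to each stored site under
the same bulge class and reports the mismatch delta. For guides one base
apart the delta is provably in {−1, 0, +1}, and a site perfectly matching
the original guide always gains exactly the intentional mismatch — the
mechanism by which an ARROW guide also *reduces* off-target pressure.
`predict_t7e1_fragments()` is a small helper giving the two cleavage
fragment sizes for gel readout of candidate sites.

## Amplicon indel quantification

A read counts as edited when an indel intersects the window around the blunt
cut 3 bp 5' of the PAM (between PAM indices 3 and 4). The landmark is
standard; the window width is not dictated by it, so we use a ±3 bp window
(configurable `window_halfwidth`), matching common amplicon-analysis
practice, and record the window bounds in every summary. Substitutions never
count as edits at any error rate.

Alignment is global Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment` (match +2, mismatch −3, gap open −10, gap
extend −1 — gap opening deliberately expensive so sequencing errors become
substitutions, not spurious indels). Indel events are extracted from the
gapped strings and **left-normalised** (VCF-style) so a gap in a homopolymer
has one canonical position; the tests assert this canonical form directly.
Reads shorter than 50 nt or below 60% alignment identity are excluded from
the denominator as unaligned — counting contaminant reads as "unedited"
would silently deflate frequencies. Base qualities are ignored by default;
inputs are single or pre-merged reads (paired-end merging is out of scope).
Duplicate read identifiers are rejected rather than deduplicated.

`discrimination_summary()` reduces a mutant/wild-type assay pair to the rate
ratio (with an infinite marker when the wild-type rate is exactly zero) and
difference. `classify_reporter_frame()` models the dual-fluorescence
frameshift reporter: with a frame offset k ∈ {1, 2} between target and ORF,
a net indel of length d restores frame iff (d + k) mod 3 == 0 — exactly one
net length in three is in-frame.

## Simulators: what they emulate, and what they do not

`make_planted_genome()` writes guide-derived sites — optionally distorted by
substitutions and a bulge — into an iid random background at recorded,
non-overlapping loci, returning a machine-checkable truth table.
`simulate_amplicon_reads()` emits full-length amplicon copies; with
probability `edited_fraction` a read receives one indel whose anchor is
uniform in the cut window and whose signed length follows a configurable
distribution (default: 1–3 bp deletions and 1 bp insertions, the dominant
repair outcomes at blunt cuts), plus iid substitution errors at 0.001 per
base, a typical short-read scale. Both generators are pure functions of
their seed (the RNG algorithm is pinned, and the caller's RNG state is
restored afterwards), so fixtures are regenerated rather than stored.

Passing tests on these fixtures demonstrates coordinate correctness,
budget/threshold behaviour, and estimator calibration under binomial
sampling — they do not demonstrate robustness to real-sequencer artefacts.
The background model has no repeats beyond chance, the error model has no
quality dependence or adapter content, edited reads carry exactly one indel,
and indel positions are exactly within the window. Real amplicon data with
homopolymer-adjacent cut sites, microhomology-mediated deletions spanning
far outside the window, or heavy contamination will stress the identity
floor and window rule in ways the simulator does not.

## Numerical and degenerate-input conventions

* Sequences are validated against {A,C,G,T,N} on ingest; RNA input (U) is
  normalised to DNA and rendered back as RNA only in reports. Empty guides,
  non-SNV allele pairs, and guides containing N (for enumeration) are
  rejected with specific errors.
* Enumeration order is fixed (ascending PAM index, base order A<C<G<T), so
  all outputs are stable across runs and platforms.
* `hamming()` counts N against anything — including N — as a mismatch.
* Problem sizes in the default test run: oracle-equivalence on twenty 2 kb
  planted genomes with budgets up to 4 mismatches and 2 nt bulges;
  edited-fraction recovery at n = 2000 reads for f ∈ {0.01, 0.1, 0.4, 0.66,
  0.77} within 3σ binomial bounds. These sizes were chosen as the smallest
  that exercise every code path (both strands, all bulge classes, fraction
  extremes) with comfortable statistical power.

## Known limitations

* The search is deliberately not genome-scale; a human-genome catalogue
  needs an indexed tool, and the package's value there is the budget
  semantics and burden comparison, not raw throughput.
* No editing-efficiency prediction: H/L labels come from user-supplied
  measurements, and no sequence-to-activity model (CFD/MIT-style scores or
  free-energy arguments) is fitted or applied.
* The indel-window rule is a counting convention, not a biological model of
  repair outcomes; window half-width is a reporting-relevant parameter and
  is therefore embedded in every summary object.
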