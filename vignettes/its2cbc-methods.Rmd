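---
title: "Delimiting coccoid green-algal species from rDNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting coccoid green-algal species from rDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2cbc)
```

## The scientific problem

Coccoid green algae such as *Choricystis* — free-living picoplankton and
endosymbionts of freshwater sponges — are nearly featureless under the light
microscope, so species boundaries must come from molecular characters.  Two
rDNA-based lines of evidence are combined here:

1. **ITS-2 secondary structure and compensatory base changes (CBCs).**  The
   internal transcribed spacer 2 folds into a conserved multiloop closed by
   the 5.8S/LSU stem, with helices I–III (helix IV can be absent in this
   group).  A *CBC* changes both partners of a base pair while keeping the
   pair (e.g. A-U → G-C); a *hemi-CBC* (HCBC) changes one partner (A-U →
   G·U).  One or more CBCs in the conserved region of ITS-2 between two
   strains is the classical signal that they belong to different biological
   species; zero CBCs groups them.
2. **SSU rDNA haplotypes.**  The small-subunit rRNA gene carries group I
   introns at positions named by homology to the *E. coli* 16S reference
   (e.g. S323, S943, S1046, S1512), and its V4 and V9 hypervariable regions
   distinguish lineages in environmental (amplicon) records.  Haplotypes of
   these regions, connected in statistical-parsimony (TCS) networks with
   habitat and geography overlays, describe the distribution of each species.

The package implements every stage of this analysis as composable R
functions, plus a seeded synthetic-data generator so each stage can be tested
against known ground truth without any external data.

## Constrained ITS-2 folding

`fold_its2()` folds a *cassette* — the ITS-2 transcript flanked by the 3'
tail of the 5.8S rRNA and the 5' head of the LSU rRNA — under the three
structural constraints used for this group of algae:

* the last `stem_len` (default 25) 5.8S bases must bind the first
  `stem_len` LSU bases, forming the stem that closes the ITS-2 multiloop;
* a pyrimidine/pyrimidine mismatch (the first RNA processing site) must sit
  within a window of base-pair indices in Helix II (default pairs 5–7);
* the green-algal GGU motif (the second processing site) must lie on the 5'
  strand of Helix III, within 6 nt of the helix start.

### Scoring model

Full thermodynamic (Turner) energies are out of scope; the engine is a
weighted base-pair maximisation dynamic programme with G-C = 3, A-U = 2,
G·U = 1, a +1 stacking bonus for each pair stacked directly on another, and
a minimum hairpin loop of 3 nt.  This preserves what the downstream analysis
actually consumes — a constraint-satisfying, score-optimal, three-helix
topology — at desk scale.  Externally computed structures (e.g. real
minimum-free-energy output in Vienna dot-bracket format) can be supplied to
`run_delimit()` via `structures=`, making the rest of the pipeline
engine-agnostic.

Constraint (1) is enforced as a hard mask: stem pairs are forced where
Watson–Crick/wobble-compatible, and incompatible positions are recorded as
coded stem mismatches rather than failures (real 5.8S/LSU stems contain
imperfections; the constraint is "must bind", not "must be perfect").  The
ITS-2 interior is then folded to optimality, helices are decomposed, and
constraints (2)–(3) are *verified*; a cassette whose optimal interior fold
violates them raises a `constraint_unsatisfiable` error naming the first
failed constraint.  We deliberately do not search for the best structure
*subject to* (2)–(3): a fold whose unconstrained optimum lacks the
processing-site signatures is biologically suspect input, and silently
refolding it would mask that.

Ties between equal-scoring structures are broken deterministically: the
leftmost base of every interval is paired whenever an optimal structure
allows it, with its smallest admissible partner.  (A full lexicographic
minimisation of the dot-bracket string would need an additional
string-comparison dynamic programme; determinism is the goal and the greedy
rule achieves it.)

### Helix decomposition

`decompose_helices()` identifies the stem as the helix containing the
outermost pair and labels the helices of the multiloop I, II, III (and IV
when present) in 5' order.  Stacked runs interrupted by at most `bulge_tol`
(default 3) unpaired bases per side merge into one helix; a symmetric 1×1
interior loop is kept *in* the helix as an unpaired "coded mismatch" row —
this is how the Helix II pyrimidine/pyrimidine processing site is
represented and later encoded as barcode digit 7.  Helix positions are
counted from the basal (multiloop-proximal) end, the alignment-stable end in
the ITS-2 literature; for the stem that is its innermost pair.

## The ITS-2 barcode and change classification

`extract_barcode()` writes the conserved region as a digit string: 16 basal
stem pairs, 5 basal Helix I pairs, 11 basal Helix II pairs (mismatch
included), and all Helix III pairs, each encoded 1 = A-U, 2 = U-A, 3 = G-C,
4 = C-G, 5 = G·U, 6 = U·G, 7 = mismatch, 8 = indel/single base.  A helix
shorter than its quota is padded with 8s and the barcode flagged partial.

`align_barcodes()` aligns two barcodes segment-wise (Needleman–Wunsch on the
digit strings, match 1 / mismatch 0 / gap −1, deterministic gap-late
tie-break), and `classify_changes()` classifies each aligned column.
Because the digits alone cannot distinguish a CBC from an HCBC in every case
(1 → 2, A-U vs U-A, changes both bases), the barcode carries the underlying
bases and classification uses them: both partners differ → CBC, exactly one
→ HCBC, gap on one side → indel, code 7 on one side → mismatch-shift.
Code-7 and code-8 columns are never counted as CBC or HCBC.

`delimit_species()` then links two sequences when their comparison shows
zero CBCs; connected components are the candidate species.  Because "total
CBCs among three taxa" is ambiguous between a union and a sum over pairwise
reports, `compare_barcodes()` returns both tallies: the union counts a
changed column once even when it separates several species pairs.

## SSU utilities

`map_to_reference()` aligns a query SSU sequence to a reference globally
(affine gaps, match 2 / mismatch −4 / gap open 16 / extend 0.25) and exposes
a column-wise coordinate map.  A global rather than ends-free alignment is
used because a terminal intron — S1512 lies only 30 nt from the reference 3'
end — is silently dropped by an ends-free aligner, which simply stops before
it.  Query blocks with no aligned reference on one side are treated as
flanking sequence, which keeps intron anchors invariant to added flanks.
The map is flagged when fewer than half the reference positions are matched.

`detect_introns()` reports every internal query-only block of at least
`min_intron_len` (default 100 nt — group I introns are hundreds of nt, and
the cutoff keeps alignment noise out) as a putative group I intron, anchored
at the reference coordinate of the last exon base 5' of the insertion (the
convention behind names like S1046); `excise_introns()` returns the
concatenated exons.  `extract_region()` cuts the V4 (reference 576–682) and
V9 (1435–1465) windows; these bounds differ among authors, so they are
arguments (`ssu_regions()`) rather than constants.

The package ships a **synthetic** 1542-nt reference
(`inst/extdata/ssu_reference_synthetic.fasta`, loaded by `ssu_reference()`)
as its default coordinate scaffold: a deterministic sequence with 16S-like
base composition.  It provides E. coli-style numbering for tests and
examples and is *not* the biological *E. coli* sequence; analyses of real
data should pass the real reference to the `reference` arguments.

`compare_v9()` folds two V9 sequences with the same engine, encodes the
dominant helix of each with the barcode alphabet and classifies the aligned
positions exactly as ITS-2 barcodes, so V9 haplotypes can be screened for
CBCs/HCBCs.  `assign_v9_haplotypes()` numbers haplotypes by decreasing
frequency (then first occurrence) of their paired-position encoding and
gives lowercase letters to variants that differ only at unpaired positions.

## Statistical-parsimony networks

`collapse_haplotypes()` collapses identical aligned sequences into nodes
with frequencies and habitat/region tallies.  `connection_limit()` computes
the maximum number of mutational steps `J` considered reliable: under a
finite-sites Jukes–Cantor model with the per-site Poisson rate estimated
from the observed proportion of differences, `parsimony_probability(j, m)`
is the probability that `j` observed differences over `m` sites involve no
superimposed change; `J` is the largest `j` keeping that probability at or
above `prob` (default 0.95), floored at 1 so single-step connections are
always made.  The probability is decreasing in `j` and `J` is
non-decreasing in `m`; as `prob` approaches 1 the limit collapses to 1, the
most conservative network.  (The original TCS publication does not print
its recursion in a reproducible form; this explicit model has the same
qualitative behaviour and is stated fully here so results are auditable.)

`build_network()` agglomerates: it repeatedly connects the closest pair of
nodes lying in different components, up to the limit, realising multi-step
connections as chains of inferred median nodes so that **every edge spans
exactly one mutational step**.  Inferred medians count as connection points
for later joins, and median chains choose the mutation order that reuses
existing nodes maximally (ties: lexicographically smallest chain) — without
this, four-haplotype cases already exceed the minimal-step construction.
Determinism: candidate pairs are ordered by distance, then descending
connected frequency, then node id.  Gaps are a fifth character state (one
indel = one step) by default; `gap_mode = "ignore"` drops gapped columns
first, and haplotypes that become identical then share a component without
an edge.  Networks are exported/imported as GML via igraph.

## The synthetic-data generator

The generator is first-class, tested code: every analysis stage has a
generator that emits inputs *plus* the exact truth the stage must recover.

* `gen_its2_cassette()` builds a cassette from a designed layout: a fully
  compatible stem, helices I–III with G-C anchor pairs at both ends and
  G-C-rich arms, a C/C Helix II mismatch flanked by A-U rows, the GGU motif
  opening Helix III, A-only hairpin loops and zero-length multiloop spacers.
  Sequence, pair set and barcode are emitted from the layout, never from the
  folding engine.  The composition rules are not cosmetic: free multiloop
  bases or wobble-rich arms admit alternative structures that match or beat
  the planted score (wrap-around pairs that enclose the whole multiloop, or
  slippage around weight-1 wobbles), which an exhaustive enumeration oracle
  exposed during development.  Each draw is therefore *certified* — the
  cassette is refolded and must reproduce the planted pairs and barcode
  exactly — and rare degenerate draws are redrawn inside the same seeded
  stream, so every emitted truth is recoverable and all generators remain
  pure functions of `(seed, params)`.
* `plant_changes()` edits the layout to introduce exactly the requested
  CBCs, HCBCs and Helix III indels, with the same certification (plus a
  check that the barcode-level classification recovers the planted totals;
  a CBC that turns a pair into a copy of its deleted neighbour would
  otherwise be alignment-ambiguous).  Supported planting region: any stem
  position (the stem is folded under the hard mask, so it tolerates
  arbitrary changes), helix positions a couple of rows away from the anchor
  pairs, the Helix II mismatch row excluded, indels in Helix III interior.
  Positions adjacent to anchors can be genuinely unsatisfiable (the only
  admissible HCBC may create a wobble that unlocks a better fold); the
  function then errors rather than emitting an unrecoverable truth.
* `gen_ssu()` derives an exon from the reference by i.i.d. per-site
  substitutions and inserts random-sequence introns after the chosen
  anchors.  Sites within 2 nt of an insertion point are left unmutated and
  intron boundary bases are chosen not to extend the exon alignment —
  emulating the conserved exon context of real group I insertion sites and
  pinning each insertion to its anchor coordinate.
* `gen_haplotype_sample()` creates haplotypes along a mutational path with
  chosen step counts (fresh sites per step, so distances are additive),
  draws a sample with at least one observation per haplotype, and attaches
  metadata; `gen_v9_haplotypes()` emits certified V9 hairpin pairs with
  planted CBCs/HCBCs.

What the generator does **not** emulate: thermodynamic realism of the
folding landscape, non-independent substitution processes, recombination,
alignment uncertainty in the barcode (segments are aligned per helix), and
sequencing error.  Tests passing on synthetic data therefore demonstrate
the correctness of the algorithms under their stated models, not their
robustness to every artefact of real rDNA data — for real analyses the
engine-agnostic entry points (Vienna structures in, user-supplied reference
and windows) are the intended route.

## Numerical choices and degenerate inputs

* Minimum hairpin loop 3 nt; IUPAC ambiguity codes are valid input but
  unpairable; pseudoknots are rejected at construction.
* `bulge_tol = 3` for helix merging is a judgement call (the counting of
  base pairs across bulges is not standardised); it is an argument
  everywhere it matters.
* Barcode alignment prefers late gaps; classification is symmetric in its
  arguments (swapping inputs swaps the columns, totals are unchanged).
* Degenerate folds: sequences shorter than `2*stem_len + 30` are rejected;
  structures with fewer than two multiloop helices raise `structure_shape`.
* Problem sizes used by the test-suite: folding-oracle panels of 200
  sequences up to 30 nt (plus 30 fully enumerated up to 13 nt), 100 planted
  change specifications, intron recovery on 1.5–3 kb sequences at up to 5%
  divergence, Steiner-equivalence toys of up to 5 haplotypes and 10 sites.

## Known limitations

* The folding score is a surrogate for free energy; helix boundary detail
  (bulge placement) can differ from thermodynamic folds, which is why
  external structures can be substituted.
* The connection-limit probability is a stated model, not a re-derivation
  of the original TCS implementation; limits may differ by a step or two
  from other software at the same 0.95 threshold.
* `run_survey()` requires extracted region segments of equal length (no
  internal indels among the compared strains); align externally first when
  that assumption fails.
* The union tally of changed columns across more than two barcodes keys
  columns by segment and position, which is exact in the fixed-length
  segments and approximate in Helix III when indels shift positions.
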