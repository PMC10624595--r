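---
title: "Cysteine-anchored alignments and structure-model evaluation with cysmsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cysteine-anchored alignments and structure-model evaluation with cysmsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysmsa)
```

## The problem

Small secreted cysteine-rich proteins — the defensin-like pollen ligands
(SP11/SCR) of Brassicaceae self-incompatibility are the motivating case —
are hard targets for MSA-driven structure predictors. They are short
(~60–70 aa), hypervariable between haplotypes, and poorly represented in
sequence databases, so automatically retrieved alignments are shallow and,
worse, systematically misalign the one conserved feature of the fold: the
cysteine scaffold that forms 4–5 disulfide bonds. A receptor–ligand complex
(eSRK–SP11) prediction inherits all of these problems and additionally
needs cross-chain coevolutionary signal, which only exists in an alignment
whose rows pair *cognate* receptor and ligand sequences.

`cysmsa` implements the surrounding machinery — alignment curation, depth
profiling, paired-alignment assembly, and model evaluation — while leaving
the neural-network inference itself to external engines.

## Cysteine-anchored alignment

### Model and assumptions

The working assumption is that cysteines occupying the same *ordinal slot*
of the family scaffold are structurally homologous (they occupy the same
position in the disulfide topology) even when the segments between them
have diverged beyond recognition. Slots are expressed per sequence as an
`anchor_assignment`: slot *k* maps to the index of the cysteine occurrence
filling it, or is absent (a 7-cysteine member of an 8-cysteine family).
The assumption fails exactly where the disulfide topology changes; the
connectivity catalog (below) is the bookkeeping for those cases, and
sequences of a different topology class belong in a different alignment.

### Two routes to an anchored MSA

1. **Barcode / external aligner.** `barcode()` replaces the cysteine in
   slot *k* with the *k*-th letter of a placeholder alphabet
   (`BJOUZ0123456789` — letters absent from the package's amino-acid
   alphabet, where `X` is a residue; digits extend the alphabet for
   10-cysteine proteins). A generic aligner then treats each placeholder as
   a rare, self-matching symbol, which in practice pins the anchors;
   `debarcode()` restores `C`/`c` afterwards. Because substitution matrices
   score `B`/`Z`/digits poorly or not at all, a warning is emitted when
   more than six placeholders are in play; the round trip
   `debarcode ∘ (column operations) ∘ barcode` is residue-exact regardless.

2. **Anchor-constrained aligner.** `anchor_align()` needs no external
   binary: sequences are split at their assigned anchors, each anchor slot
   contributes one column containing only `C` (filled) or `-` (absent), and
   each of the K+1 inter-anchor segment slots is aligned independently by
   center-star alignment. The center is the segment with the highest summed
   pairwise score against the others (ties: lowest input index); every other
   segment is merged into the center via its pairwise alignment. Center-star
   is a deliberate simplicity/optimality trade-off — it carries a classical
   2-approximation guarantee under metric scoring and is exactly
   reproducible, which matters more here than squeezing alignment score,
   because the anchors carry the structural signal.

When an anchor is absent, its residues flow into the segment *preceding*
the absent anchor and the following segment is empty for that row. This is
a convention, not a claim about the biology; its virtue is that residue
conservation and column counts stay exact.

### Pairwise core and determinism

The pairwise engine is Needleman–Wunsch/Gotoh with affine gaps: a gap run
of length L costs `gap_open + (L−1)·gap_extend`, defaults BLOSUM62 / 10 / 1
(the matrix is taken from Biostrings). Terminal gaps are charged. The
external aligner used by the original protocol is not reproduced and its
parameters are unknown; these defaults are the package's own choice and are
exposed via `scoring_scheme()`. Tie-breaking is fixed — diagonal, then
vertical (gap in the second sequence), then horizontal, applied both to the
final state and to every predecessor choice — so identical inputs give
byte-identical alignments on every platform. The test suite checks the
optimum against an exhaustive enumeration oracle that scores complete
alignments from their strings, sharing no code with the dynamic program.

`merge_into_msa()` grows an existing alignment one sequence at a time: the
newcomer is globally aligned to the ungapped sequence of its closest row
(`AUTO` = highest fraction identity, ties to the first row) and the
pairwise alignment is projected into alignment coordinates, opening all-gap
columns for insertions. No realignment pass follows; the result depends on
insertion order, which is accepted (the historical protocol added sequences
to a fixed seed alignment the same way).

## Alignment depth (Neff)

`compute_neff()` weights each row by `1 / |{rows with identity ≥ t}|`
(self included) and sums weights of rows covering each query position.
Identity is computed on match states; the denominator convention is
configurable because the literature is not unanimous: `"coverage"`
(columns where at least one row is non-gap; the default), `"shorter"`, or
`"all"`. The identity threshold defaults to **0.80**; the alternative
convention of **0.62** found in parts of the source literature is a
parameter away — the discrepancy is surfaced, not resolved. "Normalized"
Neff (division by the square root of the query length) is provided but off
by default, because no precise definition of the normalization is given in
the source material. Two invariants pin the semantics: duplicating every
row leaves the profile unchanged, and adding a row dissimilar to all others
adds exactly 1 to every position it covers.

## Paired alignments for complex prediction

Complex prediction engines consume an a3m whose first line declares
per-component query lengths and cardinalities (`#L1,L2<TAB>1,1`), followed
by three blocks: (1) the *paired* block — for each cognate pair, the
receptor row and ligand row concatenated horizontally, query pair first —
and (2, 3) the two single-chain alignments, gap-padded on the partner side.
`build_complex_bundle()` assembles this from two single-chain alignments
and an explicit cognate-pair manifest; both alignments are first converted
to a3m *relative to the query pair's rows*, so the header lengths equal the
query lengths and every row carries `L1 + L2` match states. Cardinality is
fixed at `1,1` (heteromeric prediction of one copy per chain); raising it
for homodimeric assemblies is structurally supported but untested against
any reference. Serialization is byte-stable (single-line sequences, `\n`,
no trailing whitespace), and the reader recovers block boundaries
structurally (a row with an all-gap half belongs to a padded block) — a
paired row with a fully gapped half would be misclassified, which cannot
occur for genuine cognate pairs. Row ids may repeat across blocks in this
dialect, so only the bundle reader relaxes the otherwise strict
duplicate-id rejection.

`make_refinement_job()` encodes the low-confidence-class refinement
protocol: class-restricted alignment with the query promoted to the top,
the best candidate model by mean pLDDT as template (ties: first listed),
and the recycle count raised to 9.

## Model evaluation

* **pLDDT.** Read from the B-factor column; the per-residue value is the CA
  B-factor, falling back to the mean over the residue's atoms. Values
  outside [0, 100] are a parse error by contract — this package reads
  *predicted* models, not crystallographic B-factors. Ranking
  (`rank_models()`) is by descending mean pLDDT with stable ties.
* **Disulfides.** Candidate bonds are cysteine SG pairs within 2.5 Å
  (covering the ~2.05 Å ideal bond plus model noise); conflicts are
  resolved greedily by ascending distance. Greedy can differ from optimal
  matching only in pathological geometries (chains of near-equidistant SG
  atoms); the tests compare it against exhaustive minimum-weight matching
  on the fixture geometries. `classify_connectivity()` maps bonds to
  cysteine ordinals and matches the pair set exactly against the catalog —
  `DEF8` (1–8, 2–5, 3–6, 4–7), `TEN_A` (1–10, 2–6, 3–7, 4–9, 5–8),
  `TEN_B` (1–9, 2–10, 3–6, 4–7, 5–8), `TEN_C` (1–10, 2–5, 3–7, 4–8, 6–9),
  `EIGHT_ALT` (1–4, 2–6, 3–7, 5–8) — returning `NOVEL` plus the observed
  pairs otherwise.
* **Contacts.** Heavy-atom pairs across two disjoint chain groups within a
  configurable cutoff, default 4.5 Å. There is no single community contact
  definition, so absolute counts are only comparable at a stated cutoff;
  the CLI prints the cutoff next to the count.
* **pDockQ / pDockQ2.** The interface is defined on representative
  side-chain points (CB, CA for glycine or reduced models) within 8 Å.
  pDockQ uses `x = mean interface pLDDT × log10(#residue pairs)` and the
  published sigmoid `0.724/(1+e^{−0.052(x−152.611)})+0.018`. The base-10
  logarithm is a deliberate decision: the constants are calibrated with
  log10 in the reference implementation, and with a natural logarithm the
  sigmoid would saturate for any realistic interface. Zero contacts return
  the floor `b`. pDockQ2 damps each interface pair by
  `1/(1+(PAE_ij/d0)^2)`, `d0 = 10` Å, computes a per-chain score, and
  reports the arithmetic mean over chains ("averaged for the chains").
  All constants are configurable; they are facts about the cited scoring
  methods, not re-derived here. Predicted TM-scores are *parsed* metadata
  wherever they appear; they are never recomputed.
* **RMSD.** `kabsch_superpose()` is the closed-form least-squares rigid
  superposition (SVD, reflections excluded). `rmsd_to_reference()` pools
  the CA atoms of all mapped chains into a single joint superposition —
  per-chain RMSDs after independent fits would hide inter-chain
  arrangement errors, which are exactly what complex evaluation needs to
  see. Residues are paired by author numbering plus insertion code. For
  2:2 symmetric complexes the chain pairing is ambiguous; the caller
  passes both consistent maps and the minimum is returned. Whether the
  original analysis used the joint or per-chain convention is not stated
  anywhere; the joint convention is this package's documented choice.

## The synthetic world

`gen_cysrich_family()` emulates the real input regime: families default to
98 sequences of ~60–70 residues with 8 cysteines (ancestral inter-cysteine
segments of 4–8 residues), diverged by per-site substitutions (default
0.10) and single-residue indels (default 0.05, split evenly between
insertion and deletion) confined to the segments. Those defaults are a
one-time choice of what a realistic defensin-like family looks like;
property tests run smaller families (3–6 rows) purely for time budget, and
neither the defaults nor any threshold were adjusted in response to test
outcomes. The generator guarantees — and the tests rely on — exactly
`n_cys` cysteines per sequence and ground-truth assignments;
`drop_anchor()` produces the naturally occurring 7-cysteine variant.

`gen_toy_complex()` builds a receptor–ligand dimer on well-separated
lattices with planted features: interface CA pairs at exactly 3.5 Å,
disulfide SG pairs at exactly 2.05 Å, every other intergroup distance
≥ 6 Å, uniform or per-residue pLDDT in the B-factors, and a block PAE
matrix. Every evaluation operation therefore has an *exact* expected value
by construction.

What a green suite does establish: the operations satisfy their contracts —
conservation, round trips, optimality against enumeration, exact recovery
of planted geometry, the documented formulas. What it does not establish:
that anchored alignments improve any particular predictor's output, that
the pDockQ sigmoids are well calibrated for these proteins, or that real
model ensembles behave like the lattice toys (real structures have packed
interfaces, correlated PAE, and nonuniform pLDDT). Those are properties of
external inference engines, out of scope by design.

Randomness everywhere is R's default Mersenne-Twister via `set.seed`, so
fixed seeds give byte-identical fixtures across platforms.

## Numerical choices and degenerate inputs

* Alignment ties: diagonal > vertical > horizontal, center-star center
  ties to the lowest input index, template ties to the first listed,
  ranking ties stable — every argmax in the package has a documented
  deterministic resolution.
* Empty segments are legal in the anchor aligner (zero-width slots);
  empty *sequences* are rejected at the public aligner boundary.
* a3m insertions attach to the preceding match column; a leading insertion
  attaches before column 1. Insertion blocks are left-justified when
  expanded to explicit columns.
* Kabsch requires ≥ 3 points and excludes reflections (`det = −1` branch
  flips the smallest singular direction); self-RMSD is 0 to 1e−8 Å.
* Altlocs resolve to the highest occupancy, ties to altloc `A`; hydrogens
  are kept in the model but excluded from contact counting.

## Known limitations

* No structure-guided alignment, profile HMMs, or iterative realignment;
  no Stockholm/Clustal I/O; no mmCIF reading (PDB only).
* `merge_into_msa()` is order-dependent by design.
* The O(N²) identity computation in `compute_neff()` is intended for
  alignments up to a few thousand rows; no clustering heuristics.
* The bundle reader's structural block detection assumes cognate paired
  rows never have a fully gapped half.
* Contact counts are cutoff-convention-bound; compare only at equal
  cutoffs.
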