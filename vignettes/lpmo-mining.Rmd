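---
title: "Mining and annotating bacterial AA10 LPMOs: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and annotating bacterial AA10 LPMOs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Lytic polysaccharide monooxygenases (LPMOs) are copper enzymes that
oxidatively cleave glycosidic bonds in crystalline polysaccharides. The
bacterial family AA10 (Pfam `LPMO_10`, PF03067) is dominated by
chitin-active and cellulose-active enzymes whose catalytic domain carries
a highly characteristic geometry: the mature protein begins with the
catalytic histidine (His1), a second histidine (Hx) completes the
copper-binding "histidine brace", and a conserved aromatic (Fy,
phenylalanine or tyrosine) sits beyond it. `lpmominer` implements a
complete desk-scale pipeline for mining such proteins out of metagenomic
protein-coding gene sets and annotating them: profile-HMM hit filtering,
signal-peptide removal, alignment-based motif mapping,
substrate-specificity diagnostics, domain-architecture assembly,
neighbor-joining phylogeny and Cα-level structural comparison. This
vignette is the package's account of the underlying models, the tunable
parameters and the design choices that were genuinely open.

## The mining filter

Candidate proteins come from a profile-HMM scan (e.g. `hmmsearch
--domtblout` against `LPMO_10`). A per-domain hit is accepted when all
three of the following hold:

* per-domain bit score ≥ 30 bits (inclusive bound);
* profile coverage `(hmm_to − hmm_from + 1) / profile_length` > 0.75
  (strict bound);
* bias/score ratio < 0.1 (strict bound).

The asymmetry of the bounds (inclusive on the score, strict on the other
two) follows the filter's verbal definition literally; the boundary cases
are pinned by unit tests. Hits with non-positive scores fail with an
explicit `nonpositive_score` token rather than raising — metagenomic hit
tables contain junk rows, and a pipeline that aborts on them is useless.
The per-domain (not per-sequence) score column is used: the filter is a
statement about one domain's match, and a multidomain protein with two
weak LPMO-like regions should not pass on their sum.

Completeness is a separate call. A record is *complete* when its hit
spans essentially the whole profile (at most 5 match states missing at
either end — `start_slack`/`end_slack`) and a mature sequence can be
derived (below), or the record still begins with Met. Everything else is
a *fragment* and is reported separately, never silently dropped. The
source study demoted candidates in two rounds (gene-model evidence, then
alignment inspection); at the protein level only the second operation is
available, so this operational definition stands in for it.

## Mature-sequence derivation

Secreted AA10 enzymes are numbered from the mature N-terminus, so every
downstream coordinate depends on finding the signal-peptide cleavage
point. Rather than wrapping an external signal-peptide predictor, the
package exploits the family's defining property: the mature protein
starts with His1. Candidate cleavage points are histidines at
full-sequence positions `sp_min + 1 … sp_max + 1`; each candidate mature
sequence is aligned to each reference and accepted when its first residue
occupies the reference His1 column with a positive alignment score; the
best-scoring valid candidate wins.

The window defaults are `sp_min = 10`, `sp_max = 68` residues. The
cohort this package was validated against contains signal peptides of
10, 14 and 68 residues, so a narrower window (a common default would be
15–60) silently demotes genuine full-length proteins to fragments; the
wide window costs only a few extra candidate alignments.

The positive-score gate doubles as the specificity control: a global
BLOSUM62 alignment of an unrelated (e.g. composition-shuffled) sequence
against a ~200-residue reference is expected to score below zero once
gap costs are paid, so decoys fail derivation rather than acquiring
nonsense coordinates. On 50 planted proteins + 50 composition-matched
decoys, detection precision and recall are both 1.0 (recomputed by
`scripts/acceptance.R`).

## Alignment engine and motif mapping

All alignments are Needleman–Wunsch/Gotoh global alignments with
affine gaps (BLOSUM62; a gap of length *k* costs `11 + k`). The
traceback is deterministic — on ties, diagonal > up > left, applied to
both the final state and every predecessor choice — because position
transfer must be reproducible to the residue. The DP core is compiled
(Rcpp); everything else is plain R. Multiple alignments use center-star
progressive alignment with "once a gap, always a gap" merging, the
center defaulting to the longest sequence. For single-family alignments
(which is all this pipeline needs) the star approximation is adequate
and, unlike heuristic aligners, bit-for-bit reproducible. Iterative
refinement and guide trees are deliberately out of scope.

Motif mapping is alignment-based against a small curated reference set
(one annotated mature reference per substrate class, TSV format) rather
than profile-state-based: the family's anchor residues were originally
located by inspecting alignments, and explicit reference anchors make
every mapped position auditable. The mature query is aligned to the
best-scoring reference and the reference columns are transferred:

* `hx`, `fy` — must land on His and Phe/Tyr respectively, else a
  motif-mapping error (tyrosine is accepted at Fy; some AA10s carry it);
* the substrate diagnostic (homolog of CBP21 Ile180, at Fy−7 on the
  bundled references): Ile/Val ⇒ chitin, Arg ⇒ cellulose, anything else
  or a gap ⇒ ambiguous;
* the tryptophan triad below the copper site (three reference columns);
* the conserved active-site alanine (homolog of CBP21 Ala112). The
  published numbering of this residue is on the *other* side of Hx in
  sequence (A137 vs H112 on one cohort protein); the package treats it
  purely as an anchor column — a statement about spatial proximity, not
  sequence adjacency.

One mapping subtlety: alignments against a reference are computed on the
mature *prefix* (reference length + 120 residues). Motif mapping only
concerns the catalytic region, and a fully global alignment of a
600-residue multidomain protein against a 200-residue reference pays a
~400-residue terminal gap that can push even a perfect catalytic match
below the score gate.

Two sequence-level scans need no reference: the polar motif
`[YW][EN]PQS[VL]E` of chitin-active bacterial LPMOs (bracket positions
exact, up to one mismatch at the fixed positions — the motif is only
"mainly" conserved) and the gatekeeper `VADTGNAFY` (best 9-residue
window, reported at ≥ 6/9 identity). Cysteines are counted in the
full-length protein and within the catalytic domain; disulfide capacity
is `floor(n/2)`.

The catalytic domain itself is taken to run from His1 through the
conserved aspartate six residues beyond Fy. On the validation cohort
this reproduces the published per-protein cysteine split exactly, and on
the best-characterised member it reproduces the published 1–191
catalytic span.

## Domain architectures

Accessory-domain hits (GbpA_2, CBM5, CBM73, CBM5/12, Fn3, Ig-like,
Secret_tail_C, …) are assembled into an ordered, non-overlapping
architecture. Overlaps are resolved by a fixed precedence — higher
score, then longer span, then smaller start, then profile name — with
the losing hit trimmed to its largest free run. The precedence is
deterministic and permutation-invariant by construction; a brute-force
interval oracle checks it on random hit sets.

Uncovered gaps of at least `min_space_len = 60` residues become `SPACE`
segments. The threshold is chosen so that the 88–120-residue
inter-domain "Domain-X" regions of GbpA-like proteins are captured while
ordinary linkers are not. A protein is *GbpA-like* when it carries a
catalytic domain, a GbpA_2 domain and a SPACE segment starting within
`adjacency_gap = 10` residues of the GbpA_2 end — the sequence-level
signature of the GbpA_3-like domain of *Vibrio cholerae* GbpA.
Sequence-level Domain-X calls are provisional; `classify_gbpa3_like()`
confirms them structurally, and `count_functional_domains()` accepts a
list of structurally confirmed segments.

## Phylogeny

Catalytic-domain trees use p-distances with pairwise deletion (columns
where both rows are non-gap), optionally Poisson-corrected. The
published analysis used a GUI phylogeny program whose exact distance
model is unstated; p-distance is the most assumption-free choice and the
group with a published identity value reproduces it exactly. Neighbor
joining follows Saitou–Nei with two determinism contracts that
implementations commonly leave unspecified: ties in the Q criterion are
broken by the lexicographically smallest index pair in current matrix
order, and negative branch-length estimates are clamped to zero with the
deficit transferred to the sister edge (pair total preserved). A
brute-force Q-minimisation oracle checks the join sequence on 1,000
random 6-taxon matrices, and additive matrices are recovered exactly.

Bootstrap support resamples alignment columns with replacement and
counts, per internal edge, the fraction of replicate trees containing
the same tip bipartition. Rows are sorted by label before resampling so
that supports cannot depend on input leaf order (NJ tie-breaking is
order-sensitive). Replicates whose resampled alignment leaves a pair
with no comparable columns stay in the denominator and support nothing.

Group/substrate assignment inherits each query's label from its nearest
reference leaf by path length, with exact ties reported as `ambiguous`
and queries beyond `max_ref_dist` as `unassigned`. A clade-purity rule
("a clade containing no reference") was considered and rejected: with
several queries derived from one reference, the queries routinely form a
small reference-free clade of their own, and the rule would misfile
them. The distance cutoff captures the same "distinct group into which
no reference falls" idea monotonically. Exact reproduction of the
published group memberships is explicitly out of scope — it requires the
39 external reference proteins and the original program's unstated
distance model.

## Structural comparison

`read_calpha()` parses the Cα trace of one chain (first-occurrence
altloc policy); `kabsch_superpose()` is the standard SVD solution of the
least-squares rigid-body problem with reflections excluded (determinant
+1 enforced; for degenerate point sets the proper rotation from the SVD
is used as-is). Correspondence is by list order: Domain-X windows and
the reference are compared as contiguous equal-length segments, which
matches how the published superpositions were made and avoids a
structural-alignment search. `sliding_domain_match()` scans every
window of reference length (stride `step`) and returns the RMSD-minimal
one; a SPACE segment is *GbpA_3-like* when its best window RMSD is at
most `rmsd_cutoff = 5.0` Å over at least 80% of the reference length.
The source study reports visual coincidence, not an RMSD, so the cutoff
is a package design choice: well above the noise of good models,
far below the ≥ 15 Å separation that random coils show against a compact
fold (checked by simulation).

No crystal-structure coordinates are bundled. The reference fold used in
tests and analyses is a synthetic β-meander (`make_fold_coords()`),
clearly labelled synthetic; users supply real GbpA_3 reference
coordinates as a PDB file.

## The synthetic-data generator

Every pipeline stage is validated against ground-truthed synthetic data.
Planted proteins are assembled on a shared AA10-like scaffold: three
conserved blocks — around His1, around Hx, and around Fy (the latter
carrying the diagnostic position, the gatekeeper core, two triad
tryptophans and the anchor aspartate) — separated by variable-length
random spacers. Hx offsets are drawn from 87–156 and Fy offsets from
159–227, the ranges observed in the validation cohort, so motif mapping
must genuinely transfer positions across indels rather than read fixed
offsets. Cysteine and histidine are excluded from all random draws and
planted explicitly, making cysteine censuses and His candidates exact by
construction. Decoys are composition-matched shuffles: they defeat any
annotation that keys on residue composition rather than motif geometry.
Point mutations at a configurable rate avoid planted positions; the
recorded truth always reflects the emitted sequence (the polar-motif
flag, for instance, is re-scanned after assembly).

`make_table1_cohort()` instantiates this generator once per row of the
published 31-protein characteristics table (`lpmo_table1()`): lengths,
Hx/Fy positions and cysteine counts are taken from the table, and the
census features are planted per a fixed design table — 21 complete
triads, 20 polar motifs, 29 conserved alanines, 4 arginine-diagnostic
proteins plus one Ile-with-adjacent-Arg case, 13 GbpA-like
architectures, and a three-member clone group whose catalytic domains
align at exactly 83.3% identity (165 conserved columns of 198, arranged
through 31 designed point mutations plus one compensated
deletion/insertion pair). Because the real supplementary sequences are
not redistributable, the bundled `inst/extdata` fixtures are this
synthetic stand-in at a fixed seed; every file is prefixed `synthetic_`.

What passing tests on this cohort do and do not show: they show that the
pipeline's coordinate bookkeeping, filtering, censuses and
classifications are exact on sequences with realistic motif geometry,
lengths and composition; they do not show robustness to real-world
divergence (the scaffold blocks are more conserved than a 12%-identity
natural group), to alignment ambiguity near motif boundaries, or to
profile-search idiosyncrasies, and the inter-group branch structure of
the synthetic phylogeny is essentially random because spacers carry no
shared signal.

## Numerical choices and degenerate inputs

* Alignment tie order diagonal > up > left; BLOSUM62 is built in code.
* Star-MSA padding is right-aligned after each merged insertion block;
  gap-only columns cannot occur by construction.
* `percent_identity` is the fully-conserved-column fraction — the
  published per-group "degree of identity" is not formally defined, and
  this working definition reproduces the one checkable published value.
* NJ tie and clamping rules as above; distances must be finite, and a
  pair with no comparable columns is an error, not a silent zero.
* Kabsch on collinear sets falls back to the SVD's proper rotation.
* Empty record sets run to completion with a warning and an empty
  report; per-record annotation failures become `fragment` rows.

## Problem sizes

The bundled analyses and tests run at the study's native scale where
that is cheap (31 proteins, full MSAs, 200–1,000 bootstrap replicates or
NJ property instances) and at reduced but statistically meaningful scale
elsewhere (50 + 50 end-to-end recovery records, 10-model structure
batteries), sizes chosen so the whole validation suite completes in
about half a minute on one core.

## Known limitations

* The 69→33→31 mining funnel of the source study is not reproducible at
  desk scale (it requires the ~52 Gb metagenome); the funnel *accounting*
  is validated on synthetic mixtures instead.
* Star MSA is a center-star approximation; for publication-grade
  alignments of divergent families use a dedicated aligner and import
  the result with `read_msa()`.
* Substrate assignment by nearest reference assumes the reference set
  spans the query diversity; `unassigned` calls depend on the
  `max_ref_dist` parameter, for which there is no universal default.
* Structural classification uses order-based correspondence; it will
  miss a GbpA_3-like domain whose strand order is permuted relative to
  the reference.
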