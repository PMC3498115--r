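---
title: "Methods: profile scanning, subfamily classification and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile scanning, subfamily classification and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(tpppscan)
```

This vignette is the package's own account of its methods: the domain model
and its geometry, the scoring and decision rules, the disorder and tree
stand-ins, what the synthetic generator does and does not emulate, and the
numerical choices that make every result deterministic.

## The domain model

TPPP-like proteins are defined by the p25alpha domain. The package
represents it as a *segmented* profile (`p25_model`) with four parts:

* `ntail` — the ~50 aa N-terminal tail some long-type proteins carry,
* `core` — the 119 aa body of the domain,
* `partial_core` — the conserved 31 aa C-terminal block, carrying exactly
  one `GXGXGXXGR` Rossmann-like motif,
* `extension` — the 14 aa block that follows the motif immediately in
  motif-bearing proteins.

`core + partial_core` = 150 aa, inside the documented 140–160 aa band for
the full domain; `build_model()` validates these bounds (31–32 aa for the
partial block, exactly 14 aa for the extension) whenever a model is
constructed. The motif sits at the C-terminal end of the partial block
(offset 23 of 31), so the extension window starts right at the motif's last
residue + 1 — this is what ties `detect_extension()` to
`find_rossmann_motifs()`.

The packaged default model (`default_p25_model()`) is a *designed*
consensus, not a database sequence. Its composition is coupled to the
family's structural contrast: the core is hydrophobic-leaning (so it
profiles as ordered), while the N-tail, partial core and extension are
charge-enriched (so they profile as disordered). This is a deliberate
modelling choice: it makes the ordered/disordered subfamily contrast a
*consequence of the architecture*, exactly as described for the real
family, and therefore testable end to end on synthetic data.

### Scoring

Columns are smoothed log-odds against a uniform background:
`S(i, a) = log[(count(i, a) + c)/(n + 20c)] − log(1/20)` with pseudocount
`c = 0.5` by default (a neutral Laplace-style choice; with a single seed
sequence it gives a match/mismatch contrast of about +1.0 / −0.1 nats).
`X` scores as an unseen residue. A window's *normalized score* divides its
raw score by the maximum attainable, giving a model-independent scale in
(−∞, 1]. Hits are tiered `strong` (≥ 0.80) / `weak` (≥ 0.55) /
`candidate`; the tiers play the role E-value strata play in
database-backed surveys (confident hit / worth inspection / borderline)
but are portable and deterministic. Both thresholds are exposed in
`run_config()`.

## Scanning and fragment measurement

`scan_profile()` is gapless: the segment's columns slide across the
sequence, every offset is scored, and candidate hits above
`min_normalized` are resolved greedily — highest score first, leftmost on
ties — so reported hits are non-overlapping local maxima. Gapless scanning
is sufficient here because classification needs approximate location and
length, not residue-level alignment; an affine-gap scanner would be the
natural extension.

Multidomain proteins carry p25alpha *fragments* of roughly 70–140 aa (the
first half of the domain is always present; the C-terminal extent varies).
`measure_fragments()` anchors candidates with the first 70 columns of the
combined core + partial-core profile, then picks the fragment end as the
width `w` maximizing `cumsum(column scores) − (mean column maximum / 2) · w`.
The half-match penalty makes every true-domain column (which scores near a
full match) extend the fragment and every background column (near the
mismatch score) shrink the objective, so on a noise-free sequence the
measured width equals the planted width exactly; under point mutations the
estimate degrades gracefully by at most the length of the mutated tail.
The generator guarantees the first linker residue after a fragment differs
from the next consensus column (its "boundary guarantee"), which is what
makes the zero-noise measurement exact rather than exact-up-to-one.

## Classification rules

`classify_architecture()` applies a fixed precedence: apicortin (partial
block + annotated DCX) → long-type (single 140–160 aa core + partial span,
gap ≤ 10 aa, no foreign domains; N-tail flagged at ≥ 40 preceding
residues) → short/truncated (single core-like region, no partial block) →
multidomain (fragments with foreign domains, or ≥ 2 fragments) →
partial-only → none. Two points deserve justification:

* **Foreign domains come from annotations**, never from ab initio
  detection: re-implementing Pfam/CDD is far outside this package's scope,
  and the published censuses list the foreign-domain content per accession.
  The synthetic generator mirrors this by emitting an annotation table
  alongside each FASTA.
* **Short-type vs truncated** cannot be separated by sequence alone — the
  real distinction is phylogenetic (truncated TPPPs are recent arthropod
  paralogs of long-type TPPPs; short-type TPPPs are ancient outparalogs).
  The classifier therefore uses two pieces of evidence: the region's
  normalized affinity to the *long-type* core profile (truncated cores,
  being recent paralogs, stay close to it; short-type cores are far more
  diverged) with threshold `truncated_affinity = 0.87`, and a metazoan
  taxon gate. The threshold sits halfway between the designed affinities
  of the two synthetic variants (≈ 0.96 for the truncated variant, ≈ 0.81
  for the short variant) so that at 5% mutational noise (score standard
  deviation ≈ 0.02 over 119 columns) both classes clear it with a ≥ 2 sd
  margin. When no taxon is supplied the call defaults to `short_type` and
  the ambiguity is recorded in the evidence — the conservative choice,
  since short-type is the globally common core-only architecture.

## Alignment, orthology, trees

Identity/similarity come from a global affine-gap alignment
(Needleman–Wunsch/Gotoh via Biostrings; match +2, mismatch −1, gap open
10, gap extend 0.5), with statistics computed over alignment columns
excluding terminal gaps, so a domain-only protein compared with a tailed
one is judged on the shared region. Similarity credits substitutions
within the conventional strong groups {ILVM} {FYW} {KRH} {DE} {ST} {NQ}
{AG}. Reciprocal best hits use the classic double-argmax rule with
lexicographic tie-breaking.

Bayesian tree inference is deliberately not reproduced: the claims the
package tests are *topological separations* — truncated proteins form a
clade; long + truncated separate from short — and neighbor joining
(`ape::nj`) on identity distances (`d = 1 − identity/100`) assesses those
deterministically in seconds. NJ is consistent on additive matrices (the
test suite verifies exact topology recovery for up to 8 taxa); negative
branch lengths on non-additive inputs are clamped to zero with a warning.
Clade credibilities have no analogue here and none are reported.

## The disorder profiler

The per-residue predictor is an explicitly documented charge–hydropathy
fold index, *not* a reimplementation of any machine-learned predictor:
windowed mean Kyte–Doolittle hydropathy rescaled to [0, 1] (`⟨H⟩`) and
windowed mean net charge (K, R = +1; D, E = −1; `⟨R⟩`) give
`f = 2.785⟨H⟩ − |⟨R⟩| − 1.151`, mapped through `1/(1 + exp(8 f))` so that
`f = 0` lands exactly on the conventional 0.5 threshold. The steepness 8
makes the logistic saturate at |f| ≈ 0.5, comfortably inside the range the
fold index takes on real compositions; it affects only how soft the
boundary is, never which side of 0.5 a residue falls on. The default
window of 21 residues is the common disorder-window scale; both window and
threshold are in `run_config()`. What this stand-in captures is the
composition-driven contrast (charge-rich/low-hydropathy regions score
disordered); what it cannot capture are context effects a pairwise-energy
or learned model would see. For the package's claims — ordering contrasts
between subfamilies built with contrasting compositions — composition is
precisely the signal, so the stand-in is sufficient and honest.

## The synthetic generator

`generate_dataset()` is the package's benchmark instrument. Per class it
assembles the documented architecture from the model's consensus segments
(long: tail + core + partial + extension; short/truncated: the fixed
divergent core variants; partial-only: 1–4 partial copies ± motif ±
extension joined by disordered linkers; multidomain: 1–2 fragments of
70–140 aa plus foreign marker blocks; apicortin: partial copy + DCX
marker), then applies point substitutions and linker-only indels. Three
guarantees keep the truth labels exact at nonzero noise: motif positions
are never mutated, indels never touch domain segments, and fragment/linker
boundaries are protected as described above. Default parameters are the
family's stated geometry (domain 140–160 aa, partial 31–32 aa, extension
14 aa, tail ~50 aa, fragments 70–140 aa, partial copies 1–4); the two
divergence dials that are not stated anywhere — how far the short-type and
truncated cores sit from the long-type core — were fixed once at ~18% and
~3% of core positions, matching the qualitative description (ancient
outparalog vs recent paralog) and giving the clade and affinity structure
the claims require.

What the generator does **not** emulate: real Pfam domain models (foreign
domains are composition-distinct placeholder blocks consumed via
annotations), indels inside domains (the scanner is gapless by design),
compositional drift, EST sequencing error beyond the B/Z/U/`*` → `X`
mapping, and realistic phylogenetic rate variation (mutations are i.i.d.
uniform). Passing tests therefore demonstrate that the pipeline's logic is
correct under the family's documented geometry — not that the profile
would match every divergent real family member.

## Fixtures and the census

The packaged TSVs transcribe the published truncated (22 rows),
multidomain (18 rows) and partial-domain (20 rows) tables — metadata only,
no sequences. Two reconciliation choices are documented here because the
printed tables and the printed census disagree slightly:

* The truncated table footnotes *two* entries as phylogenetically doubtful
  (an ant protein and the flatworm protein), but the census counts 21
  of the 22 rows — i.e. it dropped only the flatworm. The fixtures
  therefore carry both a `questionable` flag (both rows) and an
  `excluded` flag (flatworm only); headline counts drop only `excluded`
  rows, and every flagged row is listed in the table's footnote
  attribute. This reproduces each printed cell (Arthropoda = Metazoa =
  21) without silently discarding data.
* The partial-domain table lists five stramenopile proteins, but the
  census's partial column leaves the Chromalveolata cell blank. The
  package tabulates them (they are data) and surfaces the cell; the test
  suite pins it at 5.
* A single printed motif flag on a multi-copy row (e.g. "3 yes") is
  expanded to all copies, which is the only reading consistent with the
  flag-per-copy rows ("yes, no").

Records that classify as `none` are diverted to a diagnostics attribute,
never counted; unknown species map to an explicit `unassigned` row.

## Numerical choices

* Coordinates are 1-based inclusive throughout (the R/Biostrings
  convention); widths are `end − start + 1`.
* Greedy hit selection orders by score rounded to 1e-9, then position, so
  exact score ties (common with two-valued single-sequence profile
  columns) break deterministically leftmost regardless of floating-point
  summation order.
* Ties in the fragment-width objective prefer the shortest width; argmax
  ties in reciprocal best hits break lexicographically by id and are
  messaged.
* NJ branch lengths below zero are clamped to zero with a warning.
* All randomness flows from explicit seeds; `generate_dataset()` is
  byte-reproducible, and the pipeline's report files are byte-identical
  across reruns on the same inputs.

## Problem sizes

The test suite runs at desk scale, chosen to exercise every code path in
well under a minute per module: oracle equivalence on sequences ≤ 60 aa
(scanning) and ≤ 30 aa (alignment); label recovery on 6 classes × 10
proteins at zero noise and 6 × 60 at 5% substitution; clade structure on
13 proteins; NJ consistency on all tree shapes up to 8 taxa × 5
replicates; fixture tabulation on the full packaged tables.

## Known limitations

* Gapless scanning cannot place hits across insertions inside a domain;
  real divergent members would need an affine-gap scanner or HMM.
* The short/truncated decision depends on a caller-supplied taxon; without
  one, truncated proteins are reported as short-type (with a note in the
  evidence).
* The disorder stand-in is composition-only; it should not be quoted as a
  per-protein disorder prediction outside this package's comparative use.
* Identity distances saturate for deep divergences; the NJ trees are for
  clade-structure checks, not for publication-grade phylogenetics.
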