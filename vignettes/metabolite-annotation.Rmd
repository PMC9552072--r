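---
title: "Biotransformation-guided metabolite annotation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biotransformation-guided metabolite annotation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BiotransMS)
```

# The problem

After a drug is dosed, high-resolution LC-MS surveys of plasma, urine,
feces and tissue contain hundreds of peaks, a handful of which are
metabolites of the parent compound. BiotransMS implements the desk half
of such a survey for a glycosidic parent drug: given peak tables (with
optional MS/MS spectra) from several biological matrices and the
parent's ion formula, it proposes metabolite identities by composition
arithmetic, confirms them with neutral-loss evidence, and summarizes the
result as an annotation table, a metabolic pathway graph, and
metabolite--target(--pathway) networks. The packaged reference tables
describe mulberroside A, a stilbene diglucoside (the aglycone
oxyresveratrol carrying two glucose residues), whose published rat
metabolite survey the package reproduces end to end.

# Formula arithmetic

All identity proposals rest on exact arithmetic over elemental
compositions (named integer count vectors over C, H, N, O, S):

* **Monoisotopic mass** is the sum of monoisotopic atomic masses
  (CODATA/IUPAC values at full precision; carbon exactly 12). Full
  precision matters: with masses truncated at 8 significant digits, the
  4-decimal theoretical m/z of sulfur-containing ions such as
  C14H13O7S comes out one unit low in the last digit.
* **Ion m/z** of a singly charged ion formula subtracts the electron
  mass. The default `"reported"` convention subtracts it for *both*
  polarities — physically wrong for anions, but it is what common
  deconvolution software prints and what published reference tables
  contain; `"physical"` (adds the electron for anions, two electron
  masses heavier) is available via `ionMz(..., convention =
  "physical")`.
* **RDB (ring-plus-double-bond) equivalent** is `C - H/2 + N/2 + 1`.
  Applied to even-electron ion formulas it yields the half-integer that
  annotation tables print; no charge correction is applied.
* **ppm error** is `(experimental - theoretical) / theoretical * 1e6`.
* **Constraints**: candidate formulas are filtered by element-count
  ranges and an RDB range; the defaults (C 5--40, H 5--60, O 2--30,
  S 0--2, N 0--3, RDB 3--20) are the ranges appropriate for a C/H/O/S
  phytochemical and its phase-I/II metabolites.

Printed reference tables round to 4 decimals; comparisons against them
use round-half-even at 4 decimals, while internal arithmetic never
rounds. Printed ppm errors were computed by the original software from
unrounded masses, so recomputation from 4-decimal values is accepted
within ±0.5 ppm.

# The biotransformation engine

A biotransformation step is a named signed composition delta with a
multiplicity cap: hydrolysis (−C6H10O5 per glucose residue, up to 2),
glucuronidation (+C6H8O6, up to 2), sulfation (+SO3), hydroxylation
(+O, up to 2), dehydroxylation (−O), hydrogenation (+H2),
dehydrogenation (−H2), methylation (+CH2, up to 2), acetylation
(+C2H2O) and hydration (+H2O). Caps are the highest multiplicities
seen in glycoside surveys ("bis-"glucuronides, "di-"methylation);
forward/reverse redox pairs are mutually exclusive within one
combination so that every multiset is a canonical net transformation.

Three design choices deserve explanation:

* **Hydrolysis counts once.** For a diglucoside, losing one or both
  glucose residues is a single hydrolytic event chemically and is
  labelled plainly "hydrolysis" in reference tables either way. The
  step budget (`reactionStepCount()`) therefore counts hydrolysis once
  at either multiplicity. With per-residue counting, common four-way
  conjugates (aglycone + hydrogenation + glucuronidation + sulfation)
  would need a budget of 5, inflating the search space for no gain.
* **`explainTransformation()` returns all explanations, not just the
  most parsimonious.** Mass arithmetic alone cannot rank mass-identical
  alternatives: hydration (+H2O, one step) produces the same
  composition as hydrogenation + hydroxylation (two steps), and many
  published assignments are the longer variant because the MS/MS
  spectrum, not parsimony, decided. All multisets within the budget are
  returned, ordered by step count then label (deterministically), and
  `onlyMinimal = TRUE` restores the parsimony-only view. Downstream,
  evidence scores — not step counts — are the intended arbiter.
* **Cleavage products are special-cased.** Breakage of the anomeric
  C--O bonds yields phenol fragments that are then glucuronidated;
  these are not whole-molecule deltas and are modeled as two named
  products with fixed ion formulas (C12H13O8, C14H15O8) attached by a
  `cleavage` edge.

Candidate matching accepts every candidate within a ppm tolerance
(default 5 ppm, chosen as a round bound just above the largest error in
the packaged reference table, 4.06 ppm) and sorts by |error|, then
fewest steps, then label, so ties break identically across runs.

# MS/MS evidence

Neutral-loss assignment builds a ladder from the precursor downward:
each fragment is linked to the nearest heavier ion whose mass
difference matches one library loss within an absolute tolerance
(default 0.01 Da — published fragment lists carry two decimals), then
combinations of two, then more distant ancestors. Deeper chains emerge
from the ladder structure rather than from longer combinations, which
keeps the combination search bounded.

Diagnostic evidence flags summarize a spectrum: the aglycone skeleton
series (stilbene/dihydrostilbene product ions, curated as ion formulas
and computed, not hard-coded m/z), glucuronide markers (176.0321 loss
or the glucuronate anion at 175.024), sulfate markers (79.9568 loss or
hydrogen sulfate at 96.959), methoxy (30.011 loss) and retained
glucoside (162.053 loss). The two ions printed as "175" in reference
tables — glucuronate 175.02 and the aglycone-series ion 175.08 — are
distinct at the 0.01 Da tolerance. `evidenceScore()` is the fraction
of the candidate-implied evidence items (skeleton plus one item per
conjugation class with a spectral signature) that are observed; it is
monotone in added evidence.

# The annotation pipeline

`annotateDataset()` enumerates candidates once, matches all peaks,
keeps each peak's best match, and merges matched peaks into one record
per (formula, retention-time cluster) with a 0.05 min merge window —
reference tables report a single retention time per metabolite across
matrices, and isomers (same formula, different time) remain separate
records. Each record carries per-matrix presence, the maximum peak area
and its matrix, the best ppm error, and MS/MS evidence.

Summaries mirror the published survey: `matrixCounts()` (blood is the
union of the three plasma preparations), `preparationComparison()`
(solid-phase extraction vs methanol vs acetonitrile; the published
totals include the parent prototype, so `includePrototype = TRUE` is
the default), and `reactionClassProportions()`, where a composite
record contributes its full area to every constituent class — the
per-class decomposition of a composite metabolite is not observable
from peak areas, and full attribution is the accounting that published
per-reaction area summaries use (`split = "fractional"` divides
instead).

# Pathway and network graphs

The pathway graph is a rooted DAG. A record's multiset is ordered
canonically — hydrolysis first (deglycosylation precedes conjugation in
vivo), remaining steps lexically — and each prefix becomes a
composition-keyed intermediate node, so records with shared prefixes
share nodes: one hydrolysis passes through the monoglucoside hub, two
through the aglycone hub. The two monoglucoside isomers have the same
composition and are deliberately merged into one hub node labelled with
both names; the data cannot say which isomer a downstream conjugate
came from. Routes are classified by hydrolysis multiplicity: direct
modification (0), via the monoglucoside (1), via the aglycone (2), or
cleavage. Alternative step orderings are not enumerated; the canonical
ordering is a presentation choice, and every edge still conserves
composition exactly.

Metabolite--target networks are undirected, unweighted bipartite graphs
(igraph-backed) with exact node/edge/degree accounting; the tripartite
extension adds pathway nodes and target--pathway membership edges
additively. Target identities are not public — only per-metabolite
counts and the distinct-target total are — so
`simulateTargetAssignment()` constructs labeled assignments honoring
exactly those constraints, which suffices for every published network
statistic (node counts, edge counts, degree ranking).

# The synthetic-data generator

`simulatePeakTables()` emulates the study design: each ground-truth
metabolite (by default the packaged 72-row table, i.e. the published
presence design) emits one peak per detected matrix with

* m/z = theoretical × (1 + ε), ε ~ Normal(0, ppm sd × 1e−6); default
  1 ppm, a typical externally calibrated Orbitrap spread,
* log-normal peak areas (location log 1e6, scale 2.3 — spanning the
  1e4--1e8 range real surveys show),
* the true retention time,
* an MS/MS ladder implied by its reaction multiset
  (`simulateMs2()`), with optional per-fragment dropout,
* plus per-matrix decoy peaks drawn uniformly in the instrument's
  80--1200 window but outside ±10 ppm of every true mass, so recovery
  statistics are interpretable.

A single integer seed drives all draws through one generator stream;
identical configurations give byte-identical outputs. Under this model
the per-peak recovery rate at tolerance t has closed form
P(|ε| ≤ t) = 2Φ(t/sd) − 1, which the test suite checks by Monte Carlo
(100 seeded replicates at 2 ppm noise and 5 ppm tolerance, agreement
within 3 Monte-Carlo standard errors).

What the generator does *not* emulate — chromatographic peak shape,
isotope envelopes, matrix effects, correlated mass error, in-source
fragmentation — bounds what passing tests mean: they validate the
arithmetic, matching, merging and graph construction, not robustness to
instrument artifacts.

# Numerical and degenerate-input choices

* Empty compositions have mass 0; the empty reaction multiset is the
  parent itself and is always retained regardless of constraints.
* Reaction application refuses negative element counts (the reaction
  "does not apply") rather than clamping.
* All orderings (candidates, matches, explanations, degree tables) have
  total, documented tie-breaks, so outputs are stable across runs and
  platforms.
* Output files are written via temp-file-then-rename, and every writer
  has a reader that round-trips.
* The packaged reference table keeps internally inconsistent printed
  values verbatim and marks them (`inconsistent` column) rather than
  silently correcting: two rows print a theoretical mass that does not
  reproduce from their own formula, one row swaps theoretical and
  experimental mass, and two rows have garbled detection checkmarks
  that were resolved against the printed per-matrix totals. The feces
  column transcribes to 13 detections against a printed total of 12;
  the 13 rows are unambiguous, so the transcription is kept and the
  discrepancy documented.

# Problem sizes

The shipped analyses run at the published scale: 72 metabolites, ~130
true peaks plus decoys across seven matrices, a candidate space of
~580 formulas at a four-step budget, and networks of a few hundred
nodes. The Monte-Carlo calibration uses 100 replicates of the full
peak-table simulation. These sizes keep every check exact or tightly
calibrated while remaining fast on a single core.

# Known limitations

* Isomers are distinguished only by retention time; no structure or
  site-of-metabolism reasoning.
* The skeleton diagnostic-ion list is curated for stilbene glycosides;
  other parent scaffolds need their own list (pass a custom library).
* Only singly charged ions and the [M+H]+/[M−H]− species are modeled;
  no isotope patterns, adducts, or multiply charged ions.
* Reaction caps are inferred from observed products and are
  configurable, not mechanistic.
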