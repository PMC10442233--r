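---
title: "Open β-sheet topologies, frustration rules, and novel-fold prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open β-sheet topologies, frustration rules, and novel-fold prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetfolds)
```

## The model

An αβ-protein built on a single open β-sheet is abstracted to its sheet
topology: a permutation giving the left-to-right order of the
sequence-numbered strands, plus an up/down orientation per sheet position.
`sheetfolds` works entirely at this abstraction. Barrels (cyclic sheets),
branched sheets, multi-sheet folds, β-bulges and register shifts are outside
the model.

Two grids describe the same physical sheet when they are related by a rigid
rotation of the sheet: 180° about the strand axis (reverse positions), about
the in-plane horizontal axis (flip orientations), or about the face normal
(both). Mirror images are *not* identified — the connection rules below are
chiral, so an enantiomeric sheet is a genuinely different object. Each orbit
has exactly four members (strand labels are distinct), which collapses the
n!·2^n raw grids to n!·2^(n−2) topologies.

```{r}
nrow(enumerate_topologies(4))
```

The canonical representative of an orbit is its lexicographic minimum,
comparing the order tuple first and then orientations with u < d. Any fixed
total order would do; this one is reproducible and diffable, and reduces to
two local choices (reverse if `order[1] > order[n]`, then flip if the first
orientation is `d`). The representative a figure-style grid would pick for
an orbit may differ; every count and verdict in the package is an orbit
property and unaffected.

## Connections and faces

Strands i and i+1 form one β-X-β connection: *para* or *anti* by relative
orientation, with jump distance = intervening sheet positions. This reading
of the motif — a chain link between sequence-consecutive strands of the same
sheet, with spatial jump distance — is the only one we found under which the
worked examples and the Greek-key exemption are simultaneously consistent.

Para crossovers are right-handed; anti connections with jump ≥ 1 bend
right-handedly around the sheet edge. We realize "right-handed" uniformly as
a positive triple product along the routed path (strand direction, approach,
departure). On idealized coordinates this yields one parity law for both
kinds: *a connection crosses the back face exactly when its departing strand
points up and it travels rightward, or points down and travels leftward*.
Antiparallel hairpins (jump 0) turn within the edge plane and have no face.
Only relative faces matter; the front/back labels are a convention, and
flipping them globally changes no verdict (tested via the orientation-flip
symmetry image, which realizes exactly such a flip).

The mock-coordinate generator (`mock_coordinates()`) routes every connector
explicitly and picks its face by evaluating the triple product on real
coordinates for both candidate bows. It therefore serves as an independent
geometric oracle: the test suite checks that routed faces equal the parity
law on every connection of every 3- and 4-stranded topology.

## The three rules and their calibration

1. **Jump distance.** Para connections violate at jump ≥ 4, anti at
   jump ≥ 2, except anti jump-2 connections inside a Greek-key window: four
   consecutive positions, fully antiparallel, whose strands (relabeled by
   sequence rank) trace the Greek key or a circular permutation of it. The
   window may sit at any offset inside a larger sheet; the relabeling makes
   embedded Greek keys exempt too.
2. **Overlap.** Two connections on the same face violate when they share a
   strand or when one span nests inside the other.
3. **Ending.** Two para connections whose second strands (the later strand
   of each motif) occupy adjacent, equally oriented positions must end on
   the same face. The ending side is the connection's face for even jumps
   and the opposite face for odd jumps.

The pair-applicability choices in rules 2–3 and the parity term in the
ending side are the genuinely open parts of the design: the prose statements
of the rules underdetermine them. We fixed them by calibration against the
published anchor verdicts, which the test suite pins down:

* three-stranded sheets: 10 of 12 topologies frustration-free;
* four-stranded sheets: 43 frustration-free / 53 frustrated of 96;
* `1234:udud` (meander) clean; `1342:uddd` frustrated with a jump and an
  overlap violation and *no* ending violation; the all-parallel,
  knot-forming `3142:uuuu` clean; the Greek key `4123:dudu` and its
  circular permutants clean.

Two candidate systems satisfy every anchor, differing only in the global
sign of the anti-connection face relative to the para face; the counts
cannot distinguish them. We chose the same-sign convention because it is
what the single triple-product chirality definition yields. Within the
calibrated system, note two consequences that a naive reading would miss:
same-face spans that merely *cross* do not violate the overlap rule (their
crossovers are offset parallel diagonals — and `3142:uuuu` would otherwise
be frustrated), and the parity term in the ending side is what leaves
`1342:uddd` free of ending violations while still frustrating a second
three-stranded topology. Equal-parity para connections arriving at adjacent
parallel strands from the same travel direction share an ending side; for
opposite parities the sides differ even at equal travel direction.

```{r}
classification_counts(classify_all(4, detail = FALSE))
classify_topology(parse_topology("1342:uddd"))
```

Violations are unioned, never cancelled, so `frustration-free` means "no
rule fires". All verdicts are pure functions of the topology; there is no
tie-breaking randomness anywhere. Verdict invariance across all four
symmetry images is tested exhaustively at n ≤ 4 and on samples at n = 5–6.

Scaling: the per-topology functions are the readable reference; a
block-vectorized kernel re-expresses the same arithmetic for whole-space
runs and is tested for exact agreement against the scalar path (exhaustive
at n = 3–4, sampled at n = 5). The full eight-strand space (2,580,480
topologies) classifies in about a minute on one CPU.

## Observation statistics

Domain tables mirror the ECOD hierarchy: Family (sequence-level groups)
nested in Homology (superfamily-level groups). For homology group *i*,

$$\mathrm{OR}(i) = \frac{\sum_j^{N_\mathrm{Family}} R_\mathrm{Family}(j)}{N_\mathrm{Family}},$$

with $R_\mathrm{Family}(j)$ the fraction of family *j*'s domains carrying
the topology; the observation frequency is $\sum_i \mathrm{OR}(i)$. The
averaging makes one heavily sequenced family count no more than a sparse
one, and the sum counts evolutionarily independent observations.

Frequencies strictly below 1/4 are labeled unobserved. The threshold is
kept as the exact rational to avoid float-boundary surprises, and the
comparison is strictly less-than, so a frequency of exactly 0.25 counts as
observed. Topologies are canonicalized on ingest, so symmetry images of one
sheet aggregate under a single key. A domain may carry several qualifying
sheets (several rows); exact duplicate (domain, topology) pairs are
rejected. This is a deliberate extension of the exchange format — the
hierarchy's own semantics do not forbid multi-sheet domains.

Predicted novel folds are the frustration-free topologies labeled
unobserved. With an empty table every frustration-free topology is a
candidate; the synthetic-table generator (`make_domain_table_fixture()`)
realizes requested fractions exactly (smallest exact denominator ≤ 64 per
family), so fixture-driven expectations are arithmetic identities, e.g.
families at fractions 1 and 1/2 give OR = 0.75, and marking 35 of the 43
free four-strand topologies observed leaves 8 candidates.

What the generator does *not* emulate: real ECOD snapshots contain barrels
and marginal sheets whose assignment required manual curation, families of
wildly different sizes, and topology assignments that depend on the
secondary-structure assigner. Passing fixture tests therefore demonstrates
the statistics are computed as defined, not that any particular published
census is reproduced; published novel-fold totals depend on the database
snapshot and curation and are out of scope.

## Extraction from coordinates

`parse_structure()` (via bio3d) reads the first model, preferring altloc A.
Strand segments come from an external assignment table — the reproducible
path — or from a crude torsion-based detector (φ < 0 and ψ extended, runs of
≥ 3 residues). Pairing edges require at least two main-chain hydrogen bonds
under a documented geometric criterion: N···O ≤ 3.5 Å and CA–N···O angle
≥ 100°. These constants are this package's choice of stand-in for an
external secondary-structure assigner's bond list; marginal ladders may be
assigned differently, which is why tests use constructed fixtures rather
than database depositions. CA-only files fall back, with a warning, to
counting CA–CA rungs within 5.5 Å.

Sheets are connected components that are simple paths of ≥ 3 strands:
branched components (a strand with ≥ 3 neighbors), cycles (barrels) and
multi-chain components are discarded, and a sheet is dropped when another
candidate sheet's strand is inserted in the sequence interval between two of
its consecutive strands. Strand orientations are propagated along the path
from the pairwise para/anti labels; either traversal direction yields the
same canonical topology. Round-tripping every frustration-free four-strand
topology through mock coordinates and back is part of the acceptance suite.

## Blueprints and mock geometry

`build_blueprint()` lays out strand–connector–…–strand with strand length 5
(usual range 4–7) and helix length 13 (usual 11–17); out-of-range overrides
warn rather than fail. Loop ABEGO patterns per connection unit are fixed
sets with deterministic defaults (first listed): GB/GBA/BAAB/GABA/BA for
para αβ units, AB for para βα, BAB/GBB/AAAB for anti βα, GBB for anti αβ,
BAAGB for R-chirality hairpins and GG for L (default chirality R). Each
loop's residue count equals its pattern length — no extra padding. Anti
connections with jump ≥ 1 take a single helix or, on request, an α-turn
(helix–GBB–helix). Terminal helices are optional and use the para-unit
default loops, a convention chosen since a terminus has no preceding strand
to set the unit type. Blueprints are byte-deterministic for a fixed
configuration.

Mock coordinates place strands on a planar lattice (spacing 4.8 Å, rise
3.4 Å per residue, connector bow 4 Å) with zero register shift — consistent
with register shifts in parallel pairs being nearly always zero or positive,
and sufficient for the topological questions the mocks answer. They are not
physical backbones: no twist, no pleat, CA only.

## Limitations

* The rules are necessary-style constraints distilled from conformational
  preferences; frustration-free does not guarantee foldability, and the
  statistical derivation of the preferences is not part of this package.
* Pair-rule applicability beyond the calibration anchors (e.g. disjoint
  nested pairs in very large sheets) extrapolates the four-strand
  calibration; alternative conventions that agree on every anchor may
  diverge at n ≥ 6.
* The hydrogen-bond stand-in is geometric, not an assigner reimplementation.
* Observation statistics are only as meaningful as the supplied domain
  table.

## Problem sizes in the shipped tests

Exhaustive checks run at n ≤ 4 (orbits and verdicts), oracle and sampling
checks at n = 5–6, and one whole-space classification at n = 8; the full
suite completes in a few minutes on one CPU.
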