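# sheetfolds

Rule-based exploration of the fold space of αβ-proteins built on a single
open β-sheet.

Most globular αβ-folds can be described abstractly by their β-sheet
topology: how the strands, numbered 1..n along the sequence, are ordered
across the sheet from left to right, and which way each strand points. An
n-stranded open sheet admits n!·2^n raw order/orientation grids; identifying
grids related by the three 180° rigid rotations of the sheet (reflections are
excluded — the folds are chiral) leaves **n!·2^(n−2)** symmetry-distinct
topologies. `sheetfolds` enumerates this space exhaustively, decides for
every topology whether it is *frustration-free* (geometrically realizable
without strained connections, hence a possible fold) or *frustrated*, and
combines those verdicts with observation statistics over an ECOD-style
domain hierarchy to nominate **novel folds**: topologies that proteins could
adopt but evolution has not yet explored.

The package is aimed at structural bioinformaticians and de novo protein
designers: the same topology objects compile into Rosetta-style design
blueprints (secondary-structure strings plus ABEGO loop torsion bins) and
into idealized mock coordinates, and sheet topologies can be extracted back
from coordinates.

## The rules

For sequence-consecutive strands i, i+1 of the sheet, the chain link between
them is a β-X-β motif: *para* if the strands are parallel, *anti* otherwise,
with *jump distance* = number of sheet positions strictly between them.
Para crossovers are right-handed (Richardson's rule); anti connections with
jump ≥ 1 bend right-handedly around the sheet edge. These chirality
constraints pin each connection to one face of the sheet, and three rules
follow:

1. **Jump distance** — para jumps must stay below 4 and anti jumps below 2.
   Exception: an anti jump-2 connection inside a Greek-key motif (or one of
   its circular permutations) is allowed.
2. **Connection overlap** — two connections crossing the *same* face clash
   when they share a strand or when one connection's span nests inside the
   other's (S-type); hairpin turns, which stay in the sheet edge plane,
   never participate.
3. **Connection ending** — two para connections whose second strands sit on
   adjacent, parallel sheet positions must end on the same face; ending on
   different faces (D-type) is a violation. The ending side equals the
   connection's face for even jump distances and the opposite face for odd
   ones.

A topology violating no rule is frustration-free. For four-stranded sheets
this splits the 96 topologies into 43 frustration-free and 53 frustrated;
for three-stranded sheets, 10 of 12 are frustration-free.

Observation statistics follow the ECOD Family/Homology hierarchy: for
homology group *i*, the occupation ratio is
`OR(i) = (1/N_Family) Σ_j R_Family(j)` with `R_Family(j)` the fraction of
family *j*'s domains exhibiting the topology, and the observation frequency
of a topology is `Σ_i OR(i)`. Topologies with frequency strictly below 1/4
count as unobserved; frustration-free ∩ unobserved = predicted novel folds.

## Worked example

```r
library(sheetfolds)

cls <- classify_all(4)
classification_counts(cls)
#>            total frustration_free       frustrated
#>               96               43               53

classify_topology(parse_topology("1342:uddd"))
#> <classification> 1342:uddd: frustrated
#>   jump_distance(1)
#>   overlap(1,2)

# the knot-forming all-parallel 3142 order is frustration-free
classify_topology(parse_topology("3142:uuuu"))
#> <classification> 3142:uuuu: frustration-free

# observation frequencies from a synthetic domain table: one homology group
# with two families at match fractions 1 and 1/2 -> OR = 0.75
tab <- make_domain_table_fixture(data.frame(
  topology = "1234:udud", homologies = 1, families = 2, fraction = "1,1/2"))
observation_frequency(tab, "1234:udud")
#> [1] 0.75

nrow(predict_novel_folds(4, tab))   # meander observed, 42 candidates left
#> [1] 42

# compile a topology into a design blueprint
bp <- build_blueprint(parse_topology("3142:uuuu"))
head(bp, 7)
#>   index residue ss abego
#> 1     1       V  E     B
#> ...
```

The first call reports the four-stranded fold-space split (96 = 43 + 53);
the classification objects list each violated rule with the connection
indices involved; `predict_novel_folds()` drops observed topologies
(frequency ≥ 1/4) from the frustration-free set.

A command-line wrapper ships in `inst/cli/sheetfolds`:

```sh
Rscript inst/cli/sheetfolds enumerate --strands 4 --out topologies.tsv
Rscript inst/cli/sheetfolds classify --topology 1234:udud
```

## Package layout

- `R/topology.R` — topology strings, symmetry images, canonical forms,
  enumeration
- `R/rules.R`, `R/classify_all.R` — connection extraction, the three rules,
  scalar and whole-space classification
- `R/observation.R`, `R/fixtures.R` — ECOD-style observation frequencies and
  synthetic domain tables
- `R/extraction.R` — sheet topology extraction from PDB coordinates
- `R/blueprint.R`, `R/mock.R` — design blueprints and idealized mock
  coordinates (also the geometric oracle for the face conventions)
- `vignettes/sheet-topology-rules.Rmd` — the model, its conventions and
  their calibration
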