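# DockTriage

Post-processing toolkit for multi-target molecular-docking screens
aimed at anti-osteoarthritis candidates. The screen docks a compound
library against five inflammatory-pathway proteins — the MAPK kinases
**ERK2, JNK2, p38** and the NF-kB components **p65, IkBa** — and this
package turns the raw docking output into a ranked, filtered,
drug-likeness-annotated candidate list, then reproduces the arithmetic
of the downstream cell assays. It is written for computational
chemists and pharmacology groups running pathway-based virtual screens
who want the triage steps reproducible and testable rather than
spreadsheet-bound.

## The method

Each (compound, protein) docking run yields 10–20 poses with binding
energies *E* (kcal/mol, lower = more stable). The pipeline:

1. **Reduce** each pair's poses to a representative energy —
   `min` of the pose energies by default (the most stable complex), or
   the mean — giving a dense compound × target matrix
   (E<sub>ERK2</sub>, E<sub>JNK2</sub>, E<sub>p38</sub>,
   E<sub>p65</sub>, E<sub>IkBa</sub> per compound).
2. **Score and rank** by a signed weighted sum. The preset schemes are

   Score1 = E<sub>ERK2</sub> + E<sub>JNK2</sub> + E<sub>p38</sub> + 3 E<sub>p65</sub> − E<sub>IkBa</sub>
   Score2 = E<sub>ERK2</sub> + E<sub>JNK2</sub> + E<sub>p38</sub> + E<sub>p65</sub> − E<sub>IkBa</sub>

   IkBa enters with weight −1 because it is the anti-target: a strong
   IkBa binder would disinhibit NF-kB, so favourable IkBa energy
   *worsens* the score. Compounds are ranked ascending.
3. **Filter** by threshold: keep compounds with E < −7 kcal/mol on all
   four targets and E ≥ −7 kcal/mol on IkBa.
4. **Evaluate drug-likeness** by Lipinski's rule of 5 (MW ≤ 500 g/mol,
   LogP ≤ 5, H-bond donors ≤ 5, acceptors ≤ 10; inclusive boundaries)
   from tabulated PubChem descriptors.
5. **Select candidates**: top-10 by score, keep literature-flagged
   anti-inflammatory compounds, drop compounds with an already-known
   anti-OA effect, with a per-compound audit trail.
6. **Assay statistics**: CCK-8 viability as percent of control with
   the ISO 10993-5 ≥ 70% noncytotoxicity rule, nitrite quantification
   from a linear standard curve, and two-tailed unpaired t-tests with
   significance stars (\*, \*\*, \*\*\*, \*\*\*\* at p < 0.05, 0.01,
   0.001, 0.0001).

A seeded synthetic-data module (`generateLibrary()`,
`generatePoseFiles()`, `generateAssayPlates()`) emulates the 51 × 5
screen and the assay plates with planted effects, so the entire
pipeline is testable without any docking engine or wet lab.

## Worked example

```r
library(DockTriage)

# a synthetic 51-compound screen with one planted selective hit
spec <- librarySpec(n_compounds = 50,
                    planted_hits = plantedHit("candidateX"), seed = 7)
lib  <- generateLibrary(spec)
em   <- buildEnergyMatrix(lib$runs, targets = defaultTargets())
em
#> EnergyMatrix: 51 compounds x 5 targets (kcal/mol)
#> targets: ERK2, JNK2, p38, p65, IkBa
#>         ERK2  JNK2   p38   p65  IkBa
#> cmp001 -7.93 -7.62 -7.90 -6.97 -8.97
#> cmp002 -7.09 -7.87 -8.68 -7.47 -7.63
#> ...

ranked <- rankCompounds(em, scoreScheme("score1"))
head(ranked, 3)
#>   rank compound_id     score
#> 1    1  candidateX -72.83885
#> 2    2      cmp047 -44.25779
#> 3    3      cmp029 -42.25039

thresholdFilter(em)          # strict < -7 on targets, >= -7 on IkBa
#> [1] "cmp007"     "cmp029"     "cmp046"     "candidateX"

selectCandidates(ranked, lib$annotations, top_n = 10)
#> SelectionReport: 51 ranked -> top 10 -> 2 anti-inflammatory -> 2 selected
#> selected: candidateX, cmp047
```

The planted hit tops the Score1 ranking (its weighted sum, about
−73 kcal/mol, is far below the best decoy near −44), passes the
threshold filter because it binds the four targets strongly but IkBa
weakly, and survives the annotation filters into the final selection.

Drug-likeness on the shipped published descriptors of the five
candidate compounds:

```r
evaluateLibrary(candidateDescriptors())[, c("compound_id", "violated_rules",
                                            "violation_count", "druglike")]
#>                    compound_id violated_rules violation_count druglike
#> 1                    Corilagin     MW,HBD,HBA               3    FALSE
#> 2                    Apigetrin            HBD               1    FALSE
#> 3                    Protopine                              0     TRUE
#> 4             5-methoxyflavone                              0     TRUE
#> 5 7,3',4'-trihydroxyisoflavone                              0     TRUE
```

Corilagin breaks the molecular-weight, donor and acceptor rules;
Apigetrin only the donor rule (its 10 acceptors sit exactly on the
inclusive boundary); the other three are violation-free and drug-like.

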