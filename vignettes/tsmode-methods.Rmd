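---
title: "Graph-based internal-coordinate analysis of transition-state modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based internal-coordinate analysis of transition-state modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmode)
```

## The problem

A transition state (TS) is a first-order saddle point: it has exactly one
imaginary vibrational frequency, and the displacement field of that mode is a
local approximation to the reaction coordinate. Quantum-chemistry codes
express both geometries and mode displacements in Cartesian coordinates,
which say nothing directly about chemistry: the question a mechanistic chemist
actually asks is *which bonds form or break, what rotates, what inverts*.
Formal answers come from IRC path-following or QRC displacement-plus-
optimization, both of which cost many self-consistent-field evaluations.

`tsmode` answers the chemical question at negligible cost, and without prior
knowledge of reactant or product. It (i) perceives a molecular graph directly
from the Cartesian coordinates — including nonequilibrium TS geometries with
partially formed bonds — (ii) derives a nonredundant internal-coordinate set
(bonds, angles, dihedrals) from the graph topology, (iii) evaluates those
coordinates on structures displaced forward and backward along the imaginary
mode (or on two frames of an IRC/QRC trajectory), and (iv) screens, filters
and classifies the changes into a machine-readable report.

## Graph perception

**Connectivity.** Bond detection is a two-pass distance screen. A pair of
atoms is a candidate when its distance is below a per-class fraction of the
summed van der Waals radii: H–X `r graph_config()$factor_hx`,
nonmetal–nonmetal `r graph_config()$factor_nonmetal`, metal–ligand
`r graph_config()$factor_metal_ligand`, metal–metal
`r graph_config()$factor_metal_metal` (all within the 0.38–0.7 band; tighter
for covalent classes, looser for coordination bonds). Pairs well inside the
threshold (below `direct_accept = 0.6` of it) are accepted outright; the rest
undergo geometric validation: a candidate is rejected if it makes an angle
below 15° (metal endpoint) / 30° (nonmetal) with an existing bond at either
endpoint, or if it closes a 3-ring — or cuts a chord across an existing
4-ring — more than 1.2× longer than the mean of the ring's existing bonds.
The 1.2 ratio keeps genuine small rings (cyclopropane sides are nearly equal)
while rejecting diagonals, whose side ratio is √2 ≈ 1.41. For TS geometries a
second pass repeats the screen with every threshold scaled by
`ts_scale = 1.4`, *adding* validated bonds only, so elongated
partially-formed/broken bonds enter the graph without destabilizing the
equilibrium perception. The vdW radius table (Z = 1–86) is frozen inside the
package — a consolidated published set (Bondi/Mantina main group, Alvarez
d/f-block) — so perception is reproducible independent of external table
revisions.

**Bond orders and formal charges.** Orders are optimized by a beam search
(width 8, iteration cap 200) over single/double/triple assignments on
non-metal bonds, seeded from the all-single pattern and from a Kekulé
alternation on candidate aromatic rings (simple cycles of size 5–7, all
atoms 2–3-connected C/N/O/S, out-of-plane deviation ≤ 0.15 Å). Each step
adjusts the bonds incident to the worst-described atoms and keeps the
lowest-penalty patterns, where the penalty is
$\sum_a \left( w_v\,\mathrm{dev}(a) + w_q\,|q_a| \right)$ with
$w_v = 4 > w_q = 1$: valence satisfaction dominates charge minimization.
`dev(a)` is the distance of the order sum to the nearest allowed valence and
$q_a$ the signed difference to it (so 4-coordinate N is +1, 1-coordinate O is
−1). The global residual `total_charge − Σq` is bookkeeping, assigned after
optimization (to metals, else to the most strained atom) so charges always
sum to the stated total; it is deliberately *not* part of the objective —
including it made independent ligands (e.g. the six carbonyls of M(CO)₆)
couple through a global term and produce arbitrary mixtures of equal-penalty
patterns. Ties are broken to the lexicographically smallest order vector by a
deterministic coordinate descent; one consequence, documented here, is that
carbonyl C–O settles at order 2 (C≡O and C=O tie at equal penalty under this
scoring). Metal–ligand orders are fixed at 1 throughout and labelled dative
when the donor atom is valence-satisfied without counting its metal bonds.
Kekulé rings whose alternation survives optimization are rewritten to uniform
order 1.5. If the iteration cap is hit the best-so-far pattern is returned
with `metadata$order_warning = TRUE`.

## From mode to internal-coordinate changes

**Displacement.** The imaginary mode (most negative frequency; further
negative frequencies are reported as diagnostics) is normalized so the
largest per-atom displacement norm is 1, and the TS is displaced by
±`amplitude` along it. The default amplitude of 0.5 Å is therefore an
interpretable quantity: the most-moving atom travels exactly 0.5 Å each way.
This convention (not mass-weighted, not unit 3N-norm) is chosen because the
screening thresholds and the amplitude are coupled — the 0.4 Å bond
threshold is meaningful *at* this amplitude — and both are exposed together.
Users matching another code's convention can rescale accordingly.

**Internal coordinates.** Bonds are the TS graph's edges, optionally unioned
with reactant/product graph edges (so a forming bond missed even by the
scaled TS graph still gets a coordinate); angles are all neighbor pairs at
atoms of degree ≥ 2 (metal centers with many neighbors are enumerated
exhaustively — downstream thresholds control the noise); dihedrals are all
chains about each bond. Near-linear angles get no special auxiliary
treatment: this package reports *changes*, it does not optimize geometry.
"Nonredundant" means deduplicated under canonical orientation, nothing more.
Dihedrals use the standard signed atan2 construction (right-hand rule about
the central axis, range (−180°, 180°]), and dihedral differences are minimal
circular differences, so 170° → −170° is +20°.

**Screening.** Changes are flagged at 0.4 Å (bonds), 10° (angles), 20°
(dihedrals). If — and only if — nothing at all is flagged, one retry is made
at 50% of every threshold (`provenance = "fallback"`); this accommodates
low-magnitude modes such as hindered rotations, where the Cartesian
displacement is genuinely small. The fallback is global, not per-kind: a
flagged bond means angle/dihedral screening stays at the primary tier.
Proton transfer is often strongly asymmetric along the mode, so every flagged
hydrogen bond-breaking event looks for a partner bond of the same hydrogen
moving oppositely past a secondary threshold of 0.5 × 0.4 Å = 0.2 Å (the 0.5
mirroring the printed 50% fallback reduction); the best partner is added as
the paired formation (`provenance = "proton_pairing"`) unless it is already
bonded to that hydrogen in the TS graph, which would double-count.

**Filtering.** Angles and dihedrals touching any atom of a flagged bond
change are removed — they are geometric consequences of the bond event, not
independent motion. Dihedrals sharing a rotational axis are reduced to one
representative, the one with the heaviest terminal atoms (ties: heavier
single terminal, then lowest indices), so one hindered rotation is reported
once.

**Classification.** Bond events give `bond_change`; dihedral-only survivors
give `rotation`; pyramidal inversion is detected directly from the two
frames at any 3-coordinate center free of bond events, when the sum of its
three bond angles crosses (or touches) 354° (360° = planar) *or* its signed
out-of-plane angle changes sign with a swing beyond the dihedral threshold.
The out-of-plane test is essential: a symmetric umbrella mode produces
mirror-image frames whose bond lengths and angles are pairwise equal, so no
thresholded bond/angle/dihedral survives — only the sign flip witnesses the
inversion. Inversion events are recorded with coordinate kind `"improper"`
(the center plus its three neighbors), a deliberate extension of the
bond/angle/dihedral triad documented in the report schema. Mixed outcomes
(bond events plus surviving rotations/inversions) give `mixed`; the rare
angle-only outcome is also mapped to `mixed` since the classification
vocabulary has no angle-only label; an empty list gives `none`.

**Trajectories.** For IRC/QRC input the two compared frames are either the
endpoints or the maximum Kabsch-RMSD pair (all atoms, optimal superposition,
so rigid drift between frames never masquerades as shape change). The graph
is built — with TS scaling — at the frame nearest the arc-length midpoint
(IRC files may or may not start at the TS; the midpoint is the natural
saddle proxy), and the internal-coordinate set is augmented with the
endpoint graphs.

## The synthetic fixtures

The package generates all of its own test inputs; no external data is
required. Three model transition states cover the archetypal mode classes:

* **SN2** — trigonal-planar CH₃ with collinear axial Cl at 2.3 Å (elongated:
  present only under TS threshold scaling) and incoming F at 2.0 Å; the mode
  carries carbon along the axis with counter-motion of Cl and F. Reference:
  C–Cl break + C–F form (2 events).
* **Pyramidal inversion** — planar NH₃ with the nitrogen umbrella mode.
  Reference: inversion at N (1 event).
* **Hindered rotation** — eclipsed F–H₂C–CH₂–F with a torsional mode about
  the C–C axis. Reference: F–C–C–F rotation (1 event); the H dihedrals about
  the same axis change identically and are removed by the axis
  deduplication.

A pure rigid counter-torsion normalized to 0.5 Å at the fluorines would
change the F–C–C–F dihedral by >80°, leaving nothing for the reduced-tier
behavior to act on. Real low-frequency torsions are rarely that clean: their
displacement fields commonly mix with overall rigid rotation. The rotation
fixture therefore rotates both ends in the same sense with unequal weights
(1 : 0.27) — a torsion superposed on a rigid rotation — fixed once so that
the default amplitude changes the dihedral by ≈30° (primary tier) and a
0.4× amplitude by ≈12.6°, inside the 50% fallback window. Fixture geometry
parameters (bond lengths, axial distances, mode weights) are package design
choices frozen in the fixture source, not measured values.

A ten-molecule equilibrium library (water, methane, ethane, ethene, ethyne,
benzene, ammonia, methanol, CO₂, octahedral Cr(CO)₆) with textbook
geometries and known Lewis graphs serves as the graph-perception oracle;
for molecules with ≤ 8 adjustable bonds the test suite additionally checks
the optimized orders against exhaustive enumeration of all order patterns.
`make_path()` interpolates reverse → TS → forward trajectories, optionally
applying a seeded random rigid motion per frame to exercise the Kabsch
alignment.

What the fixtures do *not* emulate: anharmonicity, mode mixing beyond rigid
contamination, asynchronous multi-bond events, solvent/counterion contacts,
and the breadth of real vibrational spectra. Passing the suite shows the
pipeline's logic is correct under controlled conditions; accuracy on real
TS ensembles depends additionally on the quality of the underlying quantum
chemistry and is inherently limited by the single-vector nature of
normal-mode displacement (strongly asynchronous bond changes displace little
at the saddle point and can be missed at conservative thresholds — a
deliberate precision-over-recall choice).

## Numerical choices and degenerate inputs

* Connectivity candidates are processed in ascending distance order, so
  short (more certain) bonds anchor the angle and ring validation of longer
  ones. Perception never fails: pathological geometries yield sparse graphs,
  not errors.
* Angles with coincident points and dihedrals with collinear backbones raise
  explicit undefined-geometry errors; near-linear angles (> 175°) are kept
  and simply screened like any other.
* All orderings (change lists, tie-breaks, beam states) are deterministic;
  identical inputs and configuration produce byte-identical JSON reports.
* Kabsch RMSD uses the SVD construction with determinant correction, so only
  proper rotations are fitted; a mirrored copy does not compare as
  identical.
* Problem sizes throughout the tests and the acceptance script are small by
  construction (≤ 13 atoms, ≤ 28 internal coordinates, ≤ 11-frame paths):
  these are the scales at which every expected value can be verified by
  independent enumeration, brute force or closed form.

## Known limitations

* The factor table and radii are a documented stand-in for whatever
  parameterization a given production code uses; they are configurable via
  `graph_config()`.
* Formal charges are bookkeeping consistent with the penalty ordering and
  the total-charge invariant, not electronic-structure populations.
* η"-type multicenter coordination is perceived as plain metal–ligand edges;
  no multicenter bond object exists.
* Stereochemistry, 3D structure generation and any quantum-chemical
  computation (Hessians, IRC following, optimization of displaced
  structures) are out of scope; displaced pairs are written as XYZ precisely
  so external codes can take over.
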