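# tsmode

Graph-based internal-coordinate characterization of transition-state modes.

`tsmode` is for computational chemists who need to know, quickly and
programmatically, *what a transition state actually does*: which bonds form
or break, what rotates, what inverts. A TS is a first-order saddle point
whose single imaginary mode locally approximates the reaction coordinate,
but quantum-chemistry codes express that mode as Cartesian displacements,
which carry no chemistry by themselves. Formal interpretation via IRC or QRC
calculations costs hours to days per structure; `tsmode` gives a chemically
valid answer in milliseconds, with no prior knowledge of reactant or
product — suitable both for interactive mechanistic work and for
high-throughput TS validation loops.

## What it does

1. **Molecular graph perception from raw Cartesians.** Two-pass
   distance screening against per-bond-class fractions (0.38–0.7) of summed
   van der Waals radii, with geometric validation (acute-angle and
   ring-diagonal checks) of borderline candidates. For TS geometries every
   threshold is extended by 1.4× in a second, add-only pass so elongated
   partially formed/broken bonds are captured. Bond orders and formal
   charges come from a beam search minimizing a valence-charge penalty
   Σ(4·valence_deviation + |q|), with Kekulé seeding and aromatic (1.5)
   rewriting for rings, and metal–ligand orders fixed at one.
2. **Internal coordinates from graph topology.** Bonds, angles and
   dihedrals enumerated from the edges (optionally augmented with
   reactant/product graphs), evaluated on Cartesian frames.
3. **Mode analysis.** The geometry is displaced ±0.5 Å (max-moving atom)
   along the normalized imaginary mode; forward−reverse changes are screened
   at 0.4 Å / 10° / 20° with a single 50%-reduced fallback tier for
   low-magnitude modes and a secondary 0.2 Å pairing threshold for proton
   transfers. Angles/dihedrals coupled to bond events are filtered out;
   equivalent dihedrals on one axis collapse to the heaviest-terminal
   representative; pyramidal inversion is detected from angle-sum planarity
   crossing or out-of-plane sign flip at 3-coordinate centers.
4. **Structured output.** A versioned JSON report of every change (atoms,
   signed delta, classification, provenance), the mode class, the perceived
   graphs and diagnostics such as additional imaginary frequencies. IRC/QRC
   trajectories are analyzed with the same pipeline via Kabsch-RMSD frame
   selection.

## Worked example

The package generates its own model systems. The SN2 model is a
trigonal-planar CH₃ with an elongated axial C–Cl (2.3 Å) and an incoming F
(2.0 Å), plus a synthetic imaginary mode at −500 cm⁻¹ along the axis:

```r
library(tsmode)

fx  <- make_model_ts("sn2")
rep <- analyze_ts(fx$geometry, fx$modes, total_charge = -1)
rep
#> <ts_report> mode class: bond_change
#>   imaginary mode: -500 cm^-1
#> # A tibble: 2 × 5
#>   kind  coordinate delta classification provenance
#>   <chr> <chr>      <dbl> <chr>          <chr>
#> 1 bond  C0-F5       -1.3 bond_form      primary
#> 2 bond  C0-Cl4       1.2 bond_break     primary
```

Reading: between the reverse- and forward-displaced structures the C–F
distance shortens by 1.3 Å (bond formation) and the C–Cl distance grows by
1.2 Å (bond cleavage); both pass the 0.4 Å screen at the primary tier, no
angle or dihedral change survives correlation filtering, and the mode is
classified as a concerted `bond_change` — exactly the two reference events
for an SN2 saddle point. `glance(rep)` gives the one-row summary,
`autoplot(rep)` the change plot, and `write_report(rep, "sn2.json")` the
machine-readable document.

Graph perception alone:

```r
g <- perceive_graph(make_equilibrium_molecule("benzene")$geometry)
glance(g)
#> # A tibble: 1 × 6
#>   n_atoms n_bonds total_charge n_aromatic n_dative converged
#>     <int>   <int>        <int>      <int>    <int> <lgl>
#> 1      12      12            0          6        0 TRUE
```

From the shell (the same pipeline; exit code 0 = classified TS, 2 = no
imaginary frequency, 3 = parse error):

```sh
tsmode fixtures sn2 --prefix /tmp/sn2
tsmode analyze /tmp/sn2.xyz --modes /tmp/sn2.modes --charge -1 --json sn2.json
tsmode traj path.xyz --strategy max_rmsd --json traj.json
```

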