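---
title: "Methods: shells, hydrogen-bond generations and protein-referenced mobility in amorphous solid dispersions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shells, hydrogen-bond generations and protein-referenced mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdtraj)
```

## Scope and model

`asdtraj` analyses periodic molecular trajectories of amorphous solid
dispersions in which a protein excipient stabilizes a small-molecule drug.
The package answers three linked questions about such systems: where the
drug sits relative to the protein surface (shell structure), how the
hydrogen-bond network is organised (generations rooted at the protein),
and how mobile each drug molecule is in the protein's own reference frame
(diffusivity). It does **not** run molecular dynamics; inputs are
text-format trajectories (GRO series or an extended-XYZ dialect) plus a
topology sidecar, and a Brownian-dynamics generator supplies synthetic
trajectories with planted ground truth for verification.

All internal units are nm, ps and Da. Diffusivities are reported in
10⁻⁹ cm²/s; the conversion constant is derived analytically:
1 nm²/ps = 10⁻¹⁴ cm² / 10⁻¹² s = 10⁻² cm²/s, so a fitted MSD slope
`s` in nm²/ps gives `D = s/6 × 10⁷` in units of 10⁻⁹ cm²/s. (A tempting
mental shortcut of "10⁻⁵" per nm²/ps is wrong by five orders of
magnitude; the unit test `test-mobility.R` pins the constant.)

Boxes are orthorhombic only. Minimum-image distances use the standard
`d − L·round(d/L)` reduction per axis and are verified against an
explicit 27-image enumeration.

## Hydrogen bonds

A triple donor–H···acceptor is a hydrogen bond in a frame iff the
minimum-image donor–acceptor distance is ≤ `d_cut` (default 0.35 nm) and
an angular condition holds. The angular convention is genuinely ambiguous
in common tooling, so both are implemented and the choice is a parameter:

* `vertex = "donor"` (default): the H–D–A angle at the donor ≤ 30°,
  matching the GROMACS-style default;
* `vertex = "hydrogen"`: the D–H–A angle at the hydrogen ≥ 150°, the
  supplementary reading of the same 30° cutoff.

Bond identity across frames is the **atom triple**, not the molecule
pair: a molecule with two donors can hold two simultaneous bonds to the
same partner; molecule-level views are projections. Occupancy is the row
mean of the boolean existence matrix over the analysis window only.
Stability is strict: protein–drug bonds must exceed 0.80 occupancy,
drug–drug and protein–protein (and water-involved) bonds 0.50 — an
occupancy of exactly 0.80 is *not* stable. Equality cases matter when
occupancies are exact multiples of 1/n_frames, which the synthetic
generator produces deliberately.

Generations are BFS depths on the molecule graph whose edges are stable
bonds, sourced at every protein molecule: generation 1 is drug bonded
directly to protein, generation g is drug whose shortest stable-bond path
to any protein has length g, unreachable molecules get none (`NA`).
Water-involved bonds are recorded but excluded from generation tracing by
default; `include_water = TRUE` lets water act as a bridge node (it never
receives a generation itself).

Per-residue ranking aggregates protein–drug bonds by the protein-side
residue label, weighting each triple by its occupancy by default
(`weighted = FALSE` counts unique triples); residues holding more than
10% of the total are flagged "major", and output is alphabetical.

## Shells and layers

Two reference points are computed per drug molecule and frame:
`min_dist_com` (minimum over protein atoms of the distance to the drug
centre of mass) and `min_dist_atom` (minimum over protein-atom ×
drug-atom pairs). Distance histograms use `min_dist_com`; the
first-drug-shell contact flag (`min_dist_atom ≤ 0.4 nm`) and the 0.4 nm
shell index (`floor(min_dist_atom / 0.4)`) use `min_dist_atom`, because
"contact" is an atom-level notion while the histogram follows the
centre-of-mass convention. Both columns are always emitted so either
convention can be recomputed.

Second-layer membership (drug in contact only with other drug) is decided
per molecule from the **window median** of `min_dist_atom`: the median is
robust to transient excursions, and the package makes no claim about
instantaneous layer membership. Histogram bins are half-open
`[k·w, (k+1)·w)`.

The radial distribution function is the standard pair-correlation
estimator: minimum-image pair distances binned and normalized per frame
by `n_A n_B V_shell / V_box`, with self-pairs removed when selections
overlap; `r_max` must stay below half the smallest box edge.

## Mobility

Protein-motion subtraction is **translation-only**: per frame, the
displacement of the joint protein centre of mass relative to the window's
first frame is subtracted from all coordinates. A rotational
least-squares fit was rejected because systems of interest contain 4–8
separate protein molecules, for which a single rigid-body rotation is
ill-defined; translation subtraction leaves all intra-frame distances
untouched, which the tests assert exactly.

MSD is the time-origin-averaged squared COM displacement over all valid
origins. The diffusivity fit is ordinary least squares on
`MSD(τ) ≈ a + 6Dτ` over a lag window expressed as fractions of the
analysis window, default **1–10%**. This default deserves justification,
because 10–50% is a common habit: the variance of a time-averaged MSD
grows roughly linearly with lag/window, and at the package's stated world
(50 molecules, 2000 frames, 10 ps spacing) the ensemble-mean fitted D has
a standard deviation of ~6.4% under a 10–50% fit but ~3.2% under a 1–10%
fit, with no detectable bias in either (measured over 10 seeds). Only the
short-lag window gives the 10% recovery tolerance a comfortable ~3σ
margin. The usual reason to avoid short lags — ballistic contamination —
does not apply at ≥ ps frame spacing in dense amorphous media, where
momentum relaxes in under a picosecond. Windows too short to contain two
lag points fall back to the two smallest positive lags in
`diffusivity_records()` (a direct `fit_diffusivity()` call with a
degenerate window still errors). Negative fitted slopes, a
finite-sampling artifact for near-frozen molecules, are clipped to zero
and flagged.

Group statistics support the three canonical series — all molecules,
excluding generation-1/2 protein-bonded molecules, excluding every
molecule hydrogen-bonded more than half the time — crossed with the shell
index, which is taken at the window's first frame (molecules change
shells; groups are deliberately "overlapping" and the label is a
snapshot). The cumulative contribution curve sorts molecules by D
ascending and plots cumulative ΣD / total ΣD against the molecule
quantile; the reported crossing level defaults to 90% of the total.
(The source figure caption reads "0.9%" where the text reads "90%"; the
package implements the 90% reading.) Displacement classes are maximum
displacements from the window-start position, in Å, classified against
1/5/10 Å limits at molecule (COM) or atom level.

## The synthetic generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical structure the analyses assume, nothing more:

* **Rigid bodies.** Molecules have no internal dynamics; every analysis
  here operates on COMs, atom positions and bond geometry. Free molecules
  translate without rotating: the per-step displacement is Gaussian with
  variance 2·D·dt per axis, which constrains translation only, and no
  downstream statistic depends on free-molecule orientation.
* **Drug template.** Six heavy sites on a planar hexagon (ring radius
  0.31 nm) plus one polar hydrogen: exactly 1 donor, 4 acceptors,
  1 neutral site, ~381 Da, minor-axis radius of gyration ≈ 0.22 nm —
  the footprint of a small aromatic drug like indomethacin.
* **Pseudo-protein.** A rigid quasi-spherical shell (Fibonacci
  arrangement) of acceptor sites, a seeded half of which also donate,
  each labeled from a residue palette — enough surface structure for
  contact, shell and residue-ranking analyses.
* **Tethers.** A fraction of drugs follow an overdamped harmonic
  (Ornstein–Uhlenbeck) walk around a surface site. Default
  `tether_k = 10⁵ kJ/mol/nm²`, a hydrogen-bond-like restraint: its
  relaxation time k_BT/(D·k) ≈ 250 ps is far inside the default 20 ns
  window, so tethered molecules genuinely sample their plateau and their
  fitted D collapses well below the free value. (With 10⁴ the relaxation
  time is ~2.5 ns and the contrast is marginal — the reason this default
  is stiff.)
* **Hydrogen-bond schedules.** Planted occupancies must be *exact* for
  threshold tests at the 0.80/0.50 boundaries, so scheduled bonds are
  imposed geometrically: the drug is placed with its donor 0.30 nm from
  the chosen acceptor, collinear, in exactly `round(occupancy·n_frames)`
  frames (a seeded deterministic mask) and pushed to 0.55 nm otherwise.
  Steered molecules are therefore *not* simultaneously Brownian; their
  ground-truth D is `NA`.
* **Stated world.** Defaults: 6 nm cubic box, 2000 frames at 10 ps
  (a 20 ns analysis window), drug D = 0.5 × 10⁻⁹ cm²/s — the magnitude
  separating "mobile" from "stabilized" drug in these systems. The frame
  stride is a free parameter (the source analyses never state theirs);
  10 ps makes the window/stride ratio large enough for clean MSD
  statistics.

What the generator does **not** emulate: force-field energetics,
annealing protocols, emergent hydrogen-bond kinetics, water chemistry
beyond donor/acceptor geometry, molecular flexibility. A green test
therefore establishes that the *analysis* is correct on data with known
structure — not that any particular physical system behaves this way.

Two scripted fixtures exist for specific signatures: a **two-layer
fixture** (first-shell drugs at 0.15–0.30 nm atom separation, tangent
ring orientation so COM distances track atom distances; second-layer
drugs at 0.5–0.9 nm) whose planted second-layer fraction is recovered
exactly and whose COM histogram is bimodal; and a **chain fixture**
(protein → d1 → d2 → … with permanent collinear bonds 0.30 nm apart)
that pins generation tracing.

## Composition planning

Counts come from the mass balance
`n_drug = round(f_drug/f_protein · n_protein · M_protein / M_drug)`
(half-away-from-zero), water analogously; achieved fractions are then
recomputed from the integer counts and reported alongside the targets,
because integer rounding makes exact target fractions unattainable — the
error is bounded by one molecule's mass share, and the tests assert that
bound. Published molecule-count tables for such systems are not always
consistent with their stated molar masses, so the package treats printed
fractions as targets and never hard-codes counts. For pure-drug systems
(no protein) the mass scale is taken from `mass_scale` (default: four
protein masses). Defaults: drug 381.37 Da, protein 18 300 Da
(an 18.3 kDa, 162-residue whey protein), water 18.015 Da. The reference
grid is 8 dry compositions (13–100% drug) plus 7 humid ones (5% water
throughout), with 8 protein copies below 40% drug loading and 4 above —
low-loading boxes need more copies so each protein stays screened from
its periodic images.

## Numerical choices and degenerate inputs

* Molecule wholeness under PBC is repaired by nearest-image chaining in
  atom order; exact half-box ties resolve toward the negative image.
  Trajectory-level unwrapping anchors each molecule to its first atom
  within a frame (equivalent to chaining whenever the molecule diameter
  is below half the box edge, where whole-molecule reconstruction is
  unique) and enforces COM continuity across frames.
* Detection tolerances: the angular test admits a 10⁻¹² slack on the
  cosine so exactly-collinear planted geometries are never lost to
  rounding; the distance test is exact.
* Empty inputs are contracts, not errors: an empty drug set yields an
  empty shell table and histogram, an all-zero existence matrix yields an
  empty stable set, empty diffusivity groups report `n = 0` with an `NA`
  mean.
* GRO positions round-trip at the format's 3-decimal precision;
  extended-XYZ at `%.9g`. Parse errors name the offending frame and
  line.
* Everything that consumes randomness takes an explicit seed and restores
  the caller's RNG state.

## Known limitations

Orthorhombic boxes only (no triclinic); no binary trajectory formats
(XTC/TRR/DCD — convert to GRO/extended-XYZ first); no velocities, forces
or energies; no hydrogen-bond lifetime autocorrelation (occupancy
fractions only); translation-only protein reference frame; the generator
does not model emergent bonding kinetics, so occupancy dynamics (as
opposed to occupancy fractions) should not be validated against it.
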