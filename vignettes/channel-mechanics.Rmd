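---
title: "Mechanics of twist-driven channel gating: models and methods"
author: "ChannelMech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of twist-driven channel gating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChannelMech)
```

# The scientific problem

Tethered mechanosensitive TRP-family channels such as NOMPC carry a
spring made of 29 ankyrin repeats (AR) per subunit. A mechanical
stimulus — compression of the spring or a push from the intracellular
side — must be converted into the conformational change that opens the
transmembrane pore. The mechanistic questions this package addresses
are: *where* do forces flow (which residue pairs carry them), *what* is
the decomposition of those forces at the gating interface
(membrane-parallel torsion versus membrane-normal push), and *how stiff*
is the AR spring against twist and how strongly are twist and
compression coupled.

ChannelMech implements the complete downstream analysis at desk scale.
No molecular dynamics is performed: the package evaluates forces and
geometry on frames that are supplied (or generated), which keeps every
stage testable against exact oracles.

# Force model

## Pairwise force distribution

For every atom pair the engine evaluates, per frame:

* **Coulomb**: $U = k_e q_i q_j / r$ with
  $k_e = 138.935458\ \mathrm{kJ\,mol^{-1}\,nm\,e^{-2}}$;
* **Lennard-Jones**: $U = 4\varepsilon[(\sigma/r)^{12}-(\sigma/r)^6]$
  with Lorentz–Berthelot combination;
* **bonded**: harmonic bonds $\tfrac{k}{2}(r-r_0)^2$, harmonic angles
  $\tfrac{k}{2}(\theta-\theta_0)^2$, periodic dihedrals
  $k[1+\cos(n\phi-\phi_s)]$.

Nonbonded interactions are damped by the potential-switching polynomial
$S(r) = (r_c^2-r^2)^2(r_c^2+2r^2-3r_1^2)/(r_c^2-r_1^2)^3$ on
$[r_1, r_c]$ and the force is the exact derivative $-\mathrm{d}(US)/
\mathrm{d}r$: below the switch-on radius it equals the plain force,
beyond the cutoff it is exactly zero, and it is continuous in between.
Defaults $r_1 = 1.0$ nm, $r_c = 1.2$ nm (the common 10–12 Å switching
window). Both radii are parameters of `InteractionParameters`.
Reciprocal-space (PME) electrostatics have no pairwise attribution and
are deliberately outside this model; the pairwise tables contain the
short-range switched terms only. This is a known deviation shared by
pairwise force-attribution methods generally.

Exclusions follow the usual bonded-neighbour convention: 1-2 and 1-3
pairs excluded from nonbonded terms, 1-4 included (optionally scaled by
`scale14`); the policy is configurable because force fields differ.

Angle and dihedral terms involve three or four atoms; their forces are
re-expressed as central forces along the participating atom pairs. A
term with zero net force and zero net torque admits such a
decomposition exactly (3 pair scalars for an angle, 6 for a dihedral);
the package solves the corresponding linear system per term and the
test suite asserts that re-summing pair contributions reproduces each
atom's analytic force to numerical zero. Degenerate geometries
(collinear angles at equilibrium, coplanar dihedrals) fall back to a
minimum-norm solution; exactly collinear angle arms produce zero force,
which is exact at equilibrium and the stable convention off it.

Atomic pair forces are summed over the atoms of each residue pair and
stored per interaction class and per frame, with the convention that
the stored vector is the force on the first residue of the
canonically-ordered pair. Residue-level antisymmetry is therefore
structural, and the sum of a residue's pairwise entries equals its
total force (intra-residue central contributions cancel identically) —
that identity is what the brute-force oracle tests exploit.

## Net force fields

The condition-difference field subtracts the time-averaged pairwise
forces of force-free replicates from forced replicates,

$$\bar F^{net}_{r_i r_j} = \tfrac{1}{2}\big(\bar F^{A_1} + \bar F^{A_2}
- \bar F^{B_1} - \bar F^{B_2}\big),$$

with replicates weighted equally regardless of frame counts (a
frame-weighted option exists but is off by default, since the
equal-weight form is the definition of the two-replicate difference).
Per-class vectors are symmetrised first and summed afterwards where a
class-summed readout is requested; the correlation analysis consumes
the non-bonded classes only.

For a C4 tetramer the four subunits are statistically equivalent:
`symmetrizeC4` rotates every entry into the reference-chain frame
(by −90°·k about the pore axis for the chain at cycle position k),
averages the four images, and emits the exactly symmetric table. Making
the output the full symmetric table (not only the reference chain)
keeps the operation idempotent. Residue equivalence across chains is by
identical author residue id, the convention of identical-sequence
homotetramers.

The display filter removes pairs whose class-summed magnitude is below
a pN threshold (strict `<`; 5 pN is the conventional cut), using
$1\ \mathrm{kJ\,mol^{-1}\,nm^{-1}} = 1.66054$ pN, stored in one place.
Filtering and domain aggregation do not commute except at threshold 0;
the tests assert the inequality.

# Mechanics of the AR spring

The twist readout follows the closed-form least-squares rotation angle
about a fixed axis: with in-plane components $a_i$ (reference) and
$b_i$ (current), $\hat\phi = \operatorname{atan2}(\sum (a_i \times
b_i)\cdot\hat u, \sum a_i\cdot b_i)$, unwrapped across frames. Bundle
length is the distance between mass-unweighted centroids of the two end
groups (the linker-helices domain and AR8); "centroid" is taken
literally, a mass-weighted option being a trivial extension.

Two constants characterise the spring:

* the **torsion coefficient** $c$ of $M = c\,\phi$, fitted by
  origin-constrained least squares — the linear torsion law has no
  intercept, so none is estimated by default (an intercept option
  exists for diagnostics);
* the **compression–twist coupling** $k_{ct}$ of
  $L = L_0 - k_{ct}\,\phi$, fitted with an intercept; $k_{ct}$ is
  positive when the bundle shortens under twist and the fit is flagged
  extension-coupled otherwise.

Sign conventions are global and single: the membrane normal $+z$ points
extracellular; positive rotation and torque about $+z$ (right-hand
rule) appear clockwise when viewed from the intracellular side. A force
set with positive torque therefore drives increasing $\phi$ — asserted
as a property test.

# Hydrogen bonds and force correlation

H-bonds are detected geometrically: donor–acceptor distance ≤ 0.35 nm
and hydrogen–donor–acceptor angle ≤ 30°, the common trajectory-analysis
defaults; the published occupancies do not state their criteria, so
both cutoffs are parameters and are recorded with the output. Occupancy
of a residue pair is the fraction of frames with at least one bond in
either donation direction.

The correlation analysis divides the occupancy matrix and the
non-bonded net-force magnitude matrix (same residue range) into
unit-pair blocks — for a 737-residue AR9–AR29 range grouped by AR unit,
a 21×21 grid — and computes the Pearson correlation over each block's
vectorised entries, excluding residue self-pairs. Blocks with fewer
than `minPairs` entries or zero variance are flagged undefined rather
than forced to a number. `groupedPCC` applies no force filtering
itself: any weak-interaction cut is an explicit upstream step, so the
filter's effect is visible in the workflow rather than hidden in the
statistic.

# Structure metrics

Superposition is the standard Kabsch solution (SVD with a proper
rotation determinant). Helix axes are estimated as the principal axis
of sliding four-residue centres of the Cα trace: raw-PCA axes of short
helices carry a phase bias of 1–2° because the axial coordinate
correlates with the helical phase; the centre track removes nearly all
of it. Axes are oriented N→C.

Rotation/tilt of the TRP helix between two gating states: state 2 is
superposed onto state 1 via the shared S1–S4 scaffold, the rotation is
the signed angle between in-plane projections of the two helix axes
(positive = clockwise from the intracellular side), and the tilt change
is the difference of the axes' elevation above the membrane plane,
"tilt-up" meaning the C-terminal end moving extracellular. The N→C
anchoring of the tilt sign is an interpretation choice that must
accompany any cross-channel comparison. Helix axes within 5° of the
membrane normal make the in-plane projection meaningless and raise a
degeneracy error instead of returning noise.

The pore profiler is a simplified HOLE-style slice method: for each
position along the axis the in-plane centre is optimised (Nelder–Mead,
warm-started from the previous slice) to maximise the accessible radius
$\min_i(\lVert p - x_i\rVert - R_i^{vdW})$ over atoms within an axial
neighbourhood, floored at zero; empty slices are flagged undefined
rather than zero. This replaces HOLE's Monte-Carlo sphere tracing with
a deterministic local search — accurate on cylindrical fixtures to
better than 0.01 nm (tested), self-contained, and adequate for gate
radius time series; it is not a bit-for-bit HOLE reimplementation. Van
der Waals radii default to a bundled Bondi-style element table and can
be overridden per atom via the structure's `vdw` column.

# Synthetic data: what it emulates and what it does not

Each generator plants a known truth and writes it to a manifest:

* `makeToySystem` — ≤100-atom chains with all interaction classes, the
  substrate for the brute-force force oracle;
* `makeNetForcePair` — paired forced/free per-frame force series (two
  replicates each) with i.i.d. Gaussian noise and a constant injected
  delta concentrated on two "TRP" residues;
* `makeTorsionTrajectory` — a bead-spring AR bundle (4 beads per unit,
  LH ring on top, AR1–8 rigidly rotated about z) whose window series
  follow $M = c\phi$ and $L = L_0 - k_{ct}\phi$ with per-sample noise;
* `makeChannel` — an exactly C4-symmetric four-chain channel with
  radial TRP helices;
* `makeHbondFrames` — donor/hydrogen/acceptor triplets whose geometry
  is valid in exactly `round(occupancy × nframes)` frames;
* `makePore` — atom rings whose accessible radius equals a prescribed
  profile analytically;
* `makeHelixPair` — two helix states over a rigid scaffold with known
  rotation/tilt, optionally under a random rigid-body motion.

Study conditions are fixed at the published operating point: twist
windows at 2.5°, 5°, 7.5°, 10°; torque and length sampled repeatedly
within each relaxation window (100 samples per window at desk scale,
standing in for the ~10⁵ samples a 200 ns window read every 2 ps would
give) with Gaussian noise scaled relative to signal (fractions of
max |M|, of the full length change, of coordinates); elastic truths
c = 2300 kJ mol⁻¹ rad⁻¹ and k_ct = 1.32 nm rad⁻¹; interface H-bond
occupancies 57/71/24%; a gate dilating through the 2 Å open-state
criterion. Passing tests demonstrate that the *analysis* recovers
planted truths under these noise models — they do not demonstrate
force-field realism, conformational sampling, entropic contributions
(absent from any pairwise force attribution), or membrane/solvent
effects, none of which the generators model.

# Numerical choices and edge cases

* Coordinates are nm everywhere inside the package; PDB I/O converts
  Å↔nm at the boundary. Residue numbering is taken verbatim from input
  (author numbering), and AR-unit/domain boundaries are a first-class
  text input (`readDomainMap`) because they are author knowledge, not
  derivable from coordinates.
* Empty selections, atom-count mismatches, non-monotone frame times,
  ragged tables, overlapping domain labels, donors without hydrogens,
  and degenerate fits all raise typed errors naming the offence;
  nothing degrades silently.
* The unit constant (1.66054 pN per kJ mol⁻¹ nm⁻¹) and the Coulomb
  constant live in one place each.
* Problem sizes in the tests (≤30-atom oracle systems, 100-seed
  recovery loops, 33-residue correlation blocks, 4-window fits) are the
  package's chosen desk-scale operating point: large enough for the
  stated statistical bounds, small enough to run interactively.

# Known limitations

* Short-range pairwise electrostatics only (no PME reciprocal space).
* No entropic force contributions — inherent to pairwise force
  attribution from mean interactions.
* The pore profiler's local search can in principle settle into a side
  pocket of a strongly non-convex slice; warm-starting along the axis
  makes this rare for channel-like geometries but it is not a global
  optimiser.
* Trajectory support is the package's plain whitespace format;
  binary trajectory formats should be converted upstream or read via
  specialised libraries and passed in as coordinate arrays.
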