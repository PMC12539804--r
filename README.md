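# ChannelMech

Desk-scale mechanics analysis for force-gated ion channels of the TRP
family — built around the question of how a mechanical stimulus delivered
to an intracellular ankyrin-repeat (AR) spring is converted into the
torque that rotates the TRP domain and opens the transmembrane pore.

The package is aimed at structural-bioinformatics users who have MD
frames (or deposited trajectory extracts) of a tetrameric channel and
want the downstream mechanics, not the simulation engine:

- **Force distribution analysis (FDA).** Residue-pairwise force vectors
  per interaction class — harmonic bonds/angles, periodic dihedrals,
  switched Coulomb and Lennard-Jones (switch 1.0 nm, cutoff 1.2 nm by
  default) — with multi-atom bonded terms decomposed exactly into central
  pair forces (`residuePairwiseForces`).
- **Net (condition-difference) force fields.** The time-averaged
  difference between forced and force-free conditions,
  F̄net = (A₁ + A₂ − B₁ − B₂)/2 for two replicates each (`netFDA`),
  four-fold rotational symmetrisation about the pore axis
  (`symmetrizeC4`), a weak-interaction display filter in pN
  (`thresholdFilter`, 1 kJ mol⁻¹ nm⁻¹ = 1.66054 pN), and domain-level
  aggregation (`aggregateDomains`).
- **Local-frame mechanics.** Per-subunit frames with z along the membrane
  normal (extracellular-positive) and x from the pore centre along the
  TRP helix (`buildLocalFrame`), membrane-parallel/normal decomposition
  (`decomposeForce`), and torque about the pore axis (`torqueAboutAxis`;
  positive = clockwise viewed from the intracellular side).
- **Elasticity of the AR spring.** Twist readout φ by the closed-form
  least-squares rotation angle (`rotationAngle`), bundle length L by
  centroid distance (`arLength`), and the two material constants:
  the torsion coefficient c from M = cφ (`fitTorsionCoefficient`,
  origin-constrained) and the compression–twist coupling k_ct from
  L = L₀ − k_ct·φ (`fitCompressionTwist`).
- **Hydrogen bonds vs force.** Geometric H-bond detection (D–A ≤ 0.35 nm,
  H–D–A ≤ 30° by default), occupancy matrices, non-bonded net-force
  magnitude matrices, and the grouped Pearson-correlation grid over
  AR-unit blocks with intra/inter-unit summaries (`groupedPCC`,
  `diagonalSummary`).
- **Structure metrics.** Kabsch superposition, helix axes, signed
  rotation/tilt change of the TRP helix between gating states after
  S1–S4 alignment (`rotationTiltAngles`), and a simplified HOLE-style
  pore-radius profile (`poreRadiusProfile`, `minRadiusSeries`).
- **Synthetic data.** Every stage has a seeded generator
  (`makeToySystem`, `makeNetForcePair`, `makeTorsionTrajectory`,
  `makeChannel`, `makeHbondFrames`, `makePore`, `makeHelixPair`) that
  records its planted truth in a manifest.

## Worked example

Generate a twist experiment on the bead-spring AR bundle (windows at
2.5°, 5°, 7.5°, 10°; 10% per-sample noise), measure the twist angle and
bundle length from the frames, and fit both elastic constants:

```r
library(ChannelMech)

tt  <- makeTorsionTrajectory(cTrue = 2300, kctTrue = 1.32,
                             noiseFracM = 0.10, noiseFracL = 0.10,
                             seed = 11)
phi <- rotationAngle(tt$frames, tt$groups$ar18)$phi_rad[-1]
L   <- arLength(tt$frames, tt$groups$lh, tt$groups$ar8)$L_nm[-1]

fitTorsionCoefficient(phi, tt$series$M)
#> ElasticityFit (torsion): c [kJ/mol/rad] = 2312 +/- 16.9, n = 4
fitCompressionTwist(phi, L)
#> ElasticityFit (compression-twist): k_ct [nm/rad] = 1.328 +/- 0.0158, n = 4
```

The torsion coefficient is the stiffness of the AR bundle against twist
(kJ mol⁻¹ rad⁻¹); k_ct says how many nm the bundle shortens per radian
of twist, i.e. how strongly compression and twist are geometrically
coupled — the property that lets a straight push produce a gating
torque.

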