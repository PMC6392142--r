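---
title: "Modelling the gas-phase collapse of flexible antibodies"
author: "abgas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the gas-phase collapse of flexible antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abgas)
```

## The problem

Native ion-mobility mass spectrometry (IM-MS) measures a rotationally
averaged collision cross section (CCS) for an intact protein ion. For
globular proteins the measured CCS agrees well with values computed from
solution structures. Antibodies do not behave this way: IgG molecules are
Y-shaped, with two Fab arms joined to an Fc stem by a flexible hinge, and
their measured CCS is roughly 30 % *smaller* than the CCS computed from
crystal-structure-derived models. The accepted interpretation is that the
flexible molecule collapses into a compact conformation during transfer
into the gas phase.

`abgas` implements an integrative workflow that models this collapse in
three stages and compares each stage against experiment:

1. **Initial model CCS.** The projection approximation (PA) applied to the
   input structure, scaled by the fixed convention CCS = PA x 1.14.
2. **Fab-arm sampling.** A rapidly-exploring random tree (RRT) over the
   backbone dihedrals of the *upper hinge* — the residues between each Fab
   domain and the most N-terminal inter-heavy-chain disulfide — produces a
   clash-free conformational ensemble. Its CCS range (`deltaCcs`) is a
   flexibility metric; its minimum is the most compact solution-accessible
   conformation.
3. **Charged vacuum collapse.** Selected compact conformers are charged to
   the lowest experimentally observed charge state and relaxed by
   coarse-grained Langevin dynamics in vacuum. The final CCS and the CCS
   range over the final window of the trajectory are compared with the
   IM-MS measurement.

The experimental side (charge-ladder mass inference, travelling-wave CCS
calibration, multi-wave-velocity averaging, banded model/experiment
comparison) is implemented in the `inferMass`, `twimsCalibrate`,
`applyCalibration`, `averageOverWaves` and `compareToExperiment`
functions. The packaged table `igGReference()` carries published IM-MS and
modelling observables for human IgG1-4 as workflow inputs.

## The projection approximation

The model CCS is the orientation-averaged area of the union of
atom-centred disks, each of radius (element radius + probe radius),
multiplied by exactly 1.14. Orientations are uniform random rotations
(quaternion sampling). Two per-orientation estimators share those
rotations:

* `monte_carlo` — uniform points in the projected bounding box (default
  40 000 points); the production estimator.
* `grid` — square-cell rasterisation (default 0.5 A; 0.2 A in oracle
  mode); slower, used as the numerical cross-check. At a fixed seed both
  estimators see identical rotations, so their agreement isolates the
  area-estimation error, which is well below 1 %.

A single-atom structure is handled in closed form (a disk of area
pi r^2 in every orientation), so the sphere benchmark is exact.

Defaults: H 1.2, C 1.7, N 1.55, O 1.52, S 1.8 A (a standard van der Waals
set), probe 1.0 A, 300 orientations (Monte-Carlo standard error well
below 1 % on antibody-sized structures). Coarse-grained bead elements are
part of the same table: `BB` (synthetic fixture bead) and `CG`
(one-bead-per-residue collapse bead, 3.8 A). All radii are configurable;
absolute CCS values for atomistic inputs therefore carry a few-percent
parameterisation uncertainty, which is why the package's tests emphasise
relative and arithmetic properties rather than absolute atomistic values.

## Hinge kinematics and RRT sampling

Only upper-hinge residues move, through their backbone phi/psi torsions;
side chains and all three rigid bodies (Fab1, Fab2, Fc plus core hinge)
are carried as rigid units. Setting a torsion rotates every atom on the
Fab side of the bond, so the Fc core never moves and rigid-body internal
geometry is preserved to machine precision (pure rotations).

The RRT grows from the input conformation. Each iteration draws a uniform
random target dihedral vector, finds the nearest tree node under the
wrapped-Euclidean metric (lowest index wins ties), extends toward the
target, and accepts the new node iff it passes the steric test. The
extension length is expressed **per torsion** (default 45 degrees per
torsion, i.e. an extension norm of `45 * sqrt(d)` for `d` torsions):
with a flat norm, per-joint exploration shrinks as hinges get longer and
ensembles of different hinge lengths are not comparable. Because targets
are uniform over the full torsion cube, large steps make accepted nodes
approach independent random hinge conformations — matching the intent of
randomly varied, energetically unweighted Fab conformations. Sampling
deliberately ignores the energy landscape; it maps reachable space.

The steric test declares a clash when any non-exempt pair is closer than
`clashFactor * (r_i + r_j)` (default 0.7, element radii without probe).
Pairs within one rigid body, within one residue, or in sequence-adjacent
residues are exempt (covalent neighbours). A spatial hash keeps the test
near-linear; an all-pairs oracle in the test suite confirms identical
verdicts.

Ensemble descriptors: `deltaCcs = max - min` of per-conformer CCS, the
per-arm Fab centroid clouds, and their shared-space statistic
`overlapFraction` — the fraction of conformers whose Fab centroid crosses
the bisector plane between the two clouds. A voxelised share of cloud
volume was considered and rejected: voxel-set ratios shrink as clouds
spread, so they are not comparable across ensembles of different
flexibility, whereas the crossing fraction directly encodes whether arms
stay in their own hemispheres. During sampling every conformer is scored at reduced
CCS settings (100 orientations, 5 000 points); selected conformers are
re-scored at full settings by the pipeline.

"Two low CCS models" beyond the global minimum are chosen by
diversity-constrained next-lowest picks: each further pick must exceed a
backbone RMSD of 5 A (in the shared Fc-fixed frame, so arm reorientation
counts) to all previous picks; the constraint is relaxed with a warning
if the ensemble cannot satisfy it.

## The coarse-grained vacuum collapse

All-atom, multi-nanosecond vacuum MD of a 150 kDa protein is outside the
scope of a desk-scale package, so the collapse stage is a deliberately
coarse model operating at the CCS level: one bead per residue (at CA, or
the residue centroid), harmonic chain bonds (rest length = initial
length), an elastic network inside each rigid body (cutoff 15 A, the
usual residue-level anisotropic-network range; force constant
50 kJ/mol/A^2), 12-6 Lennard-Jones attraction between all non-excluded
bead pairs, and unscreened Coulomb repulsion (dielectric 1) between the
placed charges. There is no solvent and no cutoff on the nonbonded terms:
the LJ tail is the compaction driver.

Parameter choices that matter:

* `ljSigma` (default 6.6 A) matches the fixture bead diameter, so contact
  pairs sit at the potential minimum. For CA-trace inputs a value near
  4.7 A is appropriate.
* `ljEpsilon` (default 80 kJ/mol) is a *per-bead-pair* effective
  cohesion. One bead stands for an entire residue, so the well depth
  aggregates many atomic vdW contacts; at the fixture's charge densities
  (about one charge per eight residues, far higher than one per sixty in
  a real IgG) the cohesion must balance a proportionally stronger Coulomb
  term. The value was fixed by two controls: a rigid single-domain
  cluster must keep its CCS within 2 %, and the standard charged fixture
  must collapse with a narrow final CCS window.
* `friction` (default 0.05 ps^-1). In vacuum there is no solvent drag;
  the Langevin term is only a weak thermostat coupling, and heavy
  friction would suppress the arm motion that lets the molecule find its
  compact state.
* `dt` 10 fs with BAOAB splitting; `temperature` 300 K; bead mass 110 Da
  (average residue). Non-finite coordinates abort with the step index.
* Before dynamics a short capped-displacement minimisation (100 steps,
  0.05 A per-coordinate cap) relaxes steric overlaps: compact conformers
  from the sampler may hold inter-domain contacts inside the LJ repulsive
  wall, and integrating from such contacts at 10 fs is unstable. The
  reported initial frame and CCS are always the unminimised input.

Charging follows the experiment: `netCharge` equals the lowest observed
charge state (21+ for IgG1-scale work). `surface_spread` places unit
charges on exposed sites (neighbour-count proxy for exposure) by greedy
farthest-point spreading — mimicking charge migration to exposed surfaces
under the charged-residue model; `basic_residues` restricts eligible
sites to Arg/Lys/His side-chain tips for atomistic inputs.

The trajectory records CCS every `reportStride` steps. "Final window"
statistics use the final 10 % of reported frames — the desk-scale
analogue of a final-nanosecond range on a short coarse trajectory.
Replicates (`replicateCollapse`) run one simulation per selected
conformer with distinct seeds and report the spread
`100 * (max - min) / mean` of final CCS.

## The synthetic antibody fixture

`makeSyntheticAntibody` builds a Y-shaped coarse antibody: two Fab bead
clusters and an Fc cluster (uniform lattice blobs, bead radius 3 A,
spacing 2.2 radii), two flexible upper-hinge linkers of N/CA/C
pseudo-residues at the 3.8 A CA-CA virtual bond spacing, and a
disulfide-zipped core hinge running down the stem axis — the most
N-terminal SG-SG pair bounds the flexible segment exactly as annotated
hinges do, and the number of core pairs mirrors subclass disulfide counts
(2/4/11/2 for IgG1-4). Upper-hinge lengths of 5/3/12/7 residues mimic
IgG1-4. Linkers rest in a zigzag (axial rise 2.6 A per residue), so a
resting hinge stores extension headroom proportional to its length, as a
non-extended peptide does.

What the fixture reproduces: the rigid-domain/flexible-hinge topology,
hinge-length-dependent reach and conformational range, detectable
disulfides, realistic overall dimensions at a reduced bead count. What it
does not: sequence chemistry, side chains, glycans, real mass
distribution, solvent history. Passing fixture tests therefore validates
the algorithms and their scaling behaviour, not absolute atomistic CCS
values, which additionally depend on the radii parameterisation.

Default problem sizes used by the test suite and the acceptance script
(chosen as the smallest sizes at which the studied contrasts are well
clear of Monte-Carlo noise): domains of 24-40 beads, ensembles of
500-1000 conformers, collapse runs of 60 000-100 000 steps (0.6-1 ns at
10 fs). The flexibility comparison holds the *total* hinge residue count
fixed (flexible + core = 14) while moving the first disulfide, so the
compared molecules are compositionally identical and only flexibility
varies.

## Experimental-side conventions

* Mass inference assigns consecutive charges to adjacent ladder peaks,
  `z = round((m2 - mp)/(m1 - m2))` with the proton mass mp = 1.00728 Da,
  and averages `z * (m/z - mp)`; per-peak masses disagreeing by more than
  0.1 % reject the ladder.
* TWIMS calibration corrects reference CCS by `sqrt(mu)/z` (reduced mass
  mu against the drift gas, default nitrogen 28.006 Da), subtracts a
  configurable dead time, and fits `CCS' = A t'^B` by least squares in
  log-log space. `applyCalibration` is its exact inverse, monotone for
  B > 0.
* Averaging over wave velocities uses the arithmetic mean and the sample
  (n - 1) standard deviation.
* `compareToExperiment` reports the relative difference against the
  experimental mean together with a within-band verdict (band default
  6 %, a typical TWIMS accuracy) and, separately, the model-denominator
  convention used when quoting how far an extended model overshoots.
* Stage reductions in reports are percentages relative to the preceding
  stage.

## Known limitations

* The collapse stage is a CCS-level stand-in, not an all-atom force
  field; its absolute final CCS values are meaningful for fixtures and
  for relative comparisons, not as atomistic predictions.
* PA underestimates CCS for very concave shapes; the fixed 1.14 factor
  is a convention, not a physical model of gas scattering.
* The RRT explores geometry, not thermodynamics: ensemble densities carry
  no Boltzmann weights.
* Calibration helpers assume single, well-separated charge-state peaks;
  no deconvolution of overlapping glycoforms is attempted.
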