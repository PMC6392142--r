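# abgas — gas-phase conformational modelling of IgG antibodies

Native ion-mobility mass spectrometry (IM-MS) reports a collision cross
section (CCS) for an intact protein ion. For Y-shaped, hinge-flexible
antibodies the measured CCS is roughly 30 % smaller than the CCS computed
from their solution structural models: the molecule collapses on its way
into the gas phase. `abgas` is an R package for structural mass
spectrometrists and modellers that predicts this collapsed gas-phase
conformation and compares model and experiment stage by stage.

The workflow:

1. **Initial model** — projection-approximation CCS of the input
   structure. The model CCS convention is `CCS = PA x 1.14`, where PA is
   the orientation-averaged projected area of the union of atom-centred
   disks (element van der Waals radius + 1 A probe), averaged over
   uniform random rotations.
2. **Fab-arm sampling** — a rapidly-exploring random tree over the
   backbone phi/psi torsions of the *upper hinge* (the residues between
   each Fab and the most N-terminal inter-heavy-chain disulfide) yields a
   clash-free conformational ensemble. The ensemble CCS range
   (delta-CCS) is a flexibility metric; its minimum is the most compact
   solution-accessible conformation.
3. **Charged vacuum collapse** — the lowest-CCS and further low-CCS
   conformers are charged to the lowest observed experimental charge
   state (greedy farthest-point spreading over exposed sites) and relaxed
   by coarse-grained Langevin dynamics in vacuum (one bead per residue;
   elastic-network domains; Lennard-Jones cohesion; unscreened Coulomb).
   The final CCS and the CCS range over the final 10 % of frames are
   compared against experiment with a ±6 % band.

Experimental-side utilities cover charge-ladder mass inference
(`inferMass`), travelling-wave IM calibration (`twimsCalibrate` /
`applyCalibration`, power law `CCS' = A t'^B` on reduced-mass/charge
corrected values), multi-wave-velocity averaging and banded comparisons.
A synthetic Y-shaped antibody generator (`makeSyntheticAntibody`) and
synthetic calibrant/charge-ladder generators make the whole pipeline
testable without any structure downloads; `igGReference()` returns
published IM-MS and modelling observables for human IgG1–4 used as
comparison inputs.

## Worked example

Run the full pipeline on a synthetic antibody fixture (five flexible
upper-hinge residues per arm, as in IgG1), charge state 21+:

```r
library(abgas)
cfg <- workflowConfig(
  fixture  = list(flexibleResiduesPerArm = 5L, linkerRise = 3.6, seed = 1L),
  ccs      = list(nOrientations = 150L, nPoints = 20000L, seed = 1L),
  sampler  = list(nSamples = 400L, seed = 301L),
  select   = list(k = 3L, diversityRmsd = 5),
  collapse = list(netCharge = 21L, nSteps = 60000L, reportStride = 4000L,
                  seeds = 302:304, ccsOrientations = 40L, ccsPoints = 4000L),
  experiment = list(mean = 2150, sd = 40))
runWorkflow(cfg)
#> StageReport
#>   initial model CCS               2676.0 A^2 (+/- 19.9)
#>   Fab-arm sampling CCS (min)      2276.8 A^2 (+/- 19.9)
#>   collapsed model CCS             2100.2 A^2 (+/- 10.2)
#>   reduction sampling               14.9 %
#>   reduction collapse                7.8 %
```

Reading the output: the extended fixture starts at 2676 Å²; hinge
sampling finds a compact conformation at 2277 Å² (−14.9 %); the three
selected conformers, charged 21+, relax in vacuum to a mean final CCS of
2100 Å² (a further −7.8 %), within the ±6 % band of the supplied
experimental value (the initial model, 24 % above it, is not). The
`collapsedReplicateN` rows of the comparison table show each replicate's
verdict individually.

The same stage arithmetic applied to the published IgG1 values
(initial 9532, sampled 8756, collapsed 7226, experimental 6827 Å²) gives
reductions of 8.1 % and 17.5 % and a final model 5.8 % above experiment:

```r
makeReport(initialCcs = 9532, sampledMinCcs = 8756, collapsedCcs = 7226,
           experiment = list(mean = 6827, sd = 81))
```

A thin command-line interface over the same functions is installed at
`inst/scripts/abgas.R` (subcommands `run`, `fixtures`, `ccs`, `sample`,
`collapse`, `mass`, `calibrate`, `compare`).

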