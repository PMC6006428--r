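---
title: "Methods: synthetic cryo-ET phantoms and systematic density fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cryo-ET phantoms and systematic density fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(npcfit)
```

npcfit rebuilds, at desk scale and with known ground truth, the
computational chain by which in situ cryo-electron tomography resolves
the scaffold architecture of the nuclear pore complex (NPC): particle
simulation with a missing wedge, wedge-weighted alignment and averaging
with imposed C8 symmetry, exhaustive rigid-body fitting of subcomplex
models with significance assessment, and the downstream copy-number,
difference-map, register and co-expression analyses.  This vignette is
the package's own account of the models, the parameters that matter,
and the choices made where the design was genuinely open.  Every
numerical statement here is recomputed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## Conventions

All physical quantities are in nanometres.  A `density_map` is a 3-D
array whose first/second/third index runs along x/y/z, with voxel
centres at `origin + voxel_size * (index - 1)`; volumes are written and
read as MRC2014 mode-2 files with the cell in Angstrom.  Rigid
transforms are `pose` objects: intrinsic ZYZ Euler angles in degrees
followed by a translation, applied as `x' = R x + t` about the grid
centre.  A single rotation convention is used by every module, which is
what keeps the register analysis and wedge bookkeeping consistent.
Resampling is trilinear: cheap, and adequate when the target resolution
(6–8 nm here) is several voxels wide.  Exact lattice rotations
(multiples of 90 degrees) are reproduced bitwise up to floating point.

## The phantom generator

The generator is the study-condition layer: its defaults *are* the
simulated experiment, and the tests interpret every downstream number
against its ground truth.

**Subunits.** Atomic models are replaced by weighted pseudo-atom bead
models; at 6–8 nm the shape envelope, not atomic detail, determines a
rigid fit.  The Y-complex stand-in is an elongated (~25 nm) chiral Y: a
stem with two unequal arms, the short arm lifted 35 degrees out of
plane.  A *planar* Y is nearly invariant under an in-plane flip once
rendered at 6 nm, which makes orientation recovery ambiguous; the
out-of-plane lift removes that degeneracy (measured: the best flipped
orientation correlates at ~0.51 against ~0.73 for the true one at a
30-degree search step).  The inner-ring protomer stand-in is a seeded
random bead cluster of ~11–13 nm extent, the scale of the real
protomer; smaller clusters leave too few envelope voxels to carry
statistical evidence (see *Significance*).  Head and tail beads on the
Y anchor the head-to-tail adjacency analysis.

**Architecture.** `crnpc_spec()` encodes the asymmetric outer-ring
layout: 8 Y copies in the cytoplasmic ring (CR, z = +24), 16 in the
nuclear ring (NR, z = -24) as a double ring — 8 outer copies at radius
42 in rotational register with the CR plus 8 inner copies at radius 25
staggered by half a symmetry unit — and an inner ring (IR) of 8 spokes
of 4 stacked protomers (radii 22/38, z = +/-7), 56 copies in all.  The
ring radii and heights were chosen once so that (i) the scaffold spans
~60 nm axially, (ii) head-to-tail neighbours touch, and (iii) distinct
copies remain separable at the 6 nm rendering resolution — sub-rings
closer than the subunit footprint would merge into unresolvable tori
and no fitting method could count them.  Copies sit tangentially
(local +y along the ring), so elongated models arrange head-to-tail.

**Rendering.** Each bead contributes an isotropic Gaussian whose FWHM
equals the stated resolution (combined in quadrature with the bead
radius); the map integral equals the summed bead weight.  The headline
experiment renders at 6 nm on 4 nm voxels, slightly below the 8 nm
Nyquist period; for Gaussian densities the aliased amplitude at Nyquist
is ~13% and measured artefacts are negligible, so the renderer only
requires `resolution >= voxel_size` rather than the strict Nyquist
bound.

**Corruption.** Single-axis tomography is modelled as a binary Fourier
mask: with tilts in (-60, 60) degrees about y, a coefficient is sampled
iff some tilted central section passes through it; one third of the
in-plane Fourier disc is missing.  Noise is white Gaussian added after
the wedge, scaled so the map-wide signal-to-noise variance ratio equals
the requested `snr`; the default experiment uses snr 1.  Particle poses
draw a uniform in-plane azimuth, small Gaussian out-of-plane tilts (sd
4 degrees) and shifts (sd 2 nm).  Phantoms carry no membrane, crowding
or CTF; passing tests therefore demonstrate correctness of the chain
under this noise model, not robustness to everything real tomograms
contain.

**Expression matrices.** Co-expressed modules share a latent
standard-normal sample profile: a member gene's log-scale signal is
`sqrt(rho) * latent + sqrt(1 - rho) * noise`, so the pairwise Pearson
correlation is `rho` by construction on the log scale, which is where
the analysis pipeline measures it after its `log2(x + 1)` entry step.
Values are exponentiated to a non-negative FPKM-like scale.  One
caveat the tests make explicit: quantile normalization over a *small*
gene panel couples genes through the coarse rank grid and attenuates
modest correlations; the pipeline is therefore exercised
transcriptome-style over several hundred genes, as it would be used.

## Structure determination

The averaging stage follows standard missing-wedge practice.  The
constrained cross-correlation of two volumes is the normalized Fourier
product restricted to the region sampled by *both* wedges (DC
excluded).  Alignment scans translations by the correlation theorem
and rotations on a grid; wedge descriptors rotate with their volumes.
Averages are wedge-compensated: aligned Fourier data are summed and
divided by the summed wedge coverage, floored at 10% of the mean
coverage so nearly-unsampled voxels cannot blow up.  C8 symmetry is
imposed by averaging the 8 in-plane rotations.

For the fitting experiments the particle average is seeded from a
randomized perturbation of the true poses (rotation sd 4 degrees,
shift sd 2 nm) standing in for the manual coarse-orientation step of a
real workflow — full ab initio alignment is out of scope — and refined
by one local constrained-CC pass (azimuth deltas composed with the
seed, so the seeded out-of-plane angles are retained).  Sixteen
particles at snr 1 are averaged by default; with 8-fold symmetrization
this yields a target map clean enough that envelope overlaps of true
placements concentrate near 1.

Asymmetric-unit extraction rotates each aligned particle to the 8
symmetry positions and crops a unit box at the ring mid-radius on +x;
78 particles yield exactly 624 units.  With a missing wedge the 8
units of one particle are *not* voxelwise equal — their wedge
orientations differ — which is precisely why the wedge descriptor is
rotated along with each unit; the constrained CC over the shared
Fourier region restores most of the agreement.

## Systematic fitting and significance

A fit of a model map at a pose is scored by two quantities computed
over the *model envelope* (voxels where the posed model exceeds an
isovalue): `cc`, the Pearson correlation between model and map, and
`overlap`, the fraction of envelope voxels where the map exceeds its
own envelope isovalue.  The combined score is `cc * overlap`, which
penalises high-correlation fits hanging outside the density.  The
model isovalue defaults to a quarter of the model's peak — a generous
footprint chosen so the correlation rests on enough voxels to carry
evidence — and the map isovalue encloses the expected molecular volume
(copies times the model envelope volume; the elongated Y gets a 50%
smearing allowance because its large-radius, tangentially overlapping
copies blur the most under residual alignment error).  Because
trilinear resampling lowers rotated maxima by up to ~25%, every posed
model is renormalised to its nominal peak before thresholding;
otherwise the evidence envelope would shrink orientation-dependently.

The exhaustive search evaluates every orientation of a quasi-uniform
SO(3) grid (Fibonacci sphere directions crossed with in-plane spins;
552 orientations at a 30-degree step) and every translation on a voxel
lattice, using the correlation theorem; the accelerated path equals
direct evaluation within 1e-5 on 16-cubed grids, and the tests hold it
to that.

**Significance.** Candidate placements are the translational local
maxima of the score field that touch the map envelope at all.  Under
the null hypothesis that no copy sits at a pose, the envelope
correlation of `n` independent noise voxels has the exact Fisher null:
`atanh(cc) * sqrt(n - 3)` is standard normal.  Each maximum receives
an upper-tail p-value from that null, Sidak-corrected for the average
number of grid fits it represents; maxima are then greedily clustered
(best first, absorbing everything within a translational tolerance of
half the model envelope diameter) and Benjamini–Hochberg q-values are
computed across cluster representatives, since dense grid fits are
massively dependent and clusters approximate independent hypotheses.
An empirical-bulk normal null (median/MAD of all sampled scores) was
implemented first and measured: it is anticonservative on pure noise —
the score field is a mixture over overlap levels whose bulk spread
underestimates the maxima tail — and insensitive on structured maps,
where partial ring matches inflate the bulk.  The parametric null
passes both checks that matter: on pure-noise maps the mean
significant-cluster rate over 20 seeds is below alpha = 0.05, and on
planted phantoms every copy is flagged.

**Acceptance.** Significant clusters are accepted greedily in score
order.  Each candidate is first snapped to its local score optimum (a
hill-climb over one-voxel translations and 5-degree rotations, which
collapses displaced duplicate representatives onto the same position),
then re-scored against the *current* working map, from which
previously accepted placements have been masked at a tight half-peak
footprint.  A placement is accepted only if its q-value passes alpha,
its re-scored envelope overlap reaches 0.6, and it retains at least
half of its original score; accepted placements closer than the
cluster tolerance to an earlier acceptance are rejected as double
counts.  The overlap gate is what discriminates the rigid double-Y
pair: searched in the single 8-copy ring its inner half lies over
empty channel (overlap ~0.5, rejected), while in the doubled 16-copy
ring both halves are supported.  The 0.6 threshold sits midway between
the ~0.5 of half-supported fits and the 0.7–1.0 of true copies under
wedge and noise.  Bridge fits between neighbouring copies pass the
initial significance test — they sit on real density — but collapse in
the re-score once their neighbours' density has been claimed, which is
the masking step of the hierarchical procedure doing its job.

Model hierarchies run largest model first, and each (model, ring
region) pair is searched in its own masked ring map with its own
envelope isovalue, mirroring per-ring refinement; a global threshold
would let the brighter ring set an isovalue that starves the dimmer
one.

## What the experiments measure

`fit_phantom_architecture(crnpc_spec(), seed = 42)` runs the whole
chain — 16 particles, averaging, per-ring fitting — and returns
per-region counts.  At the default conditions it reports exactly 8
cytoplasmic Y, 16 nuclear Y (24 in total) and 32 inner-ring protomers,
stable across the seeds exercised in the tests.  The difference-map
experiment subtracts two normalized outer-ring averages sharing 8
in-register copies; fitting the Y into the positive difference returns
exactly the 8 staggered inner copies.  The inner-ring-only phantom is
a deliberately harder case: with a quarter of the full phantom's
signal the particle average aligns less precisely, and junction optima
between stacked protomers occasionally displace one representative
which then trips the double-count guard; it recovers 30–31 of 32
copies at the seeds tested.  The asymmetric-unit bookkeeping (78
particles, 624 units) is exact by construction once alignment
succeeds.

Problem sizes were chosen to keep every experiment at desk scale: 32-
cubed grids at 4 nm voxels, 16-particle averages, 30-degree angular
sampling (552 orientations), which puts the full phantom experiment
at roughly two minutes and the entire test suite well inside a coffee
break on one core.

## Co-expression stage

Normalization applies, in inspectable stages, `log2(x + 1)`, quantile
normalization (each sample's sorted values replaced by the
cross-sample mean order statistics, ties receiving averaged targets;
delegated to `limma::normalizeQuantiles`), and per-gene mean
centering.  Pairwise Pearson correlations carry two-sided p-values
from the exact t-transform — the conventional default at several
hundred samples — and entries above the 0.01 threshold are masked.
Gene ordering uses complete-linkage hierarchical clustering on
`1 - PCC`.  Module structure is summarised by within- and between-set
PCC collections with normal-reference-bandwidth kernel densities and
a within-median separation statistic; two planted modules at
correlations 0.8 and 0.2 separate by ~0.6 as built.  No multiplicity
correction is applied to the matrix mask (the threshold is a display
convention, not an inference), and p-values are two-sided; both were
open choices.

## Known limitations

The significance null assumes white noise within the envelope; after
low-pass filtering, voxel correlations make it mildly optimistic, which
the acceptance gates (overlap, re-score, double-count guard) absorb in
practice.  Orientation recovery is only as fine as the SO(3) grid plus
the 5-degree snap; rotational register statements are therefore made
from placement azimuths, not from recovered spins.  The wedge model is
single-axis and binary; CTF, membrane density and crowding are absent
by design.  The asymmetric-unit extraction uses a fixed nominal unit
centre rather than a refined one, which is sufficient for bookkeeping
and per-ring refinement on phantoms but would need care on real data.
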