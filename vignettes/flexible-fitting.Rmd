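---
title: "Hierarchical flexible fitting and local SMOC assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical flexible fitting and local SMOC assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexsmoc)
```

## The problem

A cryo-EM reconstruction in the 2.5–4.5 Å regime resolves secondary
structure and, at the better end, side chains — but an atomic model built
from a crystal structure of another conformational state, or from a
homology model, rarely drops into the density as-is.  Flexible fitting
deforms such a starting model to maximise its agreement with the map while
preserving stereochemistry.  Two questions then dominate practice: *how*
to deform without wrecking the chemistry, and *where* the fitted model
still disagrees with the density.

`flexsmoc` answers both in one package:

* a **hierarchical simulated-annealing engine** that moves rigid bodies
  first (domains identified by spatial clustering of secondary-structure
  elements, then individual SSEs) and individual atoms last, each stage
  under a progressively smaller per-step displacement cap;
* a **local goodness-of-fit score** — the segment-based Manders' overlap
  coefficient (SMOC) — computed per SSE and over sliding nine-residue
  windows on loops, with Z-score flagging of outlier segments and
  SMOC-ranked selection from loop-conformation ensembles.

## The scores

For a segment of residues the SMOC is

$$\mathrm{SMOC} \;=\;
\frac{\sum_{i \in \mathrm{vox}} \rho_i^{EM}\,\rho_i^{P}}
     {\sqrt{\sum_{i \in \mathrm{vox}} (\rho_i^{EM})^2
            \;\sum_{i \in \mathrm{vox}} (\rho_i^{P})^2}}$$

where the sum runs over the voxels occupied by the segment's atoms,
$\rho^{EM}$ is the experimental map and $\rho^{P}$ the model-derived
density.  No mean is subtracted: the score is invariant to positive
rescaling of either map but *sensitive to additive offsets*, which makes
it robust when the map contains density for neighbouring components.  The
global CCC (mean-subtracted Pearson correlation) is the complementary
whole-map measure and is invariant to both.  `smoc_segment()` exposes a
`mean_subtract` flag that turns the score into the mean-subtracted SCCC
variant.

"Occupied" is defined by an atom-distance cutoff: a voxel belongs to the
mask when its center lies within `radius` of any segment atom, with
`radius = max(2.5 Å, 1.5 × voxel spacing)` by default.  SMOC values shift
with this radius, so it is exposed everywhere a mask is built.

Per-residue profiles (`smoc_profile()`) give every residue inside an SSE
that SSE's segment score, and every loop residue the score of the
nine-residue window of consecutive chain residues centered on it.  Windows
are shifted inward at chain termini and shrink only when the chain itself
is shorter than the window; they may extend into flanking SSE residues, so
short loops are still scored over a sensible local neighbourhood.  An
alternative assignment that averages all windows covering a residue is
available via `loop_assign = "average"`.  Z-scores use the population
standard deviation over all residues — immaterial at chain length, fixed
for determinism — and `flag_poor_segments()` reports maximal runs of
residues with $Z$ below a threshold (default $-1$, a conventional cut for
"significantly lower than the chain average"), dropping runs shorter than
3 residues.

## The refinement engine

The objective is

$$U(\mathbf{x}) \;=\; w_{EM}\,\bigl(1 - \mathrm{CCC}(\rho^{EM},
\rho^{P}(\mathbf{x}))\bigr) \;+\; E_{\mathrm{stereo}}(\mathbf{x})$$

with the model density built by placing an isotropic Gaussian of integral
equal to the atomic number on each atom, $\sigma = 0.356 \times$
resolution (so the Fourier transform falls to half-maximum at
1/resolution), truncated at a per-axis box of $3\sigma$.  The density
force is the analytic gradient of the CCC through this Gaussian model.

The stereochemical terms follow the convention $E = k\,\Delta^2$ (no 1/2
factor), chosen so the printed non-bonded force constant of
400 kcal/mol/Å² has one unambiguous meaning:

| term | anchor | k (default) |
|---|---|---|
| bonds | value in the input conformation | 300 kcal/mol/Å² |
| angles | input conformation | 50 kcal/mol/rad² |
| impropers (carbonyl plane, peptide ω, CA chirality) | input conformation | 30 kcal/mol/rad² |
| Ramachandran | flat-bottom basins (α, β; αL for Gly) | 5 kcal/mol |
| non-bonded lower bound | min(vdW sum, input distance) | 400 kcal/mol/Å² |

Bonds and angles are detected from the input geometry (pairs within
covalent range in the same or adjacent residues), so the input structure
has exactly zero covalent restraint energy.  The Ramachandran term is a
flat-bottom basin penalty — zero inside broad allowed ellipses around the
α and β regions, harmonic in the scaled radial excess outside —
approximating a statistical (φ,ψ) potential without shipping one.

Two deliberate choices deserve emphasis:

* **Anchor-capped non-bonded bounds.**  The lower bound for a pair is the
  *minimum* of the van der Waals sum and the pair's distance in the
  conformation the restraints were built from.  An ideal α-helix holds its
  H-bonded O···N pairs slightly inside the raw vdW sum; with uncapped
  bounds those pairs would carry hundreds of kcal/mol of permanent
  "violation", dragging the model apart in the absence of a density term.
  With the cap, the term does exactly one job: it blocks the formation of
  *new* clashes during refinement.
* **Density weight $w_{EM} = 10000$.**  The relative weighting of density
  and stereochemistry is a free choice.  The default makes the density
  force on a displaced domain dominate the covalent restoring forces at
  its junctions (which would otherwise pin the domain to its starting
  pose), while local geometry remains controlled by the much stiffer
  bonded terms; on the hinge benchmark below this weight recovers the
  ground truth to well under 0.5 Å with maximum bond-length deviations
  under 0.01 Å.  It is exposed in `anneal_config()`.

### Annealing moves

Optimisation is a velocity-free capped-step descent with
temperature-scaled noise, annealed 0 K → 1000 K → 0 K piecewise-linearly
(default 200 heating and 200 cooling steps per cycle; the step counts are
configurable).  Per step:

1. every rigid body receives a translation proportional to its mean force
   and a rotation about its centroid proportional to the torque (Rodrigues
   rotation, so intra-body geometry is exact to machine precision);
   free atoms move individually down the force;
2. Gaussian noise scaled by $\sqrt{T/T_{max}}$ is added — rigidly for
   bodies, per-atom for free atoms;
3. displacements are clipped to the stage cap per axis (body motions are
   scaled uniformly so rigidity is never broken): 0.39 Å at the
   cluster-body stage, 0.15 Å at the SSE stage, 0.1 Å at the all-atom
   stage;
4. the move is accepted unless it raises the objective by more than a
   slack proportional to the temperature, so the schedule ends in strict
   descent; the step gain adapts (growing on acceptance, halving on
   rejection).

Each stage iterates annealing cycles until the global CCC changes by less
than `ccc_tol` ($10^{-4}$; the plateau criterion mirrors the observation
that global correlation flattens within a few iterations) or the cycle
limit (default 5) is reached.  When the cluster level offers fewer than
two bodies, that stage is skipped and refinement starts by constraining
SSEs — the fallback used for single-domain models.  Runs are
bit-reproducible given the seed.

### Rigid-body identification

`cluster_sses()` implements the spatial-proximity clustering of SSEs:
two SSEs are in contact when at least `min_pair_fraction` (default 10%)
of their inter-SSE Cα pairs lie within `cutoff` (default 6.5 Å); clusters
are connected components; a cluster's rigid body contains its SSEs plus
every loop lying strictly between two same-cluster SSEs along the chain;
isolated SSEs become singleton bodies and all other loops stay free.
The two knobs are declared operating points — the clustering literature
this mimics sweeps its cutoff, which is out of scope here — and both are
exposed.  β-sheets are treated at the level of individual strands; strands
of one sheet cluster naturally under any reasonable cutoff.  Bodies never
span chains.

`assign_sses()` is a fallback geometric assigner (backbone dihedral
ranges, minimum run lengths of 4 for helices and 3 for strands) used only
when no HELIX/SHEET records or TSV annotation are supplied.

### Interface freezing and loop ensembles

`freeze_interface()` adds arbitrary residue segments as extra rigid
bodies, active even at the all-atom stage.  This is the guard against
over-fitting at binding interfaces: an exposed loop facing a partner's
density would otherwise migrate into it.

`refine_loop_ensemble()` samples loop conformations by seeded random
backbone-dihedral perturbation, closes each sample onto the downstream
anchor by cyclic coordinate descent (CCD), rejects samples with heavy-atom
clashes, scores each conformation by the SMOC of the loop segment, and
substitutes the top-ranked one.  The sampler is plumbing; the scientific
content is the SMOC ranking, which is why `score_loop_ensemble()` also
accepts externally built ensembles.

## The synthetic fixtures

`make_fixture()` builds poly-Ala ground truths with ideal covalent
geometry from internal coordinates (NeRF): a 20-residue ideal helix, a
packed antiparallel helix hairpin (axes ~7.5 Å apart, connecting loop
closed by CCD and selected for clash-free packing), a two-domain hinge
protein (two hairpin domains joined by a 6-residue extended linker), and a
four-helix bundle.  Construction is deterministic per kind and residue
counts.  `perturb()` emulates the difference between a starting model and
the map's conformational state: rigid translation, hinge rotation of the
distal domain about the linker axis, and loop displacement via seeded
dihedral perturbation with CCD closure (covalent geometry stays ideal;
the displacement magnitude is matched by bisection on the perturbation
amplitude).

Simulated target maps are noise-free model densities of the ground truth
(3 Å resolution, 1 Å voxels in the benchmarks).  What passing tests on
these fixtures shows is that the machinery — scoring, clustering,
restraints, optimisation, ranking — does what it claims under controlled
conditions; what they cannot show is robustness to experimental-map
pathology (local resolution variation, noise, masking artefacts,
segmentation residue), for which no noise model is emulated beyond an
optional flat Gaussian.

## Benchmark problem sizes and numerical choices

The packaged benchmarks (test suite and `scripts/acceptance.R`) run the
annealing engine at 100 heating + 100 cooling steps per cycle and at most
3 cycles per stage — a scaled-down problem size chosen so the full
10-seed hinge study remains a desk-scale computation; the defaults
(200 + 200, 5 cycles) match the protocol described for larger systems.
Other numerical choices: map simulation reuses the target grid geometry
exactly so voxel products need no interpolation; the Gaussian box
truncation at 3σ keeps ≥ 99% of each atom's integral; SMOC masks use
1-based sorted unique linear voxel indices (set semantics); sharpening
scales Fourier amplitudes by $\exp(-B s^2/4)$ with the s = 0 term
untouched, so the mean is preserved and $B$ and $-B$ are exact inverses
away from Nyquist; Z-scores use population σ; CCD closure tolerance is
0.08 Å over the three anchor atoms with restarts over seeded random
initial torsions.

## A worked example

```{r example, eval = FALSE}
library(flexsmoc)

fx <- make_fixture("two_domain_hinge")          # ground truth + SSEs
em <- simulate_density(fx$structure, resolution = 3)
start <- perturb(fx, "hinge", magnitude = 15, seed = 5)

rmsd(fx$structure, start, "calpha")             # ~2.1 A

cfg <- anneal_config(steps_heat = 100, steps_cool = 100, cycles = 3,
                     resolution = 3, seed = 1)
ref <- hierarchical_refine(start, em, fx$sses, config = cfg)

rmsd(fx$structure, ref$structure, "calpha")     # well under 1 A
sapply(ref$trace$smoc, function(p) mean(p$residues$smoc))

z <- smoc_zscores(ref$trace$smoc$all_atom)
flag_poor_segments(z, fx$sses)
```

## Known limitations

* Single-conformer models only: alternate locations collapse to the
  highest-occupancy conformer on reading.
* Bodies never span chains, and no symmetry or multi-component assembly
  restraints exist.
* No nucleic-acid residue topology.
* No density segmentation, local-resolution estimation or half-map
  cross-validation; the map handed to the engine is taken as the target.
* The geometric SSE assigner is a fallback tuned for clean geometry;
  curated annotations should be preferred on experimental models.
* B-factors are carried through I/O but never refined.
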