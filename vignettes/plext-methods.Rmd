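---
title: "Membrane metrics for E. coli polar lipid extract models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane metrics for E. coli polar lipid extract models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plext)
```

## Scope

`plext` analyses lipid bilayer trajectories of *E. coli* polar lipid
extract (PLE) membrane models: the 14-species *Avanti* composition and the
three-species *SimplePOM*, *SimplePVM* and *SimplePVJ* reductions, all with
72% phosphatidylethanolamine (PE), 23% phosphatidylglycerol (PG) and 5%
cardiolipin (CL) and the five bacterial tail chemistries (16:0; 16:1 and
18:1 cis double bonds; cy17:0 and cy19:0 cyclopropane rings, at positions
9,10 or 11,12). The package computes structural, ordering, dynamic,
permeation, clustering and lipid–protein metrics, and ships a seeded
synthetic-bilayer generator whose ground truth makes every metric testable
without running molecular dynamics.

Units are fixed package-wide: nm for lengths, ns for times, K for
temperatures, kcal/mol for activation energies, m/N for area
compressibility, cm^2/s for diffusion coefficients.

## Composition bookkeeping

A composition is a tibble of species with mole-percent fractions. Species
codes are parsed structurally (tail letters + headgroup; `-CL` marks the
four-tailed cardiolipins), so tail fractions are derived, not stored: each
PE/PG contributes two acyl tails and each CL four. The *Avanti* fractions
are kept exactly as the vendor prints them (they sum to 99.8); fractions
are renormalised only inside the fraction computations, which preserves
the printed per-tail percentages (37.4% P, 28.0% V, 21.0% M, 9.4% Y,
4.2% N) and gives CL 4.61% of listed lipids. Integer per-leaflet counts
use the largest-remainder method with ties broken by descending fraction
and then species name; both leaflets receive identical counts, matching
the symmetric construction of extract-based in vitro membranes.

## The synthetic generator

`generate_bilayer()` builds two mirror-symmetric leaflets on a jittered
square lattice whose box area equals `n_per_leaflet * target_apl` exactly.
Acyl tails grow by torsion placement (bond 0.153 nm, angle 111 deg); each
torsion is drawn trans (180 deg +- `dihedral_jitter`) with probability
`p_trans`, otherwise gauche (+-60 deg with equal sign probability), so the
dihedral statistics of the coordinates equal the drawn Bernoulli sample.
Headgroup planes sit at `+-pp_thickness/2` with Gaussian roughness
`z_jitter` (default 0.05 nm); the hydrophobic boundary (carbonyl/first
methylene midpoint) sits `hydrophobic_offset` below each head. Lipids are
laterally rigid bodies that move by per-axis Gaussian steps of variance
`2 D dt`, which makes the diffusion ground truth exact by construction.
Water crossings are scripted: the event count is a Poisson draw with mean
`permeation_rate x total time`, each event a full midplane-crossing path;
all other waters stay strictly outside the slab. An optional rigid
cylindrical inclusion thins the surrounding headgroup planes by
`thinning_depth x exp(-(r - radius)/thinning_range)` in total (half per
leaflet) and biases first-shell species occupancy.

Defaults are the study conditions the metrics are validated under: a
SimplePOM-like leaflet of 128 lipids at 0.62 nm^2 per lipid, 3.9 nm
phosphate-phosphate thickness, 0.45 nm hydrophobic offset, trans
probability 0.58, lateral diffusion 0.6e-7 cm^2/s (the measured PLE value
near room temperature), 1 ns frames, and 0.05 scripted crossings per ns.
These are realistic liquid-crystalline PLE values; they were chosen once
and the tests inherit them.

What the generator does *not* emulate: forces, thermostats, undulations,
membrane breathing, correlated (hydrodynamic) lipid motion, tail
conformational dynamics over time (torsions are static per lipid), or
solvent density. Passing tests therefore demonstrate the estimators'
correctness on data with the assumed statistical structure, not the
physical fidelity of any force field.

Design choices worth noting:

* **Per-leaflet pulls of `thinning_depth/2`.** `thinning_depth` is defined
  as the *total* bilayer thinning at the protein wall so that the
  recovered thinning equals the parameter directly.
* **Shell enrichment bias.** Enriched classes receive first-shell
  occupancy probability `fraction x enrichment`; the remaining classes
  share the remainder proportionally. The measured
  shell-to-bulk ratio is then the planted factor in expectation, without
  a normalisation offset.
* **Protected annulus.** When the lattice holds more sites than lipids,
  surplus sites are dropped from the bulk only, so the first shell around
  an inclusion is always populated.
* **CL geometry.** Cardiolipins carry two phosphate reference particles
  0.5 nm apart, a central glycerol reference midway (the contact reference
  used by the enrichment analysis), and four tails.

## Structural metrics

**Area per lipid.** `apl_box()` is box area over leaflet count.
`apl_voronoi()` tessellates each leaflet with a periodic 2-D Voronoi
diagram over phosphate reference particles; a cardiolipin contributes two
generators and receives the sum of both cell areas, counting as one lipid.
The tessellation is computed by half-plane (bisector) clipping against the
3x3 periodic images with an early exit once no remaining neighbour can cut
the cell; cell areas tile the leaflet exactly, and the tests verify both
exact conservation and agreement with a Monte-Carlo point-sampling oracle.

**Curved-area ratio.** The phosphate surface of each leaflet is sampled
onto a regular grid by nearest-reference lookup, each grid cell is split
into two triangles (periodic wrap), and the summed triangle area is
divided by the projected area. Flat leaflets give exactly 1; a sinusoidal
corrugation reproduces the closed-form surface integral within 1% at a
50x50 grid. This grid-triangulation definition is the package's own,
documented stand-in for curved-area estimators whose exact algorithms are
not public.

**Thickness.** `thickness_grid()` evaluates, on a 15x15 grid by default,
the z difference between the nearest upper- and lower-leaflet reference
(periodic xy distance, nearest-reference assignment in the GridMAT style,
no interpolation). The `"hydrophobic"` boundary uses per-tail midpoints of
carbonyl and first methylene (atomistic) or glycerol and first tail bead
(coarse-grained).

**Interdigitation.** Cross-leaflet contacts between tail carbons,
excluding terminal methyls, per tail. The contact cutoff is not a
published constant; the defaults mirror the clustering cutoffs (0.35 nm
atomistic, 0.65 nm coarse-grained) and are exposed as arguments.

**Compressibility.** `kappa_T = n_L (sA_L)^2 / (2 k_B T <A_L>)`, with
`sA_L` the standard error of the block-averaged area series and `n_L`
interpreted as lipids per leaflet — the area per lipid is a per-leaflet
quantity; this interpretation is a documented choice. Blocks default to
single frames and are configurable (`block_frames`), mirroring the 100 ns
block-averaging convention at 1 ns frames.

## Ordering

The global ordering statistic is the fraction of tail torsions in the
trans window [130 deg, 230 deg] (endpoints included; angles reduced to
[0, 360)), over carbons 2-16 by default. It is independent of lipid tilt
and of tail chemistry, which is what makes it comparable across mixtures
with double bonds and cyclopropane rings in different positions. Bond
vectors are taken minimum-image so tails wrapped across the periodic
boundary stay intact. For coarse-grained systems, `p2_bond_order()`
computes `P2 = (3 cos^2 theta - 1)/2` per bond against the membrane
normal, bounded by [-0.5, 1] with 1 = aligned, 0 = isotropic, -0.5 =
in-plane.

## Diffusion and activation energies

`msd_lateral()` tracks per-lipid xy centres of mass (equal-weight
particles), unwraps them from frame-to-frame minimum-image displacements,
removes the per-leaflet centre-of-mass drift, and averages squared
displacements over lipids and time origins restarted every 1 ns.
`diffusion_coefficient()` fits the 10-30 ns lag window by default (the
atomistic convention; 100-300 ns is the coarse-grained one) and applies
the two-dimensional Einstein relation `D = slope/4` — stated explicitly
because lateral diffusion is a 2-D process. No finite-size hydrodynamic
correction is applied. Leaflet-COM removal introduces a `1 - 1/n`
understatement of the MSD that is negligible at the tested sizes.

`arrhenius()` fits `ln k` against `1/T` by unweighted least squares and
reports `E_a = -slope x R` in kcal/mol (R = 1.9872e-3 kcal/(mol K)).
`permeation_arrhenius()` first drops temperatures with fewer than 1 event
per 100 ns (0.01 events/ns), the convention for statistically unreliable
low-temperature points, and carries the excluded rows in the result.

## Permeation counting

Each water runs through a three-state machine (above / inside / below the
two boundary planes) on its unwrapped z. An event requires a full
traversal: fully above to fully below (or the reverse) having passed
through the inside state; excursions that return to the starting side
count zero. The planes default to the mean phosphate planes of the first
analysed frame — fixing them prevents plane breathing from generating
phantom crossings; a per-frame mode and a hysteresis buffer (default 0)
are available since no published crossing criterion fixes these choices.

## Clustering and neighbour enrichment

`neighbor_enrichment()` counts, within 0.9 nm, contacts between headgroup
reference particles (PE/PG phosphates, CL central glycerol): the mean
number of class-Y neighbours of a class-X lipid, normalised by the mean
number of class-Y neighbours of any lipid. The ratio is formed per frame
and then frame-averaged; the order of averaging is ambiguous in common
usage, so this per-frame-ratio order is fixed and documented. A
single-species system gives exactly 1.

`cluster_size_distribution()` is single-linkage: two molecules connect
when any particle of one is within the cutoff of any particle of the
other (0.35 nm atomistic / 0.65 nm coarse-grained, both leaflets pooled).
Membership comes from union-find; the tests cross-check against graph
components computed independently with igraph. Molecule fractions in
monomers/dimers/trimers/higher are reported per frame.

## Lipid-protein context

Shell membership for `shell_enrichment()` defaults to the lateral
distance of the lipid's reference particle to the nearest protein atom —
the annular-shell convention for a membrane-spanning inclusion — with an
any-particle 3-D mode available. Enrichment is the shell fraction of each
class over its bulk (outside-shell) fraction; with `per_leaflet = TRUE`
the upper/lower leaflets are reported as CP/EC, assigned from the stated
protein orientation rather than inferred. `local_thinning()` follows the
reference-restriction convention: phosphates within 0.5/1.0 nm of the
protein are selected first, paired across leaflets on a 1 nm grid, and
compared against a bulk reference (a number, a protein-free trajectory,
or the far field of the same frames). Binding analyses use any-atom
contacts at 0.65 nm with a gap tolerance of 1 frame by default; neither
constant has a published value, so both are arguments.

## Numerical choices and degenerate inputs

* Voronoi cells are clipped from a finite initial square; coincident
  generators raise an error rather than tessellating ambiguously.
* The trans window endpoints are inclusive — a measure-zero choice fixed
  for reproducibility; torsions use the IUPAC convention mapped to
  [0, 360) before windowing.
* Compositions must sum to 100 +- 0.5 (accommodating the printed 99.8);
  negative fractions, unknown presets, empty selections, inverted
  permeation boundaries, sub-2x2 grids and non-positive temperatures all
  raise errors with explicit messages.
* Coordinates are wrapped to [0, box) on read; every pairwise statistic
  uses minimum-image distances, and unwrapping for MSD/permeation assumes
  no particle moves more than half a box length between frames.

## Problem sizes used in validation

The test-suite and acceptance-script sizes are chosen so each recovery has
adequate statistics at desk scale: diffusion uses 128 lipids x 500 frames
(sampling error well under the 15% band over 10 seeds); permeation pools
20 seeds of 200 ns scripted trajectories (Poisson mean ~10); activation
energies average 50 seeded rate sets with 5% multiplicative noise (bias
resolvable below 2%); thinning averages seeds of 200-lipid bilayers
against the analytic radial profile. Planted shell enrichment is a
species-level binomial draw over a few dozen first-shell sites, so its
per-seed estimate is intrinsically noisy; the test pools counts across 20
seeds and asserts recovery within the propagated binomial error (about
0.2 at one standard deviation), rather than pretending to a precision the
statistics cannot support.

## Known limitations

* The curved-area estimator and the permeation crossing criterion are
  documented package definitions; other toolchains may differ in detail.
* Enrichment entries involving cardiolipin are noisy in small systems
  (5% of lipids), and cluster statistics for CL pool few molecules below
  ~200 lipids per leaflet.
* The generator's torsions are static in time, so ordering statistics
  gain no statistics from extra frames.
* No bending-modulus/undulation spectra, no deuterium order parameters
  (the trans-fraction statistic replaces them deliberately), and no
  osmotic permeability from scattering experiments.
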