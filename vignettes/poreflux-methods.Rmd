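---
title: "Models, conventions and design choices in poreflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices in poreflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

poreflux analyses molecular dynamics trajectories of membrane ion channels
— in particular dimeric K2P-type potassium channels, where the selectivity
filter (SF) is the gate and a cytosolic C-terminal sensor couples to it.
This vignette is the package's own account of the models it implements, the
conventions and defaults it fixes, and what its synthetic fixtures can and
cannot demonstrate.

## Units and coordinate conventions

All coordinates are handled internally in angstrom (GRO files, which store
nm, are scaled at parse time), times in ns (PLUMED-style hills logs, which
store ps, are likewise converted), energies in kJ/mol, voltages in mV and
concentrations in uM. Atom indices are 0-based and dense; residue numbers
are taken verbatim from the topology file — no renumbering is ever applied,
so published residue numbers (Y175, F284, Y315, K333, ...) can be used
directly in selections.

The pore axis is the membrane normal (box z). Its per-frame origin is the
mass-weighted centre of the SF backbone atoms, and the reported axial
coordinate places that centre at +7 A:
`Dz = z_atom - z_SFcentre + 7`. Positive Dz points extracellular. This
one-number convention makes axial profiles from different runs directly
superposable.

## Permeation counting and conductance

The literature rarely states a crossing criterion precisely, so poreflux
fixes one and exposes every piece of it: an ion scores an outward event
when, radially inside a cylinder of radius 8 A about the axis, it passes
from `Dz < lower` to `Dz > upper` without leaving the cylinder and without
retreating past its entry plane in between. The planes default to the SF
axial extent widened by 3 A on each side (`lower = 1`, `upper = 13` with
the synthetic geometry). Re-crossings of a single plane are feints, not
events; a jump across both planes within one frame interval is counted but
flagged `undersampled`. This two-plane-with-reset construction is the
standard way to make counts robust against boundary recrossing noise, and
it makes counts invariant under rigid translation and under frame-stride
refinement as long as traversals span several frames.

Counts convert to conductance as `gamma = N e / (t V)` with e the
elementary charge. Five events over 1 us at +200 mV give 4.005 pS, which
prints as the familiar 4 pS. When several replicates are pooled,
`permeation_summary()` reports both the pooled estimate (all events over
summed time) and the mean of per-run conductances, since either averaging
convention is defensible and they differ when run lengths differ.

## Occupancy normalization and binding sites

Ion-frame tallies are normalized per 0.001 cubic angstrom of bin volume per
1 us of summed trajectory time. In 2D (radial-axial) mode the bin volume is
the annulus `pi (r_out^2 - r_in^2) dz`, which removes the geometric growth
of sampling volume with radius; a uniformly filled cylinder therefore
yields a radius-independent density, which is exactly how the tests verify
the normalization. Time normalization uses the summed time of all pooled
replicates, not per-replicate time.

Published axial occupancy figures mark the K+ sites S0-S5 with dashed lines
but not numbers, so the numeric boundaries are unrecoverable from text.
poreflux defaults to the canonical K+-channel geometry: contiguous 3.4 A
intervals descending from S0 at the filter top, anchored so the SF backbone
centre (+7 A) is the S2/S3 boundary. The defaults are documented
(`default_sites()`) and fully user-overridable; they are a convention, not
a claim about any specific structure.

## Dihedral flips and helix orientation

psi is the signed N-CA-C-N(next) dihedral (IUPAC sign convention, verified
against an independent implementation), wrapped to (-180, 180]. Flip
classification needs a band, which published distributions do not state; the
default is +/-40 degrees around the reference (crystallographic) psi with a
10 degree Schmitt-trigger hysteresis: leaving the crystallographic state
requires the circular distance from the band centre to exceed
halfwidth + hysteresis, returning requires dropping back below the
halfwidth. Zero hysteresis reduces exactly to band membership, which the
tests use as a regression oracle. Angle densities are wrapped-Gaussian
kernel estimates normalized over the circle.

The helix orientation angle theta is the angle between the per-frame vector
— from the CA of the first residue of the range to the geometric centre of
the CA atoms of the inclusive range (defaults 315..333) — and the same
vector in a reference structure. It is unsigned in [0, 180]; up/down
directionality is established by comparing against both reference-state
vectors rather than by a sign.

## Contacts and difference maps

Contacts use one representative side-chain heavy atom per residue type
(`representative_atom_table()`), a strict 5 A minimum-image cutoff, and a
same-chain sequence-separation exclusion of |delta resid| >= 2 (trivially
contacting neighbours would otherwise dominate; set `min_seq_sep = 0` for
exact-reproduction attempts). The two-state difference map retains pairs
with |p_up - p_down| strictly above 0.25, keeps both signs, and classes
pairs inter- vs intra-chain by chain identity. The map is antisymmetric
under state exchange by construction.

## Structure networks

Edges weight contact frequency as `-log p`, mapping interaction intensity
onto additive path cost so Dijkstra shortest paths follow the most
persistent interaction chains. The correlation filter retains a path only
when each interior residue's fluctuation correlation with at least one path
endpoint reaches the cutoff. The cutoff is dimensionless 0.8: correlation
cutoffs are sometimes quoted with length units ("0.8 nm"), which is
dimensionally inconsistent for a correlation, so poreflux documents and
uses the dimensionless value. The metapath keeps
edges appearing in at least 20% of retained paths (configurable); both
choices are exposed rather than hard-coded because the upstream tools do
not document their internals. Dynamic cross-correlations are plain
normalized displacement covariances after a rigid-body fit, and the test
suite cross-checks them against bio3d's independent implementation.

## Metadynamics surfaces and ABMD forces

A hills log stores Gaussian centres, widths, heights and the bias factor.
The reconstruction sums the Gaussians with periodic (minimum-angular-image)
wrapping — psi collective variables live on a circle — and converts bias to
free energy with `F = -(gamma/(gamma-1)) V`, min-shifted to zero. Heights
in the log are taken as already well-tempered-scaled, the PLUMED writing
convention, so no additional rescaling is applied. The widths deserve a
units note: a stated hill width of 0.25 for a torsion variable is 0.25 rad;
poreflux works in degrees, so the default sigma is 14.32 degrees.

Basins are detected by persistence flooding: cells are processed in order
of increasing F on the periodic grid, catchments merge at saddles, and a
catchment survives as a basin only if its depth below the lowest connecting
saddle is at least `min_depth` (default 4 kJ/mol, one contour step of the
conventional 4-to-80 kJ/mol contouring).

ABMD is a ratchet: the running extremum of the collective variable toward
the target is the reference, and the harmonic bias (k = 5000 kJ/mol/nm^2,
target 0.5 nm by default) pushes only when the CV retreats from it. The
phrase "the square force was used to calculate the total force by summing"
admits two readings, so both totals are always reported and labelled:
`sum |F|` and `sum F^2`.

## The Hill dose-response model

Printed forms of the concentration-inhibition equation vary across reports
and are frequently garbled in transcription, so poreflux commits to the
standard 4-parameter Hill model
`%inh(x) = base + (max - base) / (1 + (x_half/x)^rate)` with
base = 0 and max = 100 fixed unless freed, which matches the described use
(half-maximal concentration-inhibition with IC50 semantics). Fitting is
Levenberg-Marquardt nonlinear least squares, initialized at the geometric
mean of the doses with rate 1 and the Hill coefficient bounded to
[0.3, 5]. Reported experimental IC50 values are data, never fit targets;
the 7 uM default of the generator simply mirrors the scale of a wild-type
measurement. Per-measurement normalization before averaging is supported
through the `replicate` argument.

## What the synthetic generators emulate — and what they do not

The generators plant ground truth and return it alongside the data; no
analysis function ever reads it. They emulate the statistical structure of
the real analyses, not the physics:

* `gen_ion_channel_traj()`: reflected 1D Brownian bulk ions that never
  traverse, plus Poisson-planted carrier ions driven monotonically through
  the pore over 12 frames (a traversal shorter than ~5 frames could be
  missed at coarse strides, so the driven crossing is deliberately
  resolution-proof). Event times keep a minimum separation of one traversal
  duration — a rate too high to resolve is an error, not silent aliasing.
  Default conditions: 1 us, 1 ns frames, 5 events/us, matching the
  conductive-state event rate at +200 mV.
* `gen_dihedral_series()`: a two-state telegraph process with exponential
  dwells plus wrapped Gaussian noise — the shape of carbonyl-flip traces.
* `gen_distance_series()`: i.i.d. Bernoulli contact states mapped to
  distances across the 5 A cutoff.
* `gen_hills()`: a Metropolis walker on a known double-well surface plus
  its own accumulated bias, heights decaying by the well-tempered rule
  `h = h0 exp(-V/((gamma-1) kB T))` with kB T at 300 K (2.494 kJ/mol) and
  the stated hill parameters (h0 = 1.2 kJ/mol, sigma = 0.25 rad,
  gamma = 8). The planted wells are 30 and 26 kJ/mol deep (a 4 kJ/mol gap,
  one contour step) with 30 degree widths.
* `gen_dose_response()`: the exact Hill curve plus Gaussian noise,
  truncated to [0, 100]%.

None of this reproduces real lipids, water, force-field energetics or
actual channel coordinates. Passing tests therefore demonstrate that the
*analysis machinery* is correct — counting, normalization, classification,
reconstruction and fitting recover planted truth at known tolerances — not
that any particular biological conclusion holds. Quantities that depend on
multi-microsecond sampling of a real system (absolute conductances,
occupancy patterns, basin counts of a real filter) are out of reach at desk
scale by construction.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so
the whole battery completes in well under a minute per module: 1000-frame
trajectories for permeation (50 seeded repeats), 50,000 ion-frames for the
occupancy flatness check, 10,000 frames for contact recovery, 20,000 hills
for the FES recovery (basin centres within 10 degrees, inter-basin free
energy within 2 kJ/mol of truth), and 500 replicate Hill fits. Degenerate
inputs error early and explicitly: empty selections warn, V = 0 is
undefined for conductance, mixed bias factors abort a reconstruction,
non-convergent fits report their last iterate. Ties in the basin flooding
are broken by grid order, which is immaterial above float resolution.

## Known limitations

* Trajectory input is multi-frame GRO, multi-model PDB or DCD; compressed
  GROMACS formats (XTC/TRR) are not read — convert externally, or write
  the package's own multi-frame GRO, which round-trips through the bundled
  writer to format precision (0.01 A) and carries per-frame time stamps.
* Frame times for PDB/DCD input must be supplied (`frame_dt_ns`), since
  those containers carry no reliable time metadata.
* The contact engine considers one representative atom per residue; an
  all-heavy-atom definition would find strictly more contacts.
* Orthorhombic boxes only; minimum-image distances assume rectangular
  periodicity.
* The PSN module covers correlation-filtered shortest paths and metapaths,
  not the full feature set of dedicated structure-network suites (hubs,
  interaction-strength scans).
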