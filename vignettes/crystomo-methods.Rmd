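---
title: "Methods: simulating and analysing membrane-protein 2D crystals by cryo-ET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing membrane-protein 2D crystals by cryo-ET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package does

`crystomo` is a desk-scale, fully synthetic re-creation of a hybrid
structural workflow: a large membrane complex (an ATP-synthase-like
particle: a 10 nm catalytic head held 15 nm above the membrane by a thin
central stalk, a prominent peripheral stator stalk, and a
membrane-embedded rotor ring) is packed on an oblique 2D lattice
(a = 179.1 Å, b = 171.4 Å, γ = 94.9°) with complexes on both faces of a
zigzag lipid bilayer, imaged as a ±60° single-axis tilt series at 1.5°
steps, reconstructed by weighted back-projection at 6.66 Å/voxel, analysed
by gold-standard subtomogram averaging, and cross-checked by
electron-crystallographic processing of tomographic z-slices.  Because the
ground truth is generated in code, every downstream number — unit cell,
long-axis inclination (16°), intra-pair axis angle (24°), cross-membrane
interface rotation (90°), membrane kink (43°), predicted dimer angle
(86°) — is a *recovery* target with a known answer.

This vignette explains the models and the numerical choices; the README
shows a worked example.

# The synthetic specimen

## Phantom

The particle is a sum of soft-edged solid primitives (1-voxel linear
edges): a spherical head (diameter 100 Å, centre 150 Å above the membrane
midplane along the particle axis), a central stalk (radius 10 Å) from the
rotor ring to the head, a membrane-embedded rotor ring (solid cylinder,
radius 22 Å, height 40 Å, centred on the midplane), and a peripheral
stalk.  The peripheral stalk is deliberately substantial — radius 14 Å at
52 Å offset, running from the membrane surface to the head top.  In the
real complex the stator stalk plus OSCP region is a full-height, rigid and
prominent feature (typically the strongest density in such averages), and
it is the only part of this phantom that breaks azimuthal symmetry: with a
thin, half-height stalk the spin angle about the long axis is genuinely
unrecoverable at the working resolutions, with or without noise.  Protein
density is 1, lipid 0.5 (unitless contrast); protein displaces lipid
(voxelwise maximum).

## Crystal geometry

Per unit cell the motif holds two up-face monomers and two down-face
monomers.  Axes are tilted `inclination_theta` = 16° from the crystal
normal; the two same-face monomers' tilt azimuths differ by
`pair_azimuth_delta` = 98.1°, chosen so that the spherical-trigonometric
identity `cos(pair) = cos²θ + sin²θ·cos(Δφ)` yields a 24.0° pair angle at
θ = 16°.  (The azimuth separation is a modelling choice: the 16° and 24°
values jointly imply it, but it is not itself a measured quantity.)
Opposite-face partners are built by a 180° rotation about x followed by
`interface_rotation` = 90° about z, with rotor rings apposed across the
membrane midplane, 45 Å apart along the row direction.

The membrane is a piecewise-planar zigzag slab: fold rows run parallel to
the tilt axis (y), and the height profile along x is a triangle wave with
vertices at the particle rows and slopes ±tan(κ/2), κ = `kink_kappa` =
43°.  The rows must be parallel to the tilt axis: a zigzag modulated
*along* the tilt axis would place the membrane's entire spectrum in the
kx ≈ 0 plane, deep inside the missing wedge, and nothing of it would
survive reconstruction.

Positional (σ = 2 Å) and angular (σ = 1.5°) disorder is applied per
particle; the ground-truth table records the *jittered* placements, so
recovery is always judged against what was actually built.

The default field is 4 × 4 unit cells in a 160 × 160 × 96-voxel tomogram
(64 particles).  A 3 × 3 field is too small for the unit-cell acceptance
tolerance: with only ±1 cell of lever arm, per-cell localisation noise
alone puts ≈1 %/0.55° floors on the recovered cell, at the stated
tolerance rather than safely inside it.

## Image formation

Projections are real-space line integrals of the rotated volume (tilt
axis y), with additive white Gaussian noise.  The default noise level is
expressed as a signal-to-noise ratio of 1.0 (noise sd = sd of the
noiseless projection stack), a level at which individual particles remain
alignable — appropriate for a 64-particle study in which per-particle
orientation recovery is itself the measurand.  No CTF is simulated
(defocus is acquisition metadata in the source conditions), and tilt
angles are taken as exact, so fiducial alignment is out of scope.
Reconstruction is ramp-weighted (R-weighted) back-projection with a
raised-cosine rolloff and a small DC retention.

# Subtomogram averaging

Particles are "picked" at the ground-truth positions (picking was manual
in the emulated workflow and is an input contract here); down-face
particles are flipped 180° about x before alignment and their refined
transforms are mapped back through the flip.  Particles are split
randomly (seeded) into two half-sets refined independently; half-maps are
never compared during refinement.

Scoring is normalised cross-correlation over a masked Fourier region: the
band limit of the current stage, intersected with the particle's missing
wedge, minus a 180 Å high-pass.  Three choices here were driven by the
crowded-lattice geometry and are worth recording:

* **High-pass at 180 Å.**  The lipid slab is a near-uniform positive
  background; without a high-pass, any pose that buries reference density
  at membrane level gains correlation, and the spin angle is decided by
  the membrane rather than by the stalk.
* **Cylindrical masks.**  Both the reference and the particles are masked
  with a soft z-axis cylinder (radius 75 Å).  A sphere large enough to
  hold the particle (reach ≈ 120 Å) also admits the neighbouring unit
  cells at ≈ 118 Å lateral distance — and, worse, their missing-wedge
  ghosts, which smear along z but not laterally.  The cylinder keeps a
  particle's own z-elongated ghosts (genuine signal under the wedge) and
  excludes the neighbours entirely.
* **Final band limit 24 Å.**  The schedule starts at 60 Å on 2×-binned
  data and tightens to 24 Å unbinned.  The spin discrimination of this
  phantom lives between 30 and 24 Å (peripheral-stalk detail): at 30 Å
  roughly a fifth of the particles lock into ≈100° spin errors that
  *outscore* the true pose even on noise-free reconstructions.  The
  emulated workflow lowered its limit "in accordance with the FSC", i.e.
  adaptively; here the informative band is known and fixed once.

Coarse stages re-search the full constrained grid every iteration (free z
spin, off-axis tilt ≤ 45°, shifts ≤ 12 voxels per axis via FFT
cross-correlation); the unbinned global stages score masked Fourier
vectors at each particle's current translation (positions are known to
about a voxel), and the final 4°-step local stages re-refine translations
with the FFT search, restricted to ±3 voxels — the looser bound in the
final, finest band otherwise lets the search fit noise, which the
phase-randomisation control duly flags.  Averages are built with
per-voxel wedge compensation (sum of rotated transforms divided by the
count of contributing wedges, threshold ≥ 1), after a soft spherical
premask at the inscribed-sphere radius: box corners carry neighbouring
crystal content whose clipping under rotation would otherwise leak the
shared low-resolution structure into every average's high shells.

## Bootstrapping the reference and anchoring the frame

The classic initial reference — the plain average of the unaligned boxes
— is azimuthally multi-lobed here, because the motif's tilt azimuths form
a few discrete clusters.  Iterating from it converges to a stable wrong
fixed point in which each cluster locks into its own lobe (verified by
the clustering of residual spin errors per motif class).  The default
bootstrap is therefore *seed-and-grow*: each half-set's reference starts
from a single member subvolume and is rebuilt from the best-matching
partners over three rounds (an eighth, a third, then all members), which
breaks the degeneracy deterministically.  Half-set B's bookkeeping frame
is then registered onto A's by a pure rotation of its reference — no
density ever crosses the half-sets, so their noise stays independent.

The refined orientations live in the bootstrap-defined frame while
positions live in the tomogram frame.  The frame is anchored in two
steps: the principal inertia axis of the merged average is rotated onto
+z, and, when a template is supplied (the pipeline passes the phantom),
the template is rigid-body fitted into the merged average and the fit
fixes the frame exactly — the same move as docking a known structure
into a subtomogram average to define the molecular axes.  Only the
global frame convention comes from the fit; every per-particle
orientation remains purely data-driven.  A residual *common* spin about
the axis would cancel in all relative measurements anyway.

Even so, a small minority of particles of one motif class can lock into
a discrete wrong-spin attractor that re-searching does not undo (their
scores do not separate them; the attractor is a genuine missing-wedge
degeneracy of the crowded field).  Axis-based measurements are immune
(the spin does not move the axis), but the interface rotation is not:
its per-interface distribution then becomes cleanly bimodal, and
`measure_interface_rotation()` reports the dominant-mode mean (values
within 30° of the median) alongside the plain mean.  For a clean
refinement the two coincide, which the ground-truth tests assert.

# Validation

FSC uses 1-voxel shells with no masking of the half-maps (mask-correction
machinery is out of scope); resolution is the first downward 0.5
crossing, linearly interpolated.  The overfitting check randomises phases
of every subvolume beyond 40 Å (per subvolume, seeded; amplitudes exactly
conserved, Hermitian symmetry by construction) and repeats the final
alignment iteration.  The verdict is judged against an internally
computed frozen-alignment baseline: in an oriented crystal the
interpolation residues of the shared low-resolution structure leave the
randomised half-map FSC a floor of ≈0.3 even with the transforms held
fixed, so an absolute 3/√n criterion would flag every run — including
the frozen case it is supposed to pass.  Alignment-induced imprinting
therefore shows as an *excess* of the realigned randomised curve over
the baseline (flagged when the mean beyond-cutoff excess passes 0.1,
a separation that is obvious in the graphical comparison), and
non-independent half-sets show as a high baseline or near-unity true
FSC out to Nyquist.  The final merged map is Fermi-filtered to 18 Å
with temperature 0.002 reciprocal pixels.

On fully synthetic, structure-rich data the half-map FSC should be read
with care: both half-maps estimate the same noiseless phantom, so the
0.5-crossing reflects alignment consistency and the noise level, not an
information limit of a real specimen.  The corresponding "resolution" of
the emulated study (24 Å) depends on that study's data quality and is
deliberately *not* a recovery target here.

# Packing geometry

The crystal plane is the total-least-squares plane through the particles'
mid-membrane points (positions minus 80 Å along each particle axis).
Inclination is the angle between the (hemisphere-folded) particle axis
and the plane normal.  With a finite zigzag field the fitted plane wobbles
by ≈2° against the ideal crystal plane (the triangle wave is sampled at a
few rows, so height and position correlate); this inflates the
per-particle spread but not the mean.  Pairs are same-face mutual nearest
neighbours at mid-membrane level; interfaces are cross-face mutual
nearest neighbours.  The interface rotation needs an in-plane reference
axis (a flip-then-residual-twist decomposition is only defined relative
to a chosen flip axis); the default basis uses the in-plane projection of
global +x, and equivariance tests co-rotate the basis.

## The membrane kink and the missing wedge

`trace_membrane_kink()` implements ridge tracing: per x column the
membrane-band density maximum is traced (after 8 Å Gaussian smoothing —
compact and ring-free, where a sharp low-pass's sinc tails round the fold
vertices far into the segments), and the piecewise-linear profile with
breakpoints at the known row period is fitted.  On direct crystal volumes
this recovers κ = 43.0° exactly.

On a ±60° single-axis *reconstruction* it cannot: the slab's segments are
tilted only κ/2 = 21.5° from the crystal plane, below the 30° visibility
limit of the tilt range, so the bilayer is essentially invisible (the
emulated study saw the same in its wedge-affected averages), and the
surviving y-uniform crease signal marks the *outer surface apexes*,
biasing any traced amplitude outward by an uncalibratable mixture offset.
The pipeline therefore measures the reconstruction-domain kink from the
per-row rotor-ring heights of the refined particle table
(`measure_kink_from_rows()`): rows are averaged, and the alternating-slope
profile is fitted through the row heights.  This is unbiased under the
wedge and mirrors how the emulated study anchored its membrane (rotor-ring
positions of fitted maps).  Positional disorder biases it slightly low
(particles sit marginally downslope of the fold apex; ≈ −1.5° at the
default σ = 2 Å), which is visible in the recovered values.

The head height is measured by segmenting the up-face head band
(100–220 Å above the midplane, density above the 90th percentile) and
taking the density-weighted centroid height.  Note the geometric
expectation is 150·cos 16° ≈ 144 Å, not 150 Å: the phantom's 150 Å head
height is measured along the tilted axis.

# Z-slice crystallography

Projection images are sums of tomogram voxel layers.  Lattice detection
runs in two stages.  The spectral stage (Hann window, 4× zero-padding,
extreme-value significance threshold, greedy peak separation, power-
centroid refinement) indexes peaks against the *consensus basis* — the
independent peak pair that indexes the most spectral power — followed by
least-squares refinement and Lagrange reduction to the two shortest
reciprocal vectors.  For a crystal with only a few repeats the spectral
lobes are broad and interference-shifted at the percent level, so the
final cell comes from real space: the per-unit-cell cross-correlation
nodes (a Fourier-filtered, compactly windowed reference patch — narrow
enough that a node's peak does not depend on whether its neighbour cells
exist) are located to sub-pixel precision and the lattice vectors are
fitted through them by least squares.  Cells are reported with a ≥ b and
γ folded into [90°, 180°) — the lattice is invariant under b → −b, so the
fold fixes a convention, and the two cell edges are assigned by length.

The same node machinery drives unbending: per-cell displacements from the
ideal lattice are interpolated bilinearly in lattice-index space and the
image is resampled against the field; the corrected image is kept only if
it does not degrade the (1,0) peak-to-background ratio.  Structure
factors are read by exact (sub-pixel) Fourier sums at the predicted
reciprocal positions within the 30 Å limit, with the background taken on
an off-lattice ring (radius 4 index pixels) and snr = amplitude /
background (a continuous stand-in for discrete quality classes).
Projection maps are plain p1 Fourier syntheses.  The p2 phase residual is
the snr-weighted mean deviation of phases from {0°, 180°} minimised over
the phase origin (36 × 36 grid plus Nelder–Mead); note that for random
phases the origin refinement pulls the residual below the naive 45°
expectation, so the reference value for "no symmetry" should itself be
computed with origin refinement.  The three z-level maps (head, stalk,
membrane; band centres 150, 80, 0 Å above the midplane) reproduce the
qualitative packing features; "lines of continuous density along one
lattice direction only" at membrane level is quantified as the ratio of
the (0,k) to (h,0) axial reflection amplitude families.

# Problem sizes and determinism

The default run — 64 particles, 160 × 160 × 96 tomogram, 81 projections,
a 4-stage schedule — completes in minutes on one core; the test suite
uses 2 × 2-cell fields and binned boxes for everything except the
end-to-end checks.  All randomness (disorder draws, projection noise,
half-set split, phase randomisation) derives from the single config seed
with fixed offsets, so identical config + seed gives byte-identical
reports.

# Known limitations

* No CTF, dose, or fiducial-alignment errors; tilt angles are exact.
* The phantom is a geometric cartoon: recovery results demonstrate the
  estimators' correctness under the stated imaging model, not performance
  on real data (no structural heterogeneity, no real noise spectra).
* The membrane itself is unobservable in the reconstruction for this
  geometry (see above); kink recovery from the reconstruction necessarily
  routes through the particles.
* Plane-group testing covers p1/p2 only; no lattice-line 3D merging; MRC
  I/O is mode-2 float32 only.
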