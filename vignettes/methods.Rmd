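---
title: "Modeling NIRS feasibility in dolphin-like heads: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling NIRS feasibility in dolphin-like heads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cetanirs` asks a quantitative feasibility question: can near-infrared light
launched at the skin of a medium-sized cetacean return a measurable signature
of brain (or muscle) hemodynamics, and at which wavelengths, source–detector
separations, and animal sizes? The package answers it with a simulation
chain — tissue optics, a finite-element photon-diffusion solver, adjoint
sensitivity analysis, and detector-level power metrics — exercised on
synthetic layered head phantoms. This vignette explains the model at each
stage, the tunable parameters and their defaults, and the numerical choices
that shape the results.

## Tissue optical properties

Absorption of each tissue is a weighted sum of pure chromophore spectra,

$$\mu_a(\lambda) = B\,S\,\mu_{a,\mathrm{HbO}} + B(1-S)\,\mu_{a,\mathrm{HbR}}
  + W\,\mu_{a,\mathrm{water}} + M\,\mu_{a,\mathrm{melanin}}
  + F\,\mu_{a,\mathrm{fat}},$$

with $B$ the blood volume fraction relative to whole blood at 150 g/L
hemoglobin, $S$ the hemoglobin oxygen saturation, and $W, M, F$ the water,
melanin and fat volume fractions. Reduced scattering follows the power law
$\mu_s' = a\lambda^{-b}$. Two unit conventions coexist deliberately: fitted
$a$ values are reported in the field's customary form (wavelength in nm,
$\mu_s'$ in cm$^{-1}$, e.g. $a = 1546$, $b = 0.8038$ for blubber+skin giving
$\mu_s' \approx 7.2$ cm$^{-1}$ at 800 nm), while everything internal to the
solver uses mm$^{-1}$, so `tissue_property_table()` divides power-law output
by 10. The diffusion coefficient is $\kappa = 1/\bigl(3(\mu_a +
\mu_s')\bigr)$ in mm — the only dimensionally consistent reading of the
definition, asserted on construction.

The pure-absorber basis shipped in `inst/extdata/chromophore_basis.csv` is an
approximate compilation in the style of the standard references (tabulated
hemoglobin extinction converted to whole-blood absorption at 150 g/L,
pure-water and purified-fat absorption anchors, and the melanosome power law
$1.7\times10^{12}\,\lambda^{-3.48}$ cm$^{-1}$), linearly interpolated between
anchors and covering 450–1700 nm. It reproduces the qualitative features that
drive the results — the 700–900 nm hemoglobin window, the 970/1200/1450 nm
water bands, the 930/1210 nm lipid peaks — but absolute values beyond
1000 nm (hemoglobin) are smooth extrapolations; composed spectra should be
treated as model inputs, not as reference data. Tissue compositions
(`inst/extdata/tissue_compositions.csv`) take review-compilation-style
values for brain, bone and muscle and the fitted sculp parameters for
blubber+skin; refractive indices are fixed per tissue (brain/muscle 1.37,
blubber 1.45, bone 1.55). Both tables are configuration, replaceable by the
user.

## Property estimation from frequency-domain records

`multi_distance_fit()` implements the canonical semi-infinite slope method
for multi-distance frequency-domain instruments: straight-line fits of
$\ln(r^2 \mathrm{AC})$ and phase against distance give slopes $S_{AC}$ and
$S_\phi$, whence

$$\mu_a = \frac{\omega}{2v}\Bigl(\frac{S_\phi}{S_{AC}} -
  \frac{S_{AC}}{S_\phi}\Bigr), \qquad
  \mu_s' = \frac{S_{AC}^2 - S_\phi^2}{3\mu_a} - \mu_a.$$

The estimates are invariant to detector gain and phase offset, which is what
makes the method practical on animals. `simulate_fd_record()` generates
records from the same asymptotic semi-infinite solution — the inversion is
exact on noiseless data, and the 3×3 grid round-trip in the test suite
verifies the pair. Frames failing the modulation QC (AC/DC ≤ 20% at any
distance) or producing slopes of the wrong sign are dropped rather than
propagated. Aggregation follows the measurement protocol: time-average per
record, then a median across records that excludes values beyond 1.5 IQR
from the quartiles.

Broadband absorbance is smoothed with a 15-sample boxcar (window truncated at
the spectrum edges) and calibrated to absolute $\mu_a$ by an affine
least-squares map against the FD-derived anchors in 700–900 nm. Whether the
original analysis used gain-only or gain+offset calibration is not
determinable; gain+offset is the default and `offset = FALSE` gives the
other convention.

The composition fit is a bounded least-squares problem. Although it is
naturally written in $(B, S, W, M, F)$, the model is linear in
$(BS, B(1-S), W, M, F)$, so the implementation optimizes the convex
transformed problem (L-BFGS-B with analytic gradient from the fixed midpoint
start, then an active-set polish) and maps back. This removes the flat
valley that makes the $(B,S)$ parametrization stall near $S \approx 0.9$
while changing nothing observable: residuals on noiseless in-bounds spectra
are zero to machine precision and the fit is deterministic. The default
lower bounds — 20% fat, 10% water — keep degenerate spectra in a
blubber-plausible regime; an all-zero spectrum pins $B, M, W, F$ at their
bounds and leaves $S$ at its (unidentifiable) midpoint. The power-law fit
initializes from the exact log–log linear solution and only then refines the
untransformed least squares, so noiseless data are recovered exactly.

## Phantom geometry

No imaging volume is distributed with the package, so the geometry stage is a
first-class synthetic-data generator. `generate_phantom()` builds a labeled
voxel volume from nested smooth shells: a superellipsoid body (default
semi-axes 110 × 130 × 220 mm, exponent 2.5 — about 260 mm dorsoventrally, so
that 50–120 mm separations and a ≥ 40 mm skin-to-brain distance are
geometrically realizable), a 20 mm blubber+skin shell, a 25 mm muscle layer
beneath it, and an ellipsoidal brain (40 × 35 × 45 mm semi-axes) placed
dorsally and caudally; everything between the muscle shell and the brain is
bone, so the brain is fully enclosed by the skull by construction, and a
minimum bone margin (default 15 mm) around the brain is validated at build
time. Layer membership uses the distance from each voxel center to the body
surface along its radial ray — exact for these star-shaped bodies. A
blowhole landmark on the dorsal midline (40 mm rostral of the brain center by
default) anchors the placement maps. The phantom is deterministic; a seed
only matters if the optional smooth surface perturbation is enabled.

What the phantom does *not* emulate: the melon, air sacs and decay-related
air pockets of a real specimen, asymmetries, and seasonal blubber-thickness
variation. Passing tests therefore demonstrate correct behavior of the
pipeline on a plausible layered geometry, not anatomical fidelity to any
individual animal; the single-specimen statistics quoted in the literature
(mesh node and channel counts) are reproduced only in order of magnitude.

`mesh_labeled_volume()` splits every tissue voxel into six right tetrahedra
(Kuhn/orthoscheme subdivision around a fixed diagonal), which is conforming
across voxels and nonobtuse — a property used directly by the solver (below).
A `target_element_volume` resamples the label grid to a coarser pitch first;
nodes carry the majority label of their incident voxels, elements the label
of their voxel. `scale_mesh(factor = 0.75)` produces the juvenile model:
coordinates, landmark and areas/volumes scale by the appropriate powers,
connectivity and labels are untouched.

## Forward model

The continuous-wave diffusion equation
$-\nabla\!\cdot\!(\kappa\nabla\Phi) + \mu_a\Phi = q$ is discretized with
linear tetrahedral elements; the boundary carries the Robin condition
$\Phi + 2A(n)\,\kappa\,\partial\Phi/\partial n = 0$ with the standard
critical-angle approximation for the internal-reflection factor $A$
(≈ 2.0 at $n = 1.37$, 2.9 at $n = 1.55$). Sources are point loads one
transport mean free path ($1/\mu_s'$) beneath the surface along the inward
normal; detector amplitudes are the fluence interpolated at the detector
surface position. All quantities are relative to a unit input source.

Two quadrature choices matter and were made deliberately:

* **Lumped absorption and boundary mass.** The $\mu_a$ term is integrated by
  nodal quadrature ($\mu_a(n)\,V(n)$ on the diagonal, $V(n)$ one quarter of
  each incident tetrahedron), and the Robin face term by the analogous
  area/3 rule. On nonobtuse meshes the resulting operator is an M-matrix, so
  the discrete maximum principle holds and computed fluence is positive
  everywhere — at the attenuation levels of this problem (amplitudes fall
  ten orders of magnitude over a 120 mm channel) a consistent-mass
  discretization produced oscillating, sign-violating far fields on
  affordable meshes. This is why the mesher insists on the orthoscheme
  subdivision.
* **Exact adjoint Jacobian.** With lumped absorption mass, the sensitivity
  of a channel amplitude to nodal absorption is exactly
  $J[c, n] = -\Phi_{\mathrm{src}}(n)\,\Phi_{\mathrm{det}}(n)\,V(n)$, where
  the detector field solves the adjoint (identical, symmetric) system with a
  point load at the detector. The finite-difference agreement asserted in
  the tests (≤ 1% at perturbation $10^{-4}$ mm$^{-1}$) is therefore a check
  of the solver chain, not of a quadrature approximation. Scattering
  perturbations are neglected, as appropriate for CW measurements.

Linear systems are solved by sparse supernodal Cholesky factorization, one
factorization per property assignment, reused across all source and adjoint
loads. A wavelength sweep re-assigns coefficient vectors on the fixed
geometry; the tests assert the geometry is bit-identical across the sweep.

**Accuracy and a known limitation.** Against the infinite-medium Green's
function, nodal fluence on a 2 mm homogeneous mesh is within 5% everywhere
at 10–30 mm from the source (the acceptance bound). Absolute surface
amplitudes, however, converge only first-order in the mesh pitch because the
Robin extrapolation length $2A\kappa \approx 1.3$ mm is comparable to
affordable pitches: halving the element volume moved a 60 mm-channel
amplitude by tens of percent while moving the TS index of the same channel
by 0.005%. Every reported metric (TS, Jacobian fractions, dynamic range) is
a ratio in which the amplitude-level error cancels; the refinement test in
the suite is therefore formulated on TS. Absolute powers ($P$, $\Delta P$)
should be read as order-of-magnitude quantities.

## Sensitivity metrics

Activation multiplies the target tissue's blood fraction ($B \to 1.1B$ by
default) and re-composes $\mu_a$ at the current wavelength — $\mu_s'$ is
blood-independent under the power law, so only absorption and $\kappa$
change, and only at target-tissue nodes. The four metrics are:

1. **TS index** $\mathrm{TS} = \log_{10}(\Phi_0/\Phi_{\mathrm{active}})$ per
   channel, from two full forward solves. For small activations
   $\mathrm{TS}\,\ln 10\,\Phi_0 \approx -J\,\partial\mu_a$ (verified to 10%
   at a 1% activation).
2. **Jacobian depth metric**: $\max|J|$ over target nodes divided by
   $\max|J|$ over all nodes, per channel — scale-free, in $[0, 1]$, and
   monotone in separation on layered phantoms.
3. **Flatfield reconstruction**: a uniform 1% absorption increase is
   forward-projected through $J$ for one separation bin and back-projected
   with the two-part diagonal regularization
   ($L = \mathrm{diag}(J^TJ) + \alpha$, $\alpha = 10^{-2}\max$;
   $M = \mathrm{diag}(\hat J\hat J^T) + \beta$, $\beta = 10^{-2}\max$;
   Tikhonov weight 1 on the identity, as printed — configurable, and a
   `sqrt_diag` flag provides the diag$^{1/2}$ convention some toolboxes
   use). The depth of the reconstructed maximum summarizes where that bin
   "looks"; percentage maps are normalized per group, since a global-across-
   groups normalization is equally defensible but not stated.
4. **Large-detector power**: a 100 mm² detector is emulated by a 51 × 51
   sub-detector grid (0.2 mm spacing) laid out in the local tangent plane
   and projected back to the surface; $P = (A/N)\sum\Phi_n$. From baseline
   and activated powers: $\Delta P = P_0 - P_{\mathrm{active}}$,
   $P_{\max}$, and the required dynamic range $P_{\max}/\Delta P$ (the
   reciprocal $\Delta P/P_{\max}$ is also emitted, since both orientations
   appear in practice).

Channel-level summaries average each metric over the top 1% of channels by
TS (ties broken by channel index, deterministically), with population
standard deviations (n, not n−1 — the choice is not observable in the
sources and is documented here once).

## Optode layout

Eleven equidistant slices along the body axis carry 21 radially equidistant
optodes each (angles snapped to the nearest surface node, so positions are
on the mesh surface by construction). Pruning to the 10 mm exclusion radius
is a greedy scan in placement order — ascending slice, then angle — keeping
the earliest optode of any conflicting pair; the rule is deterministic and
order-stable, and reproduces the intended outcome (a few candidates removed,
the rest alternating source/detector) without claiming to replicate an
unstated original rule. Channels are all source–detector pairs within
50–120 mm straight-line (chord) distance; chord rather than geodesic because
the forward model consumes point coordinates. Separation bins are half-open
10 mm intervals with the last bin closed. Midpoint polar coordinates put
180° at the dorsal midsagittal plane and measure longitudinal offsets
caudally from the blowhole landmark.

## Problem sizes and determinism

The package's own study conditions (the defaults of `sweep_config()`) are
the full 600–1700 nm grid in 50 nm steps, 50–120 mm separations in seven
bins, adult and juvenile scales, and a 10% brain activation. The analysis
drivers run this sweep on a 12 mm-voxel phantom with 5 × 11 optodes (about a
quarter hour on one CPU); the test suite uses 8–10 mm phantoms and small
benches chosen so the whole suite runs in a few minutes. These sizes trade
spatial resolution for tractability; the accuracy consequences are the
amplitude-level caveat above, which the ratio metrics absorb. Every stage is
deterministic given the configuration seed: reruns produce byte-identical
CSV output, which the suite asserts.

## Known limitations

* The chromophore basis is an approximate compilation; fitted compositions
  are exactly recoverable against this basis (the acceptance round trips),
  but comparisons to values fitted against other compilations can differ at
  the few-percent level.
* The phantom is a smooth idealization; placement maps and channel counts
  are qualitative analogs, not reproductions of any specimen.
* Absolute detector powers carry first-order mesh dependence (see above).
* The FD simulator is the asymptotic semi-infinite model without noise
  correlations, detector nonlinearity, or ambient-light terms; QC beyond
  modulation percentage and saturation is out of scope.
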