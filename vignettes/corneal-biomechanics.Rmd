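---
title: "Corneal biomechanics of pterygium traction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal biomechanics of pterygium traction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical question

A pterygium is vascularized conjunctival tissue that grows onto the anterior
cornea, usually from the nasal side. When the lesion regresses — for example
after beta-irradiation treatment — the shrinking tissue pulls tangentially on
the anterior corneal surface toward the limbus. Clinically this is associated
with induced astigmatism and central corneal flattening. `corneafem` asks the
biomechanical question quantitatively: given a patient's corneal tomography,
does a tangential limbus-ward pull of realistic magnitude on the pterygium
footprint reproduce the observed change in corneal shape?

The package builds a patient-specific finite-element model of the cornea plus
a scleral rim from anterior/posterior elevation maps, recovers its unloaded
(stress-free) configuration under intraocular pressure, applies the traction,
and reads off the clinical quantities an ophthalmologist would measure:
sagittal curvature maps, zone keratometry, astigmatism cylinder and axis,
best-fit-sphere elevation, pachymetry, anterior corneal wavefront
aberrations, and region-averaged tissue stress and strain.

## Tissue model

The strain energy per unit reference volume is

$$\Psi \;=\; U(J) \;+\; \bar\Psi_m(C_{10}) \;+\;
\frac{1}{\pi}\int_0^{\pi} \Phi(\theta)\,
\left[\bar\Psi_{f1}(\gamma_m,\mu_m) + \bar\Psi_{f2}(\gamma_k,\mu_k)\right]
d\theta ,$$

with:

* **Volumetric penalty** $U = \tfrac{\kappa}{2}(J-1)^2$. Corneal stroma is
  nearly incompressible; the penalty modulus defaults to $\kappa = 60$ MPa,
  three decades above $C_{10}$. At physiologic wall stress (~15 kPa) this
  keeps $|J-1| \lesssim 2\times10^{-4}$ while leaving the Newton systems well
  conditioned. (A much smaller penalty of a few MPa would allow volume errors
  above $10^{-3}$ at the same stress, which is why the larger value is the
  default.)
* **Matrix** $\bar\Psi_m = C_{10}(I_1 - 3 - 2\ln J)$, a compressible
  neo-Hookean form for the proteoglycan ground substance. In the
  incompressible limit its uniaxial response is the textbook
  $\sigma = 2C_{10}(\lambda^2 - 1/\lambda)$, which the test suite uses as a
  closed-form oracle.
* **Two fiber families** integrated over the in-plane angle $\theta$: the
  main collagen lamellae $(\gamma_m,\mu_m)$ and the cross-links
  $(\gamma_k,\mu_k)$, each with the Markert power-law potential
  $\psi_f(\lambda)=\frac{\mu}{\gamma}(\lambda^{\gamma}-1)-\mu\ln\lambda$,
  which is stress-free at $\lambda = 1$. Fibers act in **tension only**
  ($\lambda > 1$): collagen cannot support compression. The particular
  algebraic fiber form is a documented modeling choice within the
  fiber-reinforced framework this model family uses; it is selected for its
  zero-stress reference and monotone stiffening, not asserted to be
  bit-identical to any proprietary implementation.

Default constants (the human-cornea preset): $C_{10}=0.06$ MPa,
$\gamma_m=0.13$, $\mu_m=24.0$ MPa, $\gamma_k=0.08$, $\mu_k=95.0$ MPa. The
small-strain in-plane fiber stiffness implied by these is
$\mu_m\gamma_m + \mu_k\gamma_k \approx 10.7$ MPa, giving a tissue that at
15 kPa wall stress strains by about 1% — the physiologic range.

### Fiber distribution $\Phi$

$\Phi(\theta)$ is a probability weighting over fiber angles with
$\frac{1}{\pi}\int_0^\pi \Phi\,d\theta = 1$, so the angular integral is a
weighted average. X-ray scattering of human cornea shows two orthogonal
preferred directions (nasal–temporal and superior–inferior) centrally, a
circumferential annulus near the limbus, and stronger alignment in the
posterior stroma. The package parameterizes this as a mixture of an
isotropic floor and $\pi$-periodic von Mises peaks,
$\exp(b\cos 2(\theta-\mu))/I_0(b)$ — each analytically normalized — with

* orthogonal peaks at 0°/90° blending (logistic in planar radius, centered at
  4 mm with 1-mm width) into a single circumferential peak at the limbus,
* an anisotropic fraction growing linearly with normalized depth from 0.3
  (anterior) to 0.7 (posterior),
* concentration $b = 2$.

The exact peak widths and transition radius are not published alongside the
material constants, so they are exposed as configuration
(`fiber_distribution()`) with the above defaults; the solver also accepts a
uniform (isotropy-limit) and a single-direction distribution, used by the
test oracles. The angular integral uses a midpoint rule over
$[0,\pi)$ (default 32 points), which is spectrally convergent for these
smooth periodic integrands — doubling the order changes the energy by less
than $10^{-8}$ relative.

## Finite elements

Eight-node hexahedra in a total-Lagrangian formulation, 2×2×2 Gauss
quadrature. Near-incompressibility is handled by **mean dilatation**
(selective reduced integration): the penalty acts on the volume-averaged
Jacobian $\bar J$ of each element, with the exact rank-one coupling term in
the tangent. This prevents volumetric locking in bending. A consequence is
that pointwise $J$ at Gauss points may drift at the few-per-mille level in
sharp bending boundary layers (the clamped rim edge, traction-patch edges)
even though $|\bar J - 1| < 10^{-3}$ everywhere — a discretization effect
that shrinks under refinement, not a volume change the formulation fails to
penalize. The tests assert $|\bar J - 1| < 10^{-3}$ everywhere (the measure
mean dilatation enforces), pointwise $|J-1| < 10^{-3}$ over the central
3-mm clinical zone, and $J > 0$ everywhere.

The intraocular pressure is a **follower load** on the deformed posterior
surface (1 mmHg = 133.32 Pa; the physiologic 15 mmHg is 1999.8 Pa), including
its load-stiffness term — omitting it destroys the quadratic Newton tail.
The tangent is factorized by sparse Cholesky after symmetrization (the
follower-pressure stiffness of a pressure surface whose boundary ring is
fixed is conservative, so the skew part vanishes at convergence; an LU
fallback guards non-positive-definite excursions). Newton iterates to a
relative residual of $10^{-8}$ (configurable), with load stepping (default
3–5 steps) and adaptive step halving on divergence.

### Mesh

The cross-section is an O-grid — a structured central square block blended
through transition rings into exact concentric circles — avoiding the
polar-axis degeneracy of naive spherical meshes. Rings at and beyond 35% of
the radial parameter are exact circles, so the limbus ring and the 4-mm
scleral rim are circular. The template is a spherical cap (anterior radius
7.5 mm, uniform 0.55-mm corneal thickness) with the rim thickness ramping
smoothly (C1 smoothstep) to 0.75 mm — a C0 ramp would leave a curvature kink
that polynomial surface fits cannot represent. The default desk resolution
is ~3300 elements; the builder scales to the 35 000+ elements of
clinical-scale models, and the solver is verified to be resolution-convergent
(apex displacement changes < 2% on refinement), so desk-scale runs are used
throughout the tests.

The mesh cornea has a 9.0-mm diameter by default (not the full ~11.5-mm
anatomical cornea): tomography maps cover a 10-mm zone, and mesh warping
needs measured surface data over the whole corneal footprint. The scleral
rim is template geometry — it acts only as a boundary frame, fixed at its
outer edge — and the patient-specific warp displacement is tapered smoothly
to zero across it.

### Warping and prestress

Patient surfaces enter as Zernike expansions (OSA/ANSI double index,
unit-RMS normalization, order ≤ 12). The clinical analytics use the
conventional 8.0-mm zone; the *warping* surfaces are fitted over the full
9.5-mm data zone instead, because extrapolating an order-12 polynomial
beyond its fit zone amplifies high-order coefficients by
$(r/r_{zone})^{12}$ and is numerically unsafe in the presence of measurement
noise. Warping moves anterior/posterior boundary nodes axially onto the
target surfaces (interpolatory to < 0.5 µm) and displaces interior nodes by
linear through-thickness interpolation; element inversion is a hard error.

Because tomography measures the cornea *under* intraocular pressure, the
unloaded geometry is unknown. It is recovered by the classic fixed-point
iteration on the reference configuration,
$x_0 \leftarrow x_0 - \omega\,(\mathrm{inflate}(x_0) - x_{meas})$
with $\omega \in (0.5, 1]$ (default 1), iterated until re-inflation matches
the measured nodes to 1 µm. On the synthetic corneas of the test suite this
converges monotonically in 2–6 iterations.

### Traction

The retracting pterygium is modeled purely by its pull on the anterior
surface — the pterygium body itself is not meshed. Each footprint face
receives a traction toward the nearest limbus-ring point along the
footprint's central meridian, projected into the face tangent plane (zero
normal component by construction), weighted by face area and scaled so the
resultant equals the configured total force (default 30 mN, the magnitude
calibrated clinically for this treatment; it is a configuration value, not a
fitted output). The traction is applied as a dead load at fixed IOP. The
description of this pull oscillates between "pressure" and "tangential
force" in the clinical literature; the package implements it as a tangential
traction with a fixed resultant, which is the reading consistent with a
force quoted in millinewtons.

## Clinical analytics

* **Sagittal curvature** $C_S = (n-1)/R$ with the keratometric index
  $n = 1.3375$ and $R$ the distance from the surface point to the optical
  axis along the surface normal — implemented literally in this axial form.
* **Zone keratometry**: area-weighted means over the central 2.0-mm-radius
  disk and the 2.0–3.5-mm paracentral annulus.
* **Astigmatism**: meridional powers averaged per 1°-binned meridian over an
  annulus, then a $\cos 2\theta$ sinusoid fit; cylinder = steep − flat,
  axis = steep meridian. This reduces to the exact principal-power
  difference on torics and is noise-robust. Two annulus conventions appear
  in clinical practice (0.5–2.0 and 0.5–2.5 mm radius); both are supported,
  0.5–2.5 mm is the default, and on torics they agree to < 0.01 D.
* **Elevation**: signed normal distance to the best-fit sphere, which is
  apex-anchored with its center on the optical axis — a one-parameter,
  unconditionally stable fit.
* **Pachymetry**: distance along the anterior surface normal to the
  posterior surface, by a vectorized Newton ray intersection.
* **Wavefront**: $W = (n-1)\,(z_{ref} - z_{surf})$ over a 6-mm pupil with
  the pupil's best-fit sphere as reference, expanded in Zernike terms;
  named indices aggregate same-order terms by root-sum-square (spherical
  aberration is the signed $Z_4^0$), RMS-HOA covers radial orders ≥ 4.

## The synthetic tomography generator

Patient Scheimpflug data are not redistributable, so the generator is a
first-class module that emulates them: biconic anterior surfaces
$z = (x^2/R_x + y^2/R_y)\,/\,(1+\sqrt{1-(1+Q_x)x^2/R_x^2-(1+Q_y)y^2/R_y^2})$
on a 10-mm polar grid (Pentacam-like extent), a posterior surface offset
along the anterior normal by a thickness profile, optional Gaussian height
noise (single integer seed; bit-reproducible), and a parameterized
limbus-anchored wedge footprint with a rounded central apex (nasal = 0°
meridian toward $-x$ for a right eye).

Choices worth recording:

* The default spec ($R_x=R_y=7.59$ mm, $Q=-0.39$, 512 µm central / 660 µm
  peripheral thickness) targets a central sagittal power of ~44.15 D and
  paracentral ~43.28 D — the preoperative keratometry of the treatment case
  the package's defaults emulate. Higher-order patient shape is of course
  not reproducible from two numbers.
* The thickness profile interpolates **quadratically** in radius. A linear
  profile would put a cone singularity ($\propto |r|$) at the apex, which
  is unphysiologic and cannot be represented by a polynomial surface
  expansion (it leaves ~1 µm RMS and several µm of central error in an
  order-12 fit, breaking the generator's own round-trip property).
* The posterior offset is computed meridian-wise; the small azimuthal
  component of the normal on toric surfaces is neglected (sub-0.1 µm for
  clinical toricities).

What passing tests on these synthetics do **not** show: real corneas have
higher-order shape irregularity, spatially correlated (not i.i.d.) noise,
and individual material properties. The pipeline's quantitative outputs on
synthetic spheres demonstrate the mechanism and the numerics, not a
patient-specific prediction.

## What the simulation reproduces

On a spherical synthetic cornea with the default 30-mN nasal pull (desk
resolution, ~1300 elements, about half a minute of compute) the pipeline
yields: induced cylinder of a few tenths of a diopter with the steep axis
orthogonal to the pull meridian, central flattening of ~0.2 D, central
pachymetry stable to < 0.1%, and anterior-surface stress under the footprint
rising by tens of percent while the posterior surface is nearly unchanged —
the qualitative mechanism by which a retracting pterygium induces
astigmatism and flattening. All of these are recomputed, not stored, by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

The dose–response of the induced cylinder is monotone through the clinical
force range (roughly linear from 5 to ~35 mN) and then **saturates and
declines**: by 60 mN the stronger nasal pull slackens the circumferential
collagen of the orthogonal meridian (fibers carry tension only), that
meridian loses stiffness and flattens as fast as the pulled one, and the
differential — the cylinder — collapses even though central flattening keeps
growing linearly. This is a direct consequence of the tension-only fiber
constitutive choice, reproducible across mesh resolutions and solver paths;
it means "more force ⇒ more astigmatism" holds below the clinically
calibrated 30 mN but not at twice it.

## Numerical choices and degenerate inputs

* Unit system mm–N–MPa; conversions (mmHg → MPa, mN → N) are single
  documented constants.
* Zernike fits are QR-based with an explicit conditioning guard; clustered
  or meridian-poor sampling raises an error, and the mesh-surface fitting
  path degrades the order in steps of two rather than interpolating noise.
* Apex singularities (axial curvature at $\rho \to 0$, polar-grid pole) are
  avoided by cell-centered grids that never sample $\rho = 0$.
* A plane (infinite axial radius) maps to 0 D and is flagged rather than
  propagating infinities.
* Zero-width footprints, footprints outside the limbus, inverted elements,
  non-convergent Newton or fixed-point loops are all hard errors with
  diagnostic payloads, never silent.

## Known limitations

* Material properties are population-level, not patient-identified.
* The model covers the anterior segment only (cornea + 4-mm rim, rim edge
  fixed), with a uniform 15 mmHg IOP held constant through treatment.
* Radiation–tissue interaction is not modeled; the treatment enters only as
  the mechanical traction of the regressing tissue.
* The exact in-vivo fiber field and the cross-link direction structure are
  parameterized qualitatively, not imaged per patient.
* Wavefront trefoil/tetrafoil of real corneas are dominated by higher-order
  shape the two-parameter synthetic spec cannot carry.
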