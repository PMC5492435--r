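# corneafem

Patient-specific finite-element simulation of the corneal shape change caused
by a retracting pterygium, with full clinical topography analytics.

A pterygium is conjunctival tissue growing onto the anterior cornea, usually
nasally. When it regresses after treatment, the shrinking tissue pulls
tangentially on the corneal surface toward the limbus; clinically this
induces astigmatism and central corneal flattening. `corneafem` models that
mechanism quantitatively, for biomechanics researchers and computational
ophthalmology groups: it builds a 3-D hexahedral finite-element model of the
cornea plus a 4-mm scleral rim from anterior/posterior elevation tomography,
recovers the stress-free configuration under intraocular pressure, applies
the pterygium's tangential pull, and reports what a topographer would
measure.

## The model

Tissue is an anisotropic fiber-reinforced hyperelastic solid,

$$\Psi = \tfrac{\kappa}{2}(J-1)^2 + C_{10}(I_1 - 3 - 2\ln J)
  + \frac{1}{\pi}\int_0^{\pi}\Phi(\theta)\,[\psi_{f1}(\lambda_\theta)
  + \psi_{f2}(\lambda_\theta)]\,d\theta,$$

a volumetric penalty (near incompressibility), a neo-Hookean matrix, and two
tension-only Markert power-law collagen families —
$\psi_f(\lambda)=\frac{\mu}{\gamma}(\lambda^\gamma-1)-\mu\ln\lambda$ — whose
directions are weighted by an angular distribution $\Phi$ (orthogonal peaks
centrally, circumferential at the limbus, depth-dependent). Human-cornea
constants: $C_{10}=0.06$ MPa, $\gamma_m=0.13$, $\mu_m=24$ MPa,
$\gamma_k=0.08$, $\mu_k=95$ MPa.

The solver is total-Lagrangian Newton with mean-dilatation hexahedra,
follower intraocular pressure (15 mmHg = 1999.8 Pa) with its load stiffness,
fixed-point recovery of the unloaded geometry (tomography measures the
pressurized eye), and a tangential limbus-ward traction with a fixed
resultant (30 mN clinically) on the pterygium footprint.

Analytics follow clinical conventions: sagittal curvature $C_S=(n-1)/R$ with
$n=1.3375$, Zernike surface expansion (OSA/ANSI, order 12, 8-mm zone),
cylinder/axis from a meridional $\cos 2\theta$ fit over a 0.5–2.5-mm
annulus, apex-anchored best-fit-sphere elevation, pachymetry along surface
normals, and 6-mm-pupil anterior wavefront indices.

Because Scheimpflug patient data are not redistributable, a synthetic
tomography generator (biconic/toric surfaces, thickness profile, seeded
noise, parameterized nasal footprint) makes the whole pipeline testable.

## Worked example

```r
library(corneafem)

# a spherical synthetic cornea (44.06 D everywhere), nasal 30-mN pull
pair <- make_synthetic_cornea(synthetic_cornea_spec(Rx = 7.66, Ry = 7.66,
                                                    Qx = 0, Qy = 0))
res <- simulate_treatment(pair, simulation_config())
print(res)
```

```
Pterygium traction simulation
  preop:     K central 44.06 D, paracentral 44.05 D, cyl 0.00 D @ 90 deg
  predicted: K central 43.83 D, paracentral 43.92 D, cyl 0.13 D @ 90 deg
  delta cyl +0.13 D, delta central -0.23 D, pachymetry -0.03%
  stress central 3-mm: 13.3 -> 15.4 kPa; footprint anterior: 11.0 -> 15.7 kPa (+42.7%)
```

Reading this: the 30-mN nasal pull flattens the pulled (horizontal) meridian
more than the vertical one, inducing 0.13 D of cylinder with the steep axis
at 90° (orthogonal to the pull) and 0.23 D of central flattening, while
central pachymetry stays put; tissue stress rises in the central 3-mm zone
and by ~40% in the anterior surface layer under the footprint. That is the
clinical mechanism — astigmatism plus central flattening from a tangential
pull — reproduced from first principles on a featureless sphere.

`write_result(res, "out/")` exports a JSON summary, curvature-map CSVs and
VTK fields; `compare_to_followup()` scores a prediction against follow-up
tomography. A thin CLI (`inst/cli/corneafem.R`) wraps the same functions
(`synth`, `simulate`, `analyze`, `compare` subcommands with a YAML config).

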