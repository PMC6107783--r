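---
title: "Methods: virtual translesional pressure ratios for stenosed renal arteries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual translesional pressure ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Renal artery stenosis (RAS) alters renal haemodynamics, but angiographic
severity ("diameter stenosis %") correlates poorly with the physiological
significance of a lesion. The clinical reference standard is the
translesional resting pressure ratio Pd/Pa — mean pressure distal to the
stenosis over mean proximal pressure, measured invasively with a pressure
wire — with Pd/Pa ≤ 0.9 taken as physiologically significant. `stenoflow`
implements a non-invasive, *in silico* estimate of this quantity: a
stenosed-vessel geometry is meshed, the steady incompressible
Navier–Stokes equations are solved for Newtonian blood under physiological
boundary conditions, and a virtual Pd/Pa (vPd/Pa) is read off
cross-sectional pressure planes that mirror the catheter protocol. A
statistics layer quantifies agreement and diagnostic accuracy of virtual
against measured ratios for a paired validation cohort.

Because the package works from parametric synthetic geometries rather than
patient CT reconstructions, its solved pressure ratios characterize the
method — the solver, the measurement protocol, their convergence and
invariances — not any patient. The packaged validation cohort of seven
measured/virtual pairs is printed study data and is analysed, not
recomputed.

## Geometry synthesis

`build_stenosed_vessel()` composes a centerline (straight, circular bend,
or bend plus a seeded smooth tortuosity perturbation) with an axisymmetric
radius profile
\[
r(s) = \tfrac{D}{2}\Big(1 - \sum_k \tfrac{\sigma_k}{100}\,
  \beta\!\big(\tfrac{s - c_k}{\ell_k/2}\big)\Big),
\qquad \beta(u) = \tfrac12\big(1 + \cos \pi u\big)\,\mathbf 1_{|u|\le 1},
\]
where \(\sigma_k\) is the percent *diameter* stenosis, \(c_k\) the throat
position and \(\ell_k\) the constriction support. The cosine bell is a
design choice — lesion shape is not observable from a single severity
number — and is C¹, so the mesher never sees a kink; the shape function is
pluggable. Severity is defined against the healthy reference diameter, so
`percent_diameter_stenosis()` inverts the construction exactly and
severities round-trip to 0.1%.

The default `renal_vessel_template()` is a desk-scale renal-artery
stand-in: D = 5 mm, L = 40 mm, a 30° planar bend (renal arteries are
tortuous), and a single ostial stenosis centered 5 mm from the inlet,
because real renal stenoses cluster at the ostium. The constriction
support is 6 mm: with the throat at 5 mm this leaves a ~2 mm healthy
segment at the inlet for the proximal pressure plane; a longer support
would push the lesion into the inlet boundary itself, where the plug
Dirichlet condition would contaminate the proximal pressure. Tortuosity
(optional, seeded) adds three low-frequency transverse modes with
amplitude 0.15 of the radius, re-parameterized to arc length;
identical seeds give bit-identical geometry.

## Meshing

`generate_volume_mesh()` sweeps a polar cross-section template along the
centerline's parallel-transport frames and splits the resulting triangular
prisms into tetrahedra using the minimal-global-index diagonal rule, which
forces neighbouring prisms to agree on their shared quad diagonal and so
yields a conforming mesh by construction. This boundary-fitted structured
strategy replaces an octree mesher; it is deterministic and suited to tube
topology. Near-wall resolution uses `n_wall_layers = 5` radially graded
rings (growth ratio 1.2, thinnest at the wall) occupying 30% of the local
radius — a structured emulation of prismatic boundary layers. The default
target density is 200 elements/mm³, counted as cell count over the
analytic lumen volume \( \pi\int r(s)^2\,ds \); resolution integers are
chosen by a scan so the achieved density lands within ±20% of target.

Axial stations are graded (`axial_grading = TRUE`): station density is
proportional to the local area contraction \((R/r)^\gamma\) (γ = 1) and
that weight is carried, with linear decay over 10 mm, into the
post-stenotic zone — the functional analogue of octree refinement around
the throat and jet, where essentially all of the pressure loss is decided.
For an unobstructed vessel the spacing is uniform.

## Flow model and discretization

Blood is Newtonian (μ = 0.0035 Pa·s, ρ = 1066 kg/m³), the wall rigid with
no-slip, and the flow steady, laminar and incompressible. Boundary
conditions mirror resting renal physiology: a plug (uniform) inlet
velocity carrying the prescribed flow, and an outlet that is either a
fixed pressure or a peripheral resistance, \(P_{out} = P_{ref} + R\,Q\),
re-evaluated every nonlinear iteration. The packaged synthetic resting
waveforms (one heart cycle of flow and distal pressure; cycle means
500 mL/min and 13.1 kPa) supply defaults: their trapezoidal time averages
feed the steady case, and their ratio gives the default peripheral
resistance ≈ 1.57 × 10⁹ Pa·s/m³. Hyperaemic conditions are deliberately
not modelled.

The discretization is stabilized equal-order P1–P1 finite elements on the
tetrahedral mesh: SUPG on momentum and PSPG on continuity with
\(\tau = \big((2|a|/h_a)^2 + (4\nu/h^2)^2\big)^{-1/2}\), plus a
residual-based discontinuity-capturing viscosity (Codina-type, capped at
the first-order upwind level and ramped in only for element Reynolds
numbers above 20–60) that damps the under-resolved post-stenotic jet while
leaving resolved viscous flow untouched. Because the Galerkin continuity
term is not integrated by parts and pressure carries no Dirichlet
condition, summing the discrete continuity rows telescopes to
\(\int_\Omega \nabla\!\cdot u_h = 0\) exactly: converged solutions
conserve mass between inlet and outlet patches to machine precision, which
the tests verify.

The nonlinear loop is Picard with adaptive pseudo-time damping: a local
CFL number starts at 5, grows while the residual contracts and is cut back
(with trust-region memory) when a step diverges; the sparse LU
factorization (Matrix, natural ordering on the banded interleaved dof
layout) is reused across iterations as a quasi-Newton preconditioner and
refreshed when contraction degrades. Below a residual of 0.1 the
linearization switches to Newton (the convective cross-term enters the
matrix with a compensating right-hand side so the tracked residual remains
the true steady residual), the capturing viscosity field is frozen below
1e-2, and below 3e-3 damping is dropped entirely — pure Newton converges
to steady states even when they are unstable in time. The default
tolerance is a relative steady residual of 1e-5. For severely stenosed
cases at coarse resolution the practical residual floor is ≈ 1e-3 (the
jet's shear layer is at the edge of resolvability), so sweep runs use a
tolerance of 2e-3; the reported pressures are stable to ~1e-5 relative
well before that point.

Interior cross-sectional fluxes agree with each other to well under 0.5%,
but differ from the inlet-patch facet integral by an O(h) amount
concentrated in the first element layer, where the imposed plug profile
adjusts to the no-slip rim; conservation statements therefore compare
either boundary patches with each other or interior planes with each
other, and the vignette flags this as the one place where "inlet flow" is
representation-dependent.

## The measurement protocol

`extract_pd_pa()` mirrors the catheter protocol. Three distal planes are
placed 10, 15 and 20 mm past the stenosis end (the catheter measurement
range is 10–20 mm; the exact three offsets are a package choice), each a
cross-section normal to the centerline; Pd is their arithmetic mean, and
the plane-to-plane standard deviation is reported as a protocol
variability measure. The proximal plane prefers two reference diameters
upstream of the throat (and at least one diameter from the inlet) to
escape the Bernoulli acceleration zone; for ostial lesions where that
point does not exist, it falls back to 0.8 × the constriction start,
clear of the inlet boundary. Plane averages integrate the linear nodal
fields exactly over polygonal plane–cell intersections. Significance uses
the clinical threshold Pd/Pa ≤ 0.9 applied to values rounded to two
decimals — the convention under which a measured 0.903 counts as
significant, which is required to reproduce the validation cohort's
printed confusion matrix.

## Validation statistics

Differences are measured − virtual; their mean (+0.015 on the packaged
cohort) and SD (n−1 denominator; 0.087) define the Bland–Altman limits at
mean ± 2 SD, and the 95% CI of the mean difference uses the Student t
quantile with n−1 degrees of freedom (±0.08 on 7 pairs — a normal
approximation does not reproduce this). Diagnostic metrics come from the
confusion matrix of threshold classifications with measured as reference;
each proportion carries an exact Clopper–Pearson 95% interval (the
qbeta closed form, validated against `binom.test` and by simulated
coverage). On the packaged cohort one case is discordant — measured 0.958
(negative) against virtual 0.862 (positive), a false positive — giving
sensitivity 1.0, specificity 2/3, PPV 0.8, NPV 1.0, accuracy 6/7 ≈ 86%.
Two percentage-error conventions (MAE over mean measured, 7.1%; mean
case-wise relative error, 7.7%) are both computed and reported side by
side, since they genuinely differ on this cohort and neither is
privileged. The OLS best-fit line of virtual on measured backs the
correlation figure.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately modest
resolutions chosen to exercise every claim at desk scale: the Poiseuille
benchmark (straight tube, Re 50) at 40 elements/mm³, where the pressure
drop between developed-flow planes matches \(8\mu L Q/(\pi R^4)\) within
2%; the severity sweep {0, 20, 40, 60, 72}% at 20 elements/mm³ (each case
solved from the standard cold start — a field transferred between
different lesions tends to start the iteration in an oscillatory basin);
and the 72% grid-convergence pair at 20 and 40 elements/mm³, where the
fine solve is warm-started from the coarse solution through the
structured (arc length, ring fraction, angle) parameterization. The mesher
contract itself is checked at the full default 200 elements/mm³ (meshing
only). Degenerate inputs (zero-length vessels, overlapping stenoses,
severity ≥ 100%, infeasible densities, inverted cells, planes missing the
lumen) fail fast with specific errors rather than propagating.

## What the synthetic generator does and does not emulate

The generator reproduces the gross anatomy that drives translesional
pressure loss — calibre, lesion severity and extent, ostial location,
moderate tortuosity — and none of the features of real reconstructions:
lumen eccentricity and non-circular cross-sections, plaque irregularity,
branching (the aorta and contralateral artery are deliberately out of
scope), or patient-specific boundary conditions. Passing tests therefore
demonstrate that the pipeline solves the stated model correctly and
reproduces the study's statistical layer exactly; they do not demonstrate
patient-level predictive accuracy, which in the underlying study design
comes from CT-derived anatomy that a synthetic template cannot stand in
for. For the same reason the solved vPd/Pa of the synthetic 72% template
(≈ 0.4–0.6 at resting renal flow) is much lower than the printed
patient values at comparable nominal severities: a smooth axisymmetric
cosine throat at 500 mL/min is haemodynamically harsher than the eccentric,
visually-graded lesions of real arteries — an illustration of exactly the
anatomy/physiology dissociation that motivates pressure-based assessment.

## Known limitations

* Steady laminar flow only; jet Reynolds numbers at the severe end of the
  sweep reach the transitional range, where the capturing viscosity acts
  as a crude surrogate for turbulent dissipation.
* First-order spatial accuracy in the jet region; grid convergence of
  vPd/Pa for severe stenoses is slow, and the shipped convergence pair
  documents the achieved level rather than asymptotic exactness.
* The plug inlet and the rim no-slip collide in the first element layer;
  inlet-adjacent pressure planes should respect the documented fallback
  rules.
* Resistance outlets assume a fixed distal reference pressure; no
  compliance or inertance (no Windkessel), matching the steady model.
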