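---
title: "Methods: patient-specific ATAA biomechanics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-specific ATAA biomechanics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ataamech)
```

`ataamech` reimplements, at desk scale, the computational chain used to
study the biomechanics of an ascending thoracic aortic aneurysm (ATAA):
material identification from planar biaxial tests, clinically calibrated
lumped-parameter circulation, a surrogate wall-stress model including the
ventricular traction and bending mechanism, and quadrant-wise stress
summaries. This vignette is the package's own account of the science: the
models, the assumptions, the parameters that matter, and the choices made
where the design was genuinely open.

## The constitutive model

The passive wall is modelled with the invariant-based anisotropic
hyperelastic strain-energy function of Holzapfel–Ogden type,

$$\Psi = \frac{a}{2b}\left\{e^{b(I_1-3)}-1\right\}
 + \sum_{i=f,s}\frac{a_i}{2b_i}\left\{e^{b_i(I_{4i}-1)^2}-1\right\}
 + \frac{a_{fs}}{2b_{fs}}\left\{e^{b_{fs}I_{8fs}^2}-1\right\},$$

with eight material descriptors: an exponential isotropic matrix term
($a$ in MPa, $b$ dimensionless), exponential fiber terms along the fiber
axis $f$ and the sheet axis $s$, and a fiber–sheet coupling term. For the
aneurysmal aorta the coupling is switched off ($a_{fs}=b_{fs}=0$), and the
reference descriptors are $a=0.24$ MPa, $b=6.6$, $a_f=0.05$ MPa, $b_f=5.0$,
$a_s=0.02$ MPa, $b_s=2.0$ (`ataa_params()`).

Choices worth making explicit:

* **Energy normalisation.** The isotropic term is written with a $-1$
  inside the braces so that $\Psi=0$ at the identity deformation. The
  alternative (no $-1$) differs by the constant $a/2b$ and carries no
  stress; the normalised form makes the zero-energy reference test exact.
* **Fiber/sheet axes.** The fiber axis lies in the wall tangent plane at
  $\gamma = 34°$ from the circumferential direction (the aneurysmal value;
  42° is the healthy reference). The sheet axis is taken orthogonal to $f$
  in the tangent plane. The alternative reading — two symmetric families at
  $\pm\gamma$ — makes $I_{4f}\equiv I_{4s}$ and removes the identifiability
  of $(a_s, b_s)$ from biaxial data, so it is noted but not implemented.
* **Tension-only anisotropy.** The $I_4$ terms contribute only when
  $I_4>1$, the standard switch preventing nonphysical stiffening of
  compressed fibers. The energy stays $C^1$ across the switch because the
  fiber terms are quadratic in $(I_4-1)$ near the switch point.
* **Incompressibility and plane stress.** Biaxial specimens are thin:
  incompressibility is enforced exactly through
  $\lambda_r = 1/(\lambda_c\lambda_l)$ and the hydrostatic multiplier is
  eliminated by the zero radial-stress condition. The measured first
  Piola–Kirchhoff normal components are then exactly the partial
  derivatives of the condensed energy
  $\hat\Psi(\lambda_c,\lambda_l)$ — which is also how the test-suite oracle
  checks the analytic stresses by central finite differences (relative
  agreement better than $10^{-5}$ over stretches 0.95–1.20).
* **Units.** The constitutive layer works in MPa throughout; conversions
  to kPa and mmHg happen only at module boundaries (1 mmHg = 0.133322 kPa).

## Biaxial data and fitting

The test emulated is a displacement-controlled planar equibiaxial protocol
on a 15 × 15 mm square specimen (37 °C saline bath, 1 mm/min crosshead,
7% preconditioning strain), reported as Green strain
$E = \varepsilon + \varepsilon^2/2$ and first-PK stress in both material
directions. Soft-tissue curves from hook-mounted specimens are trusted
only up to a maximum engineering strain — 0.18 here — so
`truncate_to_window()` drops samples beyond the cutoff in either direction
before fitting.

`fit_ho()` minimises the pooled sum of squared first-PK residuals of both
directions (equal weights; no weighting scheme is claimed by the protocol)
with all free parameters bounded below by zero, using bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), which solves the
same box-constrained nonlinear least-squares problem as trust-region
reflective solvers. Exponential fiber models are multi-modal, so the
solver restarts from 8 log-uniformly perturbed starting points (factor
$10^{\pm 0.5}$, seeded) and keeps the best converged solution; the
accepted-objective trace is monotone by construction and asserted in the
tests. Goodness of fit is reported as the pooled Pearson correlation $r$
and a normalised RMSE; since no normalisation is canonical, the RMSE is
divided by the range (max − min) of the pooled measured stresses, the
conventional choice that yields a dimensionless score.

Fitting residuals are formed on first-PK stresses (the measure biaxial
rigs report), not Cauchy stresses. With equibiaxial-only data the two
fiber families share the same invariant ($I_{4f}=I_{4s}=\lambda^2$) and
are distinguished only through their different direction weights
($\cos^2\gamma$ vs $\sin^2\gamma$), so the split between $(a_f,b_f)$ and
$(a_s,b_s)$ is weakly identified under noise; the isotropic pair $(a,b)$
is robust. This is why recovery checks average the fitted descriptors over
20 replicate noisy datasets: at 2% multiplicative noise the replicate mean
recovers $a$ and $b$ to a few percent and $a_f$ to roughly 10–20%, while
single-replicate $a_f$ estimates scatter widely. The quoted experimental
fit quality of the original study ($r=0.93$, NRMSE 0.375) belongs to an
unreleased dataset and is not reproducible; the package asserts
recovery-style checks instead.

## The lumped circulation

The circulation is a closed-loop, two-state ODE model: a time-varying
elastance left ventricle $p_{lv}=E(t)\,(V-V_0)$ with a smooth
double-cosine activation over the 0.3 s systolic window, ideal-diode
mitral and aortic valves, a constant-pressure venous reservoir
(10 mmHg) feeding through a small mitral resistance, and a 3-element
Windkessel afterload: characteristic impedance $Z_c$ in series with the
parallel $R_{total}$–$C$ compartment, with $Z_c = 0.05\,R_{total}$ (a
standard split). Integration uses `deSolve` (lsoda, tolerances $10^{-8}$)
beat by beat; the run is declared periodic when every per-beat metric
changes by at most $2\times10^{-4}$ (relative) between consecutive beats —
deliberately much stricter than a visual steady-state rule, so that the
per-beat volume balance closes to well under $10^{-3}$.

**Calibration** applies the clinical formulas directly:
$R_{total} = \mathrm{MAP}/\mathrm{CO} = 102/4.9 = 20.8$ mmHg·min/L and
initial $C = \mathrm{SV}/(\mathrm{SBP}-\mathrm{DBP}) = 64/48 = 1.33$
mL/mmHg. The record's stated body-surface area is not available, so the
stroke volume enters unindexed; BSA appears only in the valvulo-arterial
impedance, configurably.

**Beat period.** The record gives 60 bpm; the original simulation protocol
quotes a 0.8 s cycle (75 bpm) — an internal inconsistency of the source
data. `calibrate()` derives the period from the record's own heart rate
(1.0 s here; any period can be passed explicitly). The reason is
structural, not cosmetic: for the periodic solution the Windkessel
identity forces mean aortic pressure $= R_{total}\times SV \times HR$.
With $R_{total}$ fixed by the printed formula, reproducing the record's
MAP requires $SV\times HR = CO$; only the record's own heart rate makes
that compatible with a 60% ejection fraction at an end-diastolic volume of
136–138 mL ($CO/HR = 81.7\ \mathrm{mL} \approx 0.60\times137$). At 0.8 s
the same identity would force $SV=65$ mL and an ejection fraction of 48%.

**Aortic pressure node.** The pressure matched to the cuff values and
reported as "aortic" is the Windkessel compartment pressure — the arterial
pressure distal to $Z_c$, i.e. the cuff-equivalent site — while $Z_c$
shapes the ejection flow. Reporting the proximal node
($p + Z_c q$) instead makes systolic pressure a flow spike and degrades
every calibrated metric; this was checked numerically, not assumed.

**Refinement.** `refine_to_cuff()` retunes three knobs with damped
multiplicative quasi-Newton (secant-type) steps, each knob paired with the
quantity it dominates at first order: arterial compliance on the pulse
pressure ($PP \sim SV/C$), peak elastance (the per-beat forward volume) on
the mid-pressure, and diastolic elastance on the end-diastolic volume
($EDV - V_0 \approx P_{ven}/E_{min}$). The EDV target sits inside the
admissible 136–138 mL band at the point bringing the ejection fraction
closest to its prescribed 60% ($EDV = \mathrm{clamp}(SV/0.6, 136, 138)$) —
the same rule the source protocol states (EF *set* to 60% with EDV
136–138 mL). Convergence is declared when simulated systolic and
diastolic pressures are within 1 mmHg of the record; a zero tolerance is
refused (floating-point pressures cannot match exactly) and
non-convergence returns the best parameters found, flagged.

**A known, structural discrepancy.** Once systolic and diastolic pressure
are matched to 132/84 mmHg, the *time-averaged* aortic pressure of any
RC-type diastolic decay between those fixed endpoints equals their
logarithmic mean, $(132-84)/\ln(132/84) = 106.3$ mmHg, independent of the
RC constant — the systolic phase adds slightly more. The cuff MAP of
102 mmHg is an oscillometric estimate
($\mathrm{DBP} + 0.375\,\mathrm{PP}$), not a waveform integral, so the
calibrated model's time average (~107 mmHg) sits systematically above it,
and the stroke volume ($\approx 85$ mL) and ejection fraction
($\approx 62\%$) inherit the same few-percent offset through the
Windkessel identity. The package reports these as computed; forcing the
time average to 102 would instead miss both cuff pressures by ~5 mmHg.

**PV metrics.** `pv_metrics()` reports EDV, ESV, SV, EF, stroke work (the
shoelace area of the $(V, p_{lv})$ loop, traversed counterclockwise), and
the valvulo-arterial impedance $Z_{va} = p_{lv}^{\mathrm{peak\,ej}} /
(SV/\mathrm{BSA})$; with no BSA supplied, $Z_{va}$ is omitted with a
warning rather than guessed.

## The wall-stress surrogate

The ascending aneurysm is idealised as a thin-walled curved tube (outer
diameter 54 mm, wall 2.1 mm, length 105 mm). Three longitudinal-stress
contributions superpose linearly:

$$S_L(\theta, \text{surface}) = \underbrace{\frac{p\,r}{2t}}_{\text{closed-end membrane}}
 + \underbrace{\frac{F}{2\pi r t}}_{\text{ventricular traction}}
 \pm \underbrace{\frac{M r \cos(\theta-\theta_M)}{I}}_{\text{arc bending}},
 \qquad I = \pi r^3 t,$$

with the $+$ on the inner and $-$ on the outer surface, and the
circumferential stress is the Laplace value $S_C = p r/t$ (so
$S_C = 2 S_L^{\text{membrane}}$ exactly). The traction force cycles
between 1.28 N (relaxation) and 1.92 N (peak contraction), accompanying a
systolic root displacement of 8.2 mm. The bending couple
$M = F \times \text{moment arm}$ abstracts the distal tethering of the
supra-aortic vessels into a single lever-arm parameter — the only quantity
the stress formula needs — with its axis at the major curvature
($\theta_M = 270°$). This reproduces the two qualitative mechanisms of
interest: the longitudinal-stress maximum on the major curvature, and,
when the bending term exceeds the membrane-plus-traction stress, a
transmural sign change (tensile intima, compressive adventitia) in the
quadrants facing the moment. Axial equilibrium holds by construction and
is asserted by quadrature in the tests (cross-section integral of $S_L$
equals $p\pi r^2 + F$ to well under 0.5%); the bending term integrates to
zero net force. No claim is made to reproduce finite-element stress
magnitudes (e.g. >250 kPa circumferential peaks), which depend on the full
3D solve; the surrogate covers the sign structure and location of extrema
only.

## Sections, quadrants, and transmural differences

Stress fields are point clouds with a normalised centerline arclength
$s\in[0,1]$, an angle $\theta$ (0° anterior, 90° minor curvature, 180°
posterior, 270° major curvature), a surface label, and $S_C$, $S_L$ in
kPa. Three cross-sections are taken at $s = 0.05, 0.50, 0.90$ (near the
sino-tubular junction, mid-ascending aorta, just before the
brachiocephalic trunk — the source names anatomy, not coordinates, so the
fractions are this package's choice) with a ±2.5% arclength band, clipped
at the domain boundary. Each section is split into eight 45° quadrants
centred on the anatomical directions (quadrant $k$ spans
$[45(k{-}1){-}22.5°, 45(k{-}1){+}22.5°)$), and the arithmetic mean of each
component per (section, quadrant, surface) cell is tabulated — 48 rows per
phase per component. Whether the original polar plots used means, medians,
or nodal picks is unstated; the mean is implemented. Empty cells are
reported as missing, never as zero. Inner/outer identity comes from an
explicit point label rather than geometric inference, for robustness.
`transmural_delta()` reports inner-minus-outer differences and flags
cells with tensile-inner / compressive-outer sign change.

## The synthetic-data module

`gen_biaxial()` emulates the equibiaxial protocol: a uniform
engineering-strain ramp (default 30 points to 0.18), analytic stresses,
and multiplicative lognormal noise with a 2% coefficient of variation —
lognormal because soft-tissue stress noise is heteroscedastic and
positive; the protocol itself states no noise model. `gen_patient_record()`
returns the fixed study record (132/84/102 mmHg, 64 mL, 4.9 L/min, 60 bpm,
414 mm² orifice). `gen_wall_mesh()` embeds the surrogate stresses on a
curved-tube (torus-segment) point cloud with both surfaces, writable as
legacy-ASCII VTK (written with 17 significant digits so doubles
round-trip exactly; the reader restores the tibble losslessly). All
generators are bit-reproducible under a fixed seed and never disturb the
caller's RNG stream.

What the generators do *not* emulate — and what passing tests therefore do
not show about real data: hysteresis and preconditioning history in the
biaxial curves, hook/suture stress concentrations, specimen-to-specimen
heterogeneity, wall thickness variation and residual stress in the vessel,
measured aortic waveform shapes, and any imaging-derived geometry. The
recovery tests demonstrate that the estimation machinery is correct and
well-conditioned at the stated noise level, not that the material model is
identifiable from arbitrary experimental data.

## Numerical choices and problem sizes

* Fitting: 8 multistarts, ≤200 LM iterations, `ftol = ptol = 1e-12`,
  exponents capped at 100 (beyond which the exponentials overflow);
  parameter lower bounds at $10^{-8}$. Degenerate data (all-zero stress)
  produce a flagged result, not an exception.
* ODE: lsoda with `rtol = atol = 1e-8`, 2 ms output sampling, ≤30 beats,
  periodicity at $2\times10^{-4}$ relative beat-to-beat change.
* Refinement: ≤25 iterations, exponents 0.8–1.2 on the multiplicative
  updates (damping chosen once for monotone convergence on the study
  record; it converges in 5–10 iterations).
* Recovery experiments use 20 replicate seeds of 30-point datasets — about
  two minutes of fitting — and the quadrant demonstrations use 40 × 36 × 2
  point meshes; both sizes were chosen as the smallest that make the
  statistics stable.
* Ties and edge cases: quadrant boundaries are half-open; section bands at
  the domain edge are clipped; the strain-window cutoff is inclusive.

## Known limitations

The circulation is open-loop on the venous side (constant filling
pressure) and has no atria, pulmonary circuit, or baroreflex; valves are
ideal diodes. The wall surrogate is membrane + beam superposition on an
idealised tube — no residual stress, no thickness variation, no
viscoelasticity, no contact with surrounding structures. The fitted
fiber-family split is weakly identified from equibiaxial data alone
(planned-protocol limitation, not an implementation one); non-equibiaxial
stretch ratios would condition it better. And as discussed above, a
cuff-calibrated lumped model reproduces cuff systolic/diastolic pressures
exactly but its waveform time-average necessarily exceeds the
oscillometric mean estimate.
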