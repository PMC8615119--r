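# ataamech

Patient-specific biomechanics of the ascending thoracic aortic aneurysm
(ATAA), as a desk-scale, fully testable R pipeline.

Clinical risk assessment of ATAAs increasingly leans on patient-specific
computational models that join three ingredients: the **wall material**,
identified from planar biaxial tests on resected tissue; the **systemic
circulation**, calibrated from routine cuff and echo measurements; and the
**wall stress state**, including the often-neglected longitudinal stresses
produced by the beating heart tugging on the aortic root. `ataamech`
implements that chain end to end with a seeded synthetic-data module in
place of patient data and of the commercial finite-element solve, so every
stage runs, and is verified, on any machine.

## What is inside

**Constitutive core** — the invariant-based anisotropic hyperelastic
(Holzapfel–Ogden) strain-energy function

```
Psi = a/(2b) {exp[b(I1 - 3)] - 1}
    + sum_{i=f,s} a_i/(2b_i) {exp[b_i (I_4i - 1)^2] - 1}
    + a_fs/(2b_fs) {exp[b_fs I_8fs^2] - 1}
```

with one fiber family at 34° from circumferential (sheet axis orthogonal
in-plane), tension-only fiber terms, exact incompressibility, and analytic
plane-stress first Piola–Kirchhoff stresses for biaxial states. The ATAA
configuration pins the coupling terms (`a_fs = b_fs = 0`).

**Biaxial fitting** — bounded nonlinear least squares (8 seeded multistarts)
on pooled circumferential + longitudinal first-PK residuals, restricted to
the strain-validity window (engineering strain ≤ 0.18), reporting the
pooled Pearson `r` and range-normalised RMSE.

**Circulation** — a time-varying-elastance left ventricle with diode valves
ejecting through a characteristic impedance into a Windkessel (`C` ∥
`R_total`), calibrated by the clinical formulas `R_total = MAP/CO`,
`C = SV/(SBP − DBP)`, then iteratively refined until the periodic beat
reproduces the patient's cuff pressures; PV-loop metrics include stroke
work and valvulo-arterial impedance.

**Wall-stress surrogate** — Laplace membrane stresses plus ventricular
traction and arc-bending longitudinal stress
(`S_L = p r/2t + F/2πrt ± M r cosθ / I`), reproducing the
major-curvature longitudinal maximum and the tensile-inner /
compressive-outer transmural sign change.

**Stress post-processing** — three anatomical sections × eight anatomical
quadrants × inner/outer surface mean-stress tables from VTK point clouds,
with transmural differences and sign-change flags.

**Synthetic data** — seeded generators for biaxial curves, the patient
record, and curved-tube stress meshes; `run_pipeline()` ties all stages
into one reproducible run with a JSON manifest.

## Worked example

```r
library(ataamech)

# 1. material identification from (synthetic) biaxial data
ds  <- gen_biaxial(ataa_params(), noise_cv = 0.02, seed = 42)
fit <- ds |> truncate_to_window(0.18) |> fit_ho(seed = 42)
glance(fit)
#> # A tibble: 1 x 7
#>       r   nrmse     ssr n_iter converged degenerate strain_max
#>   0.999 0.00853 0.00803     20 TRUE      FALSE            0.18

# 2. circulation calibrated to the patient record (132/84 mmHg, 4.9 L/min)
rec <- gen_patient_record()
par <- refine_to_cuff(calibrate(rec), rec, tol = 1)
sim <- simulate_circulation(par)
sim
#> <hemo_trace>  11 beats (periodic)
#>   aortic 132.4/83.7 mmHg (mean 107.0)   EDV 137.9  ESV 52.2 mL   EF 0.622

# 3. surrogate stress field and quadrant tables
field <- gen_wall_mesh(wall_geometry(), pressure = sim$metrics$SBP,
                       force = 1.92, arm = 300, seed = 1)
field |> extract_sections() |> quadrant_summary() |> transmural_delta()
```

The fit block shows near-perfect self-consistency on synthetic data
(`r ≈ 0.999`); the simulated beat reproduces the cuff pressures to well
under 1 mmHg each while the time-averaged aortic pressure (107 mmHg) sits
above the cuff-derived mean of 102 mmHg — an expected, systematic gap,
since an oscillometric mean is not a waveform integral (see the methods
vignette). The quadrant table flags the quadrants whose longitudinal
stress is tensile at the intima and compressive at the adventitia, the
bending signature implicated in dissection initiation.

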