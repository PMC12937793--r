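---
title: "Methods: a 0D electrical-analog model of arterial stenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 0D electrical-analog model of arterial stenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padflow)
```

## The model

Blood flow through a stenotic artery has a strongly nonlinear
pressure–flow relationship: mild lumen narrowing barely changes the
pressure gradient, while moderate-to-severe narrowing causes
disproportionate losses through viscous friction and flow separation.
`padflow` captures this with a zero-dimensional (lumped-parameter) model
built on the classical hemodynamic–electrical analogy: pressure ↔
voltage, flow ↔ current, and a straight elastic vessel segment ↔ an
R–L–C triplet,

$$R = \frac{8 \mu l}{\pi r^4}, \qquad
  L = \frac{\rho l}{\pi r^2}, \qquad
  C = \frac{3 \pi r^3 l}{2 E h},$$

with dynamic viscosity $\mu$ (Pa·s), density $\rho$ (kg/m³), length $l$,
lumen radius $r$, Young's modulus $E$ and wall thickness $h$ (all SI).
Two forms of the compliance formula circulate, with and without the
length factor $l$; only the form with $l$ has the units of a volume
compliance (m³/Pa), so that is the one implemented. All computation is
SI internally; mmHg and mL/s are converted at the interface with the
fixed constant 133.322 Pa/mmHg.

A focal stenosis of fractional diameter reduction
$\sigma = 1 - r_s/r_0$ narrows the lumen to $r_s = r_0(1-\sigma)$ over a
throat of length $L_s$, giving area ratio $\beta = (1-\sigma)^2$ and the
Borda–Carnot-type separation loss coefficient $\zeta = (1/\beta - 1)^2$.
The total loss at flow $Q$ is composed additively:

$$\Delta P \;=\;
  \underbrace{\frac{8\mu l}{\pi r_0^4}\,Q}_{\text{baseline}}
  \;+\; \underbrace{\frac{8\mu L_s}{\pi r_s^4}\,Q}_{\text{throat},\ \sigma>0}
  \;+\; \underbrace{\tfrac12 \rho\, \zeta \left(\frac{Q}{A_s}\right)^2}_{\text{form}}.$$

**Why this composition.** The physically tidier accounting would replace
the throat window's baseline contribution by its narrowed value rather
than adding the narrowed term on top. Both modes are implemented
(`mode = "additive-throat"` and `"replace-throat"` in
`total_pressure_loss()`), but the additive composition is the default
because it is the one that reproduces the packaged reference sweep
exactly at printed precision across all ten self-consistent cells; the
difference between the modes is a constant
$8\mu L_s Q/(\pi r_0^4)$ (about 0.07 mmHg at rest), negligible against
every nonzero-severity cell. At $\sigma = 0$ both modes coincide and the
loss is the full-length Poiseuille value only — the healthy reference
vessel has no throat term and no form loss.

Distal pressure and fractional flow reserve follow as
$P_d = P_a - \Delta P$ and $\mathrm{FFR} = P_d/P_a$. Once the loss
exceeds the perfusion pressure the raw ratio goes negative; the model
clamps the reported FFR to $[0,1]$ (keeping `ffr_raw` available), warns,
and renders clamped table cells in "~0.00" style. Throat velocity
$V = Q/A_s$ and the Poiseuille wall shear stress
$\tau_w = 4\mu Q/(\pi r_s^3)$ complete the output set.

Two cells of the packaged reference table (hyperemia at 75% and 90%)
carry printed magnitudes that equal the model's value in **pascals**
rather than mmHg — a unit slip in the source material. They are flagged
`unit_suspect_hyper` in the fixture, skipped by `reproduce_table3()`,
and the model always reports mmHg.

### Reference configuration and tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `length_l` | 0.03 | m | segment length |
| `radius_r0` | 1.5e-3 | m | healthy lumen radius |
| `wall_thickness_h` | 0.2·r0 | m | wall thickness |
| `youngs_E` | 0.4e6 | Pa | wall stiffness |
| `density_rho` | 1060 | kg/m³ | blood density |
| `viscosity_mu` | 3.5e-3 | Pa·s | dynamic viscosity (Newtonian) |
| `throat_length_Ls` | 5e-3 | m | focal throat length |
| `flow_Q` | 1e-6 / 3e-6 | m³/s | resting / hyperemic flow |
| `proximal_pressure_Pa` | 13332.2 | Pa | 100 mmHg aortic pressure |

These defaults are the study conditions of the reference severity sweep
($\sigma \in \{0, 0.25, 0.50, 0.75, 0.90\}$, rest + hyperemia).
Severity classification uses half-open clinical bins covering $[0,1)$ —
mild < 0.30 ≤ moderate < 0.70 ≤ severe < 0.90 ≤ critical — chosen
because the conventional printed ranges (≤25%, 30–60%, 70–80%, ≥90%)
leave gaps between categories.

Compliance and inertance are held constant across severities: a focal
narrowing primarily changes local resistance, while global wall
elasticity and blood inertia are essentially unchanged — the standard
reduced-order assumption.

## The circuit analog

The physical analog is a PCB ladder excited by a 0–5 V, 50 Hz sinusoid.
`mna_solve()` assembles the complex node-admittance system at
$\omega = 2\pi f$ (modified nodal analysis: one constraint row for the
voltage source) and solves it with base R's complex `solve()`; a
floating subnetwork is diagnosed by node name before assembly.

The source material names the components (series R1, R2; parallel R3 and
the potentiometer P1/R4; C1–C3; L1, L2) and their values
(R1 = 71.6 Ω, R2 = 0.8 Ω, R3 = 83.4 Ω, C1 = C2 = 490 nF,
L = 0.000209 mH) but never prints the netlist, so the default topology
is an explicit, fully overridable assumption (JSON netlists via
`netlist_from_json()`): source → R1 → R2 → L1 → proximal node (C1 to
ground) → stenosis resistor → L2 → distal node (C2 to ground, load
R3 ∥ C3) — two symmetric series cells and one parallel load cell.
Unprinted values default to C3 = C1 and L1 = L2 = L. The printed
component values themselves are consumed verbatim: the unit convention
that derived them from the arterial parameters is not reconstructable,
so they are treated as given constants, not derived quantities.

**Where the output is measured.** The measured output is the node
*proximal* to the lesion branch. As the lesion resistance rises, voltage
builds up proximal to the constriction — exactly the behavior of the
bench recordings, whose mean output rises monotonically from 3.52 V to
5.42 V across the 40-level sweep, and of arterial pressure proximal to a
tightening stenosis. Numerically, the proximal node of the default
ladder rises from 3.00 V to 4.69 V across the sweep while the distal
node falls from 2.31 V to 0.36 V (distal perfusion collapsing); both are
available in the solved phasors. The sweep protocol steps the lesion
resistance from 2.5% to 100% of full scale in 2.5% increments (40
levels); the potentiometer full scale is not printed and defaults to
1 kΩ, with the severity mapping $R_v = R_{base}(1-\sigma)^{-4}$ tying
resistance to diameter reduction.

Oscilloscope semantics: for an unclipped sinusoid of amplitude $A$,
$V_{pp} = 2A$ and $V_{avg} = (2/\pi)A$ (rectified cycle mean).
`synthesize_waveform()` reconstructs the time-domain trace, hard-clips
it at the supply rails (default ±5 V, the excitation range) and
recomputes both measurements from the clipped trace, reproducing the
flattened "rectangular" traces seen at high drive levels. The packaged
40-row bench recording is a measured-hardware artifact: it is shipped as
a fixture for the statistics layer and is *not* a target the solver is
expected to regenerate numerically (component tolerances, the unknown
potentiometer taper and the unprinted topology make that
under-determined).

## Calibration

Voltage differences convert to pressure equivalents through
$\Delta p = \Delta U / k_P$ with $k_P$ in V/mmHg (default 0.125, the
experimentally calibrated constant shipped verbatim — its raw sensor
data are not available to re-derive it). The source text writes the
relation as a product, which is dimensionally inconsistent with those
units; every printed numeric use (0.5 V → 4 mmHg, 5.4 V → 43 mmHg,
3.52 V → ≈28 mmHg) corresponds to division, which is what is
implemented. `fit_kp()` estimates $k_P$ by least squares *through the
origin* (a zero voltage difference must map to zero pressure
difference) with a case-resampling percentile bootstrap CI (1000 draws,
seed 0, both overridable) and an origin-constrained (uncentered) $R^2$.
Whether the original calibration $R^2$ was origin-constrained is not
stated; the uncentered convention is documented here as the package's
choice.

## Geometry and STL export

For CFD meshing workflows the stenosis is realized as a surface of
revolution with a cosine throat,

$$R(z) = R_0 - \frac{\Delta R}{2}\left(1 +
  \cos\frac{2\pi (z - z_c)}{L_s}\right),\quad
  z \in [z_c - L_s/2,\; z_c + L_s/2],\qquad \Delta R = R_0\,\sigma,$$

and $R(z) = R_0$ outside the window. The profile is $C^1$ at the window
edges and attains $R_0(1-\sigma)$ at the centre. Defaults: L = 30 mm,
R₀ = 1.5 mm, L_s = 5 mm, z_c = 15 mm, coordinates in millimetres
in-file (`scale = 0.001` emits metres). Axial resolution is locally
refined — spacing ≤ L_s/20 inside the throat, ≤ 1 mm outside — with 64
circumferential vertices; facet counts follow the quad-strip
combinatorics $2 n_\theta (n_z - 1)$ plus $2 n_\theta$ for optional end
caps. Both binary and ASCII STL are written and read back (the reader
exists for round-trip verification and CLI use); resolution defaults
are implementation choices, as no canonical facet counts exist for this
geometry.

## Pulsatile driving and the Windkessel load

The physical board is driven by a fixed 50 Hz sinusoid, not a
physiological pulse, so pulsatility is a simulation-side extension. The
waveform is a positive sinusoid $Q(t) = \bar Q + Q_a \sin(2\pi f t)$
with $f$ defaulting to 1.2 Hz (physiological 1.2–1.5 Hz band);
Womersley-consistent profiles are out of scope. `quasi_steady_dp()`
applies the steady loss model sample-by-sample — the quasi-steady
assumption, valid when the throat transit time is short against the
pulse period. Because $Q \mapsto \Delta P$ is convex for $\sigma > 0$,
the cycle-mean loss exceeds the loss at the mean flow (Jensen), which
the tests verify numerically.

The three-element Windkessel terminal load is implemented in its
standard form,

$$p + RC\,\frac{dp}{dt} = (Z + R)\,q + ZRC\,\frac{dq}{dt},$$

because the printed differential equation in the source material is
typographically corrupted beyond recovery; venous outlet pressure is
taken as zero. Integration is an explicit trapezoidal (Heun) update
with central-difference $dq/dt$, from $p(0) = 0$; summaries use the
final cycle. Steady-state gain $(Z+R)$ and the large-compliance limit
$p \approx Zq$ (above the mean) are verified to 1e-6 and 2%
respectively in the tests.

## Validation statistics

All conventions in one place:

- **Bootstrap**: case resampling, percentile intervals, 1000 draws,
  default seed 0, overridable everywhere randomness exists;
  bit-reproducible for a fixed seed. The RNG state of the caller is
  never disturbed.
- **Quadratic fit** $\Delta V_{pp} = a_0 + a_1\sigma + a_2\sigma^2$ via
  `stats::lm`; for constant response the coefficients vanish and $R^2$
  is defined as 0.
- **Breakpoint fit**: continuous hinge $y = b_0 + b_1 x + b_2(x-\tau)_+$
  with $\tau$ grid-searched over the observed interior $x$ values; ties
  broken toward the smallest $\tau$ (deterministic, and on purely linear
  data the earliest candidate is returned). The breakpoint is invariant
  to rescaling $y$.
- **Slope-doubling severity**: $\sigma^* = a_1/(2a_2)$, defined only for
  positive $a_1, a_2$.
- **Discrete Fréchet distance**: the standard dynamic-programming
  recurrence over monotone couplings; the tests verify it against
  exhaustive coupling enumeration for short curves and against the
  Hausdorff lower bound. The continuous Fréchet distance is out of
  scope.
- **Repeatability**: per-level mean/SD/CV across ≥2 series plus a
  two-sided paired t-test between first and last series as the drift
  check (α = 0.05 convention). Identical series give CV 0 and a
  degenerate drift p of 1; an exactly constant nonzero shift gives 0.
- **OAT sensitivity**: one-at-a-time ±20% perturbations of named
  parameters, reporting the relative change of the output curve per
  grid point; model failures are flagged per cell.

`validate_overlay()` ties these together: each bench resistance level is
mapped to an equivalent severity through the inverse fourth-power law
(baseline = first level, so the 40-level sweep spans
$\sigma \in [0, 1 - 40^{-1/4}] \approx [0, 0.60]$), both curves are
baseline-normalized, and Pearson r, Fréchet distance, the bench curve's
breakpoint and the quadratic fit are reported. The printed bench
$R^2 = 0.972$ is **not** asserted anywhere: the variable pairing behind
it (which x against which y) is not stated in the source, so the overlay
documents the choices without claiming the number. The same applies to
the patient-level correlations (r = 0.985, −0.964, 0.951): patient-level
data are not printed, so only group-mean concordance is computed.

## Clinical layer

ABI uses the lower of the two ankle pressures over the brachial
pressure; values above 1.0 are flagged. PSVR grading uses
<2.0 → normal/mild, 2.0–4.0 → moderate, >4.0 → severe/critical, with
the boundary values assigned to the moderate bin (the printed wording
"below 2.0" / "greater than 4.0" leaves equality to the middle bin).
The simplified-Bernoulli gradient $\Delta P = 4(V_{sten}^2 - V_{prox}^2)$
keeps the conventional factor 4 (m/s in, mmHg out). In the packaged
cohort summary the normal group's clinical gradient is printed only as
"< 2" and is stored as 1 with the original text preserved in a note
column; the cohort's group-mean gradients are not derivable from the
printed velocity means via the Bernoulli formula (they average
patient-level values), which is why concordance is computed on the
packaged group means as given.

## Synthetic data

The generators exist so every statistical operation has a controlled,
seeded input:

- `synth_sweep()` emulates the bench pattern — output nearly constant at
  low levels, rising steeply past a mid-range inflection — as a
  continuous linear hinge plus Gaussian noise. The hinge is deliberate:
  it makes "recover the inflection with `breakpoint_fit()`" an exact
  closed-loop test. Defaults reproduce the bench recording's range
  (3.52 → 5.42 V over 40 levels, inflection at 0.5, 10 mV noise).
- `synth_calibration_pairs()` generates $\Delta U = k_P \Delta P$ pairs
  on a 2–45 mmHg grid with relative Gaussian noise.

What they do *not* emulate: supply-rail clipping artifacts (handled
separately in the waveform synthesizer), potentiometer taper
nonlinearity, drift between sessions, electromagnetic interference, or
the heavy right tail of the real recording's top two levels. Passing
recovery tests on these generators therefore demonstrates correctness
of the estimators under clean assumptions, not robustness to every
hardware artifact.

## Numerical choices and degenerate inputs

- $\sigma \ge 1$ is rejected everywhere (no lumen); $\sigma = 0$ is the
  healthy reference with zero throat and form terms.
- `dp_total` is the exact floating-point sum of its three components;
  the component ratios between hyperemia and rest are exactly 3
  (viscous) and 9 (form).
- The MNA system is solved directly (dense complex LU); networks are
  small (≤ ~10 nodes), so conditioning is not a practical concern, and
  disconnected nodes are caught before assembly.
- Waveform and pulse sampling use half-open uniform grids over whole
  cycles so sinusoid means are exact; measurement summaries use the
  final cycle.
- Test problem sizes: 100-point (σ, Q) grids for monotonicity, 40-level
  sweeps, 1000-draw bootstraps (reduced to 100–400 where a CI is only
  smoke-checked), meshes of 10–25 axial × 8–16 circumferential
  stations. The full suite runs in well under a minute.

## Known limitations

- Newtonian, laminar, quasi-steady flow in a straight axisymmetric
  segment with a single focal lesion; no turbulence or transition
  modelling, no lesion asymmetry, no multi-lesion series, no tapering,
  no temperature dependence of viscosity.
- The 0D analog is geometry-agnostic: territories dominated by
  curvature, branching and distributed wave reflection (intracranial,
  thoracic aorta) are outside its intended range.
- Several printed quantities are consumed as constants rather than
  re-derived, because the data or conventions behind them are not
  available: the experimental calibration constant (raw sensor data
  unpublished), the bench sweep recording (hardware measurement), the
  printed circuit component values (underlying unit convention not
  reconstructable), the bench $R^2$ and the patient-level correlations
  (variable pairing / per-patient data not printed), and CFD velocity
  fields (external solver, out of scope).
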