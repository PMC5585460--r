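---
title: "Methods: electrical analog modelling of coronary hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrical analog modelling of coronary hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coranalog)
```

## The model and its assumptions

`coranalog` treats the coronary circulation as a DC resistor network under
the electronic–hydraulic analogy: voltage is pressure (1 V ≙ 1 mmHg),
current is volumetric flow (arbitrary units), resistance is the ratio of
the two.  The physiologic assumptions that make this defensible are:

* **Maximal hyperemia.** FFR is measured after adenosine; microvascular
  resistance is then minimal and approximately constant, so each myocardial
  bed is a fixed linear resistor and pressure ratios proxy flow ratios.
* **Epicardial vessels as conductors.** Normal conductance vessels present
  negligible resistance; all epicardial resistance is concentrated in
  discrete stenosis resistors.
* **Steady state.** Vascular inductance and capacitance are small at the
  scales of interest; the analysis is purely resistive (DC).  Nothing
  pulsatile, no autoregulation, no time axis.
* **Linearity.** Stenosis resistances are fixed numbers per scenario.  Real
  separation losses make lesion resistance flow-dependent; here that
  nonlinearity is deliberately ignored, which is exactly what makes
  superposition and the series–parallel reductions available as checks.

A model (`coronary_spec()`) declares segments, lesions, beds, collaterals,
sources, probes and scenarios; `build_circuit()` compiles it; `solve_dc()`
solves it by modified nodal analysis (MNA): Kirchhoff current balance in
the non-ground node voltages plus one current unknown and one constraint
row per ideal voltage source.  The venous pressure is a second ideal
source to ground — not a ground offset — so every solution stays
ground-referenced and the two-source superposition property is testable.

## Parameters that matter

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `arterial_pressure` | V ≙ mmHg | 100 | probe voltages read directly as FFR percentages |
| `venous_pressure` | V ≙ mmHg | 5 | typical central venous pressure |
| bed resistances | Ω | LAD 10, LCx 20, RCA 30 | inverse Leaman weighting for a right-dominant tree; `bed_resistances("leaman_inverse", ...)` generalizes via `R_i = scale / fraction_i` |
| `inflow_resistance` | Ω | case-specific | left-main equivalent series resistance; 0.099 Ω in the reference case (calibrated, below) |
| collateral resistance | Ω | case-specific | 5 Ω in the reference case (calibrated) |
| PCI residual | Ω | 0.1 | an effectively stented segment; exactly 0 is disallowed |
| FFR convention | — | `input` | `V/Pa`; the physiologic `(V-Pv)/(Pa-Pv)` is available but never the default, so tabulated ratios match the 100 V reading convention |

Left-dominant anatomies have no preset bed values; `bed_resistances`
refuses the combination rather than guessing, and the inverse-Leaman mode
(58/42 LAD/LCx split) covers them explicitly.

## The reference case and its calibration

The packaged case (`reference_case()`) encodes a real clinical
constellation: serial proximal (3 Ω) and distal (15 Ω) LAD lesions,
moderate LCx disease (0.75 Ω), a 10 kΩ chronic total occlusion of the
proximal RCA collateralized from the mid LAD, and the right-dominant preset
beds.  The RCA anchors at the arterial node — it has its own aortic ostium
— so the inflow resistor carries left-main flow only.  Its four scenarios
(baseline, distal PCI, both-lesion PCI, proximal-only PCI) reproduce a
frozen grid of 16 two-decimal probe ratios and 12 bed currents
(`reference_expected()`), the package's gold regression surface, to within
half a unit in the last printed digit (±0.005).

Two component values are not anatomically prescribed and were identified,
not assumed (`calibrate_unprinted_parameters()`): a brute-force grid search
over inflow ∈ [0.001, 1] Ω × collateral ∈ [1, 20] Ω minimizes the maximum
absolute deviation of the baseline scenario from its frozen row (coarse
steps 0.01/0.25 Ω, refined to 5e-4/0.05 Ω).  Because the targets are
rounded to two decimals, the objective has a flat valley (≈0.0034–0.0039
for inflow 0.094–0.100 Ω at collateral 5 Ω): every point with objective
below the 0.005 rounding half-unit is observationally equivalent given the
baseline row alone.  The calibration therefore reports that feasible set
alongside the argmin, and the fixture freezes the member of the set —
inflow 0.099 Ω, collateral 5 Ω — that also reproduces the three held-out
scenarios to ±0.005.  The nominal "0.1 Ω" is this value's rounding; a
conventional 10 mΩ left main is recorded in the fixture metadata but fails
the flows (baseline LCx current 4.57 A instead of 4.53 A).  Perturbing the
collateral by ±10% breaks cells beyond tolerance, so the values are
identified rather than cosmetic.

## Numerical choices

* **Dense direct solve.** Tens of nodes at most; sparsity machinery would
  be unjustified.  The solve is deterministic and non-iterative.
* **Minimum resistance 1e-9 Ω.** True zeros would make the nodal matrix
  singular.  Segments *at* the minimum are compiled as ideal wires by node
  merging (never as 0 Ω resistors); lesions always remain explicit
  elements so scenario overrides can resolve them.
* **Singularity is a modelling error.** A degenerate network (e.g. two
  ideal sources disagreeing across the same nodes) raises a distinct
  condition (`coranalog_singular`); it signals a malformed model, not
  numerical noise.
* **Sign conventions, stated once.** Element current is positive from
  `node_a` to `node_b`; a source's `node_a` is its positive terminal.
  Tests enforce both (Ohm-law self-consistency is exact by construction).
* **Degenerate inputs.** Validation collects *all* problems (duplicate
  ids, unreachable nodes, sub-minimum resistances, sourceless circuits,
  dangling references) and reports them together with field paths, both
  for circuits and for model files; parse errors and schema errors are
  distinct condition classes.

## Verification strategy, and what it does not show

The solver is checked against an independent oracle: `random_sp_network()`
generates series–parallel compositions (resistor values log-uniform in
[0.1, 100] Ω, recorded composition tree, seeded and deterministic) and
`sp_reduce_oracle()` solves them by recursive series/parallel reduction
with back-substitution — no matrix algebra.  The test suite demands
agreement to 1e-10 relative on 50 networks, Kirchhoff residuals below
1e-9 of the largest current and power balance to 1e-9 relative on 200
networks, exact two-source superposition, source scaling, the no-disease
limit (all probe ratios 1 within 1e-6 when every lesion and the inflow sit
at the wire floor), and the clinical property grids: collateral-dependent
flow strictly falls as the donor's distal resistance falls (steal
emergence, LAD2 over [0.1, 15] Ω), vanishes with the collateral removed,
and the proximal-lesion gradient grows monotonically as the distal lesion
shrinks.

These fixtures emulate network *structure*, not physiology: passing them
shows the arithmetic and the compiled topology are right.  They say
nothing about whether a particular patient's stenosis is well summarized
by 3 Ω — the package deliberately does not convert percent stenosis to
resistance (users supply ohms from whatever fitting procedure they trust),
and linear, hyperemic, steady-state behaviour is assumed rather than
demonstrated.

Problem sizes are chosen to keep the whole suite interactive: the largest
generated networks have a few dozen elements (composition depth ≤ 6), and
the calibration audit evaluates roughly eight thousand coarse-grid plus a
few hundred fine-grid solves in seconds.

## Design decisions that were genuinely open

* **FFR convention.** Dividing by the arterial input (`V/Pa`) is the
  tabulated convention here and the default; the physiologic
  `(V−Pv)/(Pa−Pv)` is an explicit option.  Mixing them silently would
  shift every ratio by a venous-offset factor.
* **Lesions as series resistors inside segments**, rather than segment
  replacements: multiple lesions per segment compose additively, which is
  the serial-stenosis use case.
* **Collaterals attach to nodes, not segments**, keeping the compiler
  topology-agnostic (the reference case's channel runs mid-LAD →
  distal-RCA).
* **Scenario overrides touch lesions only.** Editing segment or bed
  resistances is a different act (re-modelling, not intervening) and is
  done on the model object explicitly.
* **`steal_index` is a relative change** `(after − before)/before`; raw
  ampere differences are also reported, since the index's denominator can
  be tiny for near-unperfused territories.

## Known limitations

DC only — no pulsatility, no inductive/capacitive vessel behaviour, no
wave reflection; no autoregulation or viability effects in the beds; no
flow-dependent lesion resistance; no diagonal/obtuse-marginal branches in
the reference case (excluded for clarity of the serial-lesion point); no
percent-stenosis → ohm conversion; collateral recruitment is a fixed
resistor, not a pressure-dependent channel.  The package is an educational
and hypothesis-generating instrument, not a patient-specific predictor.
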