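---
title: "Modelling intracranial pressure and cerebral PPG waveforms with icpwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intracranial pressure and cerebral PPG waveforms with icpwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model addresses

Intracranial pressure (ICP) is normally monitored invasively.
Photoplethysmography (PPG) — the optical measurement of pulsatile blood
volume in the microcirculation — can be recorded non-invasively, and PPG
signals originating from intracranial perfusion territories should in
principle carry an imprint of ICP, because ICP is the pressure against
which the cerebral microvessels are distended.  `icpwave` implements a
forward model of this chain: a lumped-parameter (Windkessel)
cardiocerebral artery network, an intracranial pressure compartment with
cerebrospinal-fluid (CSF) exchange, and explicit
arteriole–capillary–venule circuits for the ACA, MCA and PCA perfusion
territories whose capacitor transmural pressures constitute the simulated
PPG.  The model answers, in silico: *which PPG waveform features respond
to an ICP change, and which are invariant?*

## Model structure

Everything is an electrical-analog hydraulic circuit in SI units
(pressure Pa, flow m³/s): resistors for viscous loss, inductors for blood
inertia, capacitors for compliance, smoothed diodes for one-way CSF
valves.  The generic layer (`circuit()`, `assemble()`,
`integrate_circuit()`) turns a circuit into a stiff ODE system whose
state holds node pressures and inductor flows; the nodal volume balance
`M(p) dp/dt = f(p, q, t)` is solved exactly at each evaluation, with the
(possibly pressure-dependent) capacitances collected in the mass matrix
`M`.  Integration uses `deSolve::lsoda` (relative tolerance 1e-6,
absolute 1e-8, output at 1 kHz).  The derivative evaluator exists twice:
a reference pure-R implementation and a compiled Rcpp/RcppArmadillo
version used automatically when all element laws have closed forms; the
test suite asserts they agree to machine precision on the full coupled
model.

### Artery network

The network (`build_network()`) has 33 segments: 22 intermediate
arteries — ascending aorta, two aortic-arch segments, brachiocephalic,
both common carotids, subclavians, vertebrals, two-segment internal
carotids, basilar, and the communicating arteries with the first ACA/PCA
segments closing the Circle of Willis — plus 11 outlet terminals
(thoracic aorta, brachial, external carotid, and six cerebral
territories).  Each intermediate segment is a three-element Windkessel: a
series resistance–inertance branch with the wall compliance split equally
between its end nodes.  Segment values derive from vessel anatomy
(Poiseuille resistance $8\mu l/\pi r^4$, inertance $\rho l/\pi r^2$,
thin-walled compliance $3\pi r^3 l/2Eh$, with blood viscosity 4 mPa·s and
density 1050 kg/m³); the anatomical tables ship as CSV under
`inst/extdata` with per-row provenance notes and are treated as
calibratable configuration, not ground truth.  The heart enters as a
half-sine ejection flow source (period 0.8 s, systolic fraction 0.35,
stroke volume 85 ml — calibrated so the mean aortic pressure falls in the
70–110 mmHg band).

Two elements are age-dependent and nonlinear, evaluated at the local
pressure on every solver step:

* **Aorta** — $C(P) = A_{max} L / \{\pi P_1 [1 + ((P-P_0)/P_1)^2]\}$ with
  $P_0 = 76 - 0.98\,\mathrm{age}$ and $P_1 = 57 - 0.44\,\mathrm{age}$
  (mmHg, ages 20–70), $A_{max} = 5.8\ \mathrm{cm}^2$ (male adults), the
  total aortic length distributed over the three aortic segments
  proportionally to length.
* **Common carotid** — $C(P) = a e^{-bP} [1.3 - 0.012(\mathrm{age}-20)]$
  with $a = 3.14$ ml/mmHg and $b = 0.018$ 1/mmHg.  The reference value is
  anchored at the conventional healthy mean pressure of 100 mmHg; since
  no separate reference capacitance is defined by the source equations,
  the only internally consistent reading — the exponential law evaluated
  at the reference pressure — is used.

Both laws stiffen with age; that single mechanism produces the rising
pulsatility of all distal signals in older subjects.

### ICP compartment

The ICP circuit (`build_icp_circuit()`) drains the three intracranial
supply trunks (distal internal carotids and basilar top) through equal
coupling resistances into proximal and distal arterial beds, a capillary
node, and a venous return chain to the central venous pressure (5 mmHg).
CSF forms through resistance `Rf` behind a one-way valve from the
capillary node into the ICP node and leaves through `Ro` behind a second
valve into the venous sinus.  The ICP node carries the piecewise
craniospinal capacitance

$$C(\mathrm{ICP}) = \begin{cases}
  7.502\times10^{-9}\, r & \mathrm{ICP} < 666.5\ \mathrm{Pa}\\
  (5\times10^{-6}/\mathrm{ICP})\, r & \mathrm{ICP} \ge 666.5\ \mathrm{Pa}
\end{cases}$$

(m³/Pa; knot at 5 mmHg), where $r$ is the capacitance-reduction ratio
`ratio_cd` that emulates pathological loss of intracranial compliance
(1 = normal, 0.25 = 75 % reduction).  The function is continuous at the
knot to 0.002 %, so no smoothing is applied; the stiff solver handles the
derivative jump.  Arterial-bed and intracranial venous compliances are
true two-terminal capacitors to the ICP node: arterial pulsation
physically displaces volume into the craniospinal space, which is what
generates the ICP pulse wave.

**Why mean ICP depends on `ratio_cd`.**  Because every flux charging the
craniospinal compartment is divided by a capacitance proportional to
$r$, the four capacitance conditions traverse one master charging curve
at speeds proportional to $1/r$.  Runs start from the post-drainage
reference state (ICP = 5 mmHg, the venous reference) and charge towards
the CSF formation/outflow balance point; measured in the first cardiac
cycle after 10 s, the normal compartment has reached ≈ 14.5 mmHg while
the 50 % and 75 %-reduced compartments, charging two and four times
faster along the same curve, have reached ≈ 19 and ≈ 20.7 mmHg.  `Rf`,
`Ro` and the bed resistances were calibrated so these values fall in the
reported bands (normal ≤ 15 mmHg, ≥ 15 at 50 % reduction, ≥ 20 at 75 %)
while the within-cycle ICP amplitude stays below 5 mmHg in every
scenario.

### Territory microcirculation and the PPG signal

Each simulated territory (`build_territory()`, attached by `couple()`)
replaces its cerebral terminal's lumped distal branch by the chain
RA1–RA2–RC–RV2–RV1 with the capillary capacitance CC and venular
capacitances CV1/CV2 at the RC/RV2, RV2/RV1 and RV1/outlet junctions and
an arteriovenous-anastomosis resistance RAVA bridging the arteriole
midpoint to the venule midpoint.  The chain resistances sum exactly to
the terminal's distal resistance (split
arteriole : capillary : venule = 0.55 : 0.25 : 0.20) and the three
capacitances to the terminal's capacitance (capillary fraction 0.2), per
the shipped ratio table.  RAVA defaults to ten times the total arteriole
resistance.  In the coupled model the chain's venous end and every
cerebral outlet reference are pinned to the instantaneous ICP node
pressure — the microvascular outlet pressure is derived from ICP — and
the chain capacitors are referenced to ICP, so the simulated PPG

$$\mathrm{PPG}(t) = \sum_{k \in \{CC, CV1, CV2\}} P^{trans}_k(t)\quad[\mathrm{Pa}]$$

is the summed transmural (vessel-minus-ICP) pressure: a volume-
proportional analogue of the optical signal.  A capillary-only probe is
available via `ppg_probe = "capillary"`.

Rising ICP throttles the perfusion pressure $(P_{art} - \mathrm{ICP})$,
so PPG maximum, minimum and mean all fall; because the entire chain is
driven by that single difference, the fall is close to a common scaling
and the shape-relevant ratios PI, RI and MMR move only a little.  The
residual shape drift is governed by the growth of the ICP pulse across
conditions relative to the PPG pulse amplitude; the arterial-bed
compliances `Ci_1`/`Ci_2` were calibrated to keep that residual near its
achievable minimum (≈ 2–2.5 % worst case, see Limitations).

### Waveform features

`extract_cycle()` measures one cardiac cycle: maximum, minimum,
trapezoidal mean, amplitude, min-to-max (rising-limb) time — measured
modulo the period when the sampled cycle's maximum precedes its minimum,
with plateau ties resolved to the first attaining sample — and the
ratios PI = (max−min)/mean, RI = (max−min)/max, MMR = max/mean, which
satisfy PI = RI·MMR identically.  Measurements use the first full
cardiac cycle after 10 s (cycles are phase-locked to the inflow, so the
window starts at 10.4 s for T = 0.8 s); the preceding transient is
discarded.

## Numerical choices

* Initialization: arterial nodes 80 mmHg; arteriolar/capillary beds on a
  falling gradient towards the venous side; venous and ICP nodes 5 mmHg;
  zero flows.  Starting the beds near their working pressures prevents
  the initial transient from displacing spurious volume through the
  transmural compliances into the craniospinal compartment.
* Diodes: two-conductance model smoothed over 1 Pa (forward 1e-6,
  reverse 1e-14 SI), stiff-solver friendly; reverse leakage is orders of
  magnitude below CSF flows.
* Junction nodes without physical compliance receive a 1e-11 m³/Pa
  parasitic capacitance; this regularisation is far below every
  physiological compliance in the model and keeps the system an ODE.
* Output at 1 kHz resolves the min-to-max time to 1 ms; halving the
  solver tolerances changes the standard test-circuit probes by less
  than 0.1 %.
* Everything is deterministic: repeated runs are bit-identical, and the
  grid embeds a configuration hash in every CSV header line.

## Study grid and run sizes

`run_grid(scenario_config())` reproduces the study conditions: ages
20/40/60 × capacitance reduction 0/25/50/75 % × left ACA/MCA/PCA
territories, each a 30 s run (one coupled simulation per age–condition
pair; the three territories share a run).  The twelve 30 s runs take
roughly three minutes on one CPU with the compiled evaluator.  An
`abstract_grid` preset provides the 0/20/50/75 % variant, and a second
anatomical parameter set (`"scenario2"`, same topology, moderately
different calibres) supports sensitivity exploration; its outputs are
not calibrated against the reported bands.

```{r example}
library(icpwave)
sim <- simulate_cerebral(40, ratio_cd = 0.5)
summary(sim)
plot(sim)

grid <- run_grid(scenario_config(), out_dir = "results")
grid
```

## Calibration

The quantitative behaviour of a lumped model of this kind rests on
parameter tables that are only cited, not printed, in the source
literature, so calibration is an explicit part of the build.  The
shipped tables were calibrated, in this order: terminal resistances for
the systemic/cerebral flow split and a mean aortic pressure near
95 mmHg; `Rf`/`Ro` and the bed resistances for the ICP bands above;
communicating-artery and vertebral calibres (set at the prominent end of
the normal range) to balance posterior pulse transmission; territory
time constants and the MCA terminal for the territory ordering
(MCA least pulsatile, as bed-compliance differences imply) and for
shape-feature stability; and the bed compliances `Ci_1`/`Ci_2` for the
ICP pulse amplitude.  `calibrate()` re-checks the bands with a
deterministic bounded coordinate search over `Rf`, `Ro`, stroke volume
and a terminal-resistance scale; on the shipped tables it returns the
identity with zero violation.

## What the generator does and does not emulate

The synthetic conditions emulate healthy male adults of three ages with
graded loss of craniospinal compliance as the single pathological
mechanism.  Real signals differ in ways that matter for any transfer of
conclusions: no cerebral autoregulation (flows respond passively to
pressure), no respiratory or autonomic modulation, no venous valves or
collapsible-vein behaviour, a one- or two-peak ICP wave rather than the
clinical three-peak (P1/P2/P3) morphology, no optical sensor physics or
motion artefact, and ICP elevation generated only through capacitance
reduction.  Passing the packaged tests therefore demonstrates internal
consistency of the circuit model and reproduction of the reported trend
structure, not clinical validity on measured PPG.

## Known limitations

* The worst-case relative difference of the shape features across
  capacitance conditions calibrates to ≈ 2–2.5 %, slightly above the
  2 % reported by comparable simulations.  The residual is structural:
  the compensation of the perfusion-pressure scaling by the growing ICP
  pulse is convex in the condition index for any passive linear
  coupling, while the required pattern is concave, so a fraction of a
  percent of mismatch survives at the mid conditions for some
  age–territory cells.
* Mean ICP at the measurement window is a slow charging transient by
  construction; the compartment is not at periodic steady state at 10 s,
  and cycle-to-cycle ICP drift of a few percent remains (the PPG signals
  are periodic to < 1 %).
* Right-side territories are constructible but not exercised by the
  shipped grid; the second anatomical scenario is provided uncalibrated.
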