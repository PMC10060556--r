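# icpwave

Coupled lumped-parameter simulation of intracranial pressure (ICP) and
cerebral photoplethysmography (PPG) waveforms.

ICP — the pressure in the craniospinal compartment — is normally measured
invasively. PPG signals from intracranial perfusion territories can be
acquired non-invasively and should carry an imprint of ICP, because ICP
is the external pressure distending the cerebral microvessels. `icpwave`
provides the forward model needed to study that relationship: it
simulates how a loss of intracranial compliance raises ICP and how that
change propagates into the PPG waveform of the anterior, middle and
posterior cerebral artery (ACA/MCA/PCA) territories, for subjects of
different ages.

## The model

Three interactive Windkessel (electrical-analog) circuits are integrated
as one stiff ODE system (`deSolve::lsoda`, with a compiled
Rcpp/RcppArmadillo derivative evaluator):

* **Cardiocerebral artery network** — 33 segments from the aortic root
  through the Circle of Willis, each intermediate artery a three-element
  Windkessel (R, L, C). The aorta and common carotids carry age-dependent
  nonlinear capacitances: C_aorta(P) = A·L/{π·P₁·[1+((P−P₀)/P₁)²]} with
  P₀ = 76 − 0.98·age, P₁ = 57 − 0.44·age (mmHg), and
  C_CCA(P) = a·e^(−bP)·[1.3 − 0.012·(age−20)] with a = 3.14 ml/mmHg,
  b = 0.018 /mmHg. A half-sine cardiac ejection (T = 0.8 s) drives the
  root.
* **ICP compartment** — proximal/distal arterial beds, CSF formation and
  outflow through one-way valves (Rf, Ro), a venous return chain, and the
  piecewise craniospinal capacitance
  C(ICP) = 7.502·10⁻⁹·r for ICP < 666.5 Pa and (5·10⁻⁶/ICP)·r above it,
  where r = `ratio_cd` is the capacitance-reduction ratio (1 = normal,
  0.25 = 75 % reduction).
* **Territory microcirculation** — per-territory
  arteriole–capillary–venule chains with an arteriovenous-anastomosis
  shunt, partitioned from the cerebral outlet terminals and referenced to
  the ICP node. The simulated PPG is the summed transmural pressure of
  the capillary and venular capacitance elements, in Pa.

Eight waveform features are measured on the first full cardiac cycle
after 10 s: maximum, minimum, mean, amplitude, min-to-max (rising) time,
pulsatility index PI = (max−min)/mean, resistive index RI = (max−min)/max
and max-to-mean ratio MMR = max/mean (PI = RI·MMR).

See `vignette("icpwave-methods")` for assumptions, calibration and
limitations.

## Worked example

```r
library(icpwave)
sim <- simulate_cerebral(age = 40, ratio_cd = 0.5)  # 50 % capacitance loss
summary(sim)
```

```
Scenario: age 40 y, 50% intracranial capacitance reduction
Measured cycle: first cardiac cycle after 10 s
ICP [mmHg]: min 17.73  mean 19.10  max 20.21
Aortic root [mmHg]: min 83.4  mean 98.7  max 140.0
PPG waveform features:
 territory maximum minimum mean amplitude min_to_max_time     PI     RI   MMR
     ACA-L    2332    1770 2061     561.5           0.379 0.2724 0.2408 1.131
     MCA-L    2281    1854 2078     427.3           0.389 0.2057 0.1873 1.098
     PCA-L    2301    1797 2083     504.1           0.382 0.2420 0.2191 1.104
```

Halving the intracranial capacitance has pushed mean ICP to ~19 mmHg
(normal condition: ~14.5 mmHg) while arterial pressure is unchanged. The
PPG values are transmural pressures in Pa: the MCA territory is the least
pulsatile (lowest PI/RI/MMR), and comparing conditions shows the
value-relevant features (maximum, minimum, mean) falling with rising ICP
while the shape-relevant features (min-to-max time, PI, RI, MMR) stay
almost unchanged — the central qualitative result of the model.

The full study grid (ages 20/40/60 × reductions 0/25/50/75 % × three
territories) runs in a few minutes:

```r
grid <- run_grid(scenario_config(), out_dir = "results")
grid            # per-condition ICP table and shape-feature stability
```

`plot(sim)` draws the ICP and per-territory PPG waveforms;
`write_timeseries()` exports any probe as CSV. A thin command-line
front end is installed under `inst/cli/icpwave`
(`simulate`, `grid`, `features`, `fixtures`, `calibrate`).

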