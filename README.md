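# slowbind

Quantitative analysis of slow, tight-binding enzyme inhibition by a two-step
(induced-fit) mechanism, modelled on the actinonin–peptide deformylase (PDF)
system, together with the conformational-state geometry used to visualise
the accompanying active-site closure.

Actinonin-class hydroxamate inhibitors bind PDF in two steps:

```
E + I  <--k3/k4-->  E:I  <--k5/k6-->  E:I*
```

A fast encounter step (association `k3`, dissociation `k4`, initial constant
`K_I = k4/k3`) is followed by a slow isomerization (`k5` forward, `k6`
reverse) that tightens the complex.  The package provides:

* **Closed-form kinetics** (`kinetic_scheme()` and friends): the observed
  pseudo-first-order rate `k_obs = k6 + k5[I]/(K_I+[I])` (induced fit) and
  its decreasing counterpart `k6 + k5/(1+[I]/K_I)` (conformational
  selection); the overall constant `K_I* = k4/(k3 + k3 k5/k6)`; the inverse
  relation `k6 = k5/(K_I/K_I* - 1)`; the residence half-life
  `t1/2 = 0.693 (k4+k5+k6)/(k4 k6)`; and the tightening free energy
  `ddG = RT ln(K_I/K_I*)` with `RT = 0.616 kcal/mol` at 37 °C.
* **Staged inference** (`fit_slow_binding()` and the stage functions):
  exponential-burst progress-curve fits, weighted `k_obs` saturation
  analysis, double-reciprocal diagnostics, an induced-fit vs
  conformational-selection classifier, Henderson tight-binding regression
  and Michaelis–Menten fits.
* **A synthetic assay** (`simulate_assay()`, `generate_henderson_table()`):
  a stiff ODE integration of the full mechanism coupled to substrate
  turnover, with a seeded noise model, replacing the wet-lab coupled assay.
* **Conformer geometry** (`read_structure()`, `kabsch_superpose()`,
  `aperture_angle()`, `classify_state()`, `generate_conformer()`):
  least-squares Cα superposition, the domain-closure (aperture) angle
  defined by three conserved marker residues, and classification of
  conformers into open/intermediate/closed/super-closed states in the
  (angle, r.m.s.d.) plane.

## Worked example

Simulate a full non-preincubated progress-curve assay at the plant-PDF
parameter set and run the staged analysis:

```r
library(slowbind)

scheme <- kinetic_scheme(k4 = 140, k5 = 63e-3, k6 = 4e-4)   # K_I = 140 nM
mm     <- michaelis_params(kcat = 37, Km = 1e-3)
sim    <- simulate_assay(scheme, mm, assay_design("kobs", seed = 42))
fit    <- fit_slow_binding(assay_curves(sim))
summary(fit)
```

```
Slow, tight-binding kinetic analysis
  18 progress curve(s), 18 usable k_obs point(s)
k_obs saturation fit: k5 = 0.06163 s^-1, k6 = 0.0005339 s^-1, K_I(app) = 1.408e-07 M
  mechanism: induced_fit
  K_I = 141 nM, K_I* = 1.21 nM, t1/2 = 21.6 min

Derived slow, tight-binding parameters
  K_I             141 nM
  K_I*           1.21 nM
  K_I/K_I*        116
  k5             61.6 x1e-3 s^-1
  k6             5.34 x1e-4 s^-1
  k4              141 s^-1
  t1/2           21.6 min
  ddG(tight)     2.93 kcal/mol at 310.15 K

Mechanism verdict: induced_fit
  Kendall tau = 0.800 (p = 9.58e-06), AIC induced-fit = 5.4 vs selection = 105.4
```

The 18 simulated curves (6 inhibitor concentrations × 3 replicates) yield a
rising, saturable `k_obs` — the kinetic fingerprint of induced fit — and the
recovered constants sit within the noise-calibrated tolerances of the
generating values (`k5` 63e-3 s⁻¹, `k6` 4e-4 s⁻¹, `K_I` 140 nM).  The
derived block converts them to the conventional reporting units: nM
dissociation constants, minutes of residence half-life and kcal/mol of
tightening free energy.

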