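---
title: "Two-step slow, tight-binding inhibition: model, inference and synthetic assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step slow, tight-binding inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowbind)
```

## The model

Slow, tight-binding inhibitors of metalloenzymes such as peptide deformylase
act in two steps,

$$E + I \underset{k_4}{\overset{k_3}{\rightleftharpoons}} E{:}I
\underset{k_6}{\overset{k_5}{\rightleftharpoons}} E{:}I^*,$$

a fast, weak encounter ($K_I = k_4/k_3$) followed by a slow isomerization
that tightens the complex.  Under the rapid-equilibrium treatment of the
first step, the approach to the inhibited steady state is pseudo-first-order
with

$$k_{obs} = k_6 + \frac{k_5\,[I]}{K_I + [I]},$$

a *rising* saturable hyperbola.  The contrasting limiting mechanism —
conformational selection, in which the ligand captures a pre-existing minor
conformer — predicts a *falling* dependence, $k_{obs} = k_6 + k_5/(1 +
[I]/K_I)$.  The sign of the concentration dependence of $k_{obs}$ is
therefore the kinetic discriminant between the two mechanisms, and the
package's classifier is built directly on it.

Derived quantities all follow from the four rate constants:

* overall constant $K_I^* = k_4/(k_3 + k_3 k_5/k_6) = K_I\,k_6/(k_5+k_6)$;
* inverse relation $k_6 = k_5/(K_I/K_I^* - 1)$;
* residence half-life $t_{1/2} = 0.693\,(k_4+k_5+k_6)/(k_4 k_6)$, which
  approaches $0.693/k_6$ when $k_6 \ll k_5 \ll k_4$;
* tightening free energy $\Delta\Delta G = RT\ln(K_I/K_I^*)$ with
  $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹, so $RT = 0.616$ kcal/mol at
  310.15 K.

Two conventions are kept deliberately: the association step is assumed
diffusion-limited ($k_3 = 10^9$ M⁻¹s⁻¹, overridable everywhere), and the
half-life formula uses the literal factor 0.693 so that tabulated residence
times reproduce bit-for-bit (a flag switches to exact $\ln 2$).  Internally
every quantity is SI (molar, seconds, kelvin); `scheme_report()` is the one
place where values are converted to the conventional reporting scales (nM,
$10^{-3}$/$10^{-4}$ s⁻¹, minutes, kcal/mol).

A note on the reference parameter set used throughout examples and tests
(the plant PDF–actinonin pair): the consolidated table of that study prints
$k_5 = 63\times10^{-3}$ s⁻¹ and $k_6 = 4\times10^{-4}$ s⁻¹, while its
running text quotes 0.044 and 0.0006 s⁻¹ for the same quantities.  The
tabulated values are treated as authoritative here.  Similarly, the printed
half-life of the third (bacillus) enzyme is inconsistent with the half-life
formula applied to its own row (1.1 min printed vs ~10.5 min computed), so
that entry is not used as a check anywhere.

## Inference pipeline

`fit_slow_binding()` runs the staged analysis a kineticist would do by hand:

1. **Progress curves.**  Each time course is fitted with the integrated
   burst form $P(t) = P_0 + v_s t + (v_0 - v_s)(1 - e^{-k_{obs}t})/k_{obs}$
   (the integral of the velocity equation
   $v_I = v_s + (v_0-v_s)e^{-k_{obs}t}$, which is what a plate reader's
   accumulated product signal actually records).  Because the model is
   linear in $(P_0, v_s, v_0-v_s)$ at fixed rate, starting values come from
   a profiled log-grid scan over $k_{obs}$ followed by Levenberg–Marquardt
   refinement; this avoids the classic divergence of burst fits started
   from finite-difference velocity estimates.  Curves whose curvature
   improvement over a straight line falls below `curvature_tol` (default
   $10^{-3}$ of the total variance) are declared degenerate: the slope is
   reported as $v_0$ and $k_{obs}$ is NA, never a spurious number.
2. **Saturation analysis.**  The $(I, k_{obs})$ series is fitted with the
   rising hyperbola by weighted nonlinear least squares (inverse-variance
   weights from the per-curve standard errors when available, unity
   otherwise — the weighting rule matters because $k_{obs}$ spans two
   decades across the grid).  The same profiled-grid trick over $K_I$
   provides starting values and a constrained fallback when the
   Levenberg–Marquardt normal equations are singular.
3. **Mechanism classification.**  Both monotone rate laws are fitted under
   nonnegativity constraints and compared on weighted residual sums (equal
   parameter counts make this an AIC comparison); independently, a
   two-sided Kendall rank test measures the monotone trend.  The verdict is
   `induced_fit` or `conformational_selection` only when the better model
   and the significant trend direction agree, and `ambiguous` otherwise —
   including whenever the series spans less than a 10-fold concentration
   range over fewer than 5 distinct concentrations.  Unconstrained fits
   must not be compared here: with a negative slope allowed, the rising
   hyperbola family contains every falling hyperbola re-parameterised, and
   the comparison becomes vacuous.
4. **Diagnostics.**  The double-reciprocal line $1/k_{obs}$ vs $1/[I]$ is
   computed on points with $k_{obs} > 10\,k_6$ (the classical condition
   "$k_{obs} \gg k_6$" given a concrete default, configurable).  By default
   the known $k_6$ is subtracted before inverting, which turns the
   asymptotic linearisation into an exact identity (intercept $1/k_5$,
   slope/intercept $= K_I$); the raw classical plot is available behind a
   flag.
5. **Tight-binding constant.**  `henderson_fit()` linearises equilibrated
   fractional velocities as $[I]/(1 - v_i/v_0) = E_t + K_{I^*app}(v_0/v_i)$;
   the slope is the apparent constant, the intercept the total active
   enzyme — a built-in active-site titration.  The competitive correction
   $K_I^* = K_{I^*app}/(1+S/K_m)$ is applied per substrate level and the
   corrected values pooled by mean.  (An alternative reading of the
   linearisation — taking the apparent constant from a velocity-ratio slope
   — exists in some reports; the form above is the standard one and is the
   package default.)

## The synthetic assay

`simulate_assay()` integrates the full mechanism as a stiff ODE system
(relative tolerance $10^{-8}$, absolute $10^{-12}$ M — the rates span six
decades, from $k_3[I] \sim 10^3$ s⁻¹ to $k_6 \sim 10^{-4}$ s⁻¹), tracking
free inhibitor by conservation and substrate turnover by the
Michaelis–Menten rate on free enzyme.  Two deliberate simplifications,
stated as such:

* the downstream dehydrogenase coupling of the real assay is treated as
  instantaneous and stoichiometric (the signal *is* the product
  concentration);
* substrate binding is a rapid equilibrium on free enzyme with no explicit
  ES species.  Consequently the simulated substrate competes for *turnover*
  but not for *inhibitor binding*: the encounter constant recovered from
  simulated data is the true $K_I$, and `fit_slow_binding()` applies the
  competitive correction $K_I^{app}/(1+S/K_m)$ only on request
  (`correct_competition = TRUE`, intended for real competitive assay data).

Default study conditions: the Henderson titration uses 100 nM enzyme and
2 mM substrate (the documented assay conditions of the reference system,
with an inhibitor grid spanning the enzyme concentration); the $k_{obs}$
assay, for which the source protocol does not state concentrations, uses
trace enzyme (0.2 nM), 2 mM substrate and the inhibitor grid 10 nM–3 µM, in
triplicate with 200 samples per curve.  The trace-enzyme choice keeps the
pseudo-first-order condition $[I] \ge 50\,[E]$ across the whole grid (free
inhibitor depletion under 1 % even at 10 nM); the triplicate, densely
sampled curves are ordinary practice for plate-reader kinetics and were
fixed by the Monte-Carlo calibration described below.  The noise model is
1 % multiplicative plus 2 nM additive Gaussian per sample (the protocol
reports no noise model; these are plausible figures for a coupled
absorbance assay), with one master seed driving deterministic per-curve
substreams; the noiseless signal is seed-independent.  The Michaelis
constant of the synthetic substrate is set to 1 mM — a realistic value for
short formylated peptides — because the source does not print one; the
turnover number 37 s⁻¹ is the documented catalytic rate.

Tolerances quoted in the tests (e.g. $k_5$ within 10 % and $k_6$ within
25 % as medians over seeded replicates; 5 % agreement between a
preincubated run's initial velocity and the matched steady state) were
calibrated by Monte-Carlo runs of the full pipeline at exactly these
settings and then frozen.  $k_6$ is the hardest parameter: it contributes
under 10 % of the smallest observed rate in the grid, so its recovery is
limited by the absolute precision of the lowest-concentration $k_{obs}$ —
the reason the defaults insist on replication and dense sampling.

What the simulator does *not* emulate: instrument drift and baseline steps,
substrate depletion feedback on long uninhibited curves (enzyme is trace),
coupling-enzyme lag, pipetting error correlated across a plate, and any
structural realism in the noise.  Passing the recovery tests therefore
shows that the *inference machinery* is unbiased and correctly calibrated
under the stated noise model, not that real assay data of arbitrary quality
will yield constants at these tolerances.

## Conformer geometry

The closure of the enzyme around the ligand is summarised by two numbers
per structure: the r.m.s.d. of its Cα trace against an open reference after
least-squares (Kabsch) superposition, and the aperture angle — the planar
angle at the Cα of a conserved His between the Cα of a conserved Cys and a
conserved Ile (residues 91/137/42 in the reference numbering), one marker
per conserved sequence motif.  Choices made where the convention is not
fixed by any printed number:

* **Vertex.**  The angle's vertex is not dictated by the source material;
  the package defaults to the second listed marker (the His), which sits
  between the N- and C-domain anchors, and `marker_triple()` makes the
  vertex explicit and configurable.  The alternative vertices give
  different absolute angles; comparisons are meaningful only within one
  convention.
* **Superposition.**  Plain least-squares on residue-number-matched Cα
  (SVD with the determinant correction, so reflections are impossible)
  rather than a secondary-structure-matching alignment: deterministic,
  testable, and adequate for single-domain proteins where the residue
  correspondence is trivial.
* **State zones.**  The open/intermediate/closed/super-closed regions of
  the (angle, r.m.s.d.) plane are configuration, not code: the published
  map is graphical and prints no zone boundaries, so they cannot be
  validated at desk scale.  The shipped `default_state_zones()` are an
  explicitly approximate calibration for the synthetic conformer families
  generated by `generate_conformer()`; the one hard number retained from
  experimental practice is that independently determined like-state (open)
  structures superpose below 0.25 Å r.m.s.d., which anchors the open zone's
  r.m.s.d. edge.  Ties on shared zone boundaries go to the first zone in
  configuration order; anything outside every zone is `unassigned`, never
  silently forced into a state.

`generate_conformer()` builds toy Cα scaffolds with an exactly prescribed
aperture angle (markers placed analytically; the rest of the chain fans
between the domain arms so that r.m.s.d. grows smoothly with angle change),
optional coordinate noise, and a rigid pose applied last — the basis for
the property tests that angle and r.m.s.d. are rigid-motion invariant to
numerical precision.  These scaffolds are synthetic stand-ins: real
crystallographic ensembles, electron-density work, and calorimetric
measurements are outside the package's scope, and nothing here claims to
reproduce them.

## Numerical and degenerate-input policy

* Nonlinear fits are Levenberg–Marquardt (`minpack.lm`) with profiled-grid
  starts; every failure path returns a flagged result or an informative
  error, never a silent number.
* Uninhibited (linear) progress curves: degenerate flag, $v_0$ = slope,
  $k_{obs}$ = NA.
* $k_6 = 0$: infinite half-life (warned), $K_I^*$ undefined (error naming
  the irreversible limit).
* Henderson rows with $v_i \ge v_0$ at $[I]>0$ are excluded with a warning;
  zero-inhibitor rows carry no information and are dropped; an all-excluded
  table is an error.
* Superposition requires ≥ 3 matched residues; coincident aperture markers
  are an error, not an angle of 0/NaN.
* Mass conservation of every simulated trace is asserted against solver
  tolerance at generation time.

## Problem sizes

Examples and tests run at the scale of the study design they emulate: 6
inhibitor concentrations × 3 replicates × 200 samples for one assay,
100-replicate Monte-Carlo loops for calibration-style checks, and
1000-pose invariance sweeps for the geometry — a few minutes of CPU in
total, chosen as the smallest sizes at which the stochastic tolerances
above are stable.
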