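---
title: "Surrogate-based uncertainty quantification for Mg implant degradation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-based uncertainty quantification for Mg implant degradation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mguq)
```

# Scope

`mguq` implements a complete uncertainty-quantification (UQ) workflow for
computational models of magnesium implant biodegradation: three deterministic
degradation simulators, one-shot and adaptive design of computer experiments,
three surrogate families (Kriging, polynomial chaos expansion, polynomial
chaos Kriging), surrogate validation, surrogate-based calibration, uncertainty
propagation and variance-based (Sobol) sensitivity analysis. Everything is
exercisable on synthetic data with known ground truth, so the whole chain is
testable end to end.

This vignette records the models, the numerical choices behind them, the
defaults that matter, and the known limitations — including what the synthetic
data can and cannot tell you about real degradation experiments.

# The three degradation models

## Model 1: quasi-1D corrosion of pure Mg (MDD)

Mg dissolution in simulated body fluid (SBF) shows an initial period of slow
degradation (a protective MgO film) followed by a nearly linear regime. The
effective Mg$^{2+}$ release rate at the metal interface is sigmoidal,

$$ q(t) = \frac{\varepsilon\, k_{deg}}{1 + e^{-(t - t_{init})}}, $$

with $\varepsilon$ the porosity of the degradation layer, $k_{deg}$
(mol m$^{-2}$ s$^{-1}$) the rate constant (stored negative, as tabulated; the
solver uses its magnitude) and $t_{init}$ (days) the onset time. The interface
recedes with normal velocity $v = (M_{Mg}/\rho_{Mg})\,|q(t)|$ and the mean
degradation depth is $\mathrm{MDD}(t) = \int_0^t v\,ds$, integrated by the
trapezoidal rule. We adopt the convention $\mathrm{MDD}(0) = 0$, growing to at
most the Mg-domain length $r_{initial}$ (0.2 mm by default); the alternative
convention that starts at $r_{initial}$ and decreases is algebraically
equivalent but physically awkward for a *depth*. When the domain is consumed
before the horizon the trajectory is truncated at the cap and flagged.

Note an important consequence of the published testing range
($k_{deg} \in [-10^{-4}, -10^{-9}]$) together with the porosity default
$\varepsilon = 0.5$ (not published; 0.5 is a mid-range choice for a porous
corrosion product layer): roughly the upper four decades of $|k_{deg}|$
consume the whole 0.2 mm domain before day 28, so MDD(28 d) as a function of
the inputs is a plateau with a kink. This is physically meaningful (the metal
simply runs out) but it dominates how well smooth surrogates can fit the
response, and it is why the adaptive-sampling error for this model stalls
around $10^{-3}$–$10^{-2}$ rather than reaching $10^{-4}$.

## Model 2: precipitate formation in the degradation layer (wt%)

Six dissolved species (Mg$^{2+}$, OH$^-$, H$^+$, HCO$_3^-$, Ca$^{2+}$,
HPO$_4^{2-}$) move by diffusion (optionally electromigration) on a 1D domain
spanning a static porous degradation layer (DL, 20 µm by default, effective
diffusivity $1.4\times10^{-16}$ m$^2$ s$^{-1}$) and the electrolyte (0.2 mm,
free-solution diffusivities). The metal boundary injects Mg$^{2+}$ at the
model-1 rate plus two OH$^-$ per Mg (cathodic water reduction); exactly one
mole of H$_2$ is credited per mole of Mg dissolved, and the solver keeps that
tally.

Six precipitation reactions — brucite, magnesite, nesquehonite, portlandite,
calcite, hydroxyapatite — run only inside the DL with rate

$$ \partial_t c_{p_l} = \varepsilon\, k_l\,(K_{eq,l} - c_i c_j), $$

taken literally with the tabulated signed $k_l$ (negative $k_l$ then means
growth under supersaturation). Hydroxyapatite stoichiometry is fixed as
$5\mathrm{Ca}^{2+} + 3\mathrm{HPO}_4^{2-} + 4\mathrm{OH}^- \to
\mathrm{Ca}_5(\mathrm{PO}_4)_3\mathrm{OH} + 3\mathrm{H_2O}$ (the published
reaction list leaves it implicit) and is overridable. The quantity of interest
is the elemental weight composition of the layer,
$wt_i = 100\,\rho_i / \sum_k \rho_k$ over C, Ca, P, H, O and Mg, computed from
the precipitate inventory and formula compositions.

**Numerics.** Operator splitting: backward-Euler diffusion per species
(variable-width conservative finite volumes, propagator factored once), then
an implicit reaction step per DL cell. The reaction step solves the
backward-Euler system by damped Newton/Gauss–Seidel sweeps on the residual:
stiff reactions (the tabulated $|k_l|$ span many decades, up to
$10^{16}$–$10^{20}$) therefore relax stably to their solubility equilibrium
$c_i c_j = K_{eq,l}$ instead of demanding microsecond time steps, slow
reactions take one explicit-sized step, and at most 95% of a cell's dissolved
inventory can be consumed per update, which keeps every concentration
nonnegative. This scheme converges under time refinement to better than 0.1%
in the day-28 wt% and leaves the response smooth under 1% parameter
perturbations — both checked in the test suite.

**Defaults that are conventions.** The SBF composition of the six tracked
species and the equilibrium constants $K_{eq,l}$ are not published for this
rate form; the shipped values are documented placeholders of realistic
magnitude, fully overridable, and every quantitative test of this module
(conservation, ODE-oracle equivalence, H$_2$ stoichiometry) is independent of
them. Electromigration is off by default: the published transport equation
includes the term but gives no boundary conditions for the potential; when
enabled, the field is closed with a null-current (electroneutral flux)
approximation.

## Model 3: diffusion-limited volume loss of an alloy implant (VL)

Degradation of the Mg–Gd screw is reduced to diffusion of Mg$^{2+}$ from the
implant into the electrolyte, $\partial_t c = \nabla\cdot(D\nabla c)$ (the
well-posed sign), with the implant initially at
$c_0 = 7.13\times10^{-5}$ (Mg–5Gd) or $7.07\times10^{-5}$ mol mm$^{-3}$
(Mg–10Gd), the electrolyte at zero, and a zero-concentration sink at the
outer boundary (emulating medium exchange; a closed box is available). Volume
loss is $VL(t) = 100\,(V(0)-V(t))/V(0)$ with
$V(t) = \int_{implant} c\, dV / c_0$, and the degradation rate is
$DR(t) = (V(0)-V(t))/(A(0)\,t)$ in mm/yr.

Working units are mm, seconds and mm$^2$ s$^{-1}$: the tabulated testing range
$[10^{-12}, 10^{-4}]$ with optima near $6\times10^{-9}$ is only physically
coherent in mm$^2$ s$^{-1}$ (in m$^2$ s$^{-1}$ the 56-day diffusion length
would be 0.17 m for a 2 mm screw), and matches the mol mm$^{-3}$
concentrations published alongside.

**Geometry.** The CAD screw is replaced by (a) an axisymmetric cylinder
(4 mm × Ø2 mm) centred in a cylindrical electrolyte of volume equal to the
3×3×5 mm box, meshed with graded cells refined geometrically toward the
implant surface so that the surface lies exactly on cell faces — the initial
concentration jump makes the surface flux the dominant error source, and with
this mesh halving all steps changes VL(56 d) by under 1% (0.3% at the default
24×36 mesh); and (b) an optional voxel-mask geometry on a regular 3D grid. A
1D slab reduction exists for closed-form verification: with a perfect surface
sink the early-time response obeys the half-space Fickian law
$VL(t) = 100\,(2/L)\sqrt{Dt/\pi}$, which the solver reproduces within 2%.
Time stepping is backward Euler with the sparse system factored once
(Cholesky) and reused.

# Design of experiments

One-shot designs: Monte Carlo, Latin hypercube (via the `lhs` package; one
point per marginal stratum), and Sobol and Halton low-discrepancy sequences
(implemented in-package with direction numbers for up to 12 dimensions;
randomised — digital scramble for Sobol, Cranley–Patterson rotation for
Halton — only when a seed is supplied, so the unseeded sequences are the plain
deterministic ones). The minimum one-shot size is $10N + 2$ for $N$ uncertain
parameters: 22, 82 and 12 for models 1, 2 and 3.

Adaptive sampling starts from a Latin hypercube design, fits the requested
surrogate, and stops when the normalised leave-one-out error drops below a
threshold $\theta$ ($10^{-4}$ by default). Otherwise it adds the point chosen
by a constrained min–max (CMM) rule: from a fresh seeded LHS candidate pool
(100 points per dimension), restricted to the upper quartile of the
surrogate's predictive variance when one is available, pick the candidate
maximising the minimum unit-scaled Euclidean distance to the design, ties to
the lowest index. The published description names the CMM learning function
without defining it; this maximin-with-variance-constraint rule reproduces its
stated intent (space-filling enrichment of high-uncertainty regions) but is
not guaranteed identical to the original implementation. Two further stopping
rules close the loop: the evaluation budget $N_T$, and a no-improvement rule
(10 consecutive fits with under 1% relative improvement of the best error —
the published algorithm mentions the idea without parameters). Simulator
failures reject the point and the loop continues.

# Surrogates

**PCE.** Orthonormal Legendre polynomials of the inputs scaled to $[-1,1]$
(all parameters are uniform), truncated by a hyperbolic $q$-norm index set
($q = 0.75$ by default; $q = 1$ recovers the total-degree set of size
$\binom{p+n}{n}$). Coefficients by least squares (QR), with a small ridge
fallback and warning when the design is rank-deficient. The degree is selected
automatically from a candidate range (1–10 by default) by the leave-one-out
error computed from the hat matrix; saturated bases (as many terms as points)
are skipped because an interpolating least-squares fit makes that closed form
degenerate.

**Kriging.** Gaussian-process regression with a separable anisotropic
Matérn 5/2 correlation, trend either constant (ordinary Kriging, the default;
the published formulation leaves the trend choice open) or a PCE basis.
Lengthscales by profiled maximum likelihood — trend coefficients and process
variance have closed-form profiles — with 5-start bounded L-BFGS on
log-lengthscales in $[0.05, 20]$ (unit-cube units), seeded. A $10^{-10}$
nugget conditions the correlation matrix, escalated to $10^{-6}$ if needed;
the predictor adds the nugget back on exact training-point matches so the
noise-free interpolation contract ($10^{-6}\times$ range) holds even when the
likelihood prefers near-singular lengthscales. Leave-one-out errors use the
closed form from the bordered correlation system (valid for universal
Kriging at fixed hyperparameters), verified in the tests against brute-force
refits to $10^{-8}$.

**PCK.** Sequential construction: select the LOO-optimal sparse PCE basis
first, then fit universal Kriging with that basis as the trend. With a
constant basis PCK degenerates to ordinary Kriging; on an exactly polynomial
response the GP variance collapses and PCK reproduces the PCE.

**Validation.** $\varepsilon_{LOO} = \frac{1}{N}\sum_i
(\mathcal{M}(x_i) - \mathcal{M}_{(-i)}(x_i))^2 / \mathrm{Var}(Y)$, with
$\mathrm{Var}(Y)$ the sample variance of the responses (the denominator is
ambiguous in the published formula; the response variance is the conventional
reading), defined as 0 with a warning for constant responses. $k$-fold
cross-validation is available with $k = N$ (true LOO) as the default, since
the published $k$ is not stated.
$\mathrm{NRMSE} = \sqrt{\frac{1}{N}\sum_j (y_j - \hat y_j)^2} /
(y_{max} - y_{min})$ against reference data.

# Forward UQ

**Sobol indices.** For PCE (and the PCE trend of PCK) the indices are exact
coefficient sums: $S_i$ over terms involving only input $i$, $S_{T,i}$ over
all terms involving $i$, both over the total spectral variance. For Kriging —
which has no such decomposition — a Saltelli-type pick-freeze Monte Carlo
estimator is used ($S_i$ via $\overline{y_B (y_{AB_i} - y_A)}/V$, $S_{T,i}$
via $\overline{(y_A - y_{AB_i})^2}/2V$) with bootstrap (200 resamples) error
bars; small negative estimates are reported as-is with their errors rather
than clipped. The total-index definition is the standard complementary-
variance one (the published subset-sum notation is schematic). The workflow
dispatches automatically: analytic for PCE/PCK, Monte Carlo for Kriging.

**Propagation.** Latin hypercube sample of the input box pushed through the
surrogate (or simulator), summarised by mean, variance and quantiles; aborts
if more than 10% of evaluations fail.

**Calibration.** Minimises the NRMSE between predictions and observations
over the bounded parameter box: a seeded LHS screen (1000 points by default)
followed by derivative-free local refinement — Nelder–Mead in unit
coordinates for $d \ge 2$, Brent's method on the bracket around the best
evaluated point (bounds included) for $d = 1$, because the interesting region
of the one-parameter diffusion model is a boundary layer near zero that a
uniform screen almost never hits, and Nelder–Mead is unreliable in one
dimension. Multi-element calibration for model 2 treats the 5-element wt%
vector as one residual vector (a single day of closed compositional data
makes per-element normalisation degenerate).

# Synthetic calibration data

`make_mdd_dataset()`, `make_wt_dataset()` and `make_vl_dataset()` generate
"experimental" curves from a known ground truth inside the testing ranges:
weekly sampling (days 7/14/21/28, extended by 42/56 for volume loss) to mimic
a typical degradation-experiment cadence, i.i.d. relative Gaussian noise (5%
by default; degradation measurements scale with magnitude — additive noise is
available), wt% rows renormalised to 100 after noising (compositions are
closed), VL clipped to [0, 100]. Each dataset records its truth, noise model
and seed, and can be written as CSV with a JSON sidecar.

What passing tests on these data show — and what they do not: the noiseless
loop closes (calibration recovers the truth to < 1%), the noisy rate constant
$k_{deg}$ recovers to ~5% median, and the diffusivity $D_{Mg}$ recovers via
surrogate-free calibration. They do not show robustness to the features of
real µCT/EDX/weight-loss data: systematic bias, heteroscedastic and
correlated errors, imaging artefacts, replicate structure. One quantitative
caveat is intrinsic rather than synthetic: with weekly sampling and 5%
relative noise the onset time $t_{init}$ is only identifiable to roughly
20–30% (median) — an exact least-squares fit started at the truth does no
better — because all observations sit weeks after the onset transient.
Recovering $t_{init}$ tightly would need observations within the first
2–3 days.

# Problem sizes and reproducibility

The package defaults are desk-scale by design: model 1 is effectively
closed-form (sub-millisecond), model 2 runs in ~0.3–0.5 s (30 cells,
600–1200 steps), model 3 in ~0.05 s (graded 24×36 axisymmetric mesh, 120
implicit steps). The test suite builds all fixtures in code at these sizes;
the acceptance script replays the sampling study with 5 replicate seeds per
model. Every exported stochastic function takes a seed, the workflow spawns
per-stage substreams from one master seed, and rerunning a workflow with the
same configuration and seed reproduces every CSV/JSON artifact byte-for-byte
(wall-clock timings in the manifest excepted). Fitted surrogates serialise to
JSON at 17 significant digits, which round-trips doubles exactly.

# Known limitations

* Model 1's response saturates over much of the published $k_{deg}$ testing
  range (domain consumption), which caps surrogate accuracy and makes the
  published adaptive terminal count of 15 samples unreachable here (the
  initial design alone is 20 points under the published $10 N_p$ rule).
* Model 2's published reaction-constant ranges span 7–11 decades with uniform
  weight; surrogates at ≤ 80 points plateau near
  $\varepsilon_{LOO} \sim 10^{-2}$ on the wt% responses.
* The DL in model 2 is static (no porosity evolution or layer growth), and
  precipitates do not dissolve below zero or passivate the surface.
* Model 3 treats the implant as homogeneous; microstructure, pitting and
  non-uniform corrosion are out of scope, as are electrochemical potentials,
  pH-dependent passivation and in-vivo environments.
* The CMM learning function is a documented reconstruction, not a port.
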