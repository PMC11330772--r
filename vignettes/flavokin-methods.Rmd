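---
title: "Models and numerical methods in flavokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in flavokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavokin)
```

flavokin analyses the kinetics and thermodynamics of FAD-dependent
aryl-alcohol oxidases (AAOs), enzymes that oxidize aryl alcohols to
aldehydes and re-oxidize their flavin either with O2 (oxidase activity,
yielding H2O2) or with quinones such as 1,4-benzoquinone (dehydrogenase
activity, yielding the hydroquinone). This vignette documents the models
the package fits, the conventions and tolerances it adopts, and what its
synthetic-data generators do and do not emulate.

## Bi-substrate steady-state kinetics

Initial rates normalized by enzyme concentration, $v_0/e$, over a grid of
alcohol ($A$) and acceptor ($B$) concentrations are fitted to either the
ping-pong (substituted-enzyme) law

$$\frac{v_0}{e} = \frac{k_{cat}\,A\,B}{K_{mB}A + K_{mA}B + AB}$$

or the sequential (ternary-complex) law, which adds $K_d K_{mB}$ to the
denominator, $K_d$ being the alcohol dissociation constant. The ping-pong
law is the nested $K_d \to 0$ limit. Fitting is unweighted nonlinear
least squares on the rate scale (Levenberg-Marquardt via minpack.lm):
rates on a saturating grid span less than an order of magnitude, so
variance weighting would change little, and unweighted residuals are the
common practice for initial-rate fits. Starting values come from the
Hanes-Woolf linearization ($[A]/v_0$ vs. $[A]$): at the highest acceptor
level the line's slope is close to $1/k_{cat}$ and its intercept to
$K_{mA}/k_{cat}$. Five log-normally perturbed restarts guard against
local minima.

Mechanism discrimination combines two signals. Algebraically, the
Hanes-Woolf intercept at acceptor level $B$ is $K_{mA}/k_{cat}$ for
ping-pong data — independent of $B$ — and
$(K_{mA} + K_d K_{mB}/B)/k_{cat}$ for sequential data, growing as $B$
drops. `discriminate_mechanism()` therefore chooses ping-pong when (i)
the sequential fit does not beat the ping-pong fit by more than 2 AICc
units and (ii) no pair of per-level intercepts differs by more than twice
the pooled standard error; otherwise sequential. The AICc here is
computed from the residual sum of squares under a Gaussian working
likelihood. Catalytic efficiencies $k_{cat}/K_m$ are reported in
s^-1^ mM^-1^ (concentrations are held in µM internally; the factor 1000
is applied only at the reporting boundary).

Oxygen levels stated as gas-mixture percentages are converted to
dissolved µM by `percent_o2_to_uM()`, anchored at a configurable
air-saturation value (default 258 µM at 21% O2, the 25 °C dilute-buffer
value). Because any such conversion is a convention, quantities that
depend on it — notably the O2 Michaelis constants — are reproducible only
up to that convention, and the package leaves the anchor user-settable.

## Transient-state secondary analysis

Observed stopped-flow rate constants are fitted to three secondary
models, matching the role of the varied ligand:

* **Reduction** (hyperbolic): $k_{obs} = k_{red}A/(K_d + A) + k_{rev}$,
  an enzyme–substrate complex preceding hydride transfer. When the 95% CI
  of $k_{rev}$ includes zero the fit is flagged `krev_zero` (hydride
  transfer effectively irreversible). When the largest observed $k_{obs}$
  is below 70% of the fitted $k_{red}$ the series never approached
  saturation, $k_{red}$ and $K_d$ are individually ill-determined, and
  the fit carries a `saturation_not_reached` flag — only their ratio is
  then trustworthy.
* **Reoxidation** (linear): $k_{obs} = {}^{app}k_{ox}[\text{acceptor}] +
  k_{rev}$, weighted by $1/\mathrm{se}^2$ when per-point errors exist.
  The y-intercept is reported as measured and not interpreted
  mechanistically; it is a *different* quantity from the hyperbolic
  model's $k_{rev}$, and the two live in separate result types to avoid
  conflating them.
* **Ligand binding** (linear): $k_{obs} = k_{on}[L] + k_{off}$, with the
  kinetic dissociation constant $K_d = k_{off}/k_{on}$ and a first-order
  (delta-method) standard error, i.e. relative variances of $k_{on}$ and
  $k_{off}$ add. When the $k_{off}$ CI includes zero, no dissociation was
  detected and $K_d$ is reported as an explicit `NA` ("nd"), never as 0.

## Global analysis of time-resolved spectra

Photodiode-array stopped-flow data form a matrix $D$ (times ×
wavelengths). For a sequential first-order scheme with concentration
profiles $C(k)$ (columns $A$, $B$, optionally $C$; the two-step
intermediate uses the confluent limit $k_1 t e^{-k_1 t}$ when the rates
coalesce), the model is $D = C(k)\,S + E$ with $S$ the species spectra.
The fit uses variable projection: for trial rates the spectra are the
exact linear least-squares solution $S = C^+ D$, and only the one or two
rates are optimized (log-scale coarse scan, 80 points or a 24×24
half-grid, then quasi-Newton refinement with tight tolerances, rel.tol
1e-14). This separable treatment is the standard, numerically stable way
to fit exponential models and keeps the search space one- or
two-dimensional. Rate standard errors come from the curvature of the
profiled objective.

Species spectra are *not* constrained non-negative by default:
difference spectra legitimately dip below zero. A `nonneg` flag applies a
clipped refinement when physical species spectra are wanted. For the
$A \to B \to C$ scheme the two rates can be swapped against remixed
spectra (the classic exponential ambiguity); the package reports the
$k_1 \ge k_2$ ordering as its convention, since the ordering — unlike the
amplitude split — is directly testable.

The number of spectrally distinct species is estimated from the singular
values of $D$: a component is retained when its singular value exceeds
$5\,\sigma\sqrt{\max(n_t, n_\lambda)}$, the order of the largest singular
value of an i.i.d. Gaussian noise matrix of that shape (multiplier
configurable). Model selection between one- and two-step schemes requires
the two-step AICc to improve by more than 10 *and* the rank estimate to
support a third species; rank-1 matrices (no spectral evolution) return a
one-step fit flagged `zero_amplitude`. Single-wavelength traces get the
analogous sum-of-exponentials treatment with an offset, plus a collinearity
warning when biexponential rates are separated by less than 3×. Fits are
performed on the native (typically logarithmic) time grid without
resampling, and all first-order fits are invariant to a shift of the time
origin because the basis span is unchanged.

## The catalytic cycle simulator

The turnover simulator integrates mass-action equations for the
alternating cycle: oxidized enzyme is reduced by alcohol (producing
aldehyde), reduced enzyme is re-oxidized by the acceptor. Three nested
variants are supported, because the experimental constants annotate
composite steps rather than elementary ones: (i) the minimal two-state
cycle, with reduction entering through the effective hyperbolic rate
$k_{red}A/(K_d+A)$; (ii) an added product-bound oxidized state whose
decay `krel` models rate-limiting product/hydroquinone release — the step
argued to cap the dehydrogenase turnover; (iii) explicit mass-action
alcohol binding when $k_{on}/k_{off}$ are supplied. Integration uses
deSolve's lsoda with rtol 1e-8 and atol 1e-12 µM — the rate constants
span 10^0^–10^3^ s^-1^, so a stiff method is required — and conservation
of enzyme, alcohol + aldehyde and acceptor + reduced acceptor holds to
1e-9 relative in the tests.

The King-Altman closed form for clamped pools treats the cycle as a ring
of effective first-order steps: $1/\text{turnover} = 1/k_a + 1/k_b\,
(+\,1/k_{rel})$ and each state's occupancy is proportional to the
reciprocal of its exit rate. This yields the independent oracle the ODE
path is tested against (agreement within 1e-4, using a `clamp_pools`
simulation mode). The minimal cycle's steady-state surface is *exactly*
the ping-pong law with $k_{cat} = k_{red}$, $K_{mA} = K_d$ and
$K_{mB} = 1000\,k_{red}/{}^{app}k_{ox}$ µM — an algebraic identity
`scan_apparent_kinetics()` exposes and the tests verify to machine
precision, bridging the transient constants to the steady-state fitter.

Band-I absorbance traces are reconstructed as $\sum_i \varepsilon_i
[\text{species}_i]\,\ell$. The band-I extinction defaults to an
11,300 M^-1^cm^-1^-class value with strongly bleached reduced species,
but quantitative comparison to a measured trace requires the user's own
coefficients. The steady redox state is read from the longest window in
which $|dA_{462}/dt|$ stays below 1% of the initial reduction slope; the
fraction reported is the *median* over that window (the mean carries a
small bias from the tail of the relaxation into the steady state) and is
computed both from species concentrations and from the A462 level, which
agree exactly for a two-level extinction model. Note that constants
measured at different temperatures (reduction at 25 °C, reoxidation at
12 °C for these enzymes) can be mixed in one simulation only verbatim;
the constructor warns when a temperature map says so, and simulated
redox-state percentages under mixed constants should not be compared
quantitatively with observed turnover traces.

## ITC one-site analysis

Per-injection heats follow the single-site binding polynomial with the
perfusion mixing convention: the cell volume is constant, both species
are diluted by $(1 - v/V_0)$ at each injection, and the heat of injection
$i$ is $\Delta H\, V_0 (B_i - (1 - v/V_0) B_{i-1})$ with $B$ the bound
concentration from the usual quadratic. The default cell volume is
200 µL (the low-volume instrument class standard) and the default design
19 × 2 µL injections. Fitting runs over $\log_{10}K_a$, $\Delta H$ and
$n$ from a grid of starting c-values (0.1–10^4^), with $n$ seeded from
the half-heat equivalence point and $\Delta H$ from the first-injection
heat per mole injected; a Levenberg-Marquardt polish supplies standard
errors. Derived quantities use $K_d = 1/K_a$, $\Delta G = RT\ln K_d$ (Kd
in molar, $R = 1.987\times10^{-3}$ kcal mol^-1^ K^-1^) and $-T\Delta S =
\Delta G - \Delta H$, so the thermodynamic identities hold to machine
precision by construction. The Wiseman parameter $c = nK_a[M]$ drives
flags: $c < 1$ (shallow isotherm; $K_a$ and $n$ poorly separable — the
situation for the weaker quinone binder here, $c \approx 0.55$) and $c >
1000$ ($K_a$ effectively a lower bound). A first-injection discard flag
is available but off by default. Buffer-ionization corrections are
deliberately not modelled; all enthalpies are observed values.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure the analyses assume*:
ping-pong/sequential rate surfaces with multiplicative Gaussian noise
(default 2%, typical initial-rate scatter), hyperbolic and linear kobs
series (default 3%, with an averaging mode whose scatter shrinks by
$\sqrt{\text{replicates}}$, mirroring 3–5 averaged shots), rank-2/rank-3
spectral matrices built from sum-of-Gaussian flavin band shapes (band I
at 462 nm, band II at 385 nm; additive 0.002 AU noise; default reduction
times log-spaced over 0.003–0.15 s, the span of a flavin-reduction
transient), and Wiseman isotherms at the stated nominal concentrations
with 2% heat noise. The defaults encode the reference parameter sets in
`aao_constants()`.

They do **not** emulate instrument physics: mixing dead time,
photobleaching, baseline drift, wavelength-correlated noise, or ITC
syringe-diffusion artifacts. Passing recovery tests therefore
demonstrates the estimators are unbiased and correctly propagated under
the assumed noise model — not that they are robust to structured
instrument error, which real data analysis must still assess.

## Problem sizes and reproducibility

Tests and the acceptance script use desk-scale designs chosen to mirror
the experimental ones: 5×5 concentration grids spanning 0.2–10×Km,
8-point reduction series to 6×Kd, 6-point binding series to 8 mM,
40×61 spectral matrices, 19-injection titrations, and 5–20 seeds per
recovery experiment. Every stochastic step takes an explicit integer
seed; no generator touches the global RNG state.

## Known limitations

* The sequential rate law covers the ordered ternary-complex denominator
  only; inhibition terms and pH/temperature dependence are out of scope.
* Spectral global analysis is limited to irreversible sequential
  first-order schemes with two or three species.
* The cycle simulator has no explicit oxidative-half intermediates
  (superoxide/semiquinone) — these are not spectroscopically resolved for
  these enzymes — and no downstream H2O2 chemistry.
* Exact reproduction of O2 Michaelis constants depends on the
  %O2-to-concentration convention (see above).
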