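# flavokin

Kinetic and thermodynamic analysis of flavoenzymes with dual
oxidase/dehydrogenase activity — aryl-alcohol oxidases (AAOs) and related
GMC-superfamily enzymes that oxidize aryl alcohols to aldehydes and
re-oxidize their FAD cofactor with either O2 or quinones such as
1,4-benzoquinone. The package is aimed at enzymologists who want to go
from raw instrument tables (initial rates, stopped-flow kobs values,
photodiode-array spectra, ITC injection heats) to mechanism-level
parameters in a reproducible, scriptable way, with a seeded
synthetic-data module standing in for every instrument so the whole
pipeline can be validated offline.

## What it computes

* **Bi-substrate steady-state kinetics.** Fits
  `v0/e = kcat·A·B/(KmB·A + KmA·B + A·B)` (ping-pong) and its sequential
  counterpart with the extra `Kd·KmB` denominator term, and discriminates
  the mechanisms by AICc together with the Hanes–Woolf criterion (common
  y-intercept `KmA/kcat` across acceptor levels ⇔ ping-pong). Reports
  `kcat`, the Michaelis constants and catalytic efficiencies
  `kcat/Km` in s⁻¹ mM⁻¹.
* **Transient-state secondary analysis.** Hyperbolic flavin reduction
  `kobs = kred·A/(Kd + A) + krev`, linear reoxidation
  `kobs = app_kox·[acceptor] + krev`, and linear one-step ligand binding
  `kobs = kon·[L] + koff` with the kinetic `Kd = koff/kon` and
  propagated errors ("nd" when dissociation is undetectable).
* **Global spectral analysis.** Variable-projection (separable least
  squares) fitting of A→B and A→B→C first-order schemes to time ×
  wavelength absorbance matrices, SVD rank estimation, AICc step-model
  selection, and sum-of-exponentials fits to single-wavelength traces.
* **Catalytic-cycle simulation.** Stiff mass-action ODE integration of
  the reduction/reoxidation cycle (optionally with a rate-limiting
  product-release step), band-I (462 nm) absorbance traces, steady-phase
  redox-state fractions, and a King–Altman closed form used as an
  independent oracle — the minimal cycle is exactly ping-pong.
* **ITC one-site analysis.** Wiseman isotherm simulation and fitting
  (Ka, ΔH, n), with `Kd = 1/Ka`, `ΔG = RT·ln Kd` and `−TΔS = ΔG − ΔH`.

## Worked example

Simulate a 5×5 bi-substrate grid at 2% noise from the reference
parameter set of the *P. eryngii* enzyme with O2
(`kcat = 201 s⁻¹, Km(alcohol) = 50 µM, Km(O2) = 176 µM`; see
`aao_constants()`), then identify the mechanism and fit it:

```r
library(flavokin)

d <- gen_bisubstrate(kcat = 201, Km_alcohol = 50, Km_acceptor = 176,
                     A = c(0.2, 0.5, 1, 3, 10) * 50,
                     B = c(0.2, 0.5, 1, 3, 10) * 176,
                     noise_sd = 0.02, seed = 1)
v <- discriminate_mechanism(d)
v
#> Mechanism verdict: pingpong
#>   AICc ping-pong   35.39
#>   AICc sequential  38.53  (delta 3.14)
#>   Hanes intercepts overlap (+/- 2 SE): TRUE; dispersion (CV) 0.065
v$fit_pingpong
#> Bi-substrate steady-state fit (pingpong mechanism)
#>   kcat              201.1 +/- 2.16 s^-1
#>   Km_alcohol        50.15 +/- 1.34 uM
#>   Km_acceptor       174.5 +/- 4.65 uM
#>   eff_alcohol        4009 s^-1 mM^-1
#>   eff_acceptor       1152 s^-1 mM^-1
#>   n = 25, RSS = 69.03, AICc = 35.39
```

The sequential model's extra `Kd` buys no AICc improvement and the
Hanes–Woolf intercepts coincide across acceptor levels, so the verdict
is ping-pong; the fitted parameters recover the generating values within
their standard errors, and the efficiencies are the `kcat/Km` ratios
after µM→mM conversion. Every fit object supports `tidy()`, `glance()`
and `autoplot()`:

```r
tidy(v$fit_pingpong)     # term/estimate/std.error/units tibble
autoplot(hanes_woolf(d)) # the discrimination plot
```

A tight-binding ITC titration (6 µM cell, 50 µM syringe, 19 × 2 µL):

```r
fit_itc(gen_itc(0.05, -21.4, 1, itc_experiment(6, 50),
                noise_frac = 0.02, seed = 1))
#> One-site ITC fit
#>   Ka         1.7569e+07 M^-1 (+/- 1.7e+06)
#>   dH            -21.441 kcal/mol (+/- 0.167)
#>   n             0.99788  (+/- 0.00527)
#>   Kd           0.056917 uM
#>   dG            -9.8826 kcal/mol
#>   TdS_neg        11.559 kcal/mol
#>   c_value        105.19
```

`Kd`, `ΔG` and `−TΔS` are derived from the fitted `Ka` and `ΔH` by the
standard relations, so they are exactly self-consistent.

A thin command-line wrapper over these functions is installed at
`inst/cli/flavokin.R` (subcommands `fit-steady`, `fit-transient`,
`fit-spectra`, `fit-itc`, `simulate-data`, `mechanism`; exit codes 0 ok,
2 input error, 3 fit failure).

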