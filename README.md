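# bioclimdyn

Tools for treating a long monthly climate record — sunshine duration
`x(t)` (h/month), precipitation `y(t)` (mm/month) and air temperature
`z(t)` (°C) — as observations of a low-dimensional dynamical system, and
for translating both the data and the fitted system into outdoor
bioclimatic conditions via the Universal Thermal Climate Index (UTCI).

The package is aimed at climatologists and biometeorologists who have a
century-scale monthly station record (or want to emulate one) and want to

1. **decompose** each series as `x(t) = x_s(t) + x_fp(t) + x_fc(t)` — a
   multidecadal slow trend `x_s` (10-year centred moving average followed
   by a zero-phase order-4 Butterworth low-pass, cutoff 0.0038 month⁻¹), a
   12-value seasonal profile `x_fp` (per-calendar-month means of the
   detrended data) and a standardized correlated residual `x'_fc`;
2. **model the fast part** as an autoregressive process
   `x'_fc(t) = Σ_{j≤p} φ_j (x'_fc(t−j) − μ) + ε_t`, with the order read off
   the PACF and coefficients fitted by Yule–Walker;
3. **reconstruct the slow part** as an autonomous cubic-polynomial ODE
   system `ẋ = f_s(x,y,z)`, `ẏ = f_p(x,y,z)`, `ż = f_T(x,y,z)`, each `f`
   a complete cubic (20 monomials), by the *trajectory method*: minimize
   the phase-space quality function
   `Q^i = Σ_j Σ_l |x^i_m(t_j + Δt_l) − x^i_r(t_j + Δt_l)|`
   over short model evolutions (`Δt_l = Δt·2^(l−1)`) started from observed
   states, then keep only candidates that are bounded in a long run;
4. **analyse the fitted system** — equilibria (multi-start Newton on
   `f = 0`), Jacobian eigenvalues and focus/node/saddle classification,
   long-term integration and the limit-cycle period from mean-crossings;
5. **compute UTCI series** `UTCI = f(T, v, e, T_mrt)` under constant wind
   scenarios (0.5, 1, 5 m/s), with vapour pressure from the Tetens
   formula, cloudiness from the sunshine/day-length complement, absorbed
   solar radiation from a sun-altitude model, and mean radiant temperature
   `T_mrt = ((R/Irc + 0.5·L_g + 0.5·L_a)/(s_h σ))^0.25 − 273`.

A synthetic-data generator with a *known* benchmark system (a Hopf normal
form with a slaved third variable, limit-cycle period 642 months, mapped
onto a Wrocław-like monthly climatology) makes every stage testable
end-to-end without any external data.

## Worked example

```r
library(bioclimdyn)

# a 117-year synthetic world with known truth
ds  <- generate_dataset(synthetic_config(seed = 3))
dec <- decompose_series(ds$sunshine)
dec
#> <decomposition> 1284 interior months; seasonal range [-83.6, 81.7]; residual sd 0.9835

cg <- correlogram(dec$residual_standardized)
select_order(cg)
#> [1] 1
fit_ar(dec$residual_standardized, 1)
#> <ar_model> AR(1) phi = 0.2652; mu = -1.326e-17, sigma2 = 0.9288

rep <- run_pipeline(pipeline_config(seed = 3, log_level = "quiet"))
rep
#> <run_report>
#>   months: 1404  seed: 3
#>   AR orders: sunshine=1, precipitation=2, temperature=0
#>   ODE search: 10 trials, 3 stable, best Q 0.43446
#>   dynamics: 6 equilibria, 583 years, period undefined months
#>   UTCI 0.5 m/s: mean 13.59 degC (slow 13.77)
#>   UTCI 1 m/s: mean 12.58 degC (slow 12.76)
#>   UTCI 5 m/s: mean 2.10 degC (slow 2.15)
```

Reading the output: the residual AR orders (1, 2, 0) are exactly the
orders the generator used; only 3 of 10 trajectory-method trials survive
the stability screen (reconstruction from one noisy trajectory is
genuinely hard — most fits diverge in a long run), and the surviving
best fit is bounded but does not lock onto the designed 642-month cycle
— recovering the cycle reliably takes noise-free ensemble data (see the
acceptance suite); the mean UTCI drops as the scenario wind rises, the
expected wind-chill ordering.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/bioclimdyn simulate --seed 1 --out out/
Rscript inst/cli/bioclimdyn run-all --in out/dataset.csv --out out/ --seed 1
Rscript inst/cli/bioclimdyn utci --in out/dataset.csv --wind 5 --out out/
```

Input CSVs use the canonical dialect
`year,month,sunshine_h,precip_mm,temp_c[,vapour_hpa][,wind_ms]`.

## Layout

- `R/synthetic.R` – benchmark system, climatology, dataset generator
- `R/decompose.R` – moving average, Butterworth low-pass, decomposition
- `R/ar.R` – correlogram, order selection, Yule–Walker fit, simulation
- `R/trajectory.R` – quality function, initializer, refinement, search
- `R/dynamics.R` – equilibria, classification, long runs, period
- `R/solar.R`, `R/utci.R` – solar geometry, radiation budget, UTCI
- `R/pipeline.R` – full pipeline, run report, CLI
- `vignettes/bioclimdyn-methods.Rmd` – model assumptions and numerics
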