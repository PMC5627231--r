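# rscm — regulation-structured cybernetic modeling of denitrification

`rscm` simulates and calibrates a dynamic model of microbial
denitrification in sediment batch reactors, built for biogeochemists and
modelers who need to reproduce the *delayed* enzymatic responses observed in
real communities — enzyme pools that keep rising for days after their
substrate is depleted and then persist at base levels.

The model lumps denitrification into two reactions sharing dissolved organic
carbon (CH₂O) as electron donor:

    CH2O + 2 f1 NO3-   ->  2 f1 NO2-  + f1 CO2   + (1 - f1)/5 C5H7O2N
    CH2O + 4/3 f2 NO2- ->  2/3 f2 N2  + f2 CO2   + (1 - f2)/5 C5H7O2N

where the energy fraction `f_i` splits consumed carbon between respiration
and biomass (yield `Y_i = (1 - f_i)/5`). The uptake rate of pathway *i* is
dual-substrate Monod kinetics gated by its functional enzyme pool,
`r_i = e_i · k_i · M(DOC, K_d) · M(A_i, K_a)`, and each enzyme pool sits at
the end of an explicit regulation cascade

    resource pool (rho_i)  ->  transcript (tau_i)  ->  enzyme (e_i)

with Monod-type synthesis kinetics and first-order turnover at every stage.
Allocation of inductive resource synthesis between the two competing
pathways follows the cybernetic **matching law**, `u_i = p_i / (p1 + p2)`
with return-on-investment `p_i = r_i`. The full system is 12 ODE states
(six reactor concentrations + six regulatory pools) and conserves carbon
(`DOC + DIC + 5·BM`) and denitrified nitrogen (`NO3 + NO2 + 2·N2`) exactly.

The package provides:

* `rscm_simulate()` — stiff adaptive integration (compiled RHS, `deSolve`)
  with derived series (rates, cybernetic variables, instantaneous yield);
* `lag_table()`, `depletion_time()`, `align_and_correlate()` — peak-time
  lag quantification, depletion landmarks, lag-aligned phase correlations;
* `rscm_fit()`, `rscm_bootstrap()` — bounded least-squares calibration of
  the identifiable parameter set with resampling-based 95% confidence
  intervals (uniform ±SD redraws, per-parameter quantile trimming, min/max
  of retained sets);
* `rscm_generate()` — synthetic observation sets with the batch
  experiment's replicate structure, for recovery and coverage testing;
* `rscm_main()` — a CLI dispatcher (`simulate | lags | fit | bootstrap |
  synth`) with a thin Rscript wrapper in `inst/cli/rscm.R`.

## Worked example

```r
library(rscm)

traj <- rscm_simulate()   # published defaults: 20 d, 0.01 d grid
lag_table(traj)
#>   pathway t_peak_rho t_peak_tau t_peak_e lag_RT lag_TE lag_RE
#> 1       1        2.9        5.9      6.2    3.0    0.3    3.3
#> 2       2        6.8        7.3      7.5    0.5    0.2    0.7

depletion_time(traj$time, traj$xNO2, 0.01)   # nitrite exhausted
#> [1] 6.76047
depletion_time(traj$time, traj$xNO3, 0.01)   # nitrate below 1% of initial
#> [1] 5.718837

conservation_report(traj)
#>       carbon     nitrogen
#> 1.847411e-13 8.775203e-13
```

Reading the lag table: for the nitrate pathway the resource pool peaks at
day 2.9 but the NarG/NapA-class enzyme pool not until day 6.2 — a 3.3-day
enzymatic lag, of which 3.0 days sit between resource generation and the
transcriptional response. The nitrite pathway's cascade is much tighter
(0.7 days end to end). Nitrate effectively runs out at day 5.7 — after
which the biomass yield collapses because the remaining nitrite pathway
respires 99% of the carbon it consumes — and nitrite follows at day 6.8.
The conservation drifts are pure integration error (sub-picomolar).

Calibration closes the loop on synthetic data:

```r
gen <- rscm_generate(design = default_design(noise = 0))   # noise-free truth
fit <- rscm_fit(gen$obs, free = c("k1", "f1"),
                start = c(k1 = 8.1, f1 = 0.73))
round(fit$par, 4)
#>     k1     f1
#> 6.2300 0.5600
```

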