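---
title: "A regulation-structured cybernetic model of two-step denitrification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A regulation-structured cybernetic model of two-step denitrification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rscm)
```

## The problem

Denitrifying microbial communities in sediments respond to substrate changes
with lags of several days: functional enzymes keep accumulating after their
substrate is gone, and enzyme pools persist long after reduction has ceased.
Plain Monod kinetics cannot produce this behavior, because in such models the
reaction rate tracks the substrate instantaneously. `rscm` implements a
dynamic community model in which the lag *emerges* from an explicit
regulation cascade — internal resources are allocated to transcription, and
transcripts are translated into enzymes — so that the enzymatic response is
delayed and smoothed by the turnover times of the intermediate pools.

The model is *enzyme-based* trait modeling: the community is described by the
functional enzyme pools it expresses, not by species or guild biomasses.
This keeps the parameter count independent of community composition and lets
the model be calibrated directly against enzyme concentrations measured by
signature-peptide proteomics.

## Reaction network and stoichiometry

Denitrification is lumped into two reactions sharing dissolved organic carbon
(DOC, modeled as CH$_2$O) as electron donor:

* pathway 1: CH$_2$O + $2f_1$ NO$_3^-$ $\rightarrow$ $2f_1$ NO$_2^-$ +
  $f_1$ CO$_2$ + $\frac{1-f_1}{5}$ C$_5$H$_7$O$_2$N
* pathway 2: CH$_2$O + $\frac{4}{3}f_2$ NO$_2^-$ $\rightarrow$
  $\frac{2}{3}f_2$ N$_2$ + $f_2$ CO$_2$ + $\frac{1-f_2}{5}$ C$_5$H$_7$O$_2$N

The energy fraction $f_i$ is the share of carbon respired through pathway
$i$; the rest is assimilated, giving a stoichiometric biomass yield
$Y_i = (1-f_i)/5$ per mole DOC. The intermediate species NO and N$_2$O are
assumed fast and are not carried as states; NH$_4^+$, H$^+$, and H$_2$O are
excluded from the balances.

One stoichiometric coefficient deserves a note. For pathway 2, nitrogen
balance forces the N$_2$ coefficient to be $\frac{2}{3}f_2$ per mole DOC
($\frac{4}{3}f_2$ moles of nitrite nitrogen leave as $2 \times \frac{2}{3}f_2$
moles of N$_2$ nitrogen). Renderings of this reaction network sometimes
typeset the N$_2$ row differently; this package treats elemental balance as
non-negotiable and uses $\frac{2}{3}f_2$, which makes
$\dot x_{NO_3} + \dot x_{NO_2} + 2\,\dot x_{N_2} = 0$ an exact identity. The
companion identity $\dot x_{DOC} + \dot x_{DIC} + 5\,\dot x_{BM} = 0$
(biomass C$_5$H$_7$O$_2$N carries five carbons) closes the carbon balance,
including the biomass-degradation feedback $5 k_{deg} x_{BM}$ into DOC.

## Regulated kinetics

The realized DOC uptake rate of pathway $i$ is the unregulated Monod product
gated by the enzyme pool:

$$r_i = e_i\, r_i^{kin}, \qquad
  r_i^{kin} = k_i \frac{x_{DOC}}{K_{d,i}+x_{DOC}}
                  \frac{x_{A_i}}{K_{a,i}+x_{A_i}}$$

with acceptor $A_1 =$ NO$_3^-$, $A_2 =$ NO$_2^-$. Per pathway, three
regulatory pools evolve:

$$\dot\rho_i = \alpha_{R,i} + u_i\, r_{R,i} - \beta_{R,i}\rho_i, \qquad
  \dot\tau_i = r_{T,i} - \beta_{T,i}\tau_i, \qquad
  \dot e_i = r_{E,i} - \beta_{E,i} e_i$$

where $\rho_i$ is a lumped internal resource pool (ATP, polymerases,
ribosomes, genes), $\tau_i$ the transcript pool, and $e_i$ the enzyme pool.
Synthesis kinetics mirror the uptake form: resource synthesis $r_{R,i}$ is
driven by DOC and the pathway's acceptor (with no enzyme factor — the
printed form of the model is followed here), transcription saturates in
$\rho_i$, and translation saturates in both $\tau_i$ and $\rho_i$:

$$r_{T,i} = k_{T,i}\frac{\rho_i}{K_{T,i}+\rho_i}, \qquad
  r_{E,i} = k_{E,i}\frac{\tau_i}{K^T_{E,i}+\tau_i}
                   \frac{\rho_i}{K^R_{E,i}+\rho_i}.$$

The published parameter table lists a single translation half-saturation
$K_{E,i} = 0.25$; the package applies it to both the transcript and the
resource factor, consistent with the table's "assumed equal to $K_{d,i}$"
convention.

Resource allocation between the two competing pathways follows the cybernetic
**matching law**: the fraction of inductive resource synthesis allocated to
pathway $i$ is its relative return-on-investment,

$$u_i = \frac{p_i}{p_1 + p_2}, \qquad p_i = r_i,$$

i.e. resources flow to pathways in proportion to the carbon uptake they
currently deliver. When both returns vanish ($p_1 + p_2 = 0$) the package
sets $u_1 = u_2 = 0$: inductive synthesis switches off and only the
constitutive terms $\alpha_{R,i}$ persist, which is the continuous limit and
avoids an arbitrary regularization scale. The same convention defines the
instantaneous community yield $\left(\sum_i Y_i r_i\right)/\sum_i r_i$ as 0
when no carbon is being taken up.

## Parameters that matter

| symbol | meaning | unit | default |
|---|---|---|---|
| $f_1, f_2$ | energy fraction per pathway | – | 0.56, 0.99 |
| $k_1, k_2$ | max DOC uptake per unit enzyme | mM·(g soil/pmol)/d | 6.23, 5.71 |
| $K_{d,i}$ | DOC half-saturation | mM | 0.25 |
| $K_{a,1}, K_{a,2}$ | acceptor half-saturation | mM | 0.001, 0.004 |
| $k_{deg}$ | biomass turnover | 1/d | 0.11 |
| $k_{R,i}$ | inductive resource synthesis | 1/d | 2.84, 1.03 |
| $k_{T,i}$ | transcription | 1/d | 0.13, 0.25 |
| $k_{E,i}$ | translation | 1/d | 1.84, 1.56 |
| $K_{T,i}, K^T_{E,i}, K^R_{E,i}$ | cascade half-saturations | – | 0.25 |
| $\alpha_{R,i}$ | constitutive resource synthesis | 1/d | 0.2 |
| $\beta_{R,i}, \beta_{T,i}, \beta_{E,i}$ | pool degradation | 1/d | 0.8 |

Enzyme states are carried in pmol/g soil and nutrients in mM throughout; the
unit of $k_i$ makes $e_i r_i^{kin}$ come out in mM/d with no internal
conversion. The high value $f_2 = 0.99$ means pathway 2 contributes almost
no biomass, which is why the community yield collapses once nitrate is gone
and NO$_2^-$ reduction carries the remaining flux.

## Numerical choices

* **Solver contract.** `rscm_simulate()` uses `deSolve::lsoda` (adaptive,
  stiff-capable) at `rtol = 1e-8`, `atol = 1e-10`, sampling a uniform grid
  of 0.01 d over a 20-day default horizon. The grid, not the solver steps,
  defines where derived series (rates, cybernetic variables, yield) are
  evaluated, so they are solver-agnostic. These tolerances keep the drift
  of both conserved element sums below $10^{-6}$ mM over the default run.
* **Negative excursions.** The right-hand side evaluates Monod factors on
  states clipped at zero, so the adaptive solver may probe tiny negative
  values without error; trajectories are reported unclipped and a post-hoc
  check rejects any excursion below $-10\,\cdot$ `atol`. Values inside that
  band are numerical zeros (exhausted species).
* **Peak times and ties.** Lags are differences of global-maximum times;
  ties break to the earliest time. Peak times are rounded to 0.1 d before
  differencing — the customary reporting resolution — which keeps
  `lag_RE = lag_RT + lag_TE` exact at the reported precision. A regulatory
  series whose maximum sits on the final grid point has not peaked; the lag
  table refuses to report it rather than truncating.
* **Depletion threshold.** "Depleted" is operationalized as the first
  post-peak crossing below 1% of a reference level (initial value for
  species present at $t=0$, transient maximum otherwise), linearly
  interpolated between grid points. The resulting times move by less than
  the reporting resolution for thresholds anywhere in 0.5–2%.
* **Phase alignment.** Phase-diagram correlations remove the cascade delay
  by shifting the trailing series earlier by the peak-time lag — the only
  lag definition the model commits to — then computing the Pearson
  correlation on the overlap.

## Calibration

`rscm_fit()` minimizes the sum of squared weighted residuals over the
model's identifiable free set ($k_1, k_2, k_{R,i}, k_{T,i}, k_{E,i},
k_{deg}, f_1$) with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`).
Half-saturation constants and the constitutive/degradation constants stay
fixed: a single batch trajectory cannot identify them.

* **Weighting.** Each residual is normalized by the maximum observed mean of
  its observable, making mM-scale nutrients and pmol-scale enzymes
  commensurate. SD-weighting is a documented alternative; max-mean weighting
  is the default because replicate SDs estimated from 2–3 replicates are
  themselves very noisy.
* **Local minima.** The objective surface has genuine local minima (e.g. a
  basin with $f_1 \to 1$). `rscm_fit(n_starts = )` runs a fixed-seed
  multi-start (log-uniform jitter within a factor 2) and keeps the best
  objective; five starts reliably find the global optimum on synthetic data.
* **Failed trials.** A trial simulation that blows up returns penalty
  residuals (10× the largest clean residual magnitude seen so far) instead
  of aborting, so bounded search may probe stiff corners.
* **Bootstrap CIs.** `rscm_bootstrap()` follows the replicate-scatter
  resampling scheme: each of `n_sets` datasets redraws every
  (time, observable) mean uniformly within ±SD; each dataset is refit
  (starting from the point estimate); parameter sets with any coordinate
  outside the per-parameter 2.5–97.5% linear-interpolation quantiles are
  removed; the min/max of each parameter over the retained sets are the 95%
  limits. Each set uses seed substream `seed + set`, so any subset is
  reproducible independently.

A caveat the package's own tests quantify: this min/max-with-trimming
interval is **not a calibrated joint confidence region**. With ten free
parameters, trimming discards every set extreme in *any* coordinate, and the
transcription/translation pair $(k_{T,i}, k_{E,i})$ is only weakly
identified when transcripts and resources are unobserved — the data's global
optimum can shift along that ridge by more than the resampling spread. Joint
"all ten parameters inside" coverage on synthetic data is therefore well
below 95%, and individual bounds can miss a true value narrowly. The
procedure is reported as specified because it is the published uncertainty
summary; users who need calibrated regions should use profile likelihood or
a Bayesian treatment.

## The synthetic-data generator

`rscm_generate()` emulates the batch experiment's measurement design:
21 daily sampling times over 20 days; the nutrients DOC, DIC, NO$_3^-$,
NO$_2^-$ in three replicates; the enzyme observables E1 (NarG/NapA class)
and E2 (NosZ class) as two effective replicates (the average over two
signature peptides measured in duplicate). Noise is multiplicative Gaussian,
default 5% relative — chosen because the observables span three orders of
magnitude, so a relative law keeps errors comparable across them — with the
draw clamped at $-1$ so concentrations stay non-negative; an additive law is
available. The generator is a stand-in for the real assays, not a
measurement model: it does not emulate peptide recovery, digestion
efficiency, detection limits, or correlated replicate errors, so passing
recovery tests demonstrates the estimator's behavior under idealized noise,
not performance on real proteomics data.

## Problem sizes used by the test suite

The packaged tests exercise the model at the scale of the study design:
the full 20-day, 0.01-d-grid forward run for lag and conservation checks; a
fixed-step RK4 cross-check at $\Delta t = 10^{-4}$ d against the adaptive
solution at 40 checkpoints; a ten-parameter noise-free recovery fit with
five optimizer starts; and a 50-set bootstrap (the published procedure uses
500 sets; 50 preserves the trimming fractions while keeping the refit count
proportionate for a smoke test of the interval machinery).

## Known limitations

* NO and N$_2$O are not explicit states; predictions for those intermediates
  are out of scope by construction.
* Post-translational control of enzyme *activity* is absent: regulation acts
  only through synthesis. Fast allosteric shifts would need an additional
  activity variable.
* The DNRA pathway is not modeled (the motivating experiments showed no
  ammonium formation).
* Transport is absent; the model describes a homogeneous batch reactor.
  Coupling to a reactive-transport code is an integration task, not a
  package feature.
* The kinetic constants are a single calibration for one sediment community
  and one initial condition; transferring them to other systems requires
  refitting.
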