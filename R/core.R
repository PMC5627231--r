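#' Monod saturation factor
#'
#' The saturating factor `x / (K + x)` used throughout the model for substrate
#' limitation of uptake, transcription, and translation.
#'
#' @param x substrate concentration (or dimensionless abundance), `>= 0`.
#' @param K half-saturation constant, `> 0`, same units as `x`.
#' @return Dimensionless fraction in `[0, 1)`. Vectorized over `x` and `K`.
#' @export
#' @examples
#' monod_factor(0.25, 0.25)  # half-saturation: 0.5
monod_factor <- function(x, K) {
  if (any(!is.finite(x)) || any(!is.finite(K)))
    stop("monod_factor: non-finite input")
  if (any(x < 0)) stop("monod_factor: negative concentration")
  if (any(K <= 0)) stop("monod_factor: half-saturation must be positive")
  x / (K + x)
}

#' Unregulated dual-substrate uptake kinetics
#'
#' Monod products for the two reduction pathways before enzyme regulation:
#' `r1_kin = k1 M(DOC, Kd1) M(NO3, Ka1)` and
#' `r2_kin = k2 M(DOC, Kd2) M(NO2, Ka2)`. The realized carbon uptake rate of
#' pathway i is `e_i * r_i_kin` (mM/d).
#'
#' @param state model state, see [rscm_init()].
#' @param params parameter set, see [rscm_params()].
#' @return Named numeric vector `c(r1_kin, r2_kin)`.
#' @export
unregulated_rates <- function(state, params) {
  c(r1_kin = params$k1 * monod_factor(state[["xDOC"]], params$Kd1) *
      monod_factor(state[["xNO3"]], params$Ka1),
    r2_kin = params$k2 * monod_factor(state[["xDOC"]], params$Kd2) *
      monod_factor(state[["xNO2"]], params$Ka2))
}

#' Cybernetic resource-allocation fractions (matching law)
#'
#' Distributes the inductive resource-synthesis effort between the two
#' pathways in proportion to each pathway's return-on-investment `p_i`
#' (here the pathway's carbon uptake rate): `u_i = p_i / (p_1 + p_2)`.
#' When both returns are zero no inductive allocation is made and both
#' fractions are zero, leaving only constitutive resource synthesis active.
#'
#' @param p1,p2 return-on-investment of each pathway, `>= 0`.
#' @return Named numeric vector `c(u1, u2)`; sums to 1 unless both inputs
#'   are zero.
#' @export
#' @examples
#' cybernetic_u(3, 1)  # c(0.75, 0.25)
cybernetic_u <- function(p1, p2) {
  if (!is.finite(p1) || !is.finite(p2)) stop("cybernetic_u: non-finite input")
  if (p1 < 0 || p2 < 0) stop("cybernetic_u: returns must be non-negative")
  s <- p1 + p2
  if (s > 0) c(u1 = p1 / s, u2 = p2 / s) else c(u1 = 0, u2 = 0)
}

#' Synthesis rates of resources, transcripts, and enzymes
#'
#' The regulation cascade uses the same Monod forms as substrate uptake:
#' resource synthesis is driven by DOC and the pathway's electron acceptor,
#' transcription saturates in the resource pool, and translation saturates in
#' both the transcript and the resource pool:
#' \deqn{r_{R,i} = k_{R,i} M(DOC, K_{d,i}) M(A_i, K_{a,i}), \quad
#'       r_{T,i} = k_{T,i} M(\rho_i, K_{T,i}), \quad
#'       r_{E,i} = k_{E,i} M(\tau_i, K^T_{E,i}) M(\rho_i, K^R_{E,i})}
#' with \eqn{A_1 = NO_3^-}, \eqn{A_2 = NO_2^-}.
#'
#' @inheritParams unregulated_rates
#' @return Named numeric vector `c(rR1, rR2, rT1, rT2, rE1, rE2)` (1/d).
#' @export
synthesis_rates <- function(state, params) {
  c(rR1 = params$kR1 * monod_factor(state[["xDOC"]], params$Kd1) *
      monod_factor(state[["xNO3"]], params$Ka1),
    rR2 = params$kR2 * monod_factor(state[["xDOC"]], params$Kd2) *
      monod_factor(state[["xNO2"]], params$Ka2),
    rT1 = params$kT1 * monod_factor(state[["rho1"]], params$KT1),
    rT2 = params$kT2 * monod_factor(state[["rho2"]], params$KT2),
    rE1 = params$kE1 * monod_factor(state[["tau1"]], params$KET1) *
      monod_factor(state[["rho1"]], params$KER1),
    rE2 = params$kE2 * monod_factor(state[["tau2"]], params$KET2) *
      monod_factor(state[["rho2"]], params$KER2))
}

#' Instantaneous community biomass yield
#'
#' Ratio of the biomass production rate to the total carbon uptake rate,
#' `(Y1 r1 + Y2 r2) / (r1 + r2)` with stoichiometric pathway yields
#' `Y_i = (1 - f_i)/5` (mol biomass carbon chain C5H7O2N per mol DOC).
#' Defined as 0 when both rates vanish.
#'
#' @param r1,r2 regulated carbon uptake rates, mM/d, `>= 0`.
#' @param params parameter set, see [rscm_params()].
#' @return Dimensionless yield in `[0, max(Y1, Y2)]`.
#' @export
instantaneous_yield <- function(r1, r2, params) {
  if (any(!is.finite(c(r1, r2)))) stop("instantaneous_yield: non-finite rate")
  if (any(c(r1, r2) < 0)) stop("instantaneous_yield: negative rate")
  s <- r1 + r2
  Y1 <- (1 - params$f1) / 5
  Y2 <- (1 - params$f2) / 5
  ifelse(s > 0, (Y1 * r1 + Y2 * r2) / s, 0)
}

#' All derived rate quantities at a model state
#'
#' Evaluates the unregulated kinetics, regulated rates, cybernetic variables,
#' cascade synthesis rates, and instantaneous yield at a single state.
#'
#' @inheritParams unregulated_rates
#' @return Named numeric vector with components `r1_kin, r2_kin, r1, r2,
#'   u1, u2, p1, p2, rR1, rR2, rT1, rT2, rE1, rE2, yield_inst`.
#' @export
derived_rates <- function(state, params) {
  kin <- unregulated_rates(state, params)
  r1 <- state[["e1"]] * kin[["r1_kin"]]
  r2 <- state[["e2"]] * kin[["r2_kin"]]
  u <- cybernetic_u(r1, r2)
  syn <- synthesis_rates(state, params)
  c(kin, r1 = r1, r2 = r2, u, p1 = r1, p2 = r2, syn,
    yield_inst = instantaneous_yield(r1, r2, params))
}

#' Time derivative of the full 12-state model
#'
#' Evaluates the right-hand side of the coupled nutrient/biomass and
#' regulation-cascade balances. Stoichiometry per mol DOC consumed: pathway 1
#' reduces `2 f1` NO3- to NO2- and respires `f1` C to DIC; pathway 2 reduces
#' `4/3 f2` NO2- to `2/3 f2` N2 and respires `f2` C; the unrespired fraction
#' `(1 - f_i)/5` becomes biomass, and biomass decays back to DOC at `kdeg`
#' (5 C per biomass unit). Per pathway the resource pool gains constitutive
#' synthesis `alphaR_i` plus the allocated share `u_i rR_i`, transcripts gain
#' `rT_i`, enzymes gain `rE_i`, and each regulatory pool decays first-order.
#'
#' Two exact conservation identities hold at every state:
#' `dDOC + dDIC + 5 dBM = 0` (carbon) and `dNO3 + dNO2 + 2 dN2 = 0`
#' (denitrified nitrogen).
#'
#' State components are clipped at zero before evaluating the Monod factors so
#' the derivative tolerates the tiny negative excursions an adaptive
#' integrator may produce.
#'
#' @inheritParams unregulated_rates
#' @return Named numeric vector of the 12 time derivatives (per day), in the
#'   canonical state order.
#' @export
rscm_rhs <- function(state, params) {
  if (any(!is.finite(state))) stop("rscm_rhs: non-finite state")
  y <- pmax(unclass(state), 0)
  names(y) <- names(state)
  kin <- unregulated_rates(y, params)
  r1 <- y[["e1"]] * kin[["r1_kin"]]
  r2 <- y[["e2"]] * kin[["r2_kin"]]
  u <- cybernetic_u(r1, r2)
  syn <- synthesis_rates(y, params)
  f1 <- params$f1; f2 <- params$f2
  d <- c(
    xDOC = -r1 - r2 + 5 * params$kdeg * y[["xBM"]],
    xNO3 = -2 * f1 * r1,
    xNO2 = 2 * f1 * r1 - (4 / 3) * f2 * r2,
    xN2  = (2 / 3) * f2 * r2,
    xDIC = f1 * r1 + f2 * r2,
    xBM  = (1 - f1) / 5 * r1 + (1 - f2) / 5 * r2 - params$kdeg * y[["xBM"]],
    rho1 = params$alphaR1 + u[["u1"]] * syn[["rR1"]] - params$betaR1 * y[["rho1"]],
    rho2 = params$alphaR2 + u[["u2"]] * syn[["rR2"]] - params$betaR2 * y[["rho2"]],
    tau1 = syn[["rT1"]] - params$betaT1 * y[["tau1"]],
    tau2 = syn[["rT2"]] - params$betaT2 * y[["tau2"]],
    e1   = syn[["rE1"]] - params$betaE1 * y[["e1"]],
    e2   = syn[["rE2"]] - params$betaE2 * y[["e2"]]
  )
  d
}
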