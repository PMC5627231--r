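#' Kinetic and regulation parameters for the two-step denitrification model
#'
#' Constructs the full parameter set of the regulation-structured cybernetic
#' model (RSCM). The model lumps denitrification into two reactions sharing
#' dissolved organic carbon (DOC, modeled as CH2O) as electron donor:
#' pathway 1 reduces NO3- to NO2-, pathway 2 reduces NO2- to N2. A fraction
#' `f_i` of the carbon taken up through pathway i is respired for energy; the
#' remainder is assimilated into biomass (C5H7O2N, 5 carbons per mole), so the
#' stoichiometric biomass yield of pathway i is `(1 - f_i)/5` mol BM per mol
#' DOC. Each pathway carries its own regulation cascade: an internal resource
#' pool (rho, lumping ATP, polymerases, ribosomes, genes), transcripts (tau),
#' and a functional enzyme pool (e) that multiplies the unregulated Monod
#' kinetics.
#'
#' Defaults are the published calibration for the Columbia River hyporheic
#' zone sediment batch experiment. Units: uptake rate constants `k1`, `k2`
#' (and enzyme-synthesis-scale constants) are in mM (g soil / pmol enzyme)/d
#' so that `e_i * r_i_kin` is in mM/d; half-saturation constants for DOC and
#' the electron acceptors in mM; all first-order synthesis/degradation
#' constants in 1/d; `f1`, `f2` and the regulation half-saturations are
#' dimensionless.
#'
#' @param f1,f2 fraction of energy production (respired carbon) for pathway 1
#'   (NO3- reduction) and pathway 2 (NO2- reduction), in `[0, 1]`.
#' @param k1,k2 maximum DOC-uptake rate constants per unit enzyme,
#'   mM (g soil/pmol)/d.
#' @param Kd1,Kd2 DOC half-saturation constants, mM.
#' @param Ka1,Ka2 electron-acceptor (NO3-, NO2-) half-saturation constants, mM.
#' @param kdeg first-order biomass degradation rate constant, 1/d; degraded
#'   biomass carbon is returned to the DOC pool.
#' @param kR1,kR2 inductive resource-pool synthesis rate constants, 1/d.
#' @param kT1,kT2 transcript synthesis rate constants, 1/d.
#' @param kE1,kE2 enzyme (translation) synthesis rate constants, 1/d.
#' @param KT1,KT2 half-saturation of transcription with respect to the
#'   resource pool, dimensionless.
#' @param KET1,KET2 half-saturation of translation with respect to the
#'   transcript, dimensionless.
#' @param KER1,KER2 half-saturation of translation with respect to the
#'   resource pool, dimensionless.
#' @param alphaR1,alphaR2 constitutive resource synthesis rates, 1/d.
#' @param betaR1,betaR2,betaT1,betaT2,betaE1,betaE2 first-order degradation
#'   rate constants of resources, transcripts, and enzymes, 1/d.
#'
#' @return A named list of class `rscm_params`.
#' @seealso [rscm_init()] for the companion initial state,
#'   [rscm_simulate()] to integrate the model.
#' @export
#' @examples
#' p <- rscm_params()
#' p$f1
#' rscm_params(f1 = 0.4, kdeg = 0.05)
rscm_params <- function(f1 = 0.56, f2 = 0.99,
                        k1 = 6.23, k2 = 5.71,
                        Kd1 = 0.25, Kd2 = 0.25,
                        Ka1 = 0.001, Ka2 = 0.004,
                        kdeg = 0.11,
                        kR1 = 2.84, kR2 = 1.03,
                        kT1 = 0.13, kT2 = 0.25,
                        kE1 = 1.84, kE2 = 1.56,
                        KT1 = 0.25, KT2 = 0.25,
                        KET1 = 0.25, KET2 = 0.25,
                        KER1 = 0.25, KER2 = 0.25,
                        alphaR1 = 0.2, alphaR2 = 0.2,
                        betaR1 = 0.8, betaR2 = 0.8,
                        betaT1 = 0.8, betaT2 = 0.8,
                        betaE1 = 0.8, betaE2 = 0.8) {
  p <- list(f1 = f1, f2 = f2, k1 = k1, k2 = k2,
            Kd1 = Kd1, Kd2 = Kd2, Ka1 = Ka1, Ka2 = Ka2,
            kdeg = kdeg, kR1 = kR1, kR2 = kR2,
            kT1 = kT1, kT2 = kT2, kE1 = kE1, kE2 = kE2,
            KT1 = KT1, KT2 = KT2, KET1 = KET1, KET2 = KET2,
            KER1 = KER1, KER2 = KER2,
            alphaR1 = alphaR1, alphaR2 = alphaR2,
            betaR1 = betaR1, betaR2 = betaR2,
            betaT1 = betaT1, betaT2 = betaT2,
            betaE1 = betaE1, betaE2 = betaE2)
  validate_params(p)
  structure(p, class = "rscm_params")
}

# canonical parameter order, shared with the compiled derivative function
.param_names <- c("f1", "f2", "k1", "k2", "Kd1", "Kd2", "Ka1", "Ka2",
                  "kdeg", "kR1", "kR2", "kT1", "kT2", "kE1", "kE2",
                  "KT1", "KT2", "KET1", "KET2", "KER1", "KER2",
                  "alphaR1", "alphaR2", "betaR1", "betaR2",
                  "betaT1", "betaT2", "betaE1", "betaE2")

# names a user is allowed to free in calibration (the model's fitted set)
.free_param_names <- c("k1", "k2", "kR1", "kR2", "kT1", "kT2",
                       "kE1", "kE2", "kdeg", "f1")

validate_params <- function(p) {
  miss <- setdiff(.param_names, names(p))
  if (length(miss) > 0)
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  num <- vapply(p[.param_names], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num))
    stop("non-finite or non-scalar parameter(s): ",
         paste(.param_names[!num], collapse = ", "))
  if (p$f1 < 0 || p$f1 > 1 || p$f2 < 0 || p$f2 > 1)
    stop("energy fractions f1, f2 must lie in [0, 1]")
  strict_pos <- c("k1", "k2", "Kd1", "Kd2", "Ka1", "Ka2", "kdeg",
                  "kR1", "kR2", "kT1", "kT2", "kE1", "kE2",
                  "KT1", "KT2", "KET1", "KET2", "KER1", "KER2",
                  "betaR1", "betaR2", "betaT1", "betaT2", "betaE1", "betaE2")
  bad <- strict_pos[vapply(p[strict_pos], function(x) x <= 0, logical(1))]
  if (length(bad) > 0)
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (p$alphaR1 < 0 || p$alphaR2 < 0)
    stop("constitutive synthesis rates alphaR1, alphaR2 must be non-negative")
  invisible(p)
}

#' Initial state of the 12-variable denitrification model
#'
#' The model state holds six reactor concentrations (mM) -- dissolved organic
#' carbon, nitrate, nitrite, dinitrogen, dissolved inorganic carbon, biomass --
#' and, per pathway, the internal resource pool and transcript abundances
#' (dimensionless) and the functional enzyme concentration (pmol/g soil).
#' Defaults are the batch experiment's measured initial nutrient
#' concentrations with small positive seeds for the regulatory states.
#'
#' @param xDOC,xNO3,xNO2,xN2,xDIC,xBM initial concentrations, mM.
#' @param rho1,rho2 initial internal resource pool abundances, dimensionless.
#' @param tau1,tau2 initial transcript abundances, dimensionless.
#' @param e1,e2 initial enzyme concentrations, pmol/g soil.
#'
#' @return A named numeric vector of length 12, class `rscm_state`, in the
#'   canonical order `xDOC, xNO3, xNO2, xN2, xDIC, xBM, rho1, rho2, tau1,
#'   tau2, e1, e2`.
#' @export
#' @examples
#' rscm_init()
#' rscm_init(xNO3 = 10, xBM = 0.5)
rscm_init <- function(xDOC = 61.1, xNO3 = 18.3, xNO2 = 0, xN2 = 0,
                      xDIC = 1, xBM = 1.5,
                      rho1 = 0.001, rho2 = 0.001,
                      tau1 = 0.001, tau2 = 0.001,
                      e1 = 0.001, e2 = 0.001) {
  y <- c(xDOC = xDOC, xNO3 = xNO3, xNO2 = xNO2, xN2 = xN2,
         xDIC = xDIC, xBM = xBM, rho1 = rho1, rho2 = rho2,
         tau1 = tau1, tau2 = tau2, e1 = e1, e2 = e2)
  validate_state(y)
  structure(y, class = c("rscm_state", "numeric"))
}

.state_names <- c("xDOC", "xNO3", "xNO2", "xN2", "xDIC", "xBM",
                  "rho1", "rho2", "tau1", "tau2", "e1", "e2")

validate_state <- function(y) {
  if (!is.numeric(y) || length(y) != 12L)
    stop("state must be a numeric vector of length 12")
  if (is.null(names(y)) || !identical(names(y), .state_names))
    stop("state must be named ", paste(.state_names, collapse = ", "))
  if (any(!is.finite(y)))
    stop("state contains non-finite values")
  if (any(y < 0))
    stop("state components must be non-negative: ",
         paste(.state_names[y < 0], collapse = ", "))
  invisible(y)
}

#' @export
print.rscm_params <- function(x, ...) {
  cat("RSCM parameter set (", length(.param_names), " parameters)\n", sep = "")
  cat("  energy fractions: f1 =", x$f1, " f2 =", x$f2, "\n")
  cat("  uptake: k1 =", x$k1, " k2 =", x$k2,
      " Kd =", x$Kd1, "/", x$Kd2, " Ka =", x$Ka1, "/", x$Ka2, "\n")
  cat("  regulation: kR =", x$kR1, "/", x$kR2,
      " kT =", x$kT1, "/", x$kT2, " kE =", x$kE1, "/", x$kE2, "\n")
  cat("  turnover: kdeg =", x$kdeg, " beta(R,T,E) =",
      x$betaR1, x$betaT1, x$betaE1, "\n")
  invisible(x)
}

# flat numeric vector in canonical order (for the compiled RHS)
param_vector <- function(params) {
  vapply(.param_names, function(nm) params[[nm]], numeric(1))
}
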