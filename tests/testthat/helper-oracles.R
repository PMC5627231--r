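# Shared helpers: independent brute-force oracles and state builders.

# fixed-step classical RK4 over [0, t_end] using the reference R derivative;
# returns the state at the checkpoint times (which must be multiples of dt)
rk4_oracle <- function(y0, t_end, dt, params, checkpoints) {
  y <- y0
  n <- round(t_end / dt)
  out <- matrix(NA_real_, nrow = length(checkpoints), ncol = length(y0),
                dimnames = list(NULL, names(y0)))
  chk_steps <- round(checkpoints / dt)
  ci <- 1L
  if (length(chk_steps) > 0 && chk_steps[1] == 0L) {
    out[1, ] <- y
    ci <- 2L
  }
  for (i in seq_len(n)) {
    k1 <- rscm_rhs(y, params)
    k2 <- rscm_rhs(y + dt / 2 * k1, params)
    k3 <- rscm_rhs(y + dt / 2 * k2, params)
    k4 <- rscm_rhs(y + dt * k3, params)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (ci <= length(chk_steps) && i == chk_steps[ci]) {
      out[ci, ] <- y
      ci <- ci + 1L
    }
  }
  out
}

# state builder with overrides on an all-zero background
zero_state <- function(...) {
  over <- list(...)
  args <- list(xDOC = 0, xNO3 = 0, xNO2 = 0, xN2 = 0, xDIC = 0, xBM = 0,
               rho1 = 0, rho2 = 0, tau1 = 0, tau2 = 0, e1 = 0, e2 = 0)
  args[names(over)] <- over
  do.call(rscm_init, args)
}

# random strictly-interior state for property sweeps
random_state <- function() {
  rscm_init(xDOC = runif(1, 0, 80), xNO3 = runif(1, 0, 20),
            xNO2 = runif(1, 0, 10), xN2 = runif(1, 0, 10),
            xDIC = runif(1, 0, 20), xBM = runif(1, 0, 5),
            rho1 = runif(1, 0, 1), rho2 = runif(1, 0, 1),
            tau1 = runif(1, 0, 1), tau2 = runif(1, 0, 1),
            e1 = runif(1, 0, 5), e2 = runif(1, 0, 5))
}

# near-inert parameter set: uptake and cascade synthesis switched off to
# numerical zero so linear constitutive/degradation dynamics dominate
inert_params <- function(...) {
  over <- list(...)
  args <- list(k1 = 1e-12, k2 = 1e-12, kR1 = 1e-12, kR2 = 1e-12,
               kT1 = 1e-12, kT2 = 1e-12, kE1 = 1e-12, kE2 = 1e-12,
               kdeg = 1e-12)
  args[names(over)] <- over
  do.call(rscm_params, args)
}
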