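#' Measurement design for synthetic observation sets
#'
#' Describes the sampling structure of the batch denitrification experiment
#' emulated by [rscm_generate()]: daily sampling over 20 days, nutrients in
#' three replicates, each enzyme pool as two effective replicates (the
#' average of two signature peptides measured in duplicate collapses to two
#' replicate values), and a 5% relative measurement noise scale.
#'
#' @param times sampling times, days (default daily, 0-20).
#' @param noise named numeric vector of per-observable relative noise scales
#'   (dimensionless); a single unnamed value is recycled to all six
#'   observables.
#' @param n_nutrient_rep,n_enzyme_rep replicate counts for nutrient and
#'   enzyme observables.
#' @param seed RNG seed governing all draws.
#' @param law `"multiplicative"` (default; errors proportional to the signal,
#'   appropriate when observables span orders of magnitude) or `"additive"`
#'   (errors proportional to the observable's maximum level).
#' @return List of class `rscm_noise_spec`.
#' @export
default_design <- function(times = 0:20, noise = 0.05,
                           n_nutrient_rep = 3, n_enzyme_rep = 2,
                           seed = 0, law = c("multiplicative", "additive")) {
  law <- match.arg(law)
  if (length(noise) == 1 && is.null(names(noise)))
    noise <- stats::setNames(rep(noise, 6), .observable_names)
  miss <- setdiff(.observable_names, names(noise))
  if (length(miss) > 0)
    stop("noise scale missing for observable(s): ", paste(miss, collapse = ", "))
  if (any(noise < 0)) stop("noise scales must be non-negative")
  if (n_nutrient_rep < 1 || n_enzyme_rep < 1)
    stop("replicate counts must be at least 1")
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0))
    stop("sampling times must be non-negative and strictly increasing")
  structure(list(times = times, noise = noise[.observable_names],
                 n_nutrient_rep = as.integer(n_nutrient_rep),
                 n_enzyme_rep = as.integer(n_enzyme_rep),
                 seed = as.integer(seed), law = law),
            class = "rscm_noise_spec")
}

#' Generate a synthetic observation set from a known truth
#'
#' Simulates the model as ground truth and draws replicated noisy
#' measurements of the six observables at the design's sampling times.
#' Under the multiplicative law each replicate is
#' `truth * (1 + eps)` with `eps ~ N(0, scale)` clamped below at -1 so
#' values stay non-negative; under the additive law it is
#' `max(0, truth + eps * max_t truth)`. Deterministic given the design seed.
#'
#' @param params truth parameter set.
#' @param init truth initial state.
#' @param design an `rscm_noise_spec` from [default_design()].
#' @param horizon simulation horizon, days; must cover the sampling times.
#' @return List with elements `obs` (an `rscm_obs`) and `truth` (the
#'   `rscm_trajectory` the observations were drawn from).
#' @export
#' @examples
#' sim <- rscm_generate(design = default_design(times = c(0, 5, 10), seed = 1))
#' obs_summary(sim$obs)
rscm_generate <- function(params = rscm_params(), init = rscm_init(),
                          design = default_design(), horizon = NULL) {
  if (is.null(horizon)) horizon <- max(design$times)
  if (max(design$times) > horizon)
    stop("sampling times extend beyond the simulation horizon")
  if (horizon <= 0) stop("horizon must be positive")
  truth <- rscm_simulate(params, init, horizon = horizon, grid_step = 0.01)
  # truth values at the sampling times (grid covers them to 0.01 d)
  truth_at <- function(col) {
    stats::approx(truth$time, truth[[col]], xout = design$times)$y
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)
  recs <- list()
  for (ob in .observable_names) {
    tv <- truth_at(.observable_cols[[ob]])
    nrep <- if (ob %in% c("E1", "E2")) design$n_enzyme_rep else design$n_nutrient_rep
    sc <- design$noise[[ob]]
    for (r in seq_len(nrep)) {
      eps <- stats::rnorm(length(tv), 0, sc)
      val <- if (design$law == "multiplicative") {
        tv * (1 + pmax(eps, -1))
      } else {
        pmax(tv + eps * max(tv), 0)
      }
      recs[[length(recs) + 1L]] <- data.frame(
        time = design$times, observable = ob, replicate = r, value = val)
    }
  }
  obs <- observation_set(do.call(rbind, recs))
  list(obs = obs, truth = truth)
}

# save/restore the global RNG state so generation is seed-local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
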