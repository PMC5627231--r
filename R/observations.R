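#' Replicated batch-experiment observations
#'
#' An observation set holds replicated measurements of the six calibration
#' observables: the nutrients `DOC`, `DIC`, `NO3`, `NO2` (mM) and the two
#' functional enzyme pools `E1` (the nitrate reductase NarG/NapA class) and
#' `E2` (the nitrous-oxide reductase NosZ class), in pmol/g soil. In the
#' batch design the nutrients are measured in three replicates and each
#' enzyme pool as the average of two signature peptides, each from two
#' replicates, giving two effective replicates.
#'
#' @param df data frame with columns `time` (days), `observable` (one of
#'   `DOC, DIC, NO3, NO2, E1, E2`), `replicate` (integer index), `value`.
#' @return The validated data frame with class `rscm_obs`.
#' @export
observation_set <- function(df) {
  need <- c("time", "observable", "replicate", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("observation set missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$observable), .observable_names)
  if (length(bad) > 0)
    stop("unknown observable(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stop("observation times must be finite and non-negative")
  if (any(!is.finite(df$value)))
    stop("observation values must be finite")
  structure(as.data.frame(df)[need],
            class = c("rscm_obs", "data.frame"))
}

.observable_names <- c("DOC", "DIC", "NO3", "NO2", "E1", "E2")

# trajectory column backing each observable
.observable_cols <- c(DOC = "xDOC", DIC = "xDIC", NO3 = "xNO3",
                      NO2 = "xNO2", E1 = "e1", E2 = "e2")

#' Per-timepoint means and standard deviations of an observation set
#'
#' @param obs an `rscm_obs` observation set.
#' @return Data frame with columns `time`, `observable`, `mean`, `sd`, `n`;
#'   `sd` is 0 for singleton (time, observable) cells.
#' @export
obs_summary <- function(obs) {
  key <- interaction(obs$time, obs$observable, drop = TRUE)
  agg <- lapply(split(obs, key), function(g) {
    data.frame(time = g$time[1], observable = g$observable[1],
               mean = mean(g$value),
               sd = if (nrow(g) > 1) stats::sd(g$value) else 0,
               n = nrow(g))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$observable, out$time), ]
  rownames(out) <- NULL
  out
}

#' Read / write an observation set as delimited text
#'
#' Plain CSV with header `time,observable,replicate,value`.
#'
#' @param obs an `rscm_obs`.
#' @param path file path.
#' @return `write_observations()` returns `path` invisibly;
#'   `read_observations()` returns an `rscm_obs`.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  observation_set(utils::read.csv(path))
}

#' @export
print.rscm_obs <- function(x, ...) {
  cat("RSCM observation set: ", nrow(x), " records, ",
      length(unique(x$time)), " time points, observables: ",
      paste(sort(unique(x$observable)), collapse = ", "), "\n", sep = "")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
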