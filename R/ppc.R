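#' Posterior predictive replicates
#'
#' The two-step posterior predictive check: for every posterior draw
#' `theta~`, simulate a replicate dataset `y~ ~ p(y | theta~)` from the
#' fitted likelihood.  Both the estimation uncertainty (across draws) and the
#' measurement noise propagate into the replicates.
#'
#' @param draws a `pmx_draws` object (or a matrix with one row per draw).
#' @param simulate_obs function `(theta_row, data) -> vector` drawing one
#'   replicate of the observations given a constrained parameter vector;
#'   must be consistent with the fitted likelihood.
#' @param data passed through to `simulate_obs`.
#' @param seed RNG seed.
#' @return matrix of replicates, draws x observations.
#' @export
posterior_predictive <- function(draws, simulate_obs, data = NULL,
                                 seed = 1L) {
  m <- if (inherits(draws, "pmx_draws")) as.matrix(draws) else
    as.matrix(draws)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  out <- t(apply(m, 1, function(th) simulate_obs(th, data)))
  if (nrow(out) == 1L && nrow(m) > 1L) out <- t(out)
  out
}

#' Central credible intervals of posterior predictive replicates
#'
#' Per-observation central intervals (default the 50% and 90% bands) and the
#' replicate median, for plotting against the observed data.
#'
#' @param replicates matrix from [posterior_predictive()], draws x
#'   observations (at least 100 replicates).
#' @param probs central interval masses.
#' @return a data frame with one row per observation: `median` and `lo`/`hi`
#'   columns per interval (e.g. `lo50`, `hi50`, `lo90`, `hi90`).
#' @export
ppc_intervals <- function(replicates, probs = c(0.5, 0.9)) {
  replicates <- as.matrix(replicates)
  if (nrow(replicates) < 100)
    stop("need at least 100 replicates for stable interval estimates")
  out <- data.frame(observation = seq_len(ncol(replicates)),
                    median = apply(replicates, 2, stats::median))
  for (p in probs) {
    a <- (1 - p) / 2
    tag <- round(100 * p)
    out[[paste0("lo", tag)]] <- apply(replicates, 2, stats::quantile,
                                      probs = a, names = FALSE)
    out[[paste0("hi", tag)]] <- apply(replicates, 2, stats::quantile,
                                      probs = 1 - a, names = FALSE)
  }
  out
}

#' Write PPC intervals next to the observed data
#'
#' @param intervals data frame from [ppc_intervals()].
#' @param time observation times (h).
#' @param obs observed values.
#' @param path output path.
#' @export
write_ppc_csv <- function(intervals, time, obs, path) {
  utils::write.csv(cbind(data.frame(time = time, obs = obs),
                         intervals[, -1, drop = FALSE]),
                   path, row.names = FALSE)
  invisible(path)
}
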