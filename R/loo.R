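#' Pointwise log-likelihood matrix
#'
#' Evaluates the per-observation log-likelihood at every posterior draw:
#' entry `(s, i)` is the log-density of observation `i` under draw `s`.
#' Row sums therefore reproduce the likelihood part of the log joint at each
#' draw.
#'
#' @param draws a `pmx_draws` object (or a matrix of draws, one row per draw,
#'   named columns).
#' @param loglik_fun function `(theta_row, data) -> vector` of per-observation
#'   log-densities; `theta_row` is a named numeric vector of constrained
#'   parameter values.
#' @param data data bundle passed through.
#' @return matrix, draws x observations.
#' @export
pointwise_loglik <- function(draws, loglik_fun, data = NULL) {
  m <- if (inherits(draws, "pmx_draws")) as.matrix(draws) else as.matrix(draws)
  out <- t(apply(m, 1, function(th) loglik_fun(th, data)))
  if (nrow(out) == 1L && nrow(m) > 1L) out <- t(out)  # single-observation case
  out
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density under
#' leave-one-out, `elpd_loo = sum_i log p(y_i | y_-i)`, from a single model
#' fit.  For each observation the importance ratios `r_s = exp(-loglik_si)`
#' are tail-stabilized: the largest 20% are replaced by expected order
#' statistics of a generalized Pareto distribution fitted to them (truncated
#' at the raw maximum), and the fitted shape `k_hat` diagnoses reliability --
#' estimates with `k_hat > 0.7` should not be trusted and are flagged with a
#' warning.
#'
#' @param loglik matrix of pointwise log-likelihoods, draws x observations
#'   (all entries finite).
#' @param tail_frac fraction of draws treated as the importance-ratio tail.
#' @param min_tail minimum tail size for fitting; smaller tails skip
#'   smoothing.
#' @return a `pmx_loo` object: `elpd_loo`, `se`, `pointwise` (per-observation
#'   `elpd_i`), `k_hat`, and `n_high_k` (count of `k_hat > 0.7`).
#' @export
psis_loo <- function(loglik, tail_frac = 0.2, min_tail = 5L) {
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik)))
    stop("non-finite entries in the log-likelihood matrix")
  S <- nrow(loglik)
  n <- ncol(loglik)
  if (S < 100) stop("PSIS-LOO needs at least 100 draws")
  elpd_i <- numeric(n)
  k_hat <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_weights(-loglik[, i], tail_frac = tail_frac,
                       min_tail = min_tail)
    k_hat[i] <- ps$k_hat
    lw <- ps$log_weights - logsumexp(ps$log_weights)
    elpd_i[i] <- logsumexp(lw + loglik[, i])
  }
  n_high <- sum(is.finite(k_hat) & k_hat > 0.7)
  if (n_high > 0)
    warning(n_high, " observation(s) with Pareto k_hat > 0.7; ",
            "the PSIS-LOO estimate should not be trusted for them")
  structure(list(elpd_loo = sum(elpd_i),
                 se = sqrt(n * stats::var(elpd_i)),
                 pointwise = elpd_i, k_hat = k_hat, n_high_k = n_high,
                 n_obs = n, n_draws = S),
            class = "pmx_loo")
}

#' @export
print.pmx_loo <- function(x, ...) {
  cat("<pmx_loo> elpd_loo = ", signif(x$elpd_loo, 5), " (se ",
      signif(x$se, 3), "), ", x$n_obs, " observations, ", x$n_draws,
      " draws\n", sep = "")
  if (x$n_high_k > 0)
    cat("  ", x$n_high_k, " observation(s) with k_hat > 0.7\n", sep = "")
  invisible(x)
}

# Pareto-smoothed log importance weights from raw log ratios
psis_weights <- function(log_ratios, tail_frac = 0.2, min_tail = 5L) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- floor(tail_frac * S)
  if (M < min_tail)
    return(list(log_weights = lw, k_hat = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1L):S]
  cut <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_ids]) - cut
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k))
    return(list(log_weights = lw, k_hat = fit$k))
  # replace tail by expected order statistics of the fitted GPD,
  # truncated at the raw maximum
  p <- (seq_len(M) - 0.5) / M
  smoothed <- cut + qgpd(p, fit$k, fit$sigma)
  smoothed <- pmin(smoothed, exp(max(lw)))
  lw[tail_ids[order(lw[tail_ids])]] <- log(smoothed)
  list(log_weights = lw, k_hat = fit$k)
}

# profile-likelihood generalized Pareto fit (Zhang & Stephens 2009) in the
# standard shape parametrization (k > 0 = heavy tail), with the usual weak
# prior shrinking k towards 1/2
gpd_fit <- function(y) {
  y <- sort(y[y > 0])
  n <- length(y)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  prior <- 3
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  # grid over b = -k/sigma; b < 1/max(y)
  b <- 1 / y[n] + (1 - sqrt(m / (j - 0.5))) / (prior * y[floor(n / 4 + 0.5)])
  k_of <- function(bb) mean(log1p(-bb * y))
  lp <- vapply(b, function(bb) {
    k <- k_of(bb)
    if (k == 0 || -bb / k <= 0) return(-Inf)
    n * (log(-bb / k) - k - 1)
  }, 0)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  b_hat <- sum(b * w)
  k <- k_of(b_hat)
  sigma <- -k / b_hat
  k <- (k * n + 5) / (n + 10)  # weak prior regularization towards 1/2
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Compare two LOO estimates
#'
#' Sums the pointwise `elpd` differences between two fits of the *same*
#' observations; the standard error is `sqrt(n * var(pointwise differences))`,
#' which accounts for the correlation between the two models' pointwise
#' values.
#'
#' @param a,b `pmx_loo` objects over identical observations.
#' @return a list with `elpd_diff` (a minus b) and `se`.
#' @export
elpd_compare <- function(a, b) {
  stopifnot(inherits(a, "pmx_loo"), inherits(b, "pmx_loo"))
  if (a$n_obs != b$n_obs)
    stop("LOO results cover different numbers of observations")
  d <- a$pointwise - b$pointwise
  list(elpd_diff = sum(d), se = sqrt(length(d) * stats::var(d)))
}

#' Write a LOO report CSV
#'
#' @param loo a `pmx_loo` object.
#' @param path output path.
#' @export
write_loo_csv <- function(loo, path) {
  utils::write.csv(data.frame(observation = seq_len(loo$n_obs),
                              elpd_i = loo$pointwise, k_hat = loo$k_hat),
                   path, row.names = FALSE)
  invisible(path)
}
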