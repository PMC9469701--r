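#' Fit a Bayesian compartment model to an event schedule
#'
#' The package's top-level modelling function: assembles the posterior for a
#' one- or two-compartment model (single subject, or the allometrically
#' scaled population model), samples it with adaptive HMC ([sample_hmc()]),
#' and returns a fitted-model object supporting `print()`, `summary()`,
#' `coef()`, `predict()`, `plot()`, `simulate()` and `residuals()`.
#'
#' @param data a `pmx_events` object, a data frame of event records, or the
#'   path to an events CSV.
#' @param model `"twocpt"` or `"onecpt"`.
#' @param population fit the hierarchical population model (requires a `wt`
#'   covariate and, typically, multiple subjects).
#' @param priors prior list; defaults to [default_pk_priors()] or
#'   [default_population_priors()].
#' @param chains,warmup,sampling,seed,control passed to [sample_hmc()].
#' @param inits initial values; default draws from the priors.
#' @return a `pmx_fit` object.
#' @examples
#' \donttest{
#' ev <- simulate_dataset(build_tutorial_regimen(),
#'                        twocpt_params(10, 15, 35, 105, 2), sigma = 0.2,
#'                        seed = 42)
#' fit <- pmx_fit(ev, chains = 2, warmup = 300, sampling = 300, seed = 1)
#' summary(fit)
#' }
#' @export
pmx_fit <- function(data, model = c("twocpt", "onecpt"), population = FALSE,
                    priors = NULL, chains = 4, warmup = 1000,
                    sampling = 1000, seed = 1L, control = list(),
                    inits = NULL) {
  model <- match.arg(model)
  schedule <- if (inherits(data, "pmx_events")) data
    else if (is.data.frame(data)) read_events_table(data)
    else read_events_csv(data)
  schedule <- expand_additional_doses(schedule)
  if (population) {
    if (model != "twocpt")
      stop("the population model is two-compartment")
    if (is.null(priors)) priors <- default_population_priors()
    posterior <- population_posterior(schedule, priors = priors)
  } else {
    if (is.null(priors)) priors <- default_pk_priors(model)
    posterior <- pk_posterior(schedule, model = model, priors = priors)
  }
  draws <- sample_hmc(posterior, n_chains = chains, inits = inits,
                      n_warmup = warmup, n_sampling = sampling, seed = seed,
                      control = control)
  structure(list(draws = draws, posterior = posterior, schedule = schedule,
                 model = model, population = population, seed = seed),
            class = "pmx_fit")
}

# observation bookkeeping shared by the pmx_fit methods
fit_obs <- function(fit) {
  obs <- observation_view(fit$schedule)
  y <- fit$schedule$records$dv[obs]
  keep <- !is.na(y) & y > 0
  list(idx = obs[keep], y = y[keep],
       time = fit$schedule$records$time[obs[keep]],
       id = fit$schedule$records$id[obs[keep]])
}

# predicted concentrations at the (usable) observation rows for one draw,
# given as a named constrained parameter vector
fit_chat <- function(fit, th) {
  ob <- fit_obs(fit)
  if (!fit$population) {
    nm <- if (fit$model == "twocpt") c("CL", "Q", "Vcent", "Vperi", "ka")
      else c("CL", "Vcent", "ka")
    sol <- solve_schedule_analytic(fit$schedule, unname(th[nm]),
                                   model = fit$model)
    sol[2, ob$idx] / th["Vcent"]
  } else {
    d <- fit$posterior$data
    chat <- numeric(0)
    for (s in seq_len(d$n_subj)) {
      th_s <- th[paste0("theta[", s + d$n_subj * (0:4), "]")]
      p_s <- allometric_params(unname(th_s), d$subj[[s]]$wt,
                               e_cl = d$e_cl, e_v = d$e_v,
                               ref_weight = d$ref_weight)
      sol <- cpp_solve_plan(d$subj[[s]]$plan, rbind(as.numeric(p_s)), 2L,
                            d$subj[[s]]$n_events)
      chat <- c(chat, sol[2, d$subj[[s]]$obs] / p_s["Vcent"])
    }
    chat
  }
}

#' @export
print.pmx_fit <- function(x, ...) {
  cat("Bayesian ", if (x$population) "population " else "",
      if (x$model == "twocpt") "two" else "one",
      "-compartment model fit (adaptive HMC)\n", sep = "")
  ob <- fit_obs(x)
  cat("  ", length(ob$y), " observations, ",
      nrow(x$schedule$subjects), " subject(s), ",
      dim(x$draws$draws)[2], " chains x ", dim(x$draws$draws)[1],
      " draws\n\n", sep = "")
  s <- suppressWarnings(summarize_draws(x$draws))
  keep <- !grepl("^theta\\[", s$variable)
  print(cbind(s[keep, "variable", drop = FALSE],
              round(s[keep, -1], 3)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.pmx_fit <- function(object, ...) summarize_draws(object$draws, ...)

#' @export
coef.pmx_fit <- function(object, ...) {
  m <- as.matrix(object$draws)
  colMeans(m)
}

#' Posterior predictions at the observation times
#'
#' `type = "mean"` returns credible intervals of the model-predicted
#' concentration `c_hat`; `type = "response"` propagates the lognormal
#' measurement noise as well (posterior predictive replicates of new
#' observations).
#'
#' @param object a `pmx_fit`.
#' @param type `"mean"` or `"response"`.
#' @param probs central interval masses.
#' @param seed RNG seed for the replicate noise.
#' @param ... unused.
#' @return a data frame: subject id, time, observed value, median and
#'   interval columns.
#' @export
predict.pmx_fit <- function(object, type = c("mean", "response"),
                            probs = c(0.5, 0.9), seed = 1L, ...) {
  type <- match.arg(type)
  ob <- fit_obs(object)
  m <- as.matrix(object$draws)
  reps <- posterior_predictive(
    m,
    function(th, data) {
      chat <- fit_chat(object, th)
      if (type == "response")
        chat * exp(th["sigma"] * stats::rnorm(length(chat)))
      else chat
    },
    seed = seed)
  out <- ppc_intervals(reps, probs = probs)
  cbind(data.frame(id = ob$id, time = ob$time, obs = ob$y),
        out[, -1, drop = FALSE])
}

#' @export
simulate.pmx_fit <- function(object, nsim = NULL, seed = 1L, ...) {
  m <- as.matrix(object$draws)
  if (!is.null(nsim)) m <- m[seq_len(min(nsim, nrow(m))), , drop = FALSE]
  posterior_predictive(
    m,
    function(th, data) {
      chat <- fit_chat(object, th)
      chat * exp(th["sigma"] * stats::rnorm(length(chat)))
    },
    seed = seed)
}

#' @export
residuals.pmx_fit <- function(object, ...) {
  ob <- fit_obs(object)
  chat <- fit_chat(object, coef(object))
  log(ob$y) - log(chat)
}

#' Posterior predictive check plot
#'
#' Observed concentrations against time with the posterior predictive median
#' and central 50%/90% credible bands.
#'
#' @param x a `pmx_fit`.
#' @param log_y log-scale concentration axis.
#' @param n_draws number of posterior draws used for the bands.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pmx_fit <- function(x, log_y = TRUE, n_draws = 400, ...) {
  ob <- fit_obs(x)
  m <- as.matrix(x$draws)
  m <- m[seq(1, nrow(m), length.out = min(n_draws, nrow(m))), , drop = FALSE]
  reps <- posterior_predictive(
    m, function(th, data)
      fit_chat(x, th) * exp(th["sigma"] * stats::rnorm(length(ob$y))),
    seed = x$seed)
  ci <- ppc_intervals(reps)
  ord <- order(ob$time)
  graphics::plot(ob$time, ob$y, log = if (log_y) "y" else "",
                 xlab = "time (h)", ylab = "concentration (mg/L)",
                 pch = 19, cex = 0.6, ...)
  graphics::polygon(c(ob$time[ord], rev(ob$time[ord])),
                    c(ci$lo90[ord], rev(ci$hi90[ord])),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::polygon(c(ob$time[ord], rev(ob$time[ord])),
                    c(ci$lo50[ord], rev(ci$hi50[ord])),
                    col = grDevices::adjustcolor("steelblue", 0.45),
                    border = NA)
  graphics::lines(ob$time[ord], ci$median[ord], col = "steelblue4")
  graphics::points(ob$time, ob$y, pch = 19, cex = 0.6)
  invisible(x)
}

#' Pointwise log-likelihood of a fitted model
#'
#' Per-draw, per-observation lognormal log-densities, ready for
#' [psis_loo()].
#'
#' @param fit a `pmx_fit`.
#' @return matrix, draws x observations.
#' @export
fit_pointwise_loglik <- function(fit) {
  ob <- fit_obs(fit)
  pointwise_loglik(
    fit$draws,
    function(th, data)
      stats::dlnorm(ob$y, meanlog = log(fit_chat(fit, th)),
                    sdlog = th["sigma"], log = TRUE))
}
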