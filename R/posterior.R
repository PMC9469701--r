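#' Bundle a parameter space, data and likelihood into a posterior
#'
#' A `pmx_posterior` specifies how to evaluate the unnormalized log joint
#' density `log p(D, theta)` on the unconstrained scale: prior log-densities
#' plus transform log-Jacobians plus the log-likelihood.  A solver failure at
#' a proposed parameter value maps to `-Inf` (so the sampler rejects the
#' proposal) rather than an exception -- implausible values must be survivable
#' during early exploration.
#'
#' @param space a [parameter_space()].
#' @param loglik function `(theta, data) -> scalar` log-likelihood; `theta` is
#'   the named list of constrained values.  May return `-Inf`.
#' @param data the data bundle (event schedule, observations, ...).
#' @param log_density optional fast path: function `(x) -> scalar` computing
#'   the full unconstrained log joint directly (must agree with the generic
#'   assembly; used by the bundled compartment-model posteriors for speed).
#' @return a `pmx_posterior` object.
#' @export
pmx_posterior <- function(space, loglik, data, log_density = NULL) {
  stopifnot(inherits(space, "pmx_space"), is.function(loglik))
  structure(list(space = space, loglik = loglik, data = data,
                 log_density = log_density),
            class = "pmx_posterior")
}

#' Unnormalized log joint density
#'
#' `log p(D, theta(x)) + log |J(x)|` at an unconstrained point `x`: the sum of
#' prior log-densities, any hierarchical population terms and likelihood
#' terms supplied by the posterior's `loglik`, and the transform
#' log-Jacobians.  Returns `-Inf` (not an error) when the likelihood cannot
#' be evaluated at the proposed value.
#'
#' @param posterior a [pmx_posterior()].
#' @param x unconstrained parameter vector.
#' @param include_likelihood,include_prior set to `FALSE` to evaluate only
#'   one part of the decomposition (used for checking; both default `TRUE`).
#' @return scalar.
#' @export
log_joint <- function(posterior, x, include_likelihood = TRUE,
                      include_prior = TRUE) {
  stopifnot(inherits(posterior, "pmx_posterior"))
  if (any(!is.finite(x))) stop("non-finite unconstrained parameter vector")
  if (!is.null(posterior$log_density) && include_likelihood && include_prior)
    return(posterior$log_density(x))
  cp <- constrain_pars(posterior$space, x)
  lp <- 0
  if (include_prior)
    lp <- log_prior(posterior$space, cp$theta) + cp$log_jacobian
  if (include_likelihood) {
    ll <- tryCatch(posterior$loglik(cp$theta, posterior$data),
                   error = function(e) -Inf)
    if (!is.finite(ll) || is.na(ll)) return(-Inf)
    lp <- lp + ll
  }
  lp
}

#' Gradient of the log joint by central finite differences
#'
#' Per-coordinate step `h_i = eps_mach^(1/3) * max(1, |x_i|)`.  The provider
#' is pluggable: a posterior carrying an exact-gradient function in
#' `$gradient` is used instead.
#'
#' @param posterior a [pmx_posterior()].
#' @param x unconstrained parameter vector with finite `log_joint`.
#' @return gradient vector.
#' @export
grad_log_joint <- function(posterior, x) {
  if (!is.null(posterior$gradient)) return(posterior$gradient(x))
  f <- function(z) log_joint(posterior, z)
  h <- .Machine$double.eps^(1/3) * pmax(1, abs(x))
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    fp <- f(xp); fm <- f(xm)
    if (!is.finite(fp) || !is.finite(fm))
      stop("non-finite log density within the difference stencil of ",
           "coordinate ", i)
    g[i] <- (fp - fm) / (2 * h[i])
  }
  g
}

#' Default weakly-informative priors for the compartment models
#'
#' Lognormal priors centred on textbook adult values for a drug with
#' two-compartment disposition (CL 10 L/h, Q 15 L/h, Vcent 35 L, Vperi 105 L,
#' ka 2/h; log-scale sd 0.5, i.e. roughly a factor of 1.6 at one sd) and a
#' half-normal(0.5) prior on the lognormal residual scale.
#'
#' @param model `"twocpt"` or `"onecpt"`.
#' @return a named list of `list(family, pars)` prior specifications.
#' @export
default_pk_priors <- function(model = c("twocpt", "onecpt")) {
  model <- match.arg(model)
  pri <- list(
    CL = list(family = "lognormal", pars = c(log(10), 0.5)),
    Q = list(family = "lognormal", pars = c(log(15), 0.5)),
    Vcent = list(family = "lognormal", pars = c(log(35), 0.5)),
    Vperi = list(family = "lognormal", pars = c(log(105), 0.5)),
    ka = list(family = "lognormal", pars = c(log(2), 0.5)),
    sigma = list(family = "halfnormal", pars = 0.5))
  if (model == "onecpt") pri <- pri[c("CL", "Vcent", "ka", "sigma")]
  pri
}

# shared observation bookkeeping for the single-subject PK posteriors
pk_fit_data <- function(schedule, model) {
  schedule <- expand_additional_doses(schedule)
  obs <- observation_view(schedule)
  y <- schedule$records$dv[obs]
  keep <- !is.na(y) & y > 0
  list(schedule = schedule, obs = obs[keep], y = y[keep],
       plan = as.matrix(event_grid(schedule)),
       n_events = nrow(schedule$records), model = model)
}

#' Posterior for a single-subject compartment model
#'
#' Lognormal measurement error around the model-predicted concentration
#' `c_hat = u_central / Vcent`, with independent priors on
#' `(CL, Q, Vcent, Vperi, ka, sigma)` (two-compartment) or
#' `(CL, Vcent, ka, sigma)` (one-compartment).  Observation rows with missing
#' `dv` (e.g. a pre-first-dose sample with no measurable drug) are excluded
#' from the likelihood.
#'
#' @param schedule a single-subject `pmx_events` with `dv` filled at
#'   observation rows.
#' @param model `"twocpt"` or `"onecpt"`.
#' @param priors named prior list as from [default_pk_priors()].
#' @return a [pmx_posterior()].
#' @export
pk_posterior <- function(schedule, model = c("twocpt", "onecpt"),
                         priors = default_pk_priors(model)) {
  model <- match.arg(model)
  stopifnot(inherits(schedule, "pmx_events"))
  if (nrow(schedule$subjects) != 1L)
    stop("pk_posterior() is for a single subject; see population_posterior()")
  dat <- pk_fit_data(schedule, model)
  if (!length(dat$y)) stop("no usable observations (positive dv) in schedule")
  pk_names <- if (model == "twocpt") c("CL", "Q", "Vcent", "Vperi", "ka")
    else c("CL", "Vcent", "ka")
  stopifnot(all(c(pk_names, "sigma") %in% names(priors)))
  space <- parameter_space(lapply(c(pk_names, "sigma"), function(nm)
    pmx_param(nm, lower = 0, prior = priors[[nm]])))
  mcode <- if (model == "twocpt") 2L else 1L
  n_par <- length(pk_names)
  iV <- match("Vcent", pk_names)
  plan <- dat$plan
  n_rec <- max(plan[, 7])
  obs <- unname(dat$obs)
  y <- dat$y
  log_y <- log(y)
  prior_list <- priors[c(pk_names, "sigma")]

  loglik <- function(theta, data) {
    th <- unlist(theta[pk_names], use.names = FALSE)
    sol <- cpp_solve_plan(plan, rbind(th), mcode, data$n_events)
    chat <- sol[2, obs] / theta$Vcent
    if (any(chat <= 0)) return(-Inf)
    lognormal_loglik(y, chat, theta$sigma)
  }
  post <- pmx_posterior(space, loglik, dat)
  # compiled fast path (identical, to double precision, to the generic
  # assembly): every parameter is positive with a shifted-log transform and a
  # lognormal / half-normal / normal prior
  fam_code <- c(lognormal = 0L, halfnormal = 1L, normal = 2L)
  fams <- vapply(prior_list, function(p) p$family, "")
  if (all(fams %in% names(fam_code))) {
    pf <- unname(fam_code[fams])
    pp <- t(vapply(prior_list, function(p) {
      pr <- as.numeric(p$pars)
      c(pr, rep(0, 2 - length(pr)))[1:2]
    }, numeric(2)))
    post$log_density <- function(x)
      cpp_pk_lp(x, plan, obs, log_y, pf, pp, mcode, n_rec)
    post$gradient <- function(x)
      drop(cpp_pk_lp_grad(x, plan, obs, log_y, pf, pp, mcode, n_rec))
  }
  post
}

#' Posterior for the allometrically-scaled population model
#'
#' Hierarchical two-compartment model: body-weight-normalized individual
#' parameters `theta_j ~ LogNormal(log theta_pop, Omega)` with diagonal
#' `Omega`, allometric scaling to each subject's weight, and a shared
#' lognormal residual scale.  The population absorption rate `ka_pop` is
#' bounded below by the slower hybrid disposition rate `lambda_2` evaluated
#' at the current population parameters, ruling out flip-flop
#' non-identifiability (the bound expression is configurable).
#'
#' @param schedule a multi-subject `pmx_events`; each subject's rows must
#'   carry a `wt` covariate column (kg).
#' @param priors named priors for `CL_pop`, `Q_pop`, `Vcent_pop`,
#'   `Vperi_pop`, `ka_pop`, `omega` (shared spec for all 5 components) and
#'   `sigma`.
#' @param flipflop_bound character expression for the lower bound of
#'   `ka_pop`, or `NULL` to bound at 0.
#' @param e_cl,e_v,ref_weight allometric exponents and reference weight.
#' @return a [pmx_posterior()].
#' @export
population_posterior <- function(schedule,
                                 priors = default_population_priors(),
                                 flipflop_bound = flipflop_lambda2_expr(),
                                 e_cl = 0.75, e_v = 1, ref_weight = 70) {
  stopifnot(inherits(schedule, "pmx_events"))
  schedule <- expand_additional_doses(schedule)
  if (is.null(schedule$records$wt))
    stop("population model requires a 'wt' (body weight) covariate column")
  n_subj <- nrow(schedule$subjects)
  subj <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    i0 <- schedule$subjects$start[s]; i1 <- schedule$subjects$end[s]
    rec <- schedule$records[i0:i1, , drop = FALSE]
    obs_local <- which(rec$evid == 0)
    y <- rec$dv[obs_local]
    keep <- !is.na(y) & y > 0
    subj[[s]] <- list(
      plan = as.matrix(event_grid(schedule, schedule$subjects$id[s])),
      n_events = i1 - i0 + 1L,
      obs = obs_local[keep], y = y[keep], wt = rec$wt[1])
  }
  pop_names <- c("CL_pop", "Q_pop", "Vcent_pop", "Vperi_pop", "ka_pop")
  decls <- c(
    lapply(pop_names, function(nm)
      pmx_param(nm,
                lower = if (nm == "ka_pop" && !is.null(flipflop_bound))
                  flipflop_bound else 0,
                prior = priors[[nm]])),
    list(pmx_param("omega", length = 5L, lower = 0, prior = priors$omega),
         pmx_param("sigma", lower = 0, prior = priors$sigma),
         pmx_param("theta", length = 5L * n_subj, lower = 0,
                   prior = list(family = "flat", pars = numeric()))))
  space <- parameter_space(decls)
  loglik <- function(theta, data) {
    th_pop <- unlist(theta[pop_names], use.names = FALSE)
    th <- matrix(theta$theta, nrow = data$n_subj, ncol = 5L)
    lp <- population_logprior(th, th_pop, theta$omega)
    for (s in seq_len(data$n_subj)) {
      d <- data$subj[[s]]
      p_s <- allometric_params(th[s, ], d$wt, e_cl = data$e_cl, e_v = data$e_v,
                               ref_weight = data$ref_weight)
      sol <- cpp_solve_plan(d$plan, rbind(as.numeric(p_s)), 2L, d$n_events)
      if (length(d$obs)) {
        chat <- sol[2, d$obs] / p_s["Vcent"]
        if (any(chat <= 0)) return(-Inf)
        lp <- lp + lognormal_loglik(d$y, chat, theta$sigma)
      }
    }
    lp
  }
  pmx_posterior(space, loglik,
                list(subj = subj, n_subj = n_subj, e_cl = e_cl, e_v = e_v,
                     ref_weight = ref_weight, schedule = schedule))
}

#' @rdname population_posterior
#' @export
default_population_priors <- function() {
  list(CL_pop = list(family = "lognormal", pars = c(log(10), 0.5)),
       Q_pop = list(family = "lognormal", pars = c(log(15), 0.5)),
       Vcent_pop = list(family = "lognormal", pars = c(log(35), 0.5)),
       Vperi_pop = list(family = "lognormal", pars = c(log(105), 0.5)),
       ka_pop = list(family = "lognormal", pars = c(log(2), 0.5)),
       omega = list(family = "halfnormal", pars = 0.5),
       sigma = list(family = "halfnormal", pars = 0.5))
}

#' @rdname population_posterior
#' @export
flipflop_lambda2_expr <- function() {
  paste0("0.5 * ((CL_pop/Vcent_pop + Q_pop/Vcent_pop + Q_pop/Vperi_pop) - ",
         "sqrt((CL_pop/Vcent_pop + Q_pop/Vcent_pop + Q_pop/Vperi_pop)^2 - ",
         "4 * (CL_pop/Vcent_pop) * (Q_pop/Vperi_pop)))")
}
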