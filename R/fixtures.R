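#' The tutorial dosing and sampling design
#'
#' The reference single-subject design used throughout the package's examples
#' and checks: 1200 mg oral boluses every 12 h for 14 doses, with rich plasma
#' sampling at 0.083, 0.167, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6 and 8 h
#' after the first, second and final doses, a predose (trough) sample before
#' every dose, and samples 12, 18 and 24 h after the last dose.  That gives
#' 53 observation rows and a single dose row carrying `addl = 13`
#' (14 dose events once expanded); the final event is at 180 h.  Trough rows
#' are listed before the dose at the same nominal time, so they record the
#' pre-dose state.
#'
#' @param amt dose amount (mg).
#' @param ii interdose interval (h).
#' @param n_doses number of doses.
#' @param post_dose_times sampling offsets after doses 1, 2 and the final
#'   dose (h).
#' @param washout_times sampling offsets after the final dose (h).
#' @param id subject identifier.
#' @param wt optional body-weight covariate (kg) attached to every row.
#' @return a `pmx_events` object.
#' @examples
#' ev <- build_tutorial_regimen()
#' sum(ev$records$evid == 0)  # 53 observations
#' @export
build_tutorial_regimen <- function(amt = 1200, ii = 12, n_doses = 14,
                                   post_dose_times = c(0.083, 0.167, 0.25,
                                                       0.5, 0.75, 1, 1.5, 2,
                                                       3, 4, 6, 8),
                                   washout_times = c(12, 18, 24),
                                   id = 1L, wt = NULL) {
  dose_times <- (seq_len(n_doses) - 1) * ii
  last <- dose_times[n_doses]
  obs_times <- sort(unique(c(
    outer(dose_times[c(1, 2, n_doses)], post_dose_times, `+`),
    dose_times,                 # predose troughs (incl. t = 0)
    last + washout_times)))
  rows <- data.frame(time = obs_times, amt = 0, rate = 0, ii = 0, addl = 0,
                     cmt = 1, evid = 0, ss = 0)
  dose <- data.frame(time = 0, amt = amt, rate = 0, ii = ii,
                     addl = n_doses - 1, cmt = 1, evid = 1, ss = 0)
  tab <- rbind(rows[rows$time == 0, ], dose, rows[rows$time > 0, ])
  tab$id <- id
  if (!is.null(wt)) tab$wt <- wt
  read_events_table(tab)
}

#' Simulate concentration data over a schedule
#'
#' Fills the `dv` column at observation rows with
#' `dv = c_hat * exp(sigma * z)`, `z` standard normal: the lognormal residual
#' model around the solved concentration.  Observations where the model
#' predicts no drug (e.g. the sample before the first dose) have no positive
#' concentration to perturb and are left as `NA` (below any measurable
#' level); they are excluded from likelihoods.
#'
#' @param schedule a `pmx_events` object (expanded or not).
#' @param params PK parameter set ([twocpt_params()] or [onecpt_params()]).
#' @param sigma lognormal residual scale (log-scale sd).
#' @param seed RNG seed (recorded in the result's `"seed"` attribute).
#' @return the schedule with `dv` filled (a `pmx_events` object, expanded).
#' @export
simulate_dataset <- function(schedule, params, sigma, seed = 1L) {
  stopifnot(inherits(schedule, "pmx_events"))
  schedule <- expand_additional_doses(schedule)
  model <- if (inherits(params, "onecpt_params")) "onecpt" else "twocpt"
  sol <- solve_schedule_analytic(schedule, params, model = model)
  obs <- observation_view(schedule)
  chat <- predicted_concentration(sol, params["Vcent"], obs)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  z <- stats::rnorm(length(obs))
  dv <- ifelse(chat > 0, chat * exp(sigma * z), NA_real_)
  schedule$records$dv[obs] <- dv
  attr(schedule, "seed") <- seed
  attr(schedule, "truth") <- c(as.numeric(params), sigma = sigma)
  schedule
}

#' Simulate a multi-subject population dataset
#'
#' Per subject: draw body-weight-normalized parameters lognormally around the
#' population-typical values with diagonal log-scale sd `omega`, scale to the
#' subject's body weight by allometry, solve the subject's schedule and add
#' lognormal residual noise.
#'
#' @param n_subjects number of subjects.
#' @param theta_pop population-typical `(CL, Q, Vcent, Vperi, ka)` at the
#'   reference weight.
#' @param omega log-scale sd of the inter-individual variability (length 5).
#' @param weights body weights (kg), recycled to `n_subjects`.
#' @param sigma residual scale.
#' @param regimen a single-subject `pmx_events` design applied to everyone;
#'   defaults to [build_tutorial_regimen()].
#' @param seed RNG seed.
#' @param e_cl,e_v,ref_weight allometric constants.
#' @return a multi-subject `pmx_events` with `dv` and `wt` filled; the drawn
#'   individual parameters are in the `"theta"` attribute.
#' @export
simulate_population <- function(n_subjects, theta_pop, omega, weights,
                                sigma, regimen = build_tutorial_regimen(),
                                seed = 1L, e_cl = 0.75, e_v = 1,
                                ref_weight = 70) {
  stopifnot(length(theta_pop) == 5, length(omega) == 5)
  weights <- rep_len(weights, n_subjects)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  regimen <- expand_additional_doses(regimen)
  blocks <- vector("list", n_subjects)
  theta <- matrix(NA_real_, n_subjects, 5,
                  dimnames = list(NULL, c("CL", "Q", "Vcent", "Vperi", "ka")))
  for (s in seq_len(n_subjects)) {
    th_s <- stats::rlnorm(5, meanlog = log(theta_pop), sdlog = omega)
    theta[s, ] <- th_s
    p_s <- allometric_params(th_s, weights[s], e_cl = e_cl, e_v = e_v,
                             ref_weight = ref_weight)
    sol <- solve_schedule_analytic(regimen, p_s)
    obs <- observation_view(regimen)
    chat <- predicted_concentration(sol, p_s["Vcent"], obs)
    rec <- regimen$records
    rec$id <- s
    rec$wt <- weights[s]
    z <- stats::rnorm(length(obs))
    rec$dv[obs] <- ifelse(chat > 0, chat * exp(sigma * z), NA_real_)
    blocks[[s]] <- rec
  }
  out <- read_events_table(do.call(rbind, blocks))
  attr(out, "seed") <- seed
  attr(out, "theta") <- theta
  out
}
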