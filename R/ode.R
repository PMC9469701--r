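#' ODE solver settings
#'
#' Tolerance and step-budget controls for the numerical integrator.  The
#' defaults (`rtol = 1e-6`, `atol = 1e-6`, `max_num_step = 1e5`) are explicit
#' and may be overridden per call or loaded from a run configuration.
#'
#' @param rtol relative tolerance (> 0).
#' @param atol absolute tolerance in state units (> 0).
#' @param max_num_step maximum number of internal integrator steps (> 0).
#' @return an `ode_settings` object.
#' @export
ode_settings <- function(rtol = 1e-6, atol = 1e-6, max_num_step = 100000L) {
  if (rtol <= 0 || atol <= 0 || max_num_step <= 0)
    stop("rtol, atol and max_num_step must all be positive")
  structure(list(rtol = rtol, atol = atol,
                 max_num_step = as.integer(max_num_step)),
            class = "ode_settings")
}

#' Integrate a right-hand side over an interval
#'
#' Adaptive embedded Runge-Kutta (Dormand-Prince 4(5), via \pkg{deSolve})
#' integration of `dy/dt = rhs(t, y, params)` from `t0` to `t1`, with local
#' error controlled by `rtol`/`atol`.  Exceeding the step budget raises an
#' error naming `max_num_step`; a non-finite derivative raises an error
#' identifying the time and state at which it occurred.
#'
#' @param rhs function `(t, y, params) -> dy/dt` (numeric vector).
#' @param y0 initial state.
#' @param t0,t1 integration limits (h), `t1 >= t0`.
#' @param settings an [ode_settings()] object.
#' @param params passed through to `rhs`.
#' @return the state at `t1`.
#' @examples
#' pmx_integrate(function(t, y, p) -y, 1, 0, 1)  # exp(-1)
#' @export
pmx_integrate <- function(rhs, y0, t0, t1, settings = ode_settings(),
                          params = NULL) {
  if (t1 < t0) stop("t1 must be >= t0")
  if (t1 == t0) return(y0)
  f <- function(t, y, parms) {
    dy <- rhs(t, y, parms)
    if (any(!is.finite(dy)))
      stop("non-finite derivative at t = ", signif(t, 6), ", state = (",
           paste(signif(y, 4), collapse = ", "), ")", call. = FALSE)
    list(dy)
  }
  res <- withCallingHandlers(
    deSolve::ode(y = as.numeric(y0), times = c(t0, t1), func = f,
                 parms = params, method = deSolve::rkMethod("rk45dp7"),
                 rtol = settings$rtol, atol = settings$atol,
                 maxsteps = settings$max_num_step),
    warning = function(w) {
      if (grepl("steps|maxsteps", conditionMessage(w), ignore.case = TRUE))
        stop("integration exceeded max_num_step = ", settings$max_num_step,
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  y <- as.numeric(res[nrow(res), -1])
  if (res[nrow(res), 1] < t1 || any(!is.finite(y)))
    stop("integration exceeded max_num_step = ", settings$max_num_step)
  names(y) <- names(y0)
  y
}

# Walk a solve plan applying doses in R, advancing with `advance`:
# advance(u, dt, binf, theta_row) -> state. Steady-state rows are delegated
# to `ss_state` or rejected when NULL.
walk_plan <- function(plan, n_state, advance, ss_state = NULL) {
  u <- numeric(n_state)
  binf <- numeric(n_state)
  n_rec <- max(plan$record)
  out <- matrix(NA_real_, n_state, n_rec)
  t <- plan$time[1]
  for (i in seq_len(nrow(plan))) {
    dt <- plan$time[i] - t
    if (dt > 0) {
      u <- advance(u, t, dt, binf, plan$theta[i])
      t <- plan$time[i]
    }
    op <- plan$op[i]
    if (op == 1) {
      u[plan$cmt[i]] <- u[plan$cmt[i]] + plan$amt[i]
    } else if (op == 2) {
      binf[plan$cmt[i]] <- binf[plan$cmt[i]] + plan$rate[i]
    } else if (op == 3) {
      binf[plan$cmt[i]] <- binf[plan$cmt[i]] - plan$rate[i]
    } else if (op %in% c(4, 5)) {
      if (is.null(ss_state))
        stop("steady-state dosing (ss = 1) is only supported by the linear-model solvers")
      u <- ss_state(plan$amt[i], plan$rate[i], plan$ii[i], plan$cmt[i],
                    plan$theta[i])
    }
    if (plan$record[i] > 0) out[, plan$record[i]] <- u
  }
  out
}

#' Solve a schedule with the numerical integrator
#'
#' Same dosing semantics as [solve_schedule_analytic()] (bioavailability,
#' lag times, post-dose reporting, tie-breaking), but the state is advanced
#' between events by adaptive Runge-Kutta integration of an arbitrary
#' right-hand side.  Zero-order infusion input is added to the user `rhs` by
#' the engine.
#'
#' @param schedule a `pmx_events` object with `addl` expanded.
#' @param rhs function `(t, y, params) -> dy/dt` of length `n_cmt`.
#' @param n_cmt number of states in `rhs`.
#' @param params passed through to `rhs`.
#' @param F,tlag optional overrides of the schedule's bioavailability and lag
#'   vectors.
#' @param settings an [ode_settings()] object.
#' @return a `pmx_solution` matrix, `n_cmt` x events.
#' @export
solve_schedule_numeric <- function(schedule, rhs, n_cmt, params = NULL,
                                   F = NULL, tlag = NULL,
                                   settings = ode_settings()) {
  stopifnot(inherits(schedule, "pmx_events"))
  if (any(schedule$records$addl > 0))
    stop("expand additional doses before solving")
  if (schedule$n_cmt != n_cmt) {
    if (any(schedule$records$cmt > n_cmt))
      stop("schedule doses a compartment beyond n_cmt")
    schedule$n_cmt <- n_cmt
    if (length(schedule$F) != n_cmt) schedule$F <- rep(1, n_cmt)
    if (length(schedule$tlag) != n_cmt) schedule$tlag <- rep(0, n_cmt)
  }
  if (!is.null(F)) schedule$F <- F
  if (!is.null(tlag)) schedule$tlag <- tlag
  n_ev <- nrow(schedule$records)
  out <- matrix(NA_real_, n_cmt, n_ev)
  for (s in seq_len(nrow(schedule$subjects))) {
    i0 <- schedule$subjects$start[s]
    plan <- event_grid(schedule, schedule$subjects$id[s])
    adv <- function(u, t, dt, binf, th) {
      f <- function(tt, y, p) rhs(tt, y, p) + binf
      tryCatch(pmx_integrate(f, u, t, t + dt, settings, params),
               error = function(e)
                 stop("event ", th, " (subject ", schedule$subjects$id[s],
                      "): ", conditionMessage(e), call. = FALSE))
    }
    sol <- walk_plan(plan, n_cmt, adv)
    out[, i0 + seq_len(ncol(sol)) - 1L] <- sol
  }
  structure(out, class = c("pmx_solution", "matrix"),
            times = schedule$records$time)
}

#' Solve a one-way coupled PK/PD system
#'
#' Exploits the one-way coupling of a linear PK model driving a nonlinear PD
#' system: the PK states (which receive all doses) are propagated by the
#' closed-form solution, while only the PD states are integrated numerically.
#' The PD right-hand side receives the *exact* analytic PK state at every
#' internal integrator time (a continuous-time evaluation within each event
#' segment, not a per-event zero-order hold), so the reduced system loses no
#' PK accuracy.
#'
#' @param schedule a `pmx_events` object with `addl` expanded; doses must
#'   target PK compartments only.
#' @param pk a [twocpt_params()] or [onecpt_params()] parameter set.
#' @param pd_rhs function `(t, y_pd, y_pk, params) -> dy_pd/dt`.
#' @param n_pd number of PD states.
#' @param params passed through to `pd_rhs`.
#' @param settings an [ode_settings()] object.
#' @return a `pmx_solution` matrix with the PK rows stacked above the PD rows,
#'   `(n_pk + n_pd)` x events.
#' @export
solve_schedule_coupled <- function(schedule, pk, pd_rhs, n_pd, params = NULL,
                                   settings = ode_settings()) {
  stopifnot(inherits(schedule, "pmx_events"))
  if (any(schedule$records$addl > 0))
    stop("expand additional doses before solving")
  n_pk <- n_compartments(pk)
  mcode <- model_code(pk)
  dosed <- schedule$records$cmt[schedule$records$evid == 1]
  if (any(dosed > n_pk))
    stop("doses must target PK compartments (1..", n_pk, ")")
  th <- rbind(as.numeric(pk))
  n_ev <- nrow(schedule$records)
  out <- matrix(NA_real_, n_pk + n_pd, n_ev)
  for (s in seq_len(nrow(schedule$subjects))) {
    i0 <- schedule$subjects$start[s]
    plan <- event_grid(schedule, schedule$subjects$id[s])
    u <- numeric(n_pk + n_pd)
    binf <- numeric(n_pk)
    n_rec <- max(plan$record)
    sol <- matrix(NA_real_, n_pk + n_pd, n_rec)
    t <- plan$time[1]
    for (i in seq_len(nrow(plan))) {
      dt <- plan$time[i] - t
      if (dt > 0) {
        u_pk0 <- u[seq_len(n_pk)]
        f <- function(tt, y, p) {
          y_pk <- drop(cpp_advance_model(u_pk0, th, mcode, tt - t, binf))
          pd_rhs(tt, y, y_pk, p)
        }
        u_pd <- pmx_integrate(f, u[n_pk + seq_len(n_pd)], t, t + dt,
                              settings, params)
        u_pk <- drop(cpp_advance_model(u_pk0, th, mcode, dt, binf))
        u <- c(u_pk, u_pd)
        t <- plan$time[i]
      }
      op <- plan$op[i]
      if (op == 1) {
        u[plan$cmt[i]] <- u[plan$cmt[i]] + plan$amt[i]
      } else if (op == 2) {
        binf[plan$cmt[i]] <- binf[plan$cmt[i]] + plan$rate[i]
      } else if (op == 3) {
        binf[plan$cmt[i]] <- binf[plan$cmt[i]] - plan$rate[i]
      } else if (op %in% c(4, 5)) {
        u[seq_len(n_pk)] <- drop(cpp_steady_state_model(
          th, mcode, plan$amt[i], plan$rate[i], plan$ii[i],
          as.integer(plan$cmt[i])))
      }
      if (plan$record[i] > 0) sol[, plan$record[i]] <- u
    }
    out[, i0 + seq_len(ncol(sol)) - 1L] <- sol
  }
  structure(out, class = c("pmx_solution", "matrix"),
            times = schedule$records$time)
}
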