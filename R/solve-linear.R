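#' Compartment model parameter sets
#'
#' Constructors for the parameters of the linear one- and two-compartment
#' models with first-order absorption.  The two-compartment disposition system
#' is characterised by the micro rate constants `k10 = CL/Vcent`,
#' `k12 = Q/Vcent`, `k21 = Q/Vperi` and the hybrid rates `lambda1 >= lambda2`,
#' the roots of `lambda^2 - (k10+k12+k21) lambda + k10 k21`.
#'
#' @param CL elimination clearance (L/h, > 0).
#' @param Q intercompartmental clearance (L/h, >= 0).
#' @param Vcent central volume of distribution (L, > 0).
#' @param Vperi peripheral volume (L, > 0).
#' @param ka first-order absorption rate constant (1/h, > 0).
#' @return an object of class `twocpt_params` or `onecpt_params` (a named
#'   numeric vector in the solver's canonical order).
#' @export
twocpt_params <- function(CL, Q, Vcent, Vperi, ka) {
  p <- c(CL = CL, Q = Q, Vcent = Vcent, Vperi = Vperi, ka = ka)
  if (any(!is.finite(p)) || any(p[c("CL", "Vcent", "Vperi", "ka")] <= 0) ||
      Q < 0)
    stop("two-compartment parameters must be finite and positive (Q >= 0)")
  structure(p, class = c("twocpt_params", "pmx_params"))
}

#' @rdname twocpt_params
#' @export
onecpt_params <- function(CL, Vcent, ka) {
  p <- c(CL = CL, Vcent = Vcent, ka = ka)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("one-compartment parameters must be finite and strictly positive")
  structure(p, class = c("onecpt_params", "pmx_params"))
}

model_code <- function(p) {
  if (inherits(p, "onecpt_params")) 1L else if (inherits(p, "twocpt_params"))
    2L else stop("expected onecpt_params or twocpt_params")
}

n_compartments <- function(p) if (model_code(p) == 1L) 2L else 3L

#' Rate matrix of a linear compartment model
#'
#' @param p a parameter set from [twocpt_params()] or [onecpt_params()].
#' @return the compartmental rate matrix (1/h); state order is
#'   (gut, central\[, peripheral\]).
#' @export
rate_matrix <- function(p) {
  if (model_code(p) == 1L) {
    k10 <- p["CL"] / p["Vcent"]
    ka <- p["ka"]
    matrix(c(-ka, 0, ka, -k10), 2, 2, byrow = TRUE,
           dimnames = list(c("gut", "central"), c("gut", "central")))
  } else {
    k10 <- p["CL"] / p["Vcent"]
    k12 <- p["Q"] / p["Vcent"]
    k21 <- p["Q"] / p["Vperi"]
    ka <- p["ka"]
    nm <- c("gut", "central", "peripheral")
    matrix(c(-ka, 0, 0,
             ka, -(k10 + k12), k21,
             0, k12, -k21), 3, 3, byrow = TRUE, dimnames = list(nm, nm))
  }
}

#' Micro and hybrid rate constants of the two-compartment model
#'
#' @param p a `twocpt_params` object.
#' @return named vector `(k10, k12, k21, lambda1, lambda2)` with
#'   `lambda1 >= lambda2`, satisfying `lambda1 * lambda2 = k10 * k21` and
#'   `lambda1 + lambda2 = k10 + k12 + k21`.
#' @examples
#' hybrid_constants(twocpt_params(CL = 10, Q = 15, Vcent = 35, Vperi = 105,
#'                                ka = 2))
#' @export
hybrid_constants <- function(p) {
  stopifnot(inherits(p, "twocpt_params"))
  k10 <- unname(p["CL"] / p["Vcent"])
  k12 <- unname(p["Q"] / p["Vcent"])
  k21 <- unname(p["Q"] / p["Vperi"])
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  c(k10 = k10, k12 = k12, k21 = k21,
    lambda1 = (s + disc) / 2, lambda2 = (s - disc) / 2)
}

#' Advance a state over a constant-input interval (closed form)
#'
#' Propagates the compartment amounts exactly over `dt` hours under constant
#' per-compartment zero-order input, using the bi-/tri-exponential analytic
#' solution of the linear system (with a matrix-exponential fallback when the
#' absorption rate nearly coincides with a hybrid disposition rate).
#'
#' @param u state vector of compartment amounts (mg).
#' @param p parameter set ([twocpt_params()] or [onecpt_params()]).
#' @param dt interval length (h, >= 0).
#' @param infusion per-compartment zero-order input rates (mg/h).
#' @return the state vector at the end of the interval.
#' @export
advance_interval_analytic <- function(u, p, dt,
                                      infusion = rep(0, length(u))) {
  nc <- n_compartments(p)
  if (length(u) != nc || length(infusion) != nc)
    stop("state/input length must equal the model compartment count")
  if (any(!is.finite(u)) || any(!is.finite(infusion)) || !is.finite(dt))
    stop("non-finite state, input or interval")
  if (dt < 0) stop("dt must be >= 0")
  out <- drop(cpp_advance_model(as.numeric(u), rbind(as.numeric(p)),
                                model_code(p), dt, as.numeric(infusion)))
  names(out) <- rownames(rate_matrix(p))
  out
}

#' Advance a general linear system by the matrix exponential
#'
#' Returns `exp(A dt) u` plus the particular solution for a constant input
#' `b`, computed via an augmented-matrix exponential so that `A` need not be
#' invertible.
#'
#' @param A square rate matrix (1/h).
#' @param u state vector.
#' @param dt interval (h, >= 0).
#' @param b constant input rates (state units / h).
#' @export
matrix_exponential_advance <- function(A, u, dt, b = rep(0, length(u))) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (length(u) != nrow(A) || length(b) != nrow(A))
    stop("dimension mismatch between A, u and b")
  if (dt < 0) stop("dt must be >= 0")
  drop(cpp_expm_advance(A, as.numeric(u), dt, as.numeric(b)))
}

#' Periodic steady state under repeated dosing
#'
#' Computes the state of the periodic steady state reached under doses of
#' `amt` every `ii` hours into compartment `cmt`.  For a bolus the *post-dose*
#' state `u*` solves `u* = exp(A ii) u* + F amt e_cmt`; for an infusion the
#' zero-order segment of duration `F amt / rate` is handled inside the
#' interval and the returned state is the one at the dose time (the infusion
#' adds nothing instantaneously).  Requires a strictly dissipative system;
#' a conservative configuration (e.g. `CL = 0`) has no steady state and is
#' rejected.
#'
#' @param p a parameter set, or a square rate matrix `A`.
#' @param amt dose amount (mg, > 0).
#' @param rate infusion rate (mg/h; 0 for bolus).
#' @param ii interdose interval (h, > 0).
#' @param cmt dosed compartment (1-based).
#' @param F bioavailability fraction applied to `amt`.
#' @return the steady-state state vector at the dose event.
#' @export
steady_state_state <- function(p, amt, rate = 0, ii, cmt = 1, F = 1) {
  if (ii <= 0) stop("steady-state dosing requires ii > 0")
  if (amt <= 0) stop("steady-state dosing requires amt > 0")
  if (is.matrix(p)) {
    drop(cpp_steady_state_matrix(p, F * amt, rate, ii, as.integer(cmt)))
  } else {
    out <- drop(cpp_steady_state_model(rbind(as.numeric(p)), model_code(p),
                                       F * amt, rate, ii, as.integer(cmt)))
    names(out) <- rownames(rate_matrix(p))
    out
  }
}

theta_matrix <- function(theta, model, n_events) {
  npar <- if (model == 1L) 3L else 5L
  if (inherits(theta, "pmx_params")) theta <- as.numeric(theta)
  if (is.numeric(theta) && is.null(dim(theta))) theta <- rbind(theta)
  theta <- as.matrix(theta)
  if (ncol(theta) != npar)
    stop("theta must have ", npar, " columns for this model")
  if (!nrow(theta) %in% c(1L, n_events))
    stop("theta must have 1 row or one row per event (", n_events, ")")
  if (any(!is.finite(theta)) || any(theta[, -npar, drop = FALSE] < 0))
    stop("non-finite or negative parameters in theta")
  theta
}

#' Solve a schedule with the closed-form linear solver
#'
#' Propagates the model through the full event schedule using the analytic
#' interval solution: integrate to each event time, apply dose actions, and
#' record the drug amount in every compartment at every event row (the
#' universal solver output contract).  Dose rows report post-dose amounts;
#' `ss = 1` dose rows initialize from the periodic steady state.  Parameters
#' may change between events by passing one row of `theta` per event.
#'
#' @param schedule a `pmx_events` object with `addl` expanded.
#' @param theta a parameter set, numeric vector, or matrix with one row per
#'   event.  Column order `(CL, Q, Vcent, Vperi, ka)` for `"twocpt"`,
#'   `(CL, Vcent, ka)` for `"onecpt"`.
#' @param model `"twocpt"` or `"onecpt"`.
#' @return a `pmx_solution` matrix, compartments x events (mg).
#' @examples
#' ev <- expand_additional_doses(build_tutorial_regimen())
#' sol <- solve_schedule_analytic(ev, twocpt_params(10, 15, 35, 105, 2))
#' sol[, 1:4]
#' @export
solve_schedule_analytic <- function(schedule, theta,
                                    model = c("twocpt", "onecpt")) {
  stopifnot(inherits(schedule, "pmx_events"))
  model <- match.arg(model)
  mcode <- if (model == "onecpt") 1L else 2L
  if (any(schedule$records$addl > 0))
    stop("expand additional doses before solving")
  n_ev <- nrow(schedule$records)
  th <- theta_matrix(theta, mcode, n_ev)
  nc <- if (mcode == 1L) 2L else 3L
  out <- matrix(NA_real_, nc, n_ev)
  for (s in seq_len(nrow(schedule$subjects))) {
    i0 <- schedule$subjects$start[s]
    i1 <- schedule$subjects$end[s]
    plan <- event_grid(schedule, schedule$subjects$id[s])
    th_s <- if (nrow(th) == 1L) th else th[i0:i1, , drop = FALSE]
    sol <- cpp_solve_plan(as.matrix(plan), th_s, mcode, i1 - i0 + 1L)
    out[, i0:i1] <- sol
  }
  rownames(out) <- if (mcode == 1L) c("gut", "central") else
    c("gut", "central", "peripheral")
  structure(out, class = c("pmx_solution", "matrix"),
            times = schedule$records$time)
}

#' @export
print.pmx_solution <- function(x, ...) {
  cat("<pmx_solution> ", nrow(x), " compartments x ", ncol(x), " events\n",
      sep = "")
  print(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE])
  if (ncol(x) > 6) cat("... and", ncol(x) - 6, "more events\n")
  invisible(x)
}

#' Export a solution matrix next to its source events
#'
#' Writes one row per event: the source event columns followed by the solved
#' amount in each compartment.
#'
#' @param solution a `pmx_solution` matrix.
#' @param schedule the `pmx_events` object it was solved from.
#' @param path output CSV path.
#' @export
write_solution_csv <- function(solution, schedule, path) {
  stopifnot(inherits(solution, "pmx_solution"),
            inherits(schedule, "pmx_events"),
            ncol(solution) == nrow(schedule$records))
  df <- cbind(schedule$records, as.data.frame(t(unclass(solution))))
  utils::write.csv(df, path, row.names = FALSE, na = ".")
  invisible(path)
}
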