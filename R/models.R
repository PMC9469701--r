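#' Friberg-Karlsson myelosuppression model parameters
#'
#' The semimechanistic neutropenia model: a proliferating pool feeds three
#' transit compartments and a circulating pool; feedback `(Circ0/Circ)^gamma`
#' keeps the absolute neutrophil count (ANC) at its baseline `Circ0`, and the
#' drug reduces proliferation through the linear effect
#' `Edrug = min(alpha * c, 1)` on the proliferation rate.  The transit rate
#' constant is `ktr = (n + 1)/MTT` with `n = 3` transit compartments, and the
#' proliferation rate `kprol` equals `ktr` so that the drug-free baseline is an
#' equilibrium.
#'
#' @param MTT mean transit time through the maturation chain (h, > 0).
#' @param Circ0 baseline circulating neutrophil count (ANC units, > 0).
#' @param alpha linear drug-effect slope (per mg/L, >= 0).
#' @param gamma feedback exponent (dimensionless, > 0).
#' @return an `fk_params` object (named list with derived `ktr`, `kprol`).
#' @export
fk_params <- function(MTT, Circ0, alpha, gamma) {
  if (MTT <= 0 || Circ0 <= 0 || alpha < 0 || gamma <= 0)
    stop("invalid Friberg-Karlsson parameters")
  ktr <- mtt_to_ktr(MTT)
  structure(list(MTT = MTT, Circ0 = Circ0, alpha = alpha, gamma = gamma,
                 ktr = ktr, kprol = ktr),
            class = "fk_params")
}

#' Transit rate constant from the mean transit time
#'
#' `ktr = (n + 1)/MTT` for a maturation chain with `n = 3` transit
#' compartments (proliferation pool + 3 transits precede the circulating
#' pool).
#'
#' @param MTT mean transit time (h, > 0).
#' @param n_transit number of transit compartments.
#' @return `ktr` (1/h).
#' @examples
#' mtt_to_ktr(125)  # 0.032 / h
#' @export
mtt_to_ktr <- function(MTT, n_transit = 3) {
  if (any(MTT <= 0)) stop("MTT must be > 0")
  (n_transit + 1) / MTT
}

#' Friberg-Karlsson right-hand side (baseline-shifted states)
#'
#' PD dynamics in shifted coordinates `y = actual - Circ0`, so the drug-free
#' initial condition is the zero vector.  Inside the dynamics the actual
#' counts are floored at machine precision, which keeps the feedback term
#' finite (and the feedback loop un-flipped) at any state the integrator may
#' propose; the function therefore never fails on implausible states.
#'
#' @param t time (h; unused, the system is autonomous).
#' @param y_pd shifted PD state `(yprol, ytrans1, ytrans2, ytrans3, ycirc)`.
#' @param y_pk PK state vector; the central amount is `y_pk[2]`.
#' @param p an [fk_params()] object.
#' @param pk the PK parameter set (supplies `Vcent` for the concentration).
#' @return `dy_pd/dt` in shifted coordinates.
#' @export
fk_rhs <- function(t, y_pd, y_pk, p, pk) {
  eps <- .Machine$double.eps
  a <- pmax(y_pd + p$Circ0, eps)
  chat <- y_pk[2] / pk["Vcent"]
  edrug <- min(p$alpha * max(chat, 0), 1)
  dprol <- p$kprol * a[1] * (1 - edrug) * (p$Circ0 / a[5])^p$gamma -
    p$ktr * a[1]
  c(dprol,
    p$ktr * (a[1] - a[2]),
    p$ktr * (a[2] - a[3]),
    p$ktr * (a[3] - a[4]),
    p$ktr * (a[4] - a[5]))
}

#' Right-hand side of the full coupled PK/PD system
#'
#' The 8-state system: two-compartment PK (Eq. of the linear model) stacked
#' above the five shifted Friberg-Karlsson states.  Used as the
#' full-numerical-solve reference for the coupled solver.
#'
#' @param t time (h).
#' @param y state `(gut, central, peripheral, yprol, ..., ycirc)`.
#' @param params list with elements `pk` ([twocpt_params()]) and `fk`
#'   ([fk_params()]).
#' @return `dy/dt`, length 8.
#' @export
fk_full_rhs <- function(t, y, params) {
  A <- rate_matrix(params$pk)
  dpk <- drop(A %*% y[1:3])
  c(dpk, fk_rhs(t, y[4:8], y[1:3], params$fk, params$pk))
}

#' Model-predicted drug concentration
#'
#' `c_hat = u_central / Vcent` at the requested (observation) events.
#'
#' @param sol a `pmx_solution` matrix (row 2 = central compartment).
#' @param Vcent central volume (L, > 0).
#' @param obs indices of the events at which to report the concentration.
#' @return predicted concentrations (mg/L).
#' @export
predicted_concentration <- function(sol, Vcent, obs) {
  if (Vcent <= 0) stop("Vcent must be > 0")
  if (length(obs) == 0) return(numeric(0))
  if (any(obs < 1 | obs > ncol(sol))) stop("obs indices out of range")
  unname(sol[2, obs] / Vcent)
}

#' Lognormal measurement log-likelihood
#'
#' Sum of lognormal log-densities of the observations `y` given predictions
#' `y_hat` and log-scale residual sd `sigma`:
#' `sum_i [-log y_i - log sigma - log(2 pi)/2 - (log y_i - log y_hat_i)^2 /
#' (2 sigma^2)]`.
#'
#' @param y positive observations.
#' @param y_hat positive predictions (recycled if length 1).
#' @param sigma residual scale on the log scale (> 0).
#' @return scalar log-likelihood.
#' @export
lognormal_loglik <- function(y, y_hat, sigma) {
  if (any(!is.finite(y)) || any(y <= 0))
    stop("observations must be positive for a lognormal measurement model")
  if (any(!is.finite(y_hat)) || any(y_hat <= 0))
    stop("predictions must be positive for a lognormal measurement model")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  sum(stats::dlnorm(y, meanlog = log(y_hat), sdlog = sigma, log = TRUE))
}

#' Allometric body-weight scaling of PK parameters
#'
#' Conventional power-law scaling of clearances and volumes by body weight
#' relative to a reference: `CL, Q ~ (wt/ref)^0.75`, `V ~ (wt/ref)^1`; the
#' absorption rate `ka` is not scaled.
#'
#' @param theta_norm normalized subject parameters at the reference weight
#'   (`twocpt_params` or numeric `(CL, Q, Vcent, Vperi, ka)`).
#' @param weight body weight (kg, > 0).
#' @param e_cl,e_v allometric exponents for clearances and volumes.
#' @param ref_weight reference weight (kg).
#' @return a [twocpt_params()] object at the subject's weight.
#' @export
allometric_params <- function(theta_norm, weight, e_cl = 0.75, e_v = 1,
                              ref_weight = 70) {
  if (weight <= 0) stop("body weight must be > 0")
  th <- as.numeric(theta_norm)
  w <- weight / ref_weight
  twocpt_params(CL = th[1] * w^e_cl, Q = th[2] * w^e_cl,
                Vcent = th[3] * w^e_v, Vperi = th[4] * w^e_v, ka = th[5])
}

#' Population log-prior for individual parameters
#'
#' Inter-individual variability: each subject's parameter vector is lognormal
#' around the population-typical value, `theta_j ~ LogNormal(log theta_pop,
#' Omega)` with diagonal `Omega`, so the log-density is a sum of independent
#' univariate lognormal terms with log-location `log(theta_pop_d)` and scale
#' `omega_d`.
#'
#' @param theta matrix of per-subject parameters (subjects x parameters),
#'   or a vector for a single subject.
#' @param theta_pop population-typical values (length = n parameters).
#' @param omega log-scale standard deviations (diagonal of Omega).
#' @return scalar log-density.
#' @export
population_logprior <- function(theta, theta_pop, omega) {
  if (is.null(dim(theta))) theta <- rbind(theta)
  if (ncol(theta) != length(theta_pop) || length(omega) != length(theta_pop))
    stop("dimension mismatch between theta, theta_pop and omega")
  if (any(omega <= 0)) stop("omega must be positive elementwise")
  if (any(theta <= 0) || any(theta_pop <= 0))
    stop("lognormal population model requires positive parameters")
  sum(stats::dlnorm(t(theta), meanlog = log(theta_pop), sdlog = omega,
                    log = TRUE))
}
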