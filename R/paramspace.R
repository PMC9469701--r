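#' Declare one model parameter
#'
#' A parameter declaration carries a name, a shape, a bound specification and
#' a prior.  Bounds may be numbers or character expressions referencing
#' *previously declared* parameters (evaluated per draw), e.g. a population
#' absorption rate bounded below by the slower hybrid disposition rate to
#' rule out flip-flop.
#'
#' @param name parameter name.
#' @param length number of elements (scalar by default).
#' @param lower,upper bound: `NULL` (unbounded), a number, or a character
#'   expression of earlier parameters.
#' @param prior a list `list(family, pars)`; families: `"normal"`
#'   (mean, sd), `"lognormal"` (meanlog, sdlog), `"halfnormal"` (scale),
#'   `"halfcauchy"` (scale), `"uniform"` (min, max), `"exponential"` (rate),
#'   or `"flat"` (improper).
#' @return a `pmx_param` declaration.
#' @export
pmx_param <- function(name, length = 1L, lower = NULL, upper = NULL,
                      prior = list(family = "flat", pars = numeric())) {
  stopifnot(is.character(name), length >= 1)
  structure(list(name = name, length = as.integer(length), lower = lower,
                 upper = upper, prior = prior),
            class = "pmx_param")
}

#' Assemble a parameter space
#'
#' Orders the declarations, resolves bound expressions (which may only
#' reference earlier declarations -- a later or unknown reference is rejected,
#' which also rules out cycles), and defines the bijective map between the
#' constrained region and an unconstrained vector: lower-bounded parameters
#' use a shifted log transform, upper-bounded a reflected one, and two-sided
#' bounds a scaled logistic; the log-Jacobian of the map is accumulated per
#' draw.
#'
#' @param ... `pmx_param` declarations (or a single list of them).
#' @return a `pmx_space` object.
#' @export
parameter_space <- function(...) {
  pars <- list(...)
  if (length(pars) == 1L && !inherits(pars[[1]], "pmx_param"))
    pars <- pars[[1]]
  stopifnot(all(vapply(pars, inherits, TRUE, "pmx_param")))
  nms <- vapply(pars, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate parameter names")
  for (d in seq_along(pars)) {
    for (side in c("lower", "upper")) {
      b <- pars[[d]][[side]]
      if (is.character(b)) {
        refs <- all.vars(str2lang(b))
        bad <- setdiff(refs, nms[seq_len(d - 1L)])
        if (length(bad))
          stop("bound expression for ", nms[d], " references undeclared or ",
               "later parameter(s): ", paste(bad, collapse = ", "),
               " (bounds may only use earlier declarations)")
      }
    }
  }
  lens <- vapply(pars, `[[`, 1L, "length")
  offs <- cumsum(c(0L, lens))[seq_along(pars)]
  structure(list(params = pars, names = nms, lengths = lens, offsets = offs,
                 dim = sum(lens)),
            class = "pmx_space")
}

#' @export
print.pmx_space <- function(x, ...) {
  cat("<pmx_space> ", x$dim, " unconstrained dimension(s)\n", sep = "")
  for (p in x$params)
    cat("  ", p$name, " [", p$length, "] ", p$prior$family,
        if (!is.null(p$lower)) paste0(" lower=", paste(p$lower, collapse = "")),
        if (!is.null(p$upper)) paste0(" upper=", paste(p$upper, collapse = "")),
        "\n", sep = "")
  invisible(x)
}

eval_bound <- function(b, theta_so_far) {
  if (is.null(b)) return(NULL)
  if (is.numeric(b)) return(b)
  eval(str2lang(b), envir = theta_so_far)
}

#' Map an unconstrained vector to the constrained scale
#'
#' @param space a `pmx_space`.
#' @param x unconstrained numeric vector of length `space$dim`.
#' @return a list with `theta` (named list of constrained values) and
#'   `log_jacobian` (scalar, the log absolute determinant of the map).
#' @export
constrain_pars <- function(space, x) {
  stopifnot(inherits(space, "pmx_space"), length(x) == space$dim)
  theta <- list()
  lj <- 0
  for (d in seq_along(space$params)) {
    p <- space$params[[d]]
    xi <- x[space$offsets[d] + seq_len(p$length)]
    L <- eval_bound(p$lower, theta)
    U <- eval_bound(p$upper, theta)
    if (is.null(L) && is.null(U)) {
      v <- xi
    } else if (!is.null(L) && is.null(U)) {
      v <- L + exp(xi)
      lj <- lj + sum(xi)
    } else if (is.null(L)) {
      v <- U - exp(xi)
      lj <- lj + sum(xi)
    } else {
      s <- stats::plogis(xi)
      v <- L + (U - L) * s
      lj <- lj + sum(log(U - L) + stats::plogis(xi, log.p = TRUE) +
                       stats::plogis(-xi, log.p = TRUE))
    }
    theta[[p$name]] <- v
  }
  list(theta = theta, log_jacobian = lj)
}

#' Map constrained values to the unconstrained scale
#'
#' The inverse of [constrain_pars()].  A value violating its bounds is
#' rejected with an error.
#'
#' @param space a `pmx_space`.
#' @param theta named list of constrained values.
#' @return unconstrained numeric vector.
#' @export
unconstrain_pars <- function(space, theta) {
  stopifnot(inherits(space, "pmx_space"))
  x <- numeric(space$dim)
  seen <- list()
  for (d in seq_along(space$params)) {
    p <- space$params[[d]]
    v <- theta[[p$name]]
    if (is.null(v) || length(v) != p$length)
      stop("missing or mis-sized value for parameter ", p$name)
    L <- eval_bound(p$lower, seen)
    U <- eval_bound(p$upper, seen)
    if (!is.null(L) && any(v <= L) || !is.null(U) && any(v >= U))
      stop("value for ", p$name, " violates its declared bounds")
    xi <- if (is.null(L) && is.null(U)) v
      else if (!is.null(L) && is.null(U)) log(v - L)
      else if (is.null(L)) log(U - v)
      else stats::qlogis((v - L) / (U - L))
    x[space$offsets[d] + seq_len(p$length)] <- xi
    seen[[p$name]] <- v
  }
  x
}

prior_logpdf <- function(prior, v) {
  pars <- prior$pars
  switch(prior$family,
    flat = 0,
    normal = sum(stats::dnorm(v, pars[1], pars[2], log = TRUE)),
    lognormal = sum(stats::dlnorm(v, pars[1], pars[2], log = TRUE)),
    halfnormal = sum(log(2) + stats::dnorm(v, 0, pars[1], log = TRUE)),
    halfcauchy = sum(log(2) + stats::dcauchy(v, 0, pars[1], log = TRUE)),
    uniform = sum(stats::dunif(v, pars[1], pars[2], log = TRUE)),
    exponential = sum(stats::dexp(v, pars[1], log = TRUE)),
    stop("unknown prior family: ", prior$family))
}

prior_draw <- function(prior, n) {
  pars <- prior$pars
  switch(prior$family,
    normal = stats::rnorm(n, pars[1], pars[2]),
    lognormal = stats::rlnorm(n, pars[1], pars[2]),
    halfnormal = abs(stats::rnorm(n, 0, pars[1])),
    halfcauchy = abs(stats::rcauchy(n, 0, pars[1])),
    uniform = stats::runif(n, pars[1], pars[2]),
    exponential = stats::rexp(n, pars[1]),
    flat = stop("cannot draw initial values from an improper (flat) prior"),
    stop("unknown prior family: ", prior$family))
}

#' Log prior density of a parameter space
#'
#' Sum of the declared prior log-densities evaluated at constrained values
#' (no Jacobian terms; those belong to the transform and are added by
#' [log_joint()]).
#'
#' @param space a `pmx_space`.
#' @param theta named list of constrained values.
#' @return scalar log prior density (up to truncation constants).
#' @export
log_prior <- function(space, theta) {
  lp <- 0
  for (p in space$params)
    lp <- lp + prior_logpdf(p$prior, theta[[p$name]])
  lp
}

#' Draw chain initial values from the priors
#'
#' Independent prior draws per chain, mapped to the unconstrained space.
#' Draws violating a (possibly draw-dependent) bound are redrawn; improper
#' priors are rejected.
#'
#' @param space a `pmx_space`.
#' @param n_chains number of chains.
#' @param seed RNG seed.
#' @return a matrix (`n_chains` x `space$dim`) of unconstrained initial
#'   values, with the constrained draws in attribute `"theta"`.
#' @export
init_from_prior <- function(space, n_chains, seed = 1L) {
  stopifnot(inherits(space, "pmx_space"))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  X <- matrix(NA_real_, n_chains, space$dim)
  thetas <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    theta <- list()
    for (p in space$params) {
      L <- eval_bound(p$lower, theta)
      U <- eval_bound(p$upper, theta)
      v <- prior_draw(p$prior, p$length)
      in_bounds <- function(v) {
        ok <- rep(TRUE, length(v))
        if (!is.null(L)) ok <- ok & v > L
        if (!is.null(U)) ok <- ok & v < U
        ok
      }
      for (tries in seq_len(1000L)) {
        ok <- in_bounds(v)
        if (all(ok)) break
        v[!ok] <- prior_draw(p$prior, sum(!ok))
      }
      if (!is.null(L) && any(v <= L) || !is.null(U) && any(v >= U))
        stop("could not draw an initial value for ", p$name,
             " inside its bounds; prior and bounds are incompatible")
      theta[[p$name]] <- v
    }
    thetas[[ch]] <- theta
    X[ch, ] <- unconstrain_pars(space, theta)
  }
  attr(X, "theta") <- thetas
  X
}

# save/restore the global RNG state around seeded package internals
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
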