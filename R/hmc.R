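#' Adaptive Hamiltonian Monte Carlo
#'
#' Samples a [pmx_posterior()] with leapfrog-integrated HMC.  Warmup adapts
#' the step size by dual averaging towards a target acceptance statistic
#' (default 0.8) and a diagonal metric from windowed warmup draws (an initial
#' step-size-only buffer, doubling variance-estimation windows, and a closing
#' step-size buffer); the number of leapfrog steps is jittered around a
#' configured trajectory path length.  A transition whose Hamiltonian error
#' exceeds the divergence threshold (or becomes non-finite) is rejected and
#' flagged divergent.  Sampling-phase tuning is frozen.  Given the same seed
#' the draws are bit-identical.
#'
#' @param posterior a [pmx_posterior()].
#' @param n_chains number of Markov chains.
#' @param inits matrix (`n_chains` x dim) of unconstrained initial values;
#'   defaults to independent prior draws via [init_from_prior()].
#' @param n_warmup,n_sampling iterations per phase (defaults 1000/1000).
#' @param seed integer RNG seed.
#' @param control list overriding tuning constants: `target_accept` (0.8),
#'   `path_length` (integration time, 1.5), `jitter` (relative jitter of the
#'   step count, 0.3), `max_leapfrog` (512), `divergence_threshold` (1000),
#'   `init_stepsize` (heuristic when `NULL`).
#' @return a `pmx_draws` object: constrained draws
#'   (`iterations x chains x parameters`), divergence flags, acceptance
#'   statistics, adapted step sizes and metric, and the seed record.
#' @examples
#' \donttest{
#' post <- pmx_posterior(
#'   parameter_space(pmx_param("mu", prior = list(family = "normal",
#'                                                pars = c(0, 1)))),
#'   loglik = function(theta, data) 0, data = NULL)
#' fit <- sample_hmc(post, n_chains = 2, n_warmup = 200, n_sampling = 200,
#'                   seed = 1)
#' summarize_draws(fit)
#' }
#' @export
sample_hmc <- function(posterior, n_chains = 4, inits = NULL,
                       n_warmup = 1000, n_sampling = 1000, seed = 1L,
                       control = list()) {
  stopifnot(inherits(posterior, "pmx_posterior"))
  ctl <- utils::modifyList(
    list(target_accept = 0.8, path_length = 1.5, jitter = 0.3,
         max_leapfrog = 512L, divergence_threshold = 1000,
         init_stepsize = NULL), control)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (is.null(inits))
    inits <- init_from_prior(posterior$space, n_chains,
                             seed = seed + 104729L)
  inits <- rbind(inits)
  if (nrow(inits) != n_chains)
    stop("need one row of initial values per chain")
  dim_x <- posterior$space$dim
  par_names <- flat_par_names(posterior$space)

  draws <- array(NA_real_, c(n_sampling, n_chains, dim_x),
                 dimnames = list(NULL, NULL, par_names))
  divergent <- matrix(FALSE, n_sampling, n_chains)
  accept_stat <- matrix(NA_real_, n_sampling, n_chains)
  eps_out <- numeric(n_chains)
  metric_out <- matrix(1, n_chains, dim_x)

  lp_fun <- function(x) log_joint(posterior, x)
  grad_fun <- function(x) grad_log_joint(posterior, x)

  for (ch in seq_len(n_chains)) {
    res <- run_chain(lp_fun, grad_fun, inits[ch, ], n_warmup, n_sampling, ctl)
    for (i in seq_len(n_sampling))
      draws[i, ch, ] <- constrained_vector(posterior$space, res$draws[i, ])
    divergent[, ch] <- res$divergent
    accept_stat[, ch] <- res$accept_stat
    eps_out[ch] <- res$eps
    metric_out[ch, ] <- res$inv_mass
  }
  structure(list(draws = draws, divergent = divergent,
                 accept_stat = accept_stat, stepsize = eps_out,
                 inv_metric = metric_out, seed = seed,
                 n_warmup = n_warmup, n_sampling = n_sampling,
                 space = posterior$space),
            class = "pmx_draws")
}

flat_par_names <- function(space) {
  unlist(lapply(space$params, function(p)
    if (p$length == 1L) p$name
    else paste0(p$name, "[", seq_len(p$length), "]")))
}

constrained_vector <- function(space, x) {
  unlist(constrain_pars(space, x)$theta, use.names = FALSE)
}

run_chain <- function(lp_fun, grad_fun, x, n_warmup, n_sampling, ctl) {
  dim_x <- length(x)
  lp <- lp_fun(x)
  if (!is.finite(lp))
    stop("initial value has non-finite log density; supply new inits")
  inv_mass <- rep(1, dim_x)
  eps <- if (is.null(ctl$init_stepsize))
    heuristic_stepsize(lp_fun, grad_fun, x, inv_mass) else ctl$init_stepsize

  # dual averaging state (restarted at each metric update)
  da <- da_init(eps)
  win <- adapt_windows(n_warmup)
  win_draws <- NULL
  n_accept_warm <- 0

  n_total <- n_warmup + n_sampling
  out <- matrix(NA_real_, n_sampling, dim_x)
  divergent <- logical(n_sampling)
  accept_stat <- numeric(n_sampling)

  for (it in seq_len(n_total)) {
    warm <- it <= n_warmup
    step <- hmc_transition(lp_fun, grad_fun, x, lp, eps, inv_mass, ctl)
    x <- step$x; lp <- step$lp
    if (warm) {
      n_accept_warm <- n_accept_warm + step$accepted
      da <- da_update(da, step$alpha, ctl$target_accept)
      eps <- da$eps
      if (it %in% win$collect) win_draws <- rbind(win_draws, x)
      if (it %in% win$update && !is.null(win_draws) &&
          nrow(win_draws) >= 5) {
        n <- nrow(win_draws)
        v <- apply(win_draws, 2, stats::var)
        inv_mass <- v * n / (n + 5) + 1e-3 * 5 / (n + 5)
        win_draws <- NULL
        eps <- heuristic_stepsize(lp_fun, grad_fun, x, inv_mass)
        da <- da_init(eps)
      }
      if (it == min(100L, n_warmup) && n_accept_warm == 0)
        stop("no proposal accepted during early warmup; ",
             "initial values appear pathological -- supply new inits")
      if (it == n_warmup) eps <- da$eps_bar
    } else {
      i <- it - n_warmup
      out[i, ] <- x
      divergent[i] <- step$divergent
      accept_stat[i] <- step$alpha
    }
  }
  list(draws = out, divergent = divergent, accept_stat = accept_stat,
       eps = eps, inv_mass = inv_mass)
}

hmc_transition <- function(lp_fun, grad_fun, x, lp, eps, inv_mass, ctl) {
  dim_x <- length(x)
  p <- stats::rnorm(dim_x) / sqrt(inv_mass)
  jit <- stats::runif(1, 1 - ctl$jitter, 1 + ctl$jitter)
  L <- ctl$path_length * jit / eps
  L <- if (!is.finite(L)) ctl$max_leapfrog
    else as.integer(max(1, min(ctl$max_leapfrog, round(L))))
  H0 <- -lp + 0.5 * sum(p^2 * inv_mass)
  xn <- x
  g <- tryCatch(grad_fun(xn), error = function(e) rep(NaN, dim_x))
  ok <- all(is.finite(g))
  if (ok) {
    p <- p + 0.5 * eps * g
    for (l in seq_len(L)) {
      xn <- xn + eps * inv_mass * p
      g <- tryCatch(grad_fun(xn), error = function(e) rep(NaN, dim_x))
      if (!all(is.finite(g))) { ok <- FALSE; break }
      p <- p + (if (l < L) eps else 0.5 * eps) * g
    }
  }
  lpn <- if (ok) lp_fun(xn) else -Inf
  H1 <- if (ok && is.finite(lpn)) -lpn + 0.5 * sum(p^2 * inv_mass) else Inf
  dH <- H1 - H0
  div <- !is.finite(dH) || abs(dH) > ctl$divergence_threshold
  alpha <- if (div) 0 else min(1, exp(-dH))
  if (!div && stats::runif(1) < alpha)
    list(x = xn, lp = lpn, alpha = alpha, accepted = TRUE, divergent = FALSE)
  else
    list(x = x, lp = lp, alpha = alpha, accepted = FALSE, divergent = div)
}

heuristic_stepsize <- function(lp_fun, grad_fun, x, inv_mass) {
  eps <- 0.1
  lp0 <- lp_fun(x)
  one_step <- function(eps) {
    p <- 0.5 / sqrt(inv_mass)  # deterministic probe momentum
    H0 <- -lp0 + 0.5 * sum(p^2 * inv_mass)
    g <- tryCatch(grad_fun(x), error = function(e) rep(NaN, length(x)))
    if (!all(is.finite(g))) return(-Inf)
    p1 <- p + 0.5 * eps * g
    x1 <- x + eps * inv_mass * p1
    g1 <- tryCatch(grad_fun(x1), error = function(e) rep(NaN, length(x)))
    if (!all(is.finite(g1))) return(-Inf)
    p1 <- p1 + 0.5 * eps * g1
    lp1 <- lp_fun(x1)
    if (!is.finite(lp1)) return(-Inf)
    -(-lp1 + 0.5 * sum(p1^2 * inv_mass)) + H0
  }
  dH <- one_step(eps)
  dir <- if (is.finite(dH) && exp(dH) > 0.5) 1 else -1
  for (k in seq_len(30)) {
    eps_new <- eps * 2^dir
    dH <- one_step(eps_new)
    cross <- if (dir > 0) !(is.finite(dH) && exp(dH) > 0.5)
      else (is.finite(dH) && exp(dH) > 0.5)
    if (cross) break
    eps <- eps_new
  }
  eps
}

da_init <- function(eps0) {
  list(mu = log(10 * eps0), h_bar = 0, log_eps_bar = log(eps0),
       eps = eps0, eps_bar = eps0, iter = 0,
       gamma = 0.05, t0 = 10, kappa = 0.75)
}

da_update <- function(da, alpha, target) {
  da$iter <- da$iter + 1
  m <- da$iter
  w <- 1 / (m + da$t0)
  da$h_bar <- (1 - w) * da$h_bar + w * (target - alpha)
  log_eps <- da$mu - sqrt(m) / da$gamma * da$h_bar
  da$eps <- exp(log_eps)
  wm <- m^(-da$kappa)
  da$log_eps_bar <- wm * log_eps + (1 - wm) * da$log_eps_bar
  da$eps_bar <- exp(da$log_eps_bar)
  da
}

# Stan-style warmup schedule: step-size buffer, doubling metric windows,
# closing step-size buffer.  `collect` are iterations whose draws feed the
# metric, `update` the iterations at which the metric is refreshed.
adapt_windows <- function(n_warmup) {
  if (n_warmup < 20) return(list(collect = integer(), update = integer()))
  init <- max(1L, min(75L, as.integer(0.15 * n_warmup)))
  term <- max(1L, min(50L, as.integer(0.10 * n_warmup)))
  slow_end <- n_warmup - term
  collect <- integer()
  update <- integer()
  w <- 25L
  start <- init + 1L
  while (start <= slow_end) {
    end <- min(start + w - 1L, slow_end)
    if (slow_end - end < w * 2L) end <- slow_end  # absorb the remainder
    collect <- c(collect, start:end)
    update <- c(update, end)
    start <- end + 1L
    w <- w * 2L
  }
  list(collect = collect, update = update)
}

#' @export
print.pmx_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("<pmx_draws> ", d[2], " chain(s) x ", d[1], " sampling iterations, ",
      d[3], " parameter(s)\n", sep = "")
  ndiv <- sum(x$divergent)
  if (ndiv > 0) cat("  ", ndiv, " divergent transition(s)\n", sep = "")
  cat("  adapted step sizes: ", paste(signif(x$stepsize, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Extract draws as a matrix
#'
#' @param x a `pmx_draws` object.
#' @param ... unused.
#' @return matrix of pooled draws (iterations stacked over chains) x
#'   parameters.
#' @export
as.matrix.pmx_draws <- function(x, ...) {
  d <- dim(x$draws)
  m <- matrix(x$draws, d[1] * d[2], d[3])
  colnames(m) <- dimnames(x$draws)[[3]]
  m
}

#' Write draws to CSV
#'
#' One row per iteration: chain id, iteration, constrained parameter values
#' and the divergence flag.
#'
#' @param draws a `pmx_draws` object.
#' @param path output path.
#' @export
write_draws_csv <- function(draws, path) {
  d <- dim(draws$draws)
  rows <- do.call(rbind, lapply(seq_len(d[2]), function(ch) {
    data.frame(chain = ch, iteration = seq_len(d[1]),
               draws$draws[, ch, , drop = TRUE],
               divergent = draws$divergent[, ch], check.names = FALSE)
  }))
  colnames(rows)[3:(2 + d[3])] <- dimnames(draws$draws)[[3]]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
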