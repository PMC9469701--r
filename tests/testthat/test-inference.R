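# a tiny fixed-design posterior: one dose, one observation, lognormal priors
toy_posterior <- function(y = 2.5) {
  ev <- read_events_table(data.frame(time = c(0, 2), amt = c(100, 0),
                                     cmt = 1, evid = c(1, 0),
                                     dv = c(NA, y)))
  pk_posterior(ev, model = "twocpt")
}

test_that("the log joint assembles priors, Jacobians and likelihood exactly", {
  post <- toy_posterior(y = 2.5)
  x <- log(c(10, 15, 35, 105, 2, 0.2))
  th <- exp(x)
  p <- twocpt_params(th[1], th[2], th[3], th[4], th[5])
  u <- advance_interval_analytic(c(100, 0, 0), p, 2)
  chat <- u[["central"]] / th[3]
  pri <- default_pk_priors("twocpt")
  by_hand <- sum(x) +  # Jacobians of the six log transforms
    sum(sapply(1:5, function(i)
      dlnorm(th[i], pri[[i]]$pars[1], pri[[i]]$pars[2], log = TRUE))) +
    log(2) + dnorm(th[6], 0, pri$sigma$pars, log = TRUE) +
    lognormal_loglik(2.5, chat, th[6])
  expect_equal(log_joint(post, x), by_hand, tolerance = 1e-10)

  # the compiled fast path agrees with the generic assembly
  generic <- post; generic$log_density <- NULL
  expect_equal(post$log_density(x), log_joint(generic, x),
               tolerance = 1e-10)

  # decomposition: full = prior-only + likelihood-only
  expect_equal(log_joint(generic, x),
               log_joint(generic, x, include_likelihood = FALSE) +
                 log_joint(generic, x, include_prior = FALSE),
               tolerance = 1e-10)

  expect_error(log_joint(post, c(x[-6], NA)), "non-finite")
})

test_that("adding an independent observation adds exactly its likelihood term", {
  post1 <- toy_posterior(y = 2.5)
  ev2 <- read_events_table(data.frame(time = c(0, 2, 2), amt = c(100, 0, 0),
                                      cmt = 1, evid = c(1, 0, 0),
                                      dv = c(NA, 2.5, 3.1)))
  post2 <- pk_posterior(ev2)
  x <- log(c(10, 15, 35, 105, 2, 0.2))
  th <- exp(x)
  u <- advance_interval_analytic(c(100, 0, 0),
                                 twocpt_params(th[1], th[2], th[3], th[4],
                                               th[5]), 2)
  extra <- lognormal_loglik(3.1, u[["central"]] / th[3], th[6])
  expect_equal(log_joint(post2, x), log_joint(post1, x) + extra,
               tolerance = 1e-10)
})

test_that("the log joint is finite across prior draws of the tutorial model", {
  ev <- simulate_dataset(build_tutorial_regimen(), ref_params(),
                         sigma = 0.2, seed = 5)
  post <- pk_posterior(ev)
  X <- init_from_prior(post$space, 100, seed = 8)
  lps <- apply(X, 1, function(x) log_joint(post, x))
  expect_true(all(is.finite(lps)))
})

test_that("finite-difference gradients are accurate and second order", {
  quad <- pmx_posterior(
    parameter_space(pmx_param("z", length = 3,
                              prior = list(family = "normal",
                                           pars = c(0, 1)))),
    loglik = function(theta, data) 0, data = NULL)
  x <- c(0.5, -1.3, 2)
  expect_equal(grad_log_joint(quad, x), -x, tolerance = 1e-6)

  # Richardson check on a smooth 1-D target: halving h scales the error ~h^2
  f <- function(x) sin(3 * x)
  fd <- function(h) (f(1 + h) - f(1 - h)) / (2 * h)
  e1 <- abs(fd(1e-3) - 3 * cos(3))
  e2 <- abs(fd(5e-4) - 3 * cos(3))
  expect_equal(e1 / e2, 4, tolerance = 0.2)

  # at a likelihood-flat point the gradient of a lower = 0 coordinate is the
  # derivative of its log-Jacobian plus the prior term; with a flat prior it
  # is exactly 1
  flat <- pmx_posterior(
    parameter_space(pmx_param("v", lower = 0,
                              prior = list(family = "flat",
                                           pars = numeric()))),
    loglik = function(theta, data) 0, data = NULL)
  expect_equal(grad_log_joint(flat, 0.7), 1, tolerance = 1e-6)
})

test_that("HMC recovers known Gaussian targets deterministically", {
  # 1-D standard normal
  post <- pmx_posterior(
    parameter_space(pmx_param("mu", prior = list(family = "normal",
                                                 pars = c(0, 1)))),
    loglik = function(theta, data) 0, data = NULL)
  d <- sample_hmc(post, n_chains = 4, n_warmup = 1000, n_sampling = 1000,
                  seed = 7)
  m <- as.numeric(as.matrix(d))
  mcse <- sd(m) / sqrt(ess(d, "mu"))
  expect_lt(abs(mean(m)), 3 * mcse)
  expect_lt(abs(var(m) - 1), 0.1)

  # bit-identical under the same seed
  d2 <- sample_hmc(post, n_chains = 4, n_warmup = 1000, n_sampling = 1000,
                   seed = 7)
  expect_identical(d$draws, d2$draws)

  # 5-D correlated Gaussian: sample covariance within 15% Frobenius of truth
  S <- 0.6 ^ abs(outer(1:5, 1:5, "-"))
  Sinv <- solve(S)
  post5 <- pmx_posterior(
    parameter_space(pmx_param("z", length = 5,
                              prior = list(family = "flat",
                                           pars = numeric()))),
    loglik = function(theta, data) -0.5 * drop(theta$z %*% Sinv %*% theta$z),
    data = NULL)
  d5 <- sample_hmc(post5, n_chains = 4,
                   inits = matrix(rnorm(20, sd = 0.5), 4, 5),
                   n_warmup = 1000, n_sampling = 1000, seed = 3)
  Shat <- cov(as.matrix(d5))
  expect_lt(norm(Shat - S, "F") / norm(S, "F"), 0.15)

  # pathological inits are reported
  expect_error(sample_hmc(post, n_chains = 1, inits = matrix(1e200, 1, 1),
                          n_warmup = 100, n_sampling = 10, seed = 1),
               "inits|log density")
})

test_that("pooled draws from a 2-D Gaussian pass a Kolmogorov-Smirnov check", {
  post <- pmx_posterior(
    parameter_space(pmx_param("z", length = 2,
                              prior = list(family = "normal",
                                           pars = c(0, 1)))),
    loglik = function(theta, data) 0, data = NULL)
  d <- sample_hmc(post, n_chains = 4, n_warmup = 500, n_sampling = 1000,
                  seed = 12)
  m <- as.matrix(d)
  for (j in 1:2) {
    ks <- suppressWarnings(ks.test(m[, j], pnorm))
    expect_lt(unname(ks$statistic), 0.05)
  }
})
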