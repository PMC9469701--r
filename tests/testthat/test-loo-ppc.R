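# conjugate normal-normal toy with known variance: everything about LOO is
# available in closed form, so exact leave-one-out refits are cheap
conjugate_toy <- function(n = 10, seed = 71, mu0 = 0, tau0 = 2, sigma = 1) {
  set.seed(seed)
  y <- rnorm(n, 1.2, sigma)
  post_par <- function(yy) {
    prec <- 1 / tau0^2 + length(yy) / sigma^2
    list(mean = (mu0 / tau0^2 + sum(yy) / sigma^2) / prec,
         sd = sqrt(1 / prec))
  }
  list(y = y, sigma = sigma, post_par = post_par)
}

test_that("pointwise log-likelihood matrices decompose the likelihood", {
  toy <- conjugate_toy()
  set.seed(81)
  pp <- toy$post_par(toy$y)
  mu_draws <- matrix(rnorm(4000, pp$mean, pp$sd), ncol = 1,
                     dimnames = list(NULL, "mu"))
  ll <- pointwise_loglik(mu_draws, function(th, data)
    dnorm(toy$y, th[1], toy$sigma, log = TRUE))
  expect_equal(dim(ll), c(4000, 10))
  # row sums reproduce the total likelihood at each draw
  tot <- sapply(mu_draws[1:50, 1], function(m)
    sum(dnorm(toy$y, m, toy$sigma, log = TRUE)))
  expect_equal(unname(rowSums(ll)[1:50]), tot, tolerance = 1e-10)
  # hand computation on a two-observation toy
  ll2 <- pointwise_loglik(matrix(c(0, 1), 2, 1),
                          function(th, data) dnorm(c(0.5, 2), th[1],
                                                   1, log = TRUE))
  expect_equal(ll2[1, ], dnorm(c(0.5, 2), 0, 1, log = TRUE))
  expect_equal(ll2[2, ], dnorm(c(0.5, 2), 1, 1, log = TRUE))
})

test_that("PSIS-LOO matches exact leave-one-out refits on the conjugate toy", {
  toy <- conjugate_toy(n = 10)
  set.seed(91)
  pp <- toy$post_par(toy$y)
  mu_draws <- rnorm(8000, pp$mean, pp$sd)
  ll <- sapply(seq_along(toy$y), function(i)
    dnorm(toy$y[i], mu_draws, toy$sigma, log = TRUE))
  res <- psis_loo(ll)

  # exact refits: log p(y_i | y_-i) is a normal predictive density
  exact <- sapply(seq_along(toy$y), function(i) {
    pp_i <- toy$post_par(toy$y[-i])
    dnorm(toy$y[i], pp_i$mean, sqrt(pp_i$sd^2 + toy$sigma^2), log = TRUE)
  })
  expect_lt(abs(res$elpd_loo - sum(exact)), 2 * res$se)
  expect_equal(res$elpd_loo, sum(res$pointwise), tolerance = 1e-12)
  expect_true(all(res$k_hat < 0.7, na.rm = TRUE))
})

test_that("degenerate and heavy-tailed importance ratios behave as documented", {
  # constant log-likelihood across draws: elpd_i equals that constant
  llc <- matrix(-1.7, 500, 3)
  resc <- psis_loo(llc)
  expect_equal(resc$pointwise, rep(-1.7, 3), tolerance = 1e-12)

  # a mis-specified toy (an extreme observation the posterior cannot reach)
  # produces a heavy right tail of importance ratios and k_hat > 0.7
  set.seed(101)
  theta <- rnorm(4000)
  y_out <- c(0.2, 6)
  ll <- sapply(y_out, function(yi) dnorm(yi, theta, 1, log = TRUE))
  res <- suppressWarnings(psis_loo(ll))
  expect_gt(res$n_high_k, 0)
  expect_warning(psis_loo(ll), "0.7")

  expect_error(psis_loo(matrix(c(1, -Inf), 200, 2)), "non-finite")
  expect_error(psis_loo(matrix(-1, 50, 2)), "100 draws")
})

test_that("elpd comparisons are antisymmetric and zero on identical fits", {
  set.seed(111)
  ll <- matrix(rnorm(2000, -2), 200, 10)
  a <- suppressWarnings(psis_loo(ll))
  expect_equal(elpd_compare(a, a)$elpd_diff, 0)
  ll_b <- ll + matrix(rnorm(2000, 0, 0.1), 200, 10)
  b <- suppressWarnings(psis_loo(ll_b))
  ab <- elpd_compare(a, b); ba <- elpd_compare(b, a)
  expect_equal(ab$elpd_diff, -ba$elpd_diff, tolerance = 1e-12)
  expect_equal(ab$se, ba$se, tolerance = 1e-12)
  bad <- a; bad$n_obs <- 7; bad$pointwise <- a$pointwise[1:7]
  expect_error(elpd_compare(a, bad), "different")
})

test_that("posterior predictive replicates reproduce the noise model", {
  chat <- c(2, 5, 9)
  draws <- cbind(sigma = rep(0.3, 400))
  sim <- function(th, data) chat * exp(th["sigma"] * rnorm(length(chat)))
  reps <- posterior_predictive(draws, sim, seed = 4)
  expect_equal(dim(reps), c(400, 3))
  expect_identical(posterior_predictive(draws, sim, seed = 4), reps)

  # degenerate noise: replicates equal the predictions exactly
  d0 <- cbind(sigma = rep(0, 300))
  reps0 <- posterior_predictive(d0, sim, seed = 4)
  expect_true(all(reps0 == rep(chat, each = 300)))

  # pooled replicate log-residual sd matches sigma
  lr <- log(reps / rep(chat, each = 400))
  expect_lt(abs(sd(as.numeric(lr)) - 0.3) / 0.3, 0.1)
})

test_that("PPC intervals are calibrated, nested and degenerate-safe", {
  set.seed(121)
  n_obs <- 53
  chat <- exp(rnorm(n_obs, 1, 0.5))
  sigma <- 0.25
  reps <- t(replicate(1000, chat * exp(sigma * rnorm(n_obs))))
  ci <- ppc_intervals(reps)
  expect_true(all(ci$lo90 <= ci$lo50 & ci$hi50 <= ci$hi90))

  # well-specified data: about 90% of fresh observations fall in the band
  # (coverage averaged over replicate datasets to tame binomial noise)
  cover <- mean(replicate(50, {
    y_new <- chat * exp(sigma * rnorm(n_obs))
    mean(y_new >= ci$lo90 & y_new <= ci$hi90)
  }))
  expect_lt(abs(cover - 0.9), 0.05)

  const <- matrix(3, 200, 4)
  cic <- ppc_intervals(const)
  expect_true(all(cic$hi90 - cic$lo90 == 0))
  expect_error(ppc_intervals(reps[1:50, ]), "100")
})
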