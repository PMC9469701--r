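test_that("hybrid rate constants satisfy the Vieta identities", {
  p <- ref_params()
  h <- hybrid_constants(p)
  expect_equal(h[["lambda1"]] * h[["lambda2"]], h[["k10"]] * h[["k21"]],
               tolerance = 1e-12)
  expect_equal(h[["lambda1"]] + h[["lambda2"]],
               h[["k10"]] + h[["k12"]] + h[["k21"]], tolerance = 1e-12)
  # frozen values for the reference parameter set (quadratic-root oracle)
  expect_equal(h[["lambda1"]], 0.80653590, tolerance = 1e-7)
  expect_equal(h[["lambda2"]], 0.05060696, tolerance = 1e-7)
  # decoupled limit Q = 0
  h0 <- hybrid_constants(twocpt_params(10, 0, 35, 105, 2))
  expect_equal(h0[["lambda1"]], h0[["k10"]], tolerance = 1e-12)
  expect_equal(h0[["lambda2"]], 0, tolerance = 1e-12)
  expect_error(twocpt_params(-1, 15, 35, 105, 2), "positive")
})

test_that("analytic interval advance matches closed forms and the matrix exponential", {
  p <- ref_params()
  u <- c(500, 120, 80)

  expect_identical(advance_interval_analytic(u, p, 0),
                   setNames(u, c("gut", "central", "peripheral")))

  # absorption-only system (the exact CL = 0, Q = 0 limit): gut empties into
  # central and total mass is conserved
  A <- matrix(0, 3, 3)
  A[1, 1] <- -p[["ka"]]; A[2, 1] <- p[["ka"]]
  ua <- matrix_exponential_advance(A, c(300, 0, 0), 1.3)
  expect_equal(ua[1], 300 * exp(-p[["ka"]] * 1.3), tolerance = 1e-12)
  expect_equal(ua[2], 300 * (1 - exp(-p[["ka"]] * 1.3)), tolerance = 1e-12)
  expect_equal(sum(ua), 300, tolerance = 1e-12)

  # generic states/inputs agree with the matrix-exponential oracle to 1e-10
  set.seed(1)
  for (k in 1:20) {
    pk <- twocpt_params(runif(1, 1, 20), runif(1, 1, 30), runif(1, 10, 80),
                        runif(1, 30, 200), runif(1, 0.1, 4))
    uu <- runif(3, 0, 500)
    bb <- runif(3, 0, 50)
    dt <- runif(1, 0, 24)
    a1 <- advance_interval_analytic(uu, pk, dt, bb)
    a2 <- matrix_exponential_advance(rate_matrix(pk), uu, dt, bb)
    expect_lt(rel_err(as.numeric(a1), as.numeric(a2), 0), 1e-10)
  }

  expect_error(advance_interval_analytic(c(1, NA, 0), p, 1), "finite")
})

test_that("matrix exponential advance handles scalar and nilpotent systems", {
  # 1x1: u e^(-k t) + (r/k)(1 - e^(-k t))
  k <- 0.7; r <- 5; u0 <- 10; dt <- 2.5
  got <- matrix_exponential_advance(matrix(-k), u0, dt, r)
  expect_equal(got, u0 * exp(-k * dt) + r / k * (1 - exp(-k * dt)),
               tolerance = 1e-12)
  expect_identical(matrix_exponential_advance(matrix(-k), u0, 0, r), u0)

  # strictly lower-triangular transit chain: series truncates to a polynomial
  A <- matrix(0, 3, 3); A[2, 1] <- 1; A[3, 2] <- 1
  got <- matrix_exponential_advance(A, c(1, 0, 0), 2)
  expect_equal(got, c(1, 2, 2), tolerance = 1e-12)  # (1, t, t^2/2)

  expect_error(matrix_exponential_advance(matrix(-k), c(1, 2), 1), "dimension")
})

test_that("steady-state dosing matches closed forms and brute-force dosing", {
  # one-compartment bolus into central: F amt / (1 - e^(-k10 ii))
  p1 <- onecpt_params(CL = 5, Vcent = 50, ka = 1)
  ss <- steady_state_state(p1, amt = 100, ii = 12, cmt = 2)
  expect_equal(ss[["central"]], 100 / (1 - exp(-0.1 * 12)), tolerance = 1e-12)

  # two-compartment regimen: 100-dose brute-force simulation oracle
  p <- ref_params()
  ss2 <- steady_state_state(p, amt = 1200, ii = 12, cmt = 1)
  u <- c(0, 0, 0)
  for (k in 1:100) {
    u[1] <- u[1] + 1200
    if (k < 100) u <- advance_interval_analytic(u, p, 12)
  }
  expect_lt(rel_err(as.numeric(ss2), u, 0), 1e-8)

  # fixed point: propagate one interval and re-dose returns u*
  u1 <- advance_interval_analytic(ss2, p, 12)
  u1[1] <- u1[1] + 1200
  expect_lt(rel_err(as.numeric(u1), as.numeric(ss2), 0), 1e-10)

  # ii -> infinity: a single fresh dose
  expect_equal(as.numeric(steady_state_state(p, amt = 50, ii = 5000, cmt = 1)),
               c(50, 0, 0), tolerance = 1e-8)

  # steady-state infusion agrees with brute force
  ssi <- steady_state_state(p, amt = 1200, rate = 300, ii = 12, cmt = 2)
  u <- c(0, 0, 0)
  for (k in 1:100) {
    u <- advance_interval_analytic(u, p, 4, infusion = c(0, 300, 0))
    u <- advance_interval_analytic(u, p, 8)
  }
  u1 <- advance_interval_analytic(ssi, p, 4, infusion = c(0, 300, 0))
  u1 <- advance_interval_analytic(u1, p, 8)
  expect_lt(rel_err(as.numeric(ssi), as.numeric(u1), 1e-12), 1e-10)
  expect_lt(rel_err(as.numeric(ssi), as.numeric(u), 1e-12), 1e-8)

  # a conservative system has no steady state
  A0 <- matrix(c(-1, 1, 1, -1), 2, 2)
  expect_error(steady_state_state(A0, amt = 10, ii = 12, cmt = 1),
               "no steady state")
})

test_that("schedule solutions are linear, mass-conserving and semigroup-consistent", {
  p <- ref_params()
  ev <- tutorial_expanded()
  sol <- solve_schedule_analytic(ev, p)

  # single bolus reported post-dose
  ev1 <- read_events_table(data.frame(time = c(0, 0), amt = c(1200, 0),
                                      cmt = 1, evid = c(1, 0)))
  s1 <- solve_schedule_analytic(ev1, p)
  expect_equal(unname(s1[, 2]), c(1200, 0, 0))

  # doubling every dose doubles the whole solution (linearity)
  ev2 <- ev; ev2$records$amt <- 2 * ev2$records$amt
  expect_equal(unclass(solve_schedule_analytic(ev2, p)), 2 * unclass(sol),
               tolerance = 1e-12, ignore_attr = TRUE)

  # superposition: two interleaved dose streams = sum of each alone
  mk <- function(amts) read_events_table(
    data.frame(time = c(0, 6, 10, 24), amt = amts, cmt = c(1, 2, 1, 1),
               evid = c(1, 1, 1, 0)))
  sAB <- solve_schedule_analytic(mk(c(100, 50, 80, 0)), p)
  sA <- solve_schedule_analytic(mk(c(100, 0, 80, 0)), p)
  sB <- solve_schedule_analytic(mk(c(0, 50, 0, 0)), p)
  expect_lt(rel_err(unclass(sAB), unclass(sA) + unclass(sB), 1e-12), 1e-10)

  # mass balance: with CL = 0 total drug is conserved through any sequence
  A <- rate_matrix(p)
  A[2, 2] <- A[2, 2] + p[["CL"]] / p[["Vcent"]]  # remove elimination
  u <- c(700, 0, 0)
  for (dt in c(0.3, 2, 5, 11)) u <- matrix_exponential_advance(A, u, dt)
  expect_equal(sum(u), 700, tolerance = 700 * 1e-10)

  # semigroup: advance(dt1) o advance(dt2) = advance(dt1 + dt2)
  u <- c(400, 100, 30)
  u12 <- advance_interval_analytic(advance_interval_analytic(u, p, 3.7), p, 8.1)
  expect_lt(rel_err(as.numeric(u12),
                    as.numeric(advance_interval_analytic(u, p, 11.8)), 0),
            1e-10)

  # ss = 1 rows initialize the schedule at steady state
  evss <- read_events_table(data.frame(time = c(0, 6), amt = c(1200, 0),
                                       cmt = 1, evid = c(1, 0), ii = c(12, 0),
                                       ss = c(1, 0)))
  sss <- solve_schedule_analytic(evss, p)
  expect_equal(unname(sss[, 1]),
               as.numeric(steady_state_state(p, 1200, ii = 12, cmt = 1)),
               tolerance = 1e-10)

  # per-event parameters: theta may change between events
  ev3 <- read_events_table(data.frame(time = c(0, 12, 24), amt = c(100, 0, 0),
                                      cmt = 1, evid = c(1, 0, 0)))
  th <- rbind(as.numeric(p), as.numeric(p),
              as.numeric(twocpt_params(20, 15, 35, 105, 2)))
  s3 <- solve_schedule_analytic(ev3, th)
  ref12 <- advance_interval_analytic(c(100, 0, 0), p, 12)
  expect_equal(unname(s3[, 2]), unname(ref12), tolerance = 1e-10)
  ref24 <- advance_interval_analytic(ref12, twocpt_params(20, 15, 35, 105, 2), 12)
  expect_equal(unname(s3[, 3]), unname(ref24), tolerance = 1e-10)
})

test_that("near-degenerate absorption rates fall back gracefully", {
  p <- ref_params()
  h <- hybrid_constants(p)
  pd <- twocpt_params(p[["CL"]], p[["Q"]], p[["Vcent"]], p[["Vperi"]],
                      ka = h[["lambda1"]] * (1 + 1e-10))
  u <- c(100, 20, 5)
  a1 <- advance_interval_analytic(u, pd, 6)
  a2 <- matrix_exponential_advance(rate_matrix(pd), u, 6)
  expect_lt(rel_err(as.numeric(a1), as.numeric(a2), 0), 1e-9)
})
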