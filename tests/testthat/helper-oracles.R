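# Shared fixtures and independent brute-force oracles used across tests.

ref_params <- function() twocpt_params(CL = 10, Q = 15, Vcent = 35,
                                       Vperi = 105, ka = 2)

tutorial_expanded <- function() expand_additional_doses(build_tutorial_regimen())

# mixed relative error: |a - b| relative to |b| with a floor of `floor_frac`
# of the largest magnitude in b (compartments empty to machine noise would
# otherwise dominate a pure relative error)
rel_err <- function(a, b, floor_frac = 1e-8) {
  scale <- max(abs(b))
  max(abs(a - b) / (abs(b) + floor_frac * scale))
}

# --- brute-force diagnostics oracles: direct loop implementations of the ---
# --- published rank-normalized split R-hat / ESS estimators              ---

brute_split <- function(ch) {
  n <- nrow(ch) %/% 2L
  out <- NULL
  for (j in seq_len(ncol(ch)))
    out <- cbind(out, ch[1:n, j], ch[(nrow(ch) - n + 1):nrow(ch), j])
  out
}

brute_ranknorm <- function(x) {
  r <- rank(as.numeric(x), ties.method = "average")
  array(qnorm((r - 0.375) / (length(r) + 0.25)), dim(x))
}

brute_rhat_basic <- function(sp) {
  n <- nrow(sp); m <- ncol(sp)
  mj <- numeric(m); vj <- numeric(m)
  for (j in 1:m) {
    mj[j] <- sum(sp[, j]) / n
    vj[j] <- sum((sp[, j] - mj[j])^2) / (n - 1)
  }
  W <- mean(vj)
  B <- n / (m - 1) * sum((mj - mean(mj))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

brute_rhat <- function(ch) {
  sp <- brute_split(ch)
  max(brute_rhat_basic(brute_ranknorm(sp)),
      brute_rhat_basic(brute_ranknorm(abs(sp - median(sp)))))
}

brute_ess_basic <- function(sp) {
  n <- nrow(sp); m <- ncol(sp)
  mj <- colMeans(sp)
  vj <- apply(sp, 2, var)
  W <- mean(vj)
  B <- n * var(mj)
  var_plus <- (n - 1) / n * W + B / n
  acov <- matrix(0, n, m)
  for (j in 1:m) {
    xc <- sp[, j] - mj[j]
    for (t in 0:(n - 1))
      acov[t + 1, j] <- sum(xc[1:(n - t)] * xc[(1 + t):n]) / n
  }
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  P <- c()
  for (k in 0:floor((n - 1) / 2)) {
    if (2 * k + 2 > n) break
    pk <- rho[2 * k + 1] + rho[2 * k + 2]
    if (k > 0 && pk < 0) break
    P <- c(P, pk)
  }
  for (k in seq_along(P)) P[k] <- min(P[1:k])
  n * m / max(-1 + 2 * sum(P), .Machine$double.eps)
}

brute_ess <- function(ch, kind = "bulk") {
  sp <- brute_split(ch)
  if (kind == "bulk") return(brute_ess_basic(brute_ranknorm(sp)))
  q <- quantile(sp, c(0.05, 0.95), names = FALSE)
  min(brute_ess_basic(0 + (sp <= q[1])), brute_ess_basic(0 + (sp <= q[2])))
}

# stationary AR(1) chains with known ESS ratio (1 - rho) / (1 + rho)
ar1_chains <- function(n, m, rho, seed = 1) {
  set.seed(seed)
  sapply(seq_len(m), function(j) {
    x <- numeric(n)
    x[1] <- rnorm(1)
    for (i in 2:n) x[i] <- rho * x[i - 1] + sqrt(1 - rho^2) * rnorm(1)
    x
  })
}
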