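# Particle ensemble and SIR filter.

test_that("effective sample size follows the stated formula", {
  expect_equal(effective_sample_size(rep(0.01, 100)), 100 / 1.01)
  w <- c(1, rep(0, 99))
  expect_equal(effective_sample_size(w), 50)
  expect_equal(effective_sample_size(c(0.5, 0.5)), 2 / 1.5)
  expect_error(effective_sample_size(c(0.5, 0.2)), "normalized")
})

test_that("systematic resampling copies particles in proportion to weight", {
  set.seed(1)
  e <- particle_ensemble(matrix(1:4, ncol = 1), c(1, 0, 0, 0))
  r <- systematic_resample(e)
  expect_equal(as.vector(r$states), rep(1, 4))
  expect_equal(r$weights, rep(0.25, 4))
  # (0.5, 0.5) with N = 2 yields exactly one copy of each for any offset
  for (i in 1:25) {
    r2 <- systematic_resample(particle_ensemble(matrix(1:2, ncol = 1)))
    expect_equal(sort(as.vector(r2$states)), c(1, 2))
  }
  # copy counts are floor(N w) or ceiling(N w) for random ensembles
  for (i in 1:20) {
    n <- 32
    w <- stats::rexp(n)
    w <- w / sum(w)
    r3 <- systematic_resample(particle_ensemble(matrix(seq_len(n), ncol = 1), w))
    counts <- tabulate(as.vector(r3$states), n)
    expect_true(all(counts >= floor(n * w) & counts <= ceiling(n * w)))
  }
})

test_that("uninformative observations leave weights unchanged and uniform weights avoid resampling", {
  set.seed(2)
  states <- matrix(stats::rnorm(100), ncol = 2)
  e <- particle_ensemble(states)
  om <- list(
    observe = function(s) s,
    loglik = function(o, s) rep(-1.3, nrow(s)) # identical for all particles
  )
  tm <- function(s, a) s
  out <- sir_update(e, 0, c(0, 0), tm, om)
  expect_equal(out$weights, e$weights, tolerance = 1e-12)
  expect_equal(out$states, e$states)
  expect_equal(sum(out$weights), 1, tolerance = 1e-9)
})

test_that("total belief-observation conflict resets weights with a warning", {
  e <- particle_ensemble(matrix(1:4, ncol = 1), c(0.7, 0.1, 0.1, 0.1))
  om <- list(
    observe = function(s) s,
    loglik = function(o, s) rep(-1000, nrow(s))
  )
  expect_warning(
    out <- sir_update(e, 0, 9, function(s, a) s, om),
    "total conflict"
  )
  expect_equal(out$weights, rep(0.25, 4))
})

test_that("weights are normalized after every update and uniform after resampling", {
  set.seed(3)
  e <- particle_ensemble(matrix(stats::rnorm(200), ncol = 1))
  om <- list(
    observe = function(s) s,
    loglik = function(o, s) stats::dnorm(o, s[, 1], 0.1, log = TRUE)
  )
  tm <- function(s, a) s + stats::rnorm(nrow(s), 0, 0.05)
  for (i in 1:10) {
    e <- sir_update(e, 0, 0.5, tm, om)
    expect_equal(sum(e$weights), 1, tolerance = 1e-9)
  }
  # a sharp observation forces weight collapse and hence resampling
  om_sharp <- list(
    observe = function(s) s,
    loglik = function(o, s) stats::dnorm(o, s[, 1], 1e-3, log = TRUE)
  )
  e2 <- particle_ensemble(matrix(stats::rnorm(200), ncol = 1))
  e2 <- sir_update(e2, 0, 0, function(s, a) s, om_sharp)
  expect_equal(e2$weights, rep(1 / 200, 200))
})

test_that("SIR posterior tracks the exact discrete filter on a 2-state chain", {
  set.seed(11)
  prior <- c(0.5, 0.5)
  trans <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  emit <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  sim <- hmm_simulate(30, prior, trans, emit)
  exact <- hmm_exact_filter(prior, trans, emit, sim$obs)
  n <- 2000
  e <- particle_ensemble(matrix(sample.int(2, n, TRUE, prob = prior), ncol = 1))
  tm <- hmm_transition_model(trans)
  om <- hmm_observation_model(emit)
  tv <- numeric(30)
  for (t in 1:30) {
    e <- sir_update(e, 0, sim$obs[t], tm, om)
    p1 <- sum(e$weights[e$states[, 1] == 1])
    tv[t] <- tv_dist(c(p1, 1 - p1), exact[t, ])
  }
  expect_lt(max(tv), 0.1)
})

test_that("particle mean tracks a Kalman filter on a linear-Gaussian system", {
  set.seed(21)
  a <- 0.95
  q <- 0.3^2
  r <- 0.5^2
  n_steps <- 25
  x <- 0
  obs <- numeric(n_steps)
  for (t in 1:n_steps) {
    x <- a * x + stats::rnorm(1, 0, sqrt(q))
    obs[t] <- x + stats::rnorm(1, 0, sqrt(r))
  }
  kf <- kalman_filter(0, 1, a, q, r, obs)
  n <- 5000
  e <- particle_ensemble(matrix(stats::rnorm(n, 0, 1), ncol = 1))
  tm <- function(s, act) a * s + stats::rnorm(nrow(s), 0, sqrt(q))
  om <- list(
    observe = function(s) s,
    loglik = function(o, s) stats::dnorm(o, s[, 1], sqrt(r), log = TRUE)
  )
  for (t in 1:n_steps) {
    e <- sir_update(e, 0, obs[t], tm, om)
    m <- sum(e$weights * e$states[, 1])
    se <- sqrt(kf[t, 2] / n) * 3 + 0.03 # 3 standard errors plus slack
    expect_lt(abs(m - kf[t, 1]), 3 * sqrt(kf[t, 2])) # within posterior spread
  }
  # final mean within a few standard errors of the exact posterior mean
  expect_lt(abs(sum(e$weights * e$states[, 1]) - kf[n_steps, 1]),
    0.2 * sqrt(kf[n_steps, 2]) + 0.05
  )
})

test_that("belief initialization reproduces the configured presence prior", {
  cfg <- occlusion_config()
  set.seed(4)
  b <- initialize_occlusion_belief(cfg, 0.2, 1000)
  expect_lt(abs(mean(b$states[, 7]) - 0.2), 0.05)
  b0 <- initialize_occlusion_belief(cfg, 0, 100)
  expect_equal(sum(b0$states[, 7]), 0)
  expect_true(all(b0$states[, 8] == -1000))
  b1 <- initialize_occlusion_belief(cfg, 1, 100)
  expect_equal(sum(b1$states[, 7]), 100)
  expect_true(all(b1$states[, 8] == cfg$ped_site[1]))
  expect_error(initialize_belief(function(n) matrix(0, n, 1), 1), "N >= 2")
})
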