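# EFE engine: KDE entropy estimator, epistemic/pragmatic values, rollouts,
# and agreement between the plain-R reference path and the compiled batch
# scorer used by the planner.

test_that("kde_entropy recovers closed-form Gaussian entropies", {
  set.seed(5)
  h1 <- kde_entropy(stats::rnorm(2000))
  expect_lt(abs(h1 - 0.5 * log(2 * pi * exp(1))) / (0.5 * log(2 * pi * exp(1))), 0.1)
  x2 <- cbind(stats::rnorm(2000), stats::rnorm(2000))
  h2 <- kde_entropy(x2)
  expect_lt(abs(h2 - log(2 * pi * exp(1))) / log(2 * pi * exp(1)), 0.1)
})

test_that("kde_entropy handles degenerate and tiny inputs", {
  expect_equal(kde_entropy(matrix(1, 1, 1)), 0) # fewer than 2 samples
  same <- matrix(2.5, 50, 2)
  # identical samples: floor-bandwidth kernel entropy, never below the clamp
  expect_equal(kde_entropy(same), 2 * log(sqrt(2 * pi) * aidriver:::KDE_BANDWIDTH_FLOOR),
    tolerance = 1e-9
  )
  expect_gte(kde_entropy(same), -10 * 2)
})

test_that("kde_entropy of a well-separated mixture adds the mixing entropy", {
  set.seed(6)
  x <- c(stats::rnorm(1000, 0, 2), stats::rnorm(1000, 100, 2))
  est <- kde_entropy(x)
  oracle <- (0.5 * log(2 * pi * exp(1) * 4)) + log(2)
  expect_lt(abs(est - oracle) / oracle, 0.1)
  # mixture-weight entropy is isolated by differencing 80/20 vs 50/50
  mk <- function(k) cbind(c(rep(0, k), rep(500, 2000 - k)))
  d <- kde_entropy(mk(1600)) - kde_entropy(mk(1000))
  bern <- function(p) -p * log(p) - (1 - p) * log(1 - p)
  expect_equal(d, bern(0.2) - bern(0.5), tolerance = 0.01)
})

test_that("epistemic value is zero for degenerate beliefs and positive for null-code mixtures", {
  same <- matrix(c(1, 5, 2), 40, 3, byrow = TRUE)
  expect_equal(epistemic_value(same, 1:3), 0)
  # belief mixing the null code with a true position beyond the line of sight
  mixed <- same
  mixed[1:8, 2:3] <- -1000
  expect_gt(epistemic_value(mixed, 1:3), 0)
})

test_that("rollout follows closed-form kinematics", {
  cfg <- occlusion_config()
  tm <- aidriver:::occlusion_transition(cfg)
  om <- aidriver:::occlusion_observation_model(cfg, 0.02)
  st <- matrix(c(0, 10, 0, 0, 0, 0, 0, -1000, -1000, 0), 2, 10, byrow = TRUE)
  e <- particle_ensemble(st)
  # constant acceleration 1 m/s^2: v = 10 + 1 * tau * dt
  pol <- list(actions = matrix(c(rep(1, 5), rep(0, 5)), 5, 2))
  ro <- rollout(e, pol, tm, om)
  expect_equal(ro$states[[5]][1, 2], 11)
  expect_equal(ro$states[[5]][1, 1], 0.2 * sum(10 + 0:4 * 0.2))
  # identity transition keeps states constant
  ro2 <- rollout(e, pol, function(s, a) s, om)
  expect_equal(ro2$states[[1]], ro2$states[[5]])
})

test_that("G equals minus the summed pragmatic and epistemic values, additively over the horizon", {
  cfg <- occlusion_config()
  set.seed(7)
  e <- initialize_occlusion_belief(cfg, 0.2, 24)
  tm <- aidriver:::occlusion_transition(cfg)
  om <- aidriver:::occlusion_observation_model(cfg, 0.02)
  prefs <- aidriver:::occlusion_preferences(cfg, FALSE)
  pol <- list(actions = cbind(rep(-0.5, 12), 0))
  bd <- expected_free_energy(e, pol, tm, om, prefs, aidriver:::OCC_EPI_DIMS)
  expect_equal(bd$G, -sum(bd$pragmatic + bd$epistemic), tolerance = 1e-9)
  # truncating the horizon gives the partial sums of the full breakdown
  pol6 <- list(actions = pol$actions[1:6, , drop = FALSE])
  bd6 <- expected_free_energy(e, pol6, tm, om, prefs, aidriver:::OCC_EPI_DIMS)
  expect_equal(bd6$pragmatic, bd$pragmatic[1:6], tolerance = 1e-9)
  expect_equal(bd6$G, -sum(bd$pragmatic[1:6] + bd$epistemic[1:6]),
    tolerance = 1e-9
  )
})

test_that("a zero-uncertainty belief reduces G to pure goal-seeking", {
  cfg <- occlusion_config()
  e <- initialize_occlusion_belief(cfg, 0, 16) # all particles identical
  tm <- aidriver:::occlusion_transition(cfg)
  om <- aidriver:::occlusion_observation_model(cfg, 0.02)
  prefs <- aidriver:::occlusion_preferences(cfg, FALSE)
  pol <- list(actions = cbind(rep(0, 20), 0))
  bd <- expected_free_energy(e, pol, tm, om, prefs, aidriver:::OCC_EPI_DIMS)
  expect_equal(bd$epistemic, rep(0, 20))
  expect_equal(bd$G, -sum(bd$pragmatic))
})

test_that("crossing the line of sight lowers G under an uncertain belief", {
  cfg <- occlusion_config()
  set.seed(8)
  e <- initialize_occlusion_belief(cfg, 0.25, 32)
  e$states[, 1] <- 16 # close enough that cruising crosses the line of sight
  e$states[, 2] <- 5
  tm <- aidriver:::occlusion_transition(cfg)
  om <- aidriver:::occlusion_observation_model(cfg, 0.02)
  prefs <- aidriver:::occlusion_preferences(cfg, FALSE)
  # braking to a stop never reaches x = 22; holding speed does
  stay <- list(actions = cbind(rep(-2.5, 20), 0))
  cross <- list(actions = cbind(rep(0, 20), 0))
  g_stay <- expected_free_energy(e, stay, tm, om, prefs, aidriver:::OCC_EPI_DIMS)
  g_cross <- expected_free_energy(e, cross, tm, om, prefs, aidriver:::OCC_EPI_DIMS)
  expect_gt(sum(g_cross$epistemic), sum(g_stay$epistemic))
})

test_that("compiled scorer agrees with the R reference on the occlusion scenario", {
  cfg <- occlusion_config()
  ag <- agent_config("test")
  set.seed(9)
  e <- initialize_occlusion_belief(cfg, 0.2, 16)
  tm <- aidriver:::occlusion_transition(cfg)
  om <- aidriver:::occlusion_observation_model(cfg, ag$sigma_obs)
  for (lateral in c(FALSE, TRUE)) {
    prefs <- aidriver:::occlusion_preferences(cfg, lateral)
    nc <- if (lateral) 2 else 1
    acts <- matrix(stats::runif(20 * nc, -2, 0.5), 20, nc)
    cont <- array(acts, dim = c(1, 20, nc))
    cppcfg <- aidriver:::occlusion_cpp_cfg(cfg, ag, lateral)
    sc <- aidriver:::score_policies_cpp(e$states, cont, NULL, 1L, cppcfg)
    pol <- list(actions = if (lateral) acts else cbind(acts[, 1], 0))
    bd <- expected_free_energy(e, pol, tm, om, prefs, aidriver:::OCC_EPI_DIMS,
      ag$bandwidth_floor, ag$bandwidth_cap
    )
    expect_equal(as.vector(sc$pragmatic), bd$pragmatic, tolerance = 1e-8)
    expect_equal(as.vector(sc$epistemic), bd$epistemic, tolerance = 1e-8)
    expect_equal(sc$G[1], bd$G, tolerance = 1e-8)
  }
})

test_that("compiled scorer agrees with the R reference on the time-sharing scenario", {
  cfg <- timesharing_config(sigma_w = 0) # deterministic for exact agreement
  ag <- agent_config("test")
  set.seed(10)
  st <- aidriver:::timesharing_init_state(cfg)[rep(1, 16), , drop = FALSE]
  st[, 2] <- stats::rnorm(16, 0, 0.2)
  st[, 3] <- stats::rnorm(16, 0, 0.01)
  e <- particle_ensemble(st)
  tm <- aidriver:::timesharing_transition(cfg)
  om <- aidriver:::timesharing_observation_model(cfg, ag$sigma_obs,
    ag$bandwidth_floor
  )
  prefs <- aidriver:::timesharing_preferences(cfg)
  acts <- cbind(stats::runif(20, -1, 1), stats::runif(20, -0.1, 0.1))
  gaze <- rep(c(0, 0, 0, 1), 5)
  cont <- array(acts, dim = c(1, 20, 2))
  disc <- array(gaze, dim = c(1, 20, 1))
  cppcfg <- aidriver:::timesharing_cpp_cfg(cfg, ag)
  sc <- aidriver:::score_policies_cpp(e$states, cont, disc, 2L, cppcfg)
  pol <- list(actions = cbind(acts, gaze))
  bd <- expected_free_energy(e, pol, tm, om, prefs, aidriver:::TS_EPI_DIMS,
    ag$bandwidth_floor, ag$bandwidth_cap
  )
  expect_equal(as.vector(sc$pragmatic), bd$pragmatic, tolerance = 1e-8)
  expect_equal(as.vector(sc$epistemic), bd$epistemic, tolerance = 1e-8)
  expect_equal(sc$G[1], bd$G, tolerance = 1e-8)
})
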