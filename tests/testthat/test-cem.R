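# Cross-entropy-method planner.

test_that("refit recovers elite moments with the std floor", {
  pcfg <- planner_config(
    horizon = 4L, m_samples = 32L, cont_bounds = cbind(c(-2, 2))
  )
  # identical elites: mean = that sequence, std = floor
  seq1 <- matrix(0.7, 3, 4)
  el <- list(cont = array(rep(t(seq1), each = 1), dim = c(3, 4, 1)), disc = NULL)
  for (i in 1:3) el$cont[i, , 1] <- seq1[i, ]
  d <- refit(el, pcfg)
  expect_equal(as.vector(d$mean), rep(0.7, 4))
  expect_equal(as.vector(d$std), rep(pcfg$std_floor, 4))
  # population std of {-1, 0, 1}; all steps identical so row smoothing is
  # transparent
  el2 <- list(cont = array(0, dim = c(3, 4, 1)), disc = NULL)
  el2$cont[1, , 1] <- -1
  el2$cont[3, , 1] <- 1
  d2 <- refit(el2, pcfg)
  expect_equal(as.vector(d2$mean), rep(0, 4))
  expect_equal(as.vector(d2$std), rep(max(sqrt(2 / 3), pcfg$std_floor), 4),
    tolerance = 1e-9
  )
  expect_error(refit(list(cont = array(0, dim = c(1, 4, 1))), pcfg))
})

test_that("discrete refit uses clamped elite frequencies", {
  pcfg <- planner_config(
    horizon = 2L, m_samples = 70L, cont_bounds = cbind(c(-1, 1)),
    n_disc = 1L
  )
  el <- list(
    cont = array(0, dim = c(7, 2, 1)),
    disc = array(0, dim = c(7, 2, 1))
  )
  el$disc[1, , 1] <- 1 # 6 of 7 off-road
  d <- refit(el, pcfg)
  expect_equal(as.vector(d$p_disc_raw), rep(1 / 7, 2))
  expect_equal(as.vector(d$p_disc), rep(max(1 / 7, pcfg$prob_clamp), 2))
  # fully degenerate frequencies are clamped away from 0 and 1
  el$disc[, , 1] <- 1
  d1 <- refit(el, pcfg)
  expect_equal(as.vector(d1$p_disc), rep(1 - pcfg$prob_clamp, 2))
})

test_that("planned action approaches the grid-search optimum on a quadratic problem", {
  set.seed(31)
  e <- particle_ensemble(matrix(2, 4, 1)) # known state x = 2
  pcfg <- planner_config(
    horizon = 1L, m_samples = 64L, k_iters = 8L, elite_fraction = 0.1,
    n_planning = 4L, cont_bounds = cbind(c(-2, 2)), noise_rho = 0
  )
  scorer <- quadratic_scorer(x0 = 2, mu = 0.8, sigma = 0.5)
  # brute-force grid oracle over the action interval
  grid <- seq(-2, 2, by = 0.001)
  oracle <- grid[which.max(stats::dnorm(2 + grid, 0.8, 0.5, log = TRUE))]
  acts <- replicate(10, cem_plan(e, scorer, pcfg)$action$cont)
  expect_lt(abs(median(acts) - oracle), 0.1 * max(abs(oracle), 1))
})

test_that("median best-elite G is non-increasing across CEM iterations", {
  cfg1 <- occlusion_config()
  cfg2 <- timesharing_config()
  ag <- agent_config("test")
  for (scenario in 1:2) {
    best <- matrix(NA, 20, ag$k_iters)
    for (s in 1:20) {
      set.seed(s)
      if (scenario == 1) {
        e <- initialize_occlusion_belief(cfg1, 0.2, 64)
        cppcfg <- aidriver:::occlusion_cpp_cfg(cfg1, ag, FALSE)
        pcfg <- planner_config(
          horizon = 20L, m_samples = 32L, k_iters = ag$k_iters,
          n_planning = 16L, cont_bounds = cbind(c(-4, 2.5))
        )
        scorer <- function(p, cont, disc) {
          aidriver:::score_policies_cpp(p, cont, NULL, 1L, cppcfg)
        }
      } else {
        st <- aidriver:::timesharing_init_state(cfg2)[rep(1, 64), , drop = FALSE]
        st[, 2] <- stats::rnorm(64, 0, 0.1)
        e <- particle_ensemble(st)
        cppcfg <- aidriver:::timesharing_cpp_cfg(cfg2, ag)
        pcfg <- planner_config(
          horizon = 20L, m_samples = 32L, k_iters = ag$k_iters,
          n_planning = 16L, cont_bounds = cbind(c(-4, 2.5), c(-0.5, 0.5)),
          n_disc = 1L
        )
        noise <- stats::rnorm(16 * 20) # one disturbance draw per plan
        scorer <- function(p, cont, disc) {
          aidriver:::score_policies_cpp(p, cont, disc, 2L, cppcfg, noise)
        }
      }
      best[s, ] <- cem_plan(e, scorer, pcfg)$diagnostics$best_g
    }
    med <- apply(best, 2, median)
    expect_true(all(diff(med) <= 1e-9))
  }
})

test_that("action bounds are respected in every returned action", {
  set.seed(32)
  e <- particle_ensemble(matrix(0, 4, 1))
  pcfg <- planner_config(
    horizon = 3L, m_samples = 32L, k_iters = 2L, n_planning = 4L,
    cont_bounds = cbind(c(-0.3, 0.2)), n_disc = 1L
  )
  seen <- new.env()
  seen$lo <- Inf
  seen$hi <- -Inf
  scorer <- function(p, cont, disc) {
    seen$lo <- min(seen$lo, cont)
    seen$hi <- max(seen$hi, cont)
    m <- dim(cont)[1]
    list(G = stats::runif(m), pragmatic = matrix(0, m, 3),
      epistemic = matrix(0, m, 3))
  }
  for (i in 1:10) {
    a <- cem_plan(e, scorer, pcfg)$action
    expect_gte(a$cont, -0.3)
    expect_lte(a$cont, 0.2)
    expect_true(a$disc %in% c(0L, 1L))
  }
  expect_gte(seen$lo, -0.3)
  expect_lte(seen$hi, 0.2)
})

test_that("identically scoring policies trigger the degenerate-plan warning", {
  set.seed(33)
  e <- particle_ensemble(matrix(0, 4, 1))
  pcfg <- planner_config(
    horizon = 2L, m_samples = 32L, k_iters = 2L, n_planning = 4L,
    cont_bounds = cbind(c(-1, 1))
  )
  scorer <- function(p, cont, disc) {
    m <- dim(cont)[1]
    list(G = rep(5, m), pragmatic = matrix(0, m, 2), epistemic = matrix(0, m, 2))
  }
  expect_warning(cem_plan(e, scorer, pcfg), "identically")
})

test_that("with epistemic value off and a certain belief the planner tracks the speed prior", {
  # open straight road: a very wide lane removes boundary effects
  cfg <- timesharing_config(lane_width = 30, log_p_on = 0, sigma_w = 0)
  ag <- agent_config("test", use_epistemic = FALSE)
  tr <- run_quiet(run_timesharing_simulation(cfg, ag, seed = 1))
  settled <- tr$v[tr$t > 20]
  expect_lt(abs(mean(settled) - cfg$speed_mu) / cfg$speed_mu, 0.02)
})
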