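# Scenario 2: visual time-sharing between lane keeping and a secondary task.
# A kinematic bicycle model keeps lane on a straight road; a small stochastic
# steering disturbance makes the lateral position drift. The driver chooses,
# alongside acceleration and steering rate, a binary gaze action. During
# off-road glances the positional observations (x, y, heading) are nulled and
# belief dispersion grows by process-noise propagation; lane-crossing flags
# remain observable (rumble strips). An on-road glance resets the dispersion
# within a single step.
#
# State / observation layout (columns): x, y, theta, delta, v, a, w,
# gaze (0 off-road / 1 on-road), Cl, Cr.

TS_EPI_DIMS <- c(1L, 2L, 3L) # x, y, theta observations

#' Time-sharing scenario configuration
#'
#' @param lane_width Lane width (m); default 3, narrow condition 2.5.
#' @param wheelbase Bicycle-model wheelbase L (m).
#' @param sigma_w Steering-rate disturbance, sd of the zero-mean Gaussian
#'   noise added to the steering rate each step (rad/s). The same noise is
#'   used in the agent's rollouts (generative model matches the process).
#' @param dt Timestep (s).
#' @param episode_s Episode length (s).
#' @param log_p_on Gaze preference: log probability of an on-road glance
#'   (0 = baseline with no secondary task, -7 default, more negative =
#'   stronger secondary-task motivation).
#' @param speed_mu,speed_sigma Speed prior (m/s); the scale controls how much
#'   speed may be sacrificed for secondary-task time.
#' @param accel_sigma Longitudinal-acceleration prior scale (m/s^2).
#' @param steer_sigma Steering-rate prior scale (rad/s). The default 0.1
#'   penalizes idle steering activity strongly enough that planned steering
#'   converges on small corrective inputs, while deliberate corrections
#'   remain affordable.
#' @param delta_max Steering-angle limit (rad).
#' @param init_speed Initial speed (m/s).
#' @return Named list.
#' @export
timesharing_config <- function(lane_width = 3, wheelbase = 2.7,
                               sigma_w = 0.001, dt = 0.2, episode_s = 30,
                               log_p_on = -7, speed_mu = 10, speed_sigma = 2,
                               accel_sigma = 2, steer_sigma = 0.1,
                               delta_max = 0.5, init_speed = 10) {
  stopifnot(lane_width > 0, sigma_w >= 0, log_p_on <= 0)
  list(
    lane_width = lane_width, lane_half_width = lane_width / 2,
    wheelbase = wheelbase, sigma_w = sigma_w, dt = dt,
    episode_s = episode_s, log_p_on = log_p_on, speed_mu = speed_mu,
    speed_sigma = speed_sigma, accel_sigma = accel_sigma,
    steer_sigma = steer_sigma, delta_max = delta_max, init_speed = init_speed
  )
}

#' One kinematic bicycle step
#'
#' Steering angle integrates the commanded steering rate plus the Gaussian
#' disturbance; heading, position and speed follow in sequence (speed floored
#' at 0, steering angle clamped at `delta_max`).
#'
#' @param state Ego vector `c(x, y, theta, delta, v, a, w)`.
#' @param action `c(a, w)`: acceleration (m/s^2) and steering rate (rad/s).
#' @param dt Timestep (s), > 0.
#' @param sigma_w Steering disturbance sd (rad/s); 0 for a noise-free step.
#' @param wheelbase Wheelbase L (m).
#' @param delta_max Steering-angle limit (rad).
#' @return Updated ego vector.
#' @export
bicycle_step <- function(state, action, dt, sigma_w = 0, wheelbase = 2.7,
                         delta_max = 0.5) {
  stopifnot(dt > 0)
  eta <- if (sigma_w > 0) stats::rnorm(1, 0, sigma_w) else 0
  delta <- min(max(state[4] + (action[2] + eta) * dt, -delta_max), delta_max)
  theta <- state[3] + state[5] / wheelbase * tan(delta) * dt
  x <- state[1] + state[5] * cos(theta) * dt
  y <- state[2] + state[5] * sin(theta) * dt
  v <- max(0, state[5] + action[1] * dt)
  c(x, y, theta, delta, v, action[1], action[2])
}

#' Deterministic gaze transition
#'
#' The gaze action sets the gaze state directly.
#'
#' @param gaze Current gaze (ignored; transitions are deterministic).
#' @param gaze_action Commanded gaze (0 off-road, 1 on-road).
#' @return New gaze state.
#' @export
gaze_transition <- function(gaze, gaze_action) {
  gaze_action
}

# Vectorized transition over a particle matrix; action = c(a, w, gaze).
timesharing_transition <- function(config) {
  dt <- config$dt
  hw <- config$lane_half_width
  function(states, action) {
    s <- states
    n <- nrow(s)
    eta <- if (config$sigma_w > 0) stats::rnorm(n, 0, config$sigma_w) else 0
    s[, 4] <- pmin(pmax(s[, 4] + (action[2] + eta) * dt, -config$delta_max),
      config$delta_max
    )
    s[, 3] <- s[, 3] + s[, 5] / config$wheelbase * tan(s[, 4]) * dt
    s[, 1] <- s[, 1] + s[, 5] * cos(s[, 3]) * dt
    s[, 2] <- s[, 2] + s[, 5] * sin(s[, 3]) * dt
    s[, 5] <- pmax(0, s[, 5] + action[1] * dt)
    s[, 6] <- action[1]
    s[, 7] <- action[2]
    s[, 8] <- gaze_transition(s[, 8], action[3])
    s[, 9] <- as.numeric(s[, 2] > hw)
    s[, 10] <- as.numeric(s[, 2] < -hw)
    s
  }
}

#' Time-sharing observation map
#'
#' On-road glances observe the full state exactly; off-road glances null the
#' longitudinal and lateral position and the heading angle. Steering angle,
#' speed, control inputs, gaze and the lane-crossing flags (rumble strips)
#' are always observable.
#'
#' @param states Particle (or true-state) matrix.
#' @param config A [timesharing_config()].
#' @return Observation matrix with the same layout.
#' @export
observe_timesharing <- function(states, config) {
  o <- states
  off <- states[, 8] < 0.5
  o[off, 1] <- -1000
  o[off, 2] <- -1000
  o[off, 3] <- -1000
  o
}

timesharing_observation_model <- function(config, sigma_obs,
                                           sigma_reset = KDE_BANDWIDTH_FLOOR) {
  # x, y, theta reset at the epistemic resolution floor when observed;
  # delta, v, a, w are sensed coarsely (the steering disturbance realization
  # is never resolved, so positional uncertainty keeps building off-road)
  widths <- c(rep(sigma_reset, 3), rep(sigma_obs, 4), rep(NA, 3))
  list(
    observe = function(states) observe_timesharing(states, config),
    loglik = function(observation, states) {
      pred <- observe_timesharing(states, config)
      kernel_loglik(observation, pred,
        cont_dims = 1:7, disc_dims = 8:10, sigma_obs = widths
      )
    },
    mask = function(states, action) {
      on <- states[1, 8] > 0.5 # gaze is shared across particles
      c(on, on, on, rep(TRUE, 7))
    }
  )
}

timesharing_preferences <- function(config) {
  preference_model(
    lane = pref_triangular(2, 0, -config$lane_half_width,
      config$lane_half_width
    ),
    speed = pref_gaussian(5, config$speed_mu, config$speed_sigma),
    accel = pref_gaussian(6, 0, config$accel_sigma),
    steer = pref_gaussian(7, 0, config$steer_sigma),
    gaze = pref_bernoulli_gaze(8, config$log_p_on),
    exit_left = pref_categorical(9),
    exit_right = pref_categorical(10)
  )
}

timesharing_init_state <- function(config) {
  matrix(c(0, 0, 0, 0, config$init_speed, 0, 0, 1, 0, 0), nrow = 1)
}

timesharing_cpp_cfg <- function(config, agent) {
  list(
    dt = config$dt, bandwidth_floor = agent$bandwidth_floor,
    bandwidth_cap = agent$bandwidth_cap,
    log_floor = LOG_FLOOR, speed_mu = config$speed_mu,
    speed_sigma = config$speed_sigma, accel_sigma = config$accel_sigma,
    lane_half_width = config$lane_half_width, wheelbase = config$wheelbase,
    sigma_w = config$sigma_w, delta_max = config$delta_max,
    steer_sigma = config$steer_sigma, log_p_on = config$log_p_on
  )
}

#' Run one closed-loop visual time-sharing simulation
#'
#' Loop per timestep: plan (acceleration, steering rate and gaze jointly by
#' CEM over expected free energy), execute in the true environment (which
#' adds the steering disturbance), observe, update the belief, record.
#' During on-road steps the belief over position collapses to the observed
#' value within the step; during off-road steps the lateral-position
#' dispersion sigma(b_y) grows by process-noise propagation.
#'
#' @param config A [timesharing_config()].
#' @param agent An [agent_config()].
#' @param seed Integer seed.
#' @return A data.frame trace: `t, x, y, theta, delta, v, a, w, gaze, Cl,
#'   Cr, sigma_by, pragmatic, epistemic, G`.
#' @export
run_timesharing_simulation <- function(config = timesharing_config(),
                                       agent = agent_config(), seed = 1L) {
  set.seed(seed)
  steps <- round(config$episode_s / config$dt)
  transition <- timesharing_transition(config)
  obs_model <- timesharing_observation_model(config, agent$sigma_obs,
    sigma_reset = agent$bandwidth_floor
  )

  init <- timesharing_init_state(config)
  belief <- particle_ensemble(
    init[rep(1, agent$n_particles), , drop = FALSE]
  )

  pcfg <- planner_config(
    horizon = agent$horizon, m_samples = agent$m_samples,
    k_iters = agent$k_iters, elite_fraction = agent$elite_fraction,
    n_planning = agent$n_planning,
    cont_bounds = cbind(c(-4, 2.5), c(-0.5, 0.5)), n_disc = 1L,
    std_floor = agent$std_floor, prob_clamp = agent$prob_clamp,
    noise_rho = agent$noise_rho, action_selection = agent$action_selection,
    smoothing = agent$smoothing
  )
  cppcfg <- timesharing_cpp_cfg(config, agent)
  make_scorer <- function(noise) {
    function(particles, cont, disc) {
      sc <- score_policies_cpp(particles, cont, disc, 2L, cppcfg, noise)
      if (!agent$use_epistemic) {
        sc$G <- sc$G + rowSums(sc$epistemic)
        sc$epistemic[] <- 0
      }
      sc
    }
  }

  truth <- init
  out <- vector("list", steps)
  warm <- NULL
  for (k in seq_len(steps)) {
    # one disturbance realization per planning step: retained elites stay
    # comparable across CEM iterations
    noise <- stats::rnorm(agent$n_planning * agent$horizon)
    pl <- cem_plan(belief, make_scorer(noise), pcfg, init_dist = warm)
    if (agent$warm_start) {
      warm <- shift_action_distribution(pl$diagnostics$final_dist, pcfg)
    }
    a <- c(pl$action$cont, pl$action$disc)
    truth <- transition(truth, a)
    obs <- obs_model$observe(truth)[1, ]
    belief <- sir_update(belief, a, obs, transition, obs_model)
    bd <- pl$diagnostics$breakdown
    out[[k]] <- data.frame(
      t = k * config$dt,
      x = truth[1, 1], y = truth[1, 2], theta = truth[1, 3],
      delta = truth[1, 4], v = truth[1, 5], a = truth[1, 6],
      w = truth[1, 7], gaze = truth[1, 8],
      Cl = truth[1, 9], Cr = truth[1, 10],
      sigma_by = belief_moments(belief, 2)[["sd"]],
      pragmatic = sum(bd$pragmatic), epistemic = sum(bd$epistemic),
      G = bd$G
    )
  }
  trace <- do.call(rbind, out)
  attr(trace, "meta") <- list(
    scenario = "timesharing", seed = seed, dt = config$dt,
    lane_width = config$lane_width, log_p_on = config$log_p_on
  )
  trace
}

#' Single-step value curves for on-road vs off-road glances
#'
#' Reproduces the glance-decision analysis: artificial belief particles with
#' growing lateral-position dispersion are generated by propagating a
#' collapsed belief through the off-road generative model (so heading and
#' position disperse jointly along the actual drift manifold, exactly as they
#' do during an off-road glance), and at each dispersion level the one-step
#' pragmatic and epistemic value of an on-road vs an off-road glance is
#' evaluated. For export, absolute-preference log probabilities are truncated
#' at -100 so the decision-relevant structure remains visible.
#'
#' @param dispersion_grid Strictly increasing sigma(b_y) values (m).
#' @param gaze_pref Gaze preference `log_p_on` to evaluate.
#' @param config A [timesharing_config()] (its `log_p_on` is ignored in
#'   favour of `gaze_pref`).
#' @param agent An [agent_config()].
#' @param n_particles Artificial ensemble size.
#' @param max_steps Cap on drift propagation steps.
#' @param export_floor Truncation for absolute preferences in the exported
#'   values.
#' @return List with `table` (one row per grid sigma: pragmatic, epistemic
#'   and total value for gaze on and off) and `crossover`, the smallest grid
#'   sigma whose total on-road value exceeds the off-road value (NA if the
#'   curves never cross on the grid).
#' @export
value_curves <- function(dispersion_grid, gaze_pref,
                         config = timesharing_config(),
                         agent = agent_config(), n_particles = 512L,
                         max_steps = 2000L, export_floor = -100) {
  stopifnot(all(diff(dispersion_grid) > 0))
  cfg <- config
  cfg$log_p_on <- gaze_pref
  hw <- cfg$lane_half_width
  transition <- timesharing_transition(cfg)
  states <- timesharing_init_state(cfg)[rep(1, n_particles), , drop = FALSE]

  eval_at <- function(states, sigma) {
    on_obs <- states
    on_obs[, 8] <- 1
    off_obs <- states
    off_obs[, 8] <- 0
    off_obs[, 1:3] <- -1000
    shared <- gaussian_logpdf(states[, 5], cfg$speed_mu, cfg$speed_sigma) +
      gaussian_logpdf(states[, 6], 0, cfg$accel_sigma) +
      gaussian_logpdf(states[, 7], 0, cfg$steer_sigma) +
      categorical_logprob(states[, 9] > 0.5, export_floor) +
      categorical_logprob(states[, 10] > 0.5, export_floor)
    prag_on <- mean(shared + gaze_pref +
      triangular_logpdf(states[, 2], 0, -hw, hw, floor = export_floor))
    prag_off <- mean(shared +
      bernoulli_gaze_logprob(rep(0, nrow(states)), gaze_pref,
        floor = export_floor
      ))
    epi_on <- epistemic_value(on_obs, TS_EPI_DIMS, agent$bandwidth_floor,
      agent$bandwidth_cap
    )
    epi_off <- epistemic_value(off_obs, TS_EPI_DIMS, agent$bandwidth_floor,
      agent$bandwidth_cap
    )
    data.frame(
      sigma = sigma, pragmatic_on = prag_on, pragmatic_off = prag_off,
      epistemic_on = epi_on, epistemic_off = epi_off,
      total_on = prag_on + epi_on, total_off = prag_off + epi_off
    )
  }

  rows <- vector("list", length(dispersion_grid))
  g <- 1L
  for (k in seq_len(max_steps)) {
    if (g > length(dispersion_grid)) break
    states <- transition(states, c(0, 0, 0))
    while (g <= length(dispersion_grid) &&
      stats::sd(states[, 2]) >= dispersion_grid[g]) {
      rows[[g]] <- eval_at(states, dispersion_grid[g])
      g <- g + 1L
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  crossover <- NA_real_
  if (!is.null(tab)) {
    hit <- which(tab$total_on > tab$total_off)
    if (length(hit)) crossover <- tab$sigma[min(hit)]
  }
  list(table = tab, crossover = crossover)
}
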