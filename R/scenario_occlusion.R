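# Scenario 1: passing an occluding object that may hide a pedestrian.
# The ego vehicle is a point mass on a straight lane. A pedestrian may be
# present at a fixed site beyond an occluding object; if present it is
# assumed to step into the ego's path, so a conflict occurs whenever the
# longitudinal gap falls below a safe distance. The pedestrian site is hidden
# until the ego crosses the line of sight through the occluder's corner;
# until then the pedestrian-position observation is the null code and the
# belief over presence is not updated.
#
# State / observation layout (columns): x, v_x, a_x, y, v_y, a_y,
# I (present), ped_x, ped_y, C (conflict or lane exit). Observation column 7
# is o_I (1 = not observed, 2 = observed).

OCC_EPI_DIMS <- c(7L, 8L, 9L) # o_I and the pedestrian-position observation

#' Occlusion scenario configuration
#'
#' Geometry and physical parameters. The sight corner and pedestrian site are
#' a canonical calibration: with the ego starting 28 m upstream of the corner
#' the straight-ahead line of sight is reached at x = 22 m, which a
#' belief-slowed approach reaches around t = 3 s.
#'
#' @param lane_half_width Half lane width (m); lane is centred at y = 0.
#' @param speed_limit Preferred speed (m/s), mode of the speed prior.
#' @param speed_sigma Speed-prior scale (m/s).
#' @param accel_sigma Acceleration-prior scale (m/s^2), x and y.
#' @param corner Sight corner (x, y) of the occluding object (m).
#' @param ped_site Pedestrian site (x, y) (m), beyond the corner.
#' @param safe_distance Longitudinal conflict distance (m).
#' @param p_present Prior probability that the pedestrian is present.
#' @param dt Simulation timestep (s).
#' @param episode_s Episode length (s).
#' @param init_speed Initial ego speed (m/s).
#' @return Named list.
#' @export
occlusion_config <- function(lane_half_width = 1.5, speed_limit = 10,
                             speed_sigma = 1, accel_sigma = 2,
                             corner = c(28, -1.8), ped_site = c(32, -3),
                             safe_distance = 2, p_present = 0.2, dt = 0.2,
                             episode_s = 10, init_speed = 10) {
  stopifnot(
    corner[2] < -lane_half_width, ped_site[1] > corner[1], safe_distance > 0,
    p_present >= 0, p_present <= 1
  )
  list(
    lane_half_width = lane_half_width, speed_limit = speed_limit,
    speed_sigma = speed_sigma, accel_sigma = accel_sigma,
    corner = corner, ped_site = ped_site, safe_distance = safe_distance,
    p_present = p_present, dt = dt, episode_s = episode_s,
    init_speed = init_speed
  )
}

#' One point-mass kinematic step
#'
#' Position advances with the current velocity, then velocity is updated with
#' the commanded acceleration (longitudinal speed floored at 0); the stored
#' acceleration is the commanded action.
#'
#' @param ego Ego state vector `c(x, v_x, a_x, y, v_y, a_y)`.
#' @param action `c(a_x, a_y)` (m/s^2).
#' @param dt Timestep (s), > 0.
#' @return Updated ego state vector.
#' @export
point_mass_step <- function(ego, action, dt) {
  stopifnot(dt > 0)
  c(
    ego[1] + ego[2] * dt,
    max(0, ego[2] + action[1] * dt),
    action[1],
    ego[4] + ego[5] * dt,
    ego[5] + action[2] * dt,
    action[2]
  )
}

#' Line-of-sight visibility of the pedestrian site
#'
#' The pedestrian site is occluded while it lies on the far side of the ray
#' from the ego through the occluder's corner; visibility is the sign of the
#' planar cross product (ties count as visible).
#'
#' @param ego_xy Ego position `c(x, y)`.
#' @param corner_xy Occluder corner `c(x, y)`.
#' @param ped_xy Pedestrian site `c(x, y)`.
#' @return `TRUE` if the site is visible.
#' @export
is_visible <- function(ego_xy, corner_xy, ped_xy) {
  cross <- (corner_xy[1] - ego_xy[1]) * (ped_xy[2] - ego_xy[2]) -
    (corner_xy[2] - ego_xy[2]) * (ped_xy[1] - ego_xy[1])
  cross >= 0
}

#' Conflict / lane-exit flag
#'
#' A conflict occurs when the pedestrian is present and the longitudinal gap
#' is below the safe distance, or when the vehicle exits the lane.
#'
#' @param ego_x,ego_y Ego position (m).
#' @param ped_x Pedestrian longitudinal position (m).
#' @param present Logical, pedestrian present.
#' @param safe_distance Safe longitudinal distance (m).
#' @param lane_half_width Lane half width (m).
#' @return Logical flag.
#' @export
detect_conflict <- function(ego_x, ego_y, ped_x, present, safe_distance,
                            lane_half_width) {
  (present & abs(ego_x - ped_x) < safe_distance) |
    (abs(ego_y) > lane_half_width)
}

# Vectorized transition over a particle matrix (also steps the true state).
occlusion_transition <- function(config) {
  dt <- config$dt
  function(states, action) {
    s <- states
    s[, 1] <- s[, 1] + s[, 2] * dt
    s[, 4] <- s[, 4] + s[, 5] * dt
    s[, 2] <- pmax(0, s[, 2] + action[1] * dt)
    s[, 5] <- s[, 5] + action[2] * dt
    s[, 3] <- action[1]
    s[, 6] <- action[2]
    # conflict is absorbing: a conflict that has occurred along a predicted
    # trajectory stays on the trajectory (a collision does not un-happen)
    s[, 10] <- pmax(s[, 10], as.numeric(detect_conflict(
      s[, 1], s[, 4], s[, 8], s[, 7] > 0.5,
      config$safe_distance, config$lane_half_width
    )))
    s
  }
}

#' Occlusion observation map
#'
#' Ego kinematics are copied exactly. When the ego has line of sight the
#' context observation is "observed" (2) and the pedestrian-position
#' observation equals the true value (which is the null code -1000 when the
#' pedestrian is absent); otherwise the context observation is
#' "not observed" (1) and the position observation is the null code.
#'
#' @param states Particle (or true-state) matrix.
#' @param config An [occlusion_config()].
#' @return Observation matrix with the same layout.
#' @export
observe_occlusion <- function(states, config) {
  o <- states
  cross <- (config$corner[1] - states[, 1]) * (config$ped_site[2] - states[, 4]) -
    (config$corner[2] - states[, 4]) * (config$ped_site[1] - states[, 1])
  vis <- cross >= 0
  o[, 7] <- ifelse(vis, 2, 1)
  o[, 8] <- ifelse(vis, states[, 8], -1000)
  o[, 9] <- ifelse(vis, states[, 9], -1000)
  o
}

occlusion_observation_model <- function(config, sigma_obs) {
  # every observable dimension is seen exactly in this scenario; the narrow
  # kernel only smooths the 0/1 likelihood of the deterministic map
  list(
    observe = function(states) observe_occlusion(states, config),
    loglik = function(observation, states) {
      pred <- observe_occlusion(states, config)
      kernel_loglik(observation, pred,
        cont_dims = c(1:6, 8, 9), disc_dims = c(7, 10),
        sigma_obs = sigma_obs
      )
    },
    mask = NULL # all preference dimensions observable in this scenario
  )
}

occlusion_preferences <- function(config, lateral_enabled) {
  prefs <- list(
    speed = pref_gaussian(2, config$speed_limit, config$speed_sigma),
    accel_x = pref_gaussian(3, 0, config$accel_sigma),
    accel_y = pref_gaussian(6, 0, config$accel_sigma),
    conflict = pref_categorical(10)
  )
  if (lateral_enabled) {
    prefs$lane <- pref_triangular(
      4, 0, -config$lane_half_width, config$lane_half_width
    )
  }
  do.call(preference_model, prefs)
}

#' Initialize the occlusion belief
#'
#' Ego kinematics are known exactly; the pedestrian-presence indicator is
#' drawn i.i.d. from the prior, with the pedestrian at the configured site
#' when present and at the null code when absent.
#'
#' @param config An [occlusion_config()].
#' @param p_present Prior presence probability.
#' @param n_particles Ensemble size.
#' @return A [particle_ensemble()].
#' @export
initialize_occlusion_belief <- function(config, p_present, n_particles) {
  ego <- c(0, config$init_speed, 0, 0, 0, 0)
  initialize_belief(function(n) {
    present <- stats::runif(n) < p_present
    cbind(
      matrix(ego, n, 6, byrow = TRUE),
      as.numeric(present),
      ifelse(present, config$ped_site[1], -1000),
      ifelse(present, config$ped_site[2], -1000),
      0
    )
  }, n_particles)
}

occlusion_cpp_cfg <- function(config, agent, lateral_enabled) {
  list(
    dt = config$dt, bandwidth_floor = agent$bandwidth_floor,
    bandwidth_cap = agent$bandwidth_cap,
    log_floor = LOG_FLOOR, speed_mu = config$speed_limit,
    speed_sigma = config$speed_sigma, accel_sigma = config$accel_sigma,
    lane_half_width = config$lane_half_width,
    corner_x = config$corner[1], corner_y = config$corner[2],
    ped_x = config$ped_site[1], ped_y = config$ped_site[2],
    safe_distance = config$safe_distance, lateral_enabled = lateral_enabled
  )
}

#' Run one closed-loop occlusion simulation
#'
#' Variants: `"1a"` (20% presence prior, straight only), `"1b"` (0% prior,
#' straight only), `"1c"` (20% prior, lateral action enabled), `"1d"` (0%
#' prior, lateral enabled). The true environment never contains a pedestrian;
#' the variants differ only in the agent's prior belief and action space.
#'
#' Loop per timestep: plan by CEM over expected free energy, execute the
#' first action in the true environment, observe, update the belief by SIR
#' filtering, record.
#'
#' @param config An [occlusion_config()].
#' @param agent An [agent_config()].
#' @param variant One of `"1a"`, `"1b"`, `"1c"`, `"1d"`.
#' @param seed Integer seed; the run is fully reproducible from
#'   (config, agent, variant, seed).
#' @return A data.frame trace with one row per timestep: `t`, ego kinematics,
#'   `o_I`, posterior `p_present`, belief dispersion `sigma_by`, and the
#'   selected policy's summed `pragmatic`, `epistemic` and `G`.
#' @export
run_occlusion_simulation <- function(config = occlusion_config(),
                                     agent = agent_config(),
                                     variant = c("1a", "1b", "1c", "1d"),
                                     seed = 1L) {
  variant <- match.arg(variant)
  set.seed(seed)
  lateral <- variant %in% c("1c", "1d")
  p_present <- if (variant %in% c("1a", "1c")) config$p_present else 0
  steps <- round(config$episode_s / config$dt)

  transition <- occlusion_transition(config)
  obs_model <- occlusion_observation_model(config, agent$sigma_obs)
  belief <- initialize_occlusion_belief(config, p_present, agent$n_particles)

  bounds <- if (lateral) cbind(c(-4, 2.5), c(-2, 2)) else cbind(c(-4, 2.5))
  pcfg <- planner_config(
    horizon = agent$horizon, m_samples = agent$m_samples,
    k_iters = agent$k_iters, elite_fraction = agent$elite_fraction,
    n_planning = agent$n_planning, cont_bounds = bounds, n_disc = 0L,
    std_floor = agent$std_floor, prob_clamp = agent$prob_clamp,
    noise_rho = agent$noise_rho, action_selection = agent$action_selection,
    smoothing = agent$smoothing
  )
  cppcfg <- occlusion_cpp_cfg(config, agent, lateral)
  scorer <- function(particles, cont, disc) {
    sc <- score_policies_cpp(particles, cont, NULL, 1L, cppcfg)
    if (!agent$use_epistemic) {
      sc$G <- sc$G + rowSums(sc$epistemic)
      sc$epistemic[] <- 0
    }
    sc
  }

  truth <- matrix(c(0, config$init_speed, 0, 0, 0, 0, 0, -1000, -1000, 0),
    nrow = 1
  )
  out <- vector("list", steps)
  warm <- NULL
  for (k in seq_len(steps)) {
    pl <- cem_plan(belief, scorer, pcfg, init_dist = warm)
    if (agent$warm_start) {
      warm <- shift_action_distribution(pl$diagnostics$final_dist, pcfg)
    }
    a <- if (lateral) pl$action$cont else c(pl$action$cont, 0)
    truth <- transition(truth, a)
    obs <- obs_model$observe(truth)[1, ]
    belief <- sir_update(belief, a, obs, transition, obs_model)
    bd <- pl$diagnostics$breakdown
    out[[k]] <- data.frame(
      t = k * config$dt,
      x = truth[1, 1], y = truth[1, 4],
      v_x = truth[1, 2], v_y = truth[1, 5],
      a_x = truth[1, 3], a_y = truth[1, 6],
      o_I = obs[7],
      conflict = truth[1, 10],
      p_present = sum(belief$weights * (belief$states[, 7] > 0.5)),
      sigma_by = belief_moments(belief, 4)[["sd"]],
      pragmatic = sum(bd$pragmatic), epistemic = sum(bd$epistemic),
      G = bd$G
    )
  }
  trace <- do.call(rbind, out)
  attr(trace, "meta") <- list(
    scenario = "occlusion", variant = variant, seed = seed, dt = config$dt,
    p_prior = p_present
  )
  trace
}

#' Epistemic saliency map over ego positions
#'
#' Fixes the belief over pedestrian presence at `fixed_belief_p`, places a
#' stationary ego at each grid position, and scores the epistemic value of
#' observing from that pose, summed over the planning horizon under a
#' zero-action policy (for a stationary ego every lookahead step contributes
#' the same value). Positions beyond the line of sight see diverse
#' pedestrian-position observations across belief particles and score high;
#' occluded positions see only the null code and score the baseline.
#'
#' @param y_grid,x_grid Grid coordinates (m).
#' @param fixed_belief_p Fixed presence probability in (0, 1), or 0/1 for the
#'   degenerate map.
#' @param config An [occlusion_config()].
#' @param agent An [agent_config()] (horizon and bandwidth floor are used).
#' @param n_particles Belief particles per position (presence counts are set
#'   deterministically to `round(p * n)` so the map itself is deterministic).
#' @return Matrix of epistemic values, `length(y_grid)` rows by
#'   `length(x_grid)` columns.
#' @export
epistemic_saliency_map <- function(y_grid, x_grid, fixed_belief_p,
                                   config = occlusion_config(),
                                   agent = agent_config(),
                                   n_particles = 128L) {
  n_pres <- round(fixed_belief_p * n_particles)
  present <- c(rep(1, n_pres), rep(0, n_particles - n_pres))
  ped_x <- ifelse(present > 0, config$ped_site[1], -1000)
  ped_y <- ifelse(present > 0, config$ped_site[2], -1000)
  out <- matrix(0, length(y_grid), length(x_grid))
  for (i in seq_along(y_grid)) {
    for (j in seq_along(x_grid)) {
      vis <- is_visible(
        c(x_grid[j], y_grid[i]), config$corner, config$ped_site
      )
      obs <- cbind(
        o_I = rep(if (vis) 2 else 1, n_particles),
        ped_x = if (vis) ped_x else rep(-1000, n_particles),
        ped_y = if (vis) ped_y else rep(-1000, n_particles)
      )
      out[i, j] <- agent$horizon *
        epistemic_value(obs, 1:3, agent$bandwidth_floor, agent$bandwidth_cap)
    }
  }
  out
}
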