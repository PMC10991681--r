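# Cross-entropy-method model predictive control over mixed
# discrete/continuous action sequences scored by expected free energy.
# Each timestep: draw a planning subset of belief particles by weight, then
# iteratively (i) sample a batch of policies from the current action-sequence
# distribution (temporally correlated noise; the batch always contains the
# distribution mode and the best policy found so far), (ii) score each
# policy's expected free energy, (iii) keep the lowest-G elite fraction and
# refit the distribution -- Gaussian moments for continuous dimensions and
# Bernoulli frequencies for discrete dimensions, fitted separately, with
# smoothed spread updates. The executed action defaults to the first action
# of the best policy; between timesteps the distribution can be warm-started
# by shifting it one step (see shift_action_distribution).

#' Planner configuration
#'
#' @param horizon Policy length H (steps). Default 20 (4 s at 0.2 s steps).
#' @param m_samples Policies sampled per CEM iteration.
#' @param k_iters CEM iterations per timestep.
#' @param elite_fraction Fraction r of lowest-G policies refit per iteration
#'   (elite count `ceiling(m_samples * r)`, must be >= 2).
#' @param n_planning Number of particles drawn from the belief for planning.
#' @param cont_bounds 2 x n_cont matrix; row 1 lower, row 2 upper bounds for
#'   each continuous action dimension.
#' @param n_disc Number of binary discrete action dimensions (0 or 1 here).
#' @param std_floor Lower bound on the refit standard deviations.
#' @param prob_clamp Epsilon keeping discrete probabilities in
#'   `[eps, 1 - eps]`.
#' @param noise_rho Temporal AR(1) correlation of the sampled continuous
#'   action noise. Correlated (colored) noise proposes sustained manoeuvres
#'   (a braking ramp, a lateral arc) far more often than white noise while
#'   leaving the per-step marginals of the action distribution unchanged.
#' @param smoothing Weight of the freshly fitted elite standard deviations
#'   and discrete probabilities in the distribution update (1 = replace,
#'   smaller = slower variance shrink). The mean always tracks the elites;
#'   smoothing only the spread keeps exploration alive across iterations so
#'   the search does not freeze on first-iteration elite noise.
#' @param action_selection `"best"` executes the first action of the
#'   lowest-G policy found in the final iteration; `"sample"` draws the
#'   executed action from the final distribution's step-1 marginals.
#'   Marginal sampling discards the within-policy temporal correlation (a
#'   sampled first action loses the later steps that would have compensated
#'   it), which at small sampling budgets injects substantial uncompensated
#'   control noise; executing the best policy's first action keeps the
#'   action consistent with its own planned continuation. `"mean"` executes
#'   the final distribution's step-1 mean (discrete dims by majority), the
#'   lowest-noise conventional MPC choice.
#' @return A `planner_config` list.
#' @export
planner_config <- function(horizon = 20L, m_samples = 64L, k_iters = 3L,
                           elite_fraction = 0.1, n_planning = 32L,
                           cont_bounds, n_disc = 0L, std_floor = 0.002,
                           prob_clamp = 0.02, noise_rho = 0.8,
                           smoothing = 0.5,
                           action_selection = c("best", "sample", "mean")) {
  cont_bounds <- as.matrix(cont_bounds)
  stopifnot(
    nrow(cont_bounds) == 2, all(is.finite(cont_bounds)),
    all(cont_bounds[1, ] < cont_bounds[2, ]),
    elite_fraction > 0, elite_fraction < 1,
    ceiling(m_samples * elite_fraction) >= 2
  )
  list(
    horizon = as.integer(horizon), m_samples = as.integer(m_samples),
    k_iters = as.integer(k_iters), elite_fraction = elite_fraction,
    n_planning = as.integer(n_planning), cont_bounds = cont_bounds,
    n_disc = as.integer(n_disc), std_floor = std_floor,
    prob_clamp = prob_clamp, noise_rho = noise_rho, smoothing = smoothing,
    action_selection = match.arg(action_selection)
  )
}

# Initial action distribution: zero-mean Gaussian with std = half the bound
# range per continuous dimension, p = 0.5 per discrete dimension.
init_action_distribution <- function(config) {
  nc <- ncol(config$cont_bounds)
  h <- config$horizon
  list(
    mean = matrix(0, h, nc),
    std = matrix(rep((config$cont_bounds[2, ] - config$cont_bounds[1, ]) / 4,
      each = h
    ), h, nc),
    p_disc = if (config$n_disc > 0) matrix(0.5, h, config$n_disc) else NULL
  )
}

#' Shift an action distribution one timestep forward
#'
#' Warm start for receding-horizon planning: the marginals for steps
#' 2..H seed steps 1..H-1 of the next plan, the last step reverts to the
#' cold-start prior, and the standard deviations are re-inflated to at least
#' a fraction of the cold-start exploration so the planner keeps exploring.
#' Warm starting gives the planner temporal commitment: a manoeuvre whose
#' payoff is indifferent to when it starts (moving left, glancing back)
#' would otherwise be re-postponed at every replanning step.
#'
#' @param dist An action distribution from [cem_plan()] diagnostics.
#' @param config A [planner_config()].
#' @param explore_frac Lower bound on std as a fraction of the cold-start
#'   std.
#' @return An action distribution.
#' @export
shift_action_distribution <- function(dist, config, explore_frac = 0.15) {
  h <- config$horizon
  init <- init_action_distribution(config)
  mean_ <- rbind(dist$mean[-1, , drop = FALSE], init$mean[h, , drop = FALSE])
  std_ <- rbind(dist$std[-1, , drop = FALSE], init$std[h, , drop = FALSE])
  std_ <- pmax(std_, explore_frac * init$std)
  p_disc <- NULL
  if (!is.null(dist$p_disc)) {
    p_disc <- rbind(dist$p_disc[-1, , drop = FALSE],
      init$p_disc[h, , drop = FALSE]
    )
  }
  list(mean = mean_, std = std_, p_disc = p_disc)
}

sample_policies <- function(dist, config) {
  h <- config$horizon
  nc <- ncol(config$cont_bounds)
  m <- config$m_samples
  cont <- array(stats::rnorm(m * h * nc), dim = c(m, h, nc))
  rho <- config$noise_rho
  if (rho > 0 && h > 1) {
    sc <- sqrt(1 - rho^2)
    for (t in 2:h) cont[, t, ] <- rho * cont[, t - 1, ] + sc * cont[, t, ]
  }
  for (j in seq_len(nc)) {
    v <- sweep(cont[, , j, drop = FALSE] * rep(dist$std[, j], each = m), 2,
      dist$mean[, j],
      FUN = "+"
    )
    cont[, , j] <- pmin(pmax(v, config$cont_bounds[1, j]),
      config$cont_bounds[2, j]
    )
  }
  disc <- NULL
  if (config$n_disc > 0) {
    disc <- array(stats::runif(m * h * config$n_disc), dim = c(m, h, config$n_disc))
    for (j in seq_len(config$n_disc)) {
      disc[, , j] <- (disc[, , j] < rep(dist$p_disc[, j], each = m)) * 1
    }
  }
  # the first candidate is always the distribution mode, so the batch (and
  # hence the executed best policy) is never worse than the current plan
  for (j in seq_len(nc)) {
    cont[1, , j] <- pmin(pmax(dist$mean[, j], config$cont_bounds[1, j]),
      config$cont_bounds[2, j]
    )
  }
  if (!is.null(disc)) {
    for (j in seq_len(config$n_disc)) disc[1, , j] <- (dist$p_disc[, j] >= 0.5) * 1
  }
  list(cont = cont, disc = disc)
}

#' Refit the action distribution to elite policies
#'
#' Per-step, per-dimension Gaussian mean and population standard deviation
#' from the elite continuous actions (std floored), and clamped Bernoulli
#' frequencies from the elite discrete actions, fitted separately. When a
#' previous distribution is supplied the moments are blended with it by the
#' configured smoothing weight, which filters the sampling noise of the
#' small elite set.
#'
#' @param elites List with `cont` (E x H x n_cont array) and `disc`
#'   (E x H x n_disc array or NULL) of elite action sequences.
#' @param config A [planner_config()].
#' @param previous Optional previous action distribution to smooth toward.
#' @return An action distribution (list of `mean`, `std`, `p_disc`).
#' @export
refit <- function(elites, config, previous = NULL) {
  e <- dim(elites$cont)[1]
  stopifnot(e >= 2)
  h <- dim(elites$cont)[2]
  nc <- dim(elites$cont)[3]
  mean_ <- matrix(0, h, nc)
  std_ <- matrix(0, h, nc)
  for (j in seq_len(nc)) {
    x <- elites$cont[, , j, drop = FALSE]
    dim(x) <- c(e, h)
    mu <- colMeans(x)
    # optimal control sequences are smooth in time; smoothing the fitted
    # mean across neighbouring steps filters the sampling noise of the
    # small elite set without introducing closed-loop lag
    if (h > 2) {
      mu <- c(
        0.75 * mu[1] + 0.25 * mu[2],
        0.25 * mu[-c(h - 1, h)] + 0.5 * mu[-c(1, h)] + 0.25 * mu[-c(1, 2)],
        0.25 * mu[h - 1] + 0.75 * mu[h]
      )
    }
    mean_[, j] <- mu
    std_[, j] <- pmax(sqrt(colMeans(sweep(x, 2, mu)^2)), config$std_floor)
  }
  p_disc <- NULL
  p_disc_raw <- NULL
  if (!is.null(elites$disc)) {
    nd <- dim(elites$disc)[3]
    p_disc_raw <- matrix(0, h, nd)
    for (j in seq_len(nd)) {
      x <- elites$disc[, , j, drop = FALSE]
      dim(x) <- c(e, h)
      p_disc_raw[, j] <- colMeans(x)
    }
    # the clamp keeps exploration alive inside the CEM loop; the raw elite
    # frequency is kept for executing the first action
    p_disc <- pmin(pmax(p_disc_raw, config$prob_clamp),
      1 - config$prob_clamp
    )
  }
  if (!is.null(previous)) {
    al <- config$smoothing
    std_ <- pmax(al * std_ + (1 - al) * previous$std, config$std_floor)
    if (!is.null(p_disc) && !is.null(previous$p_disc)) {
      p_disc <- al * p_disc + (1 - al) * previous$p_disc
      p_disc <- pmin(pmax(p_disc, config$prob_clamp), 1 - config$prob_clamp)
    }
  }
  list(mean = mean_, std = std_, p_disc = p_disc, p_disc_raw = p_disc_raw)
}

#' Plan the next action by cross-entropy-method search
#'
#' @param ensemble A [particle_ensemble()] (the current belief).
#' @param scorer Function `(particles, cont, disc) -> list(G, pragmatic,
#'   epistemic)` scoring a batch of policies: `particles` is the planning
#'   subset (matrix), `cont` an M x H x n_cont array, `disc` an
#'   M x H x n_disc array or NULL; `G` a length-M vector and `pragmatic` /
#'   `epistemic` M x H matrices.
#' @param config A [planner_config()].
#' @param init_dist Optional warm-start action distribution (typically the
#'   previous timestep's final distribution shifted one step, see
#'   [shift_action_distribution()]); default is the cold-start
#'   zero-mean/half-bound distribution.
#' @return List with `action` (list `cont` vector, `disc` integer vector or
#'   NULL) and `diagnostics` (per-iteration best G, elite G spread, the
#'   best policy's per-step pragmatic/epistemic breakdown, and the final
#'   action distribution).
#' @export
cem_plan <- function(ensemble, scorer, config, init_dist = NULL) {
  n <- length(ensemble$weights)
  idx <- sample.int(n, config$n_planning, replace = TRUE,
    prob = ensemble$weights
  )
  particles <- ensemble$states[idx, , drop = FALSE]
  dist <- if (is.null(init_dist)) init_action_distribution(config) else init_dist
  n_elite <- ceiling(config$m_samples * config$elite_fraction)
  best_g <- numeric(config$k_iters)
  elite_spread <- numeric(config$k_iters)
  degenerate <- FALSE
  best_breakdown <- NULL
  best_first <- NULL
  best_pol <- NULL
  best_g_so_far <- Inf
  for (k in seq_len(config$k_iters)) {
    pol <- sample_policies(dist, config)
    if (!is.null(best_pol)) {
      # elite retention: the best policy found so far stays in the batch,
      # so the best score is non-increasing across iterations
      pol$cont[2, , ] <- best_pol$cont
      if (!is.null(pol$disc)) pol$disc[2, , ] <- best_pol$disc
    }
    sc <- scorer(particles, pol$cont, pol$disc)
    ord <- order(sc$G)
    el <- ord[seq_len(n_elite)]
    best_g[k] <- sc$G[ord[1]]
    elite_spread[k] <- sc$G[el[n_elite]] - sc$G[el[1]]
    if (sc$G[ord[1]] <= best_g_so_far) {
      best_g_so_far <- sc$G[ord[1]]
      best_breakdown <- list(
        pragmatic = sc$pragmatic[ord[1], ],
        epistemic = sc$epistemic[ord[1], ],
        G = sc$G[ord[1]]
      )
      best_pol <- list(
        cont = pol$cont[ord[1], , , drop = TRUE],
        disc = if (!is.null(pol$disc)) pol$disc[ord[1], , , drop = TRUE] else NULL
      )
      best_first <- list(
        cont = pol$cont[ord[1], 1, ],
        disc = if (!is.null(pol$disc)) as.integer(pol$disc[ord[1], 1, ]) else NULL
      )
    }
    if (diff(range(sc$G)) == 0) {
      warning("cem_plan: all sampled policies scored identically")
      degenerate <- TRUE
      break
    }
    elites <- list(
      cont = pol$cont[el, , , drop = FALSE],
      disc = if (!is.null(pol$disc)) pol$disc[el, , , drop = FALSE] else NULL
    )
    dist <- refit(elites, config, previous = dist)
  }
  nc <- ncol(config$cont_bounds)
  if (config$action_selection == "best") {
    a_cont <- best_first$cont
    # the discrete first action follows the fitted elite-frequency schedule
    # (majority vote), which integrates elite evidence across iterations and
    # is far less noisy than any single policy's first bit
    a_disc <- if (config$n_disc > 0) {
      as.integer(dist$p_disc[1, ] >= 0.5)
    } else {
      NULL
    }
  } else if (config$action_selection == "mean") {
    a_cont <- pmin(pmax(dist$mean[1, ], config$cont_bounds[1, ]),
      config$cont_bounds[2, ]
    )
    a_disc <- NULL
    if (config$n_disc > 0) {
      p1 <- if (!is.null(dist$p_disc_raw)) dist$p_disc_raw[1, ] else dist$p_disc[1, ]
      a_disc <- as.integer(p1 >= 0.5)
    }
  } else {
    a_cont <- pmin(
      pmax(
        stats::rnorm(nc, dist$mean[1, ], dist$std[1, ]),
        config$cont_bounds[1, ]
      ),
      config$cont_bounds[2, ]
    )
    a_disc <- NULL
    if (config$n_disc > 0) {
      p1 <- if (!is.null(dist$p_disc_raw)) dist$p_disc_raw[1, ] else dist$p_disc[1, ]
      a_disc <- as.integer(stats::runif(config$n_disc) < p1)
    }
  }
  list(
    action = list(cont = a_cont, disc = a_disc),
    diagnostics = list(
      best_g = best_g, elite_spread = elite_spread,
      degenerate = degenerate, breakdown = best_breakdown,
      final_dist = dist
    )
  )
}
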