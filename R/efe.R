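# Expected-free-energy engine. A policy (length-H action sequence) is scored
# by rolling the belief particles forward open-loop through the transition
# and observation models and accumulating, per lookahead step tau:
#   pragmatic value  = mean log preference probability of the predicted
#                      observations over the observable dimensions, and
#   epistemic value  = posterior-predictive entropy of the predicted
#                      observations (KDE estimate over the epistemic
#                      dimensions) minus the expected ambiguity.
# G(policy) = -sum_tau (pragmatic_tau + epistemic_tau); lower is better.
#
# With this package's deterministic observation maps the expected ambiguity
# is the constant entropy of the floor-bandwidth kernel, so a degenerate
# belief (all particles identical) scores exactly zero epistemic value.
#
# This file is the plain-R reference implementation; the CEM planner calls a
# C++ scorer that implements the identical arithmetic for batches of
# policies (see src/score_policies.cpp). Tests assert agreement.

#' Default KDE bandwidth floor (native units per observation dimension)
#'
#' Acts as the effective resolution of the agent's predicted observations:
#' belief dispersion below this scale yields no epistemic value. Chosen small
#' relative to the dispersions the steering noise produces (metres, radians)
#' so that the information gain of an observation can outweigh preference
#' log-probability differences of a few nats; see the methods vignette.
#' @keywords internal
KDE_BANDWIDTH_FLOOR <- 3e-4

#' Default KDE bandwidth cap (native units per observation dimension)
#'
#' Upper bound on the per-dimension kernel bandwidth. Outcomes further apart
#' than this count as distinct categories rather than one broad smoothed
#' blob, which keeps the entropy of well-separated observation clusters
#' (e.g. pedestrian seen at its site vs the -1000 null code) finite and
#' invariant to the arbitrary magnitude of the null code.
#' @keywords internal
KDE_BANDWIDTH_CAP <- 1.0

# Saturation of the squared scaled pair distance in the KDE: observation
# pairs further apart than sqrt(60) ~ 7.7 bandwidths contribute a floored
# kernel value exp(-30) instead of their true (astronomically small) tail
# mass, so the surprise of an isolated outcome is finite and the entropy of
# well-separated clusters does not depend on the arbitrary numeric distance
# between them (e.g. the -1000 null code).
KDE_SQDIST_SAT <- 60

#' Kernel-density Monte-Carlo estimate of differential entropy
#'
#' Estimates H(X) = -E log f(X) from samples using a Gaussian product kernel
#' with per-dimension Scott's-rule bandwidth clipped to
#' `[bandwidth_floor, bandwidth_cap]`, and leave-one-out density evaluation.
#' The cap keeps the estimate close to the mixture entropy for widely
#' separated observation clusters (Scott's rule alone would oversmooth them
#' into a single blob whose apparent entropy grows with the arbitrary
#' separation). Degenerate inputs are clamped: fewer than 2 samples give 0,
#' and the estimate is clamped below at -10 per dimension.
#'
#' @param samples Numeric matrix (rows = samples) or vector.
#' @param bandwidth_floor Per-dimension lower bound on the bandwidth.
#' @param bandwidth_cap Per-dimension upper bound on the bandwidth.
#' @return Scalar entropy estimate (nats).
#' @export
kde_entropy <- function(samples, bandwidth_floor = KDE_BANDWIDTH_FLOOR,
                        bandwidth_cap = KDE_BANDWIDTH_CAP) {
  x <- as.matrix(samples)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2) return(0)
  h <- pmin(
    pmax(apply(x, 2, stats::sd) * n^(-1 / (d + 4)), bandwidth_floor),
    bandwidth_cap
  )
  # leave-one-out log density per sample, via per-dimension scaled distances
  z <- sweep(x, 2, h, "/")
  sq <- pmin(as.matrix(stats::dist(z))^2, KDE_SQDIST_SAT)
  lk <- -0.5 * sq - 0.5 * d * log(2 * pi) - sum(log(h))
  diag(lk) <- -Inf # leave one out
  m <- apply(lk, 1, max)
  loo <- m + log(rowSums(exp(lk - m))) - log(n - 1)
  max(-mean(loo), -10 * d)
}

#' Expected-ambiguity constant of the observation kernel
#'
#' Analytic entropy of the floor-bandwidth Gaussian product kernel evaluated
#' as the leave-one-out KDE of coincident samples; subtracting it makes a
#' degenerate belief score exactly zero epistemic value, matching the regime
#' where precise observations carry no ambiguity.
#'
#' @param n_dims Number of epistemic observation dimensions.
#' @param bandwidth_floor Per-dimension bandwidth floor.
#' @return Scalar constant (nats).
#' @export
ambiguity_constant <- function(n_dims, bandwidth_floor = KDE_BANDWIDTH_FLOOR) {
  n_dims * log(sqrt(2 * pi) * bandwidth_floor)
}

#' Roll a belief forward under a policy
#'
#' Recursively samples next states from the transition model and observations
#' from the observation model for each particle, for each of the H lookahead
#' steps. Open loop: predicted observations do not feed back into the
#' predicted states.
#'
#' @param ensemble A [particle_ensemble()] (typically the planning subset of
#'   the belief).
#' @param policy List with `actions`: H x A matrix, one action vector per
#'   lookahead step.
#' @param transition_model Function `(states, action) -> states`.
#' @param observation_model List with `observe(states) -> obs` and optional
#'   `mask(states, action) -> logical` marking observable dimensions.
#' @return List with `states` and `obs` (lists of H matrices) and `mask`
#'   (H x obs-dims logical matrix).
#' @export
rollout <- function(ensemble, policy, transition_model, observation_model) {
  actions <- as.matrix(policy$actions)
  h <- nrow(actions)
  states <- ensemble$states
  st <- vector("list", h)
  ob <- vector("list", h)
  mask <- NULL
  for (tau in seq_len(h)) {
    a <- actions[tau, ]
    states <- transition_model(states, a)
    o <- observation_model$observe(states)
    st[[tau]] <- states
    ob[[tau]] <- o
    mrow <- if (is.null(observation_model$mask)) {
      rep(TRUE, ncol(o))
    } else {
      observation_model$mask(states, a)
    }
    if (is.null(mask)) mask <- matrix(NA, h, length(mrow))
    mask[tau, ] <- mrow
  }
  list(states = st, obs = ob, mask = mask)
}

#' Pragmatic value of predicted observation particles
#'
#' Mean over particles of the summed prior log probability over the
#' observable preference dimensions. Masked (unobservable) dimensions
#' contribute nothing.
#'
#' @param observation_particles Matrix of predicted observations.
#' @param observability_mask Logical vector over observation dimensions.
#' @param preferences A [preference_model()].
#' @return Scalar pragmatic value (higher is better).
#' @export
pragmatic_value <- function(observation_particles, observability_mask,
                            preferences) {
  mean(log_preference(preferences, observation_particles,
    mask = observability_mask
  ))
}

#' Epistemic value of a one-step observation prediction
#'
#' Posterior-predictive entropy of the observation particles over the
#' epistemic dimensions (KDE estimate) minus the expected-ambiguity constant.
#' Positive when the belief's dispersion would show up in the observation
#' (information to be gained), zero for a degenerate belief or when the
#' dimensions are nulled (no observation diversity).
#'
#' @param observation_particles Matrix of predicted observations at one
#'   lookahead step.
#' @param epistemic_dims Column indices of the epistemic observation
#'   dimensions.
#' @param bandwidth_floor KDE bandwidth floor.
#' @param bandwidth_cap KDE bandwidth cap.
#' @return Scalar epistemic value (nats).
#' @export
epistemic_value <- function(observation_particles, epistemic_dims,
                            bandwidth_floor = KDE_BANDWIDTH_FLOOR,
                            bandwidth_cap = KDE_BANDWIDTH_CAP) {
  x <- as.matrix(observation_particles)[, epistemic_dims, drop = FALSE]
  if (nrow(x) >= 2 && all(apply(x, 2, stats::sd) <= bandwidth_floor)) {
    # dispersion below the observation-resolution floor carries no
    # epistemic value: exactly 0, with no estimator noise
    return(0)
  }
  kde_entropy(x, bandwidth_floor, bandwidth_cap) -
    ambiguity_constant(length(epistemic_dims), bandwidth_floor)
}

#' Expected free energy of a policy
#'
#' Rolls the belief out under the policy and returns the per-step pragmatic
#' and epistemic values and their total `G = -sum(pragmatic + epistemic)`.
#'
#' @inheritParams rollout
#' @param preferences A [preference_model()].
#' @param epistemic_dims Observation dimensions entering the epistemic term.
#' @param bandwidth_floor KDE bandwidth floor.
#' @param bandwidth_cap KDE bandwidth cap.
#' @return List of class `efe_breakdown` with `pragmatic`, `epistemic`
#'   (length-H vectors) and `G` (scalar).
#' @export
expected_free_energy <- function(ensemble, policy, transition_model,
                                 observation_model, preferences,
                                 epistemic_dims,
                                 bandwidth_floor = KDE_BANDWIDTH_FLOOR,
                                 bandwidth_cap = KDE_BANDWIDTH_CAP) {
  ro <- rollout(ensemble, policy, transition_model, observation_model)
  h <- length(ro$obs)
  prag <- numeric(h)
  epi <- numeric(h)
  for (tau in seq_len(h)) {
    prag[tau] <- pragmatic_value(ro$obs[[tau]], ro$mask[tau, ], preferences)
    epi[tau] <- epistemic_value(ro$obs[[tau]], epistemic_dims,
      bandwidth_floor, bandwidth_cap
    )
  }
  structure(
    list(pragmatic = prag, epistemic = epi, G = -sum(prag + epi)),
    class = "efe_breakdown"
  )
}
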