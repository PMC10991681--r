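# Independent oracles and tiny toy models used across the suite.

# Exact forward filter for a discrete HMM (the oracle the SIR filter is
# checked against).
hmm_exact_filter <- function(prior, trans, emit, obs_seq) {
  p <- prior
  out <- matrix(NA, length(obs_seq), length(prior))
  for (t in seq_along(obs_seq)) {
    p <- as.vector(p %*% trans) * emit[, obs_seq[t]]
    p <- p / sum(p)
    out[t, ] <- p
  }
  out
}

# Simulate a 2-state HMM; returns states and observations.
hmm_simulate <- function(n_steps, prior, trans, emit) {
  s <- integer(n_steps)
  o <- integer(n_steps)
  cur <- sample.int(length(prior), 1, prob = prior)
  for (t in seq_len(n_steps)) {
    cur <- sample.int(nrow(trans), 1, prob = trans[cur, ])
    s[t] <- cur
    o[t] <- sample.int(ncol(emit), 1, prob = emit[cur, ])
  }
  list(states = s, obs = o)
}

# SIR machinery adapters for the discrete HMM: particles are a 1-column
# matrix of state labels.
hmm_transition_model <- function(trans) {
  function(states, action) {
    lab <- states[, 1]
    nxt <- lab
    for (k in seq_len(nrow(trans))) {
      idx <- which(lab == k)
      if (length(idx)) {
        nxt[idx] <- sample.int(ncol(trans), length(idx),
          replace = TRUE, prob = trans[k, ]
        )
      }
    }
    matrix(nxt, ncol = 1)
  }
}

hmm_observation_model <- function(emit) {
  list(
    observe = function(states) states,
    loglik = function(observation, states) {
      log(pmax(emit[states[, 1], observation], 1e-300))
    }
  )
}

# Scalar linear-Gaussian system and its exact Kalman filter.
kalman_filter <- function(mu0, var0, a, q, r, obs_seq) {
  mu <- mu0
  v <- var0
  out <- matrix(NA, length(obs_seq), 2)
  for (t in seq_along(obs_seq)) {
    mu_p <- a * mu
    v_p <- a^2 * v + q
    k <- v_p / (v_p + r)
    mu <- mu_p + k * (obs_seq[t] - mu_p)
    v <- (1 - k) * v_p
    out[t, ] <- c(mu, v)
  }
  out
}

# Total variation distance between two discrete distributions.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Quadratic single-step planning problem: state is a scalar position, the
# action moves it directly, and the only preference is a Gaussian prior on
# the resulting position. Used to check the CEM against a grid search.
quadratic_scorer <- function(x0, mu, sigma) {
  function(particles, cont, disc) {
    m <- dim(cont)[1]
    h <- dim(cont)[2]
    prag <- matrix(NA, m, h)
    pos <- matrix(x0, m, 1)
    for (t in seq_len(h)) {
      pos <- pos + cont[, t, 1]
      prag[, t] <- stats::dnorm(pos, mu, sigma, log = TRUE)
    }
    list(G = -rowSums(prag), pragmatic = prag, epi = matrix(0, m, h),
      epistemic = matrix(0, m, h))
  }
}

# Test-profile agent shared by the scenario tests.
test_agent <- function(...) agent_config("test", ...)

run_quiet <- function(expr) suppressWarnings(expr)
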