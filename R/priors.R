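# Preference priors: log probabilities of observations under the prior
# distributions that encode the driver's goals. These are the building blocks
# of pragmatic value. All evaluators return finite values; zero-density points
# return a configurable log floor instead of -Inf so that expected-free-energy
# arithmetic stays finite.

#' Internal log-probability floor used in place of -Inf
#'
#' Zero-density points (triangular bounds, degenerate Bernoulli, forbidden
#' categorical outcomes) evaluate to this floor during planning. A milder
#' truncation at -100 is applied only when exporting value traces for
#' plotting (see [value_curves()]), where very large negative values would
#' hide the decision-relevant structure.
#' @keywords internal
LOG_FLOOR <- -1000

#' Triangular-prior log floor
#'
#' Floor for the lane-keeping prior at and beyond the lane boundaries.
#' Strongly unpreferred but not absolute: the absolute prohibition of
#' leaving the lane is carried by the categorical lane-exit/conflict priors,
#' so the graded lane-keeping prior must not duplicate the -1000 penalty
#' (doubling it makes the planner's sampled-policy noise near the boundary
#' dominate unrelated decisions such as speed keeping).
#' @keywords internal
TRI_FLOOR <- -50

#' Gaussian log density
#'
#' Log density of a normal preference prior, used for speed keeping
#' (centered at the speed limit), comfortable acceleration and steering rate
#' (centered at zero).
#'
#' @param x Observation value(s), native units.
#' @param mu Prior mode (preferred observation).
#' @param sigma Prior scale (> 0); its inverse variance is the preference
#'   precision, i.e. how strongly the agent insists on the preferred value.
#' @return Log density, vectorized over `x`.
#' @examples
#' gaussian_logpdf(10, 10, 1)  # -0.5 * log(2 * pi)
#' @export
gaussian_logpdf <- function(x, mu, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    stop("gaussian_logpdf: sigma must be > 0", call. = FALSE)
  }
  stats::dnorm(x, mean = mu, sd = sigma, log = TRUE)
}

#' Symmetric triangular log density
#'
#' Lane-keeping preference: triangular density peaking at the lane centre and
#' falling to zero at the lane boundaries. Values at or beyond the bounds
#' return `floor` rather than -Inf.
#'
#' @param y Observation value(s) (lateral position, m).
#' @param center Peak location (lane centre).
#' @param lower,upper Bounds (lane edges), `lower < center < upper`.
#' @param floor Log value returned where the density is zero.
#' @return Log density, vectorized over `y`.
#' @examples
#' triangular_logpdf(0, 0, -1.5, 1.5)      # log(2/3)
#' triangular_logpdf(0.75, 0, -1.5, 1.5)   # log(1/3)
#' @export
triangular_logpdf <- function(y, center, lower, upper, floor = TRI_FLOOR) {
  if (!(lower < center && center < upper)) {
    stop("triangular_logpdf: need lower < center < upper", call. = FALSE)
  }
  peak <- 2 / (upper - lower)
  dens <- ifelse(y <= center,
    peak * (y - lower) / (center - lower),
    peak * (upper - y) / (upper - center)
  )
  out <- ifelse(dens > 0 & y > lower & y < upper, log(pmax(dens, 1e-300)), floor)
  out
}

#' Bernoulli gaze log probability
#'
#' Gaze preference: the log probability of an on-road glance is specified
#' directly (e.g. -7), and the off-road probability is the normalized
#' complement `log(1 - exp(log_p_on))`. A more negative `log_p_on` encodes a
#' stronger motivation to look off-road (at the secondary task).
#'
#' @param gaze `"on_road"`/`"off_road"`, or a logical/0-1 vector where
#'   `TRUE`/1 means on-road.
#' @param log_p_on Log probability of an on-road glance, must be <= 0.
#' @param floor Log value returned for the zero-probability outcome when
#'   `log_p_on = 0` (degenerate Bernoulli: off-road glances impossible).
#' @return Log probability, vectorized over `gaze`.
#' @examples
#' bernoulli_gaze_logprob("off_road", -7)  # log(1 - exp(-7))
#' @export
bernoulli_gaze_logprob <- function(gaze, log_p_on, floor = LOG_FLOOR) {
  if (!is.numeric(log_p_on) || length(log_p_on) != 1 || log_p_on > 0) {
    stop("bernoulli_gaze_logprob: log_p_on must be a single value <= 0",
      call. = FALSE
    )
  }
  on <- if (is.character(gaze)) gaze == "on_road" else as.logical(gaze)
  # log(1 - exp(x)) computed stably; exactly the floor when log_p_on == 0
  log_p_off <- if (log_p_on == 0) floor else log1p(-exp(log_p_on))
  ifelse(on, log_p_on, log_p_off)
}

#' Categorical log probability for absolute preferences
#'
#' Absolute "never do this" preferences (conflict with a pedestrian, exiting
#' the lane): the preferred state has probability ~1 (log probability 0), the
#' forbidden state gets a very large negative log probability.
#'
#' @param flag Logical vector; `TRUE` means the forbidden outcome occurred.
#' @param forbidden_logprob Log probability assigned to the forbidden
#'   outcome (default the internal floor).
#' @return 0 for preferred outcomes, `forbidden_logprob` otherwise.
#' @export
categorical_logprob <- function(flag, forbidden_logprob = LOG_FLOOR) {
  ifelse(as.logical(flag), forbidden_logprob, 0)
}

#' Construct a preference model
#'
#' A named collection of preference priors over observation dimensions.
#' Each entry is created by one of [pref_gaussian()], [pref_triangular()],
#' [pref_bernoulli_gaze()], [pref_categorical()] and carries the observation
#' dimension (column of the observation vector) it evaluates.
#'
#' @param ... Named prior entries.
#' @return An object of class `preference_model`.
#' @export
preference_model <- function(...) {
  entries <- list(...)
  if (length(entries) == 0 || is.null(names(entries)) || any(names(entries) == "")) {
    stop("preference_model: all entries must be named", call. = FALSE)
  }
  structure(list(entries = entries), class = "preference_model")
}

#' @rdname preference_model
#' @param dim Observation dimension (column index) the prior evaluates.
#' @param mu,sigma Gaussian parameters.
#' @export
pref_gaussian <- function(dim, mu, sigma) {
  stopifnot(sigma > 0)
  list(family = "gaussian", dim = dim, mu = mu, sigma = sigma)
}

#' @rdname preference_model
#' @param center,lower,upper Triangular parameters.
#' @export
pref_triangular <- function(dim, center, lower, upper) {
  stopifnot(lower < center, center < upper)
  list(family = "triangular", dim = dim, center = center, lower = lower,
       upper = upper)
}

#' @rdname preference_model
#' @param log_p_on Log probability of the on-road glance.
#' @export
pref_bernoulli_gaze <- function(dim, log_p_on) {
  stopifnot(log_p_on <= 0)
  list(family = "bernoulli_gaze", dim = dim, log_p_on = log_p_on)
}

#' @rdname preference_model
#' @param forbidden_logprob Log probability of the forbidden outcome.
#' @export
pref_categorical <- function(dim, forbidden_logprob = LOG_FLOOR) {
  stopifnot(forbidden_logprob <= -100)
  list(family = "categorical", dim = dim, forbidden_logprob = forbidden_logprob)
}

# Evaluate one prior entry on a vector of observation values.
eval_prior <- function(entry, x, floor = LOG_FLOOR) {
  switch(entry$family,
    gaussian = gaussian_logpdf(x, entry$mu, entry$sigma),
    triangular = triangular_logpdf(x, entry$center, entry$lower, entry$upper,
      floor = TRI_FLOOR),
    bernoulli_gaze = bernoulli_gaze_logprob(x, entry$log_p_on, floor = floor),
    categorical = categorical_logprob(x, entry$forbidden_logprob),
    stop("unknown prior family: ", entry$family, call. = FALSE)
  )
}

#' Log preference probability of observation particles
#'
#' Sums prior log probabilities over the observable preference dimensions for
#' each observation particle (row). Masked dimensions contribute nothing:
#' preferences are defined over observations, so dimensions that cannot be
#' observed (e.g. lateral position during an off-road glance) are not
#' evaluated.
#'
#' @param preferences A [preference_model()].
#' @param obs Matrix of observation particles (rows) in observation space.
#' @param mask Optional logical vector over observation dimensions; `FALSE`
#'   marks unobservable dimensions whose priors are skipped. Default: all
#'   observable.
#' @return Numeric vector: per-particle summed log preference probability.
#' @export
log_preference <- function(preferences, obs, mask = NULL) {
  stopifnot(inherits(preferences, "preference_model"))
  obs <- as.matrix(obs)
  total <- numeric(nrow(obs))
  for (entry in preferences$entries) {
    if (!is.null(mask) && !mask[entry$dim]) next
    total <- total + eval_prior(entry, obs[, entry$dim])
  }
  total
}
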