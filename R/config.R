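# Agent hyperparameters and config-file plumbing.

#' Agent hyperparameters
#'
#' Bundles the filter, planner and EFE-estimator settings shared by both
#' scenarios. The `"default"` profile is the headline configuration; the
#' `"test"` profile scales the particle and sample counts down so that full
#' experiment batteries run at desk scale.
#'
#' @param profile `"default"` (N = 1024, planning particles 32, CEM 64 x 3)
#'   or `"test"` (N = 256, planning particles 16, CEM 32 x 2).
#' @param ... Named overrides of individual fields.
#' @return A list of agent hyperparameters.
#' @export
agent_config <- function(profile = c("default", "test"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    n_particles = 1024L,   # filter ensemble size N
    n_planning = 32L,      # particles drawn from the belief for planning
    m_samples = 64L,       # CEM policies per iteration
    k_iters = 12L,         # CEM iterations
    elite_fraction = 0.15,
    horizon = 20L,         # 4 s at dt = 0.2 s
    sigma_obs = 0.02,      # coarse observation kernel (native units);
                           # exactly-visible dims reset at bandwidth_floor
    bandwidth_floor = KDE_BANDWIDTH_FLOOR,
    bandwidth_cap = KDE_BANDWIDTH_CAP,
    std_floor = 0.002,
    prob_clamp = 0.02,
    noise_rho = 0.8,       # temporal correlation of CEM action noise
    action_selection = "best",
    smoothing = 0.5,       # std/probability update weight (mean tracks elites)
    warm_start = TRUE,     # shift the action distribution between steps
    use_epistemic = TRUE
  )
  if (profile == "test") {
    cfg$n_particles <- 256L
    cfg$n_planning <- 16L
    cfg$m_samples <- 32L
  }
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("agent_config: unknown field ", nm, call. = FALSE)
    cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

#' Read a run configuration file
#'
#' YAML file with optional sections `scenario`, `preferences`, `planner`,
#' `filter`, `experiment`; keys mirror the fields of [occlusion_config()],
#' [timesharing_config()] and [agent_config()]. Unknown keys raise a
#' configuration error naming the offending key.
#'
#' @param path Path to a YAML config file.
#' @return Named list of sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("scenario", "preferences", "planner", "filter", "experiment")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  cfg
}

# Merge a config-file section into a defaults list, erroring on unknown keys.
merge_config <- function(defaults, overrides, what) {
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults)) {
      stop("unknown ", what, " key: ", nm, call. = FALSE)
    }
    defaults[[nm]] <- overrides[[nm]]
  }
  defaults
}
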