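# Behavioral summary metrics computed from simulation traces.

#' Standard deviation of lane position (SDLP)
#'
#' Population standard deviation of the true lateral position over the
#' episode, the standard lateral-control variability metric.
#'
#' @param trace Simulation trace with a lateral-position column (`y`).
#' @return SDLP (m).
#' @export
sdlp <- function(trace) {
  y <- trace$y
  sqrt(mean((y - mean(y))^2))
}

#' Steering reversal count
#'
#' Number of timesteps at which the front-wheel angle magnitude strictly
#' exceeds the threshold (default 0.0025 rad / 0.14 deg), implemented exactly
#' as defined.
#'
#' @param trace Trace with a steering-angle column (`delta`).
#' @param threshold Threshold (rad).
#' @return Integer count.
#' @export
steering_reversal_count <- function(trace, threshold = 0.0025) {
  sum(abs(trace$delta) > threshold)
}

#' Off-road glance statistics
#'
#' Maximal runs of consecutive off-road steps count as single glances;
#' duration is run length times the timestep.
#'
#' @param trace Trace with a `gaze` column (0 off-road, 1 on-road).
#' @param dt Timestep (s); taken from the trace metadata when present.
#' @return List: `mean_offroad_duration` (s, 0 when there are no glances),
#'   `offroad_count`, `onroad_count` (number of maximal on-road runs).
#' @export
glance_stats <- function(trace, dt = NULL) {
  if (is.null(dt)) {
    meta <- attr(trace, "meta")
    dt <- if (!is.null(meta$dt)) meta$dt else 0.2
  }
  r <- rle(trace$gaze < 0.5)
  off_lengths <- r$lengths[r$values]
  list(
    mean_offroad_duration = if (length(off_lengths)) {
      mean(off_lengths) * dt
    } else {
      0
    },
    offroad_count = length(off_lengths),
    onroad_count = sum(!r$values)
  )
}

#' Belief-resolution time
#'
#' First simulation time at which the posterior pedestrian-presence
#' probability leaves the open band (collapses toward 0 or 1); 0 when the
#' initial posterior is already outside, NA when it never leaves.
#'
#' @param trace Occlusion trace with `p_present` and `t` columns.
#' @param band Open band `(lo, hi)`.
#' @param p0 Prior presence probability at t = 0 (checked against the band).
#' @return Time (s) or NA.
#' @export
resolution_time <- function(trace, band = c(0.05, 0.95), p0 = NULL) {
  if (is.null(p0)) {
    meta <- attr(trace, "meta")
    if (!is.null(meta$p_prior)) p0 <- meta$p_prior
  }
  if (!is.null(p0) && (p0 <= band[1] || p0 >= band[2])) return(0)
  idx <- which(trace$p_present <= band[1] | trace$p_present >= band[2])
  if (!length(idx)) return(NA_real_)
  trace$t[idx[1]]
}

#' Per-run summary of a trace
#'
#' @param trace A simulation trace from either scenario.
#' @return One-row data.frame of the metrics applicable to the trace's
#'   scenario.
#' @export
summarize_trace <- function(trace) {
  meta <- attr(trace, "meta")
  if (is.null(meta)) meta <- list()
  pick <- function(x) if (is.null(x)) NA else x
  if (identical(meta$scenario, "timesharing")) {
    gs <- glance_stats(trace)
    data.frame(
      scenario = "timesharing", seed = pick(meta$seed),
      mean_speed = mean(trace$v), sdlp = sdlp(trace),
      reversals = steering_reversal_count(trace),
      mean_offroad_duration = gs$mean_offroad_duration,
      offroad_count = gs$offroad_count,
      conflict_count = sum(trace$Cl > 0.5 | trace$Cr > 0.5)
    )
  } else {
    data.frame(
      scenario = "occlusion", variant = pick(meta$variant),
      seed = pick(meta$seed),
      mean_speed = mean(trace$v_x), min_speed = min(trace$v_x),
      final_speed = trace$v_x[nrow(trace)], max_abs_y = max(abs(trace$y)),
      resolution_time = resolution_time(trace),
      conflict_count = sum(trace$conflict > 0.5)
    )
  }
}
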