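# Experiment registry: named batteries of simulation runs over seeds, with
# per-run trace files and a summary table (per-run metrics plus median/IQR
# aggregates per condition). Everything is deterministic given
# (config, seed list).

median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  c(median = q[2], iqr = q[3] - q[1])
}

aggregate_summaries <- function(per_run, condition_cols, metric_cols) {
  conds <- unique(per_run[, condition_cols, drop = FALSE])
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    sel <- rep(TRUE, nrow(per_run))
    for (cc in condition_cols) sel <- sel & per_run[[cc]] == conds[[cc]][i]
    row <- conds[i, , drop = FALSE]
    for (mc in metric_cols) {
      mi <- median_iqr(per_run[[mc]][sel])
      row[[paste0(mc, "_median")]] <- mi[["median"]]
      row[[paste0(mc, "_iqr")]] <- mi[["iqr"]]
    }
    row$n_runs <- sum(sel)
    out[[i]] <- row
  }
  do.call(rbind, out)
}

write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace file written by [run_experiment()]
#'
#' @param path CSV trace path.
#' @param scenario Optional scenario name to restore metadata.
#' @param dt Timestep for metadata.
#' @return data.frame trace.
#' @export
read_trace <- function(path, scenario = NULL, dt = 0.2) {
  tr <- utils::read.csv(path)
  if (!is.null(scenario)) {
    attr(tr, "meta") <- list(scenario = scenario, dt = dt)
  }
  tr
}

occlusion_battery <- function(variants, config, agent, seeds, out_dir, tag) {
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      tr <- run_occlusion_simulation(config, agent, v, s)
      if (!is.null(out_dir)) {
        write_trace(tr, file.path(out_dir, sprintf("%s_%s_seed%d.csv", tag, v, s)))
      }
      sm <- summarize_trace(tr)
      rows[[length(rows) + 1]] <- sm
    }
  }
  do.call(rbind, rows)
}

timesharing_battery <- function(conditions, agent, seeds, out_dir, tag) {
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    cfg <- timesharing_config(
      lane_width = conditions$lane_width[i],
      log_p_on = conditions$log_p_on[i],
      speed_sigma = conditions$speed_sigma[i]
    )
    for (s in seeds) {
      tr <- run_timesharing_simulation(cfg, agent, s)
      if (!is.null(out_dir)) {
        write_trace(tr, file.path(
          out_dir,
          sprintf("%s_cond%d_seed%d.csv", tag, i, s)
        ))
      }
      sm <- summarize_trace(tr)
      sm$lane_width <- conditions$lane_width[i]
      sm$log_p_on <- conditions$log_p_on[i]
      sm$speed_sigma <- conditions$speed_sigma[i]
      rows[[length(rows) + 1]] <- sm
    }
  }
  do.call(rbind, rows)
}

#' Run a named experiment
#'
#' Reproduces the study's simulation batteries:
#' \describe{
#'   \item{sim1a/sim1b/sim1c/sim1d}{occlusion variants over seeds}
#'   \item{saliency}{epistemic saliency map at fixed presence belief 0.2 and
#'     at 0 (deterministic; no seeds)}
#'   \item{sim2a}{time-sharing, gaze preference 0 (baseline) vs -7 (VTS)}
#'   \item{sim2b}{time-sharing at gaze preference -7, lane width 3 vs 2.5 m}
#'   \item{value_curves}{single-step glance value curves at gaze preferences
#'     -7 and -10, with crossover dispersions}
#'   \item{pref_sweep}{gaze preference \{-5, -7, -10\} crossed with
#'     speed-prior sd \{0.5, 2.0\} m/s}
#' }
#'
#' @param name Experiment name (see above).
#' @param config_path Optional YAML config file overriding scenario /
#'   planner / filter keys (see [read_run_config()]).
#' @param n_seeds Runs per condition (seeds `0:(n_seeds-1)`).
#' @param out_dir Output directory for trace and summary CSV files, or NULL
#'   to skip writing.
#' @param profile Agent profile, `"default"` or `"test"`.
#' @return List with `per_run` (per-run metric rows) and `aggregate`
#'   (median/IQR per condition); for `saliency` and `value_curves`, their
#'   respective outputs.
#' @export
run_experiment <- function(name, config_path = NULL, n_seeds = 10,
                           out_dir = NULL, profile = "default") {
  known <- c(
    "sim1a", "sim1b", "sim1c", "sim1d", "saliency", "sim2a", "sim2b",
    "value_curves", "pref_sweep"
  )
  if (!name %in% known) {
    stop("unknown experiment name: ", name, call. = FALSE)
  }
  stopifnot(n_seeds >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  agent_over <- list()
  occ_over <- list()
  ts_over <- list()
  if (!is.null(config_path)) {
    fc <- read_run_config(config_path)
    agent_over <- c(fc$planner, fc$filter)
    occ_over <- ts_over <- c(fc$scenario, fc$preferences)
  }
  agent <- do.call(agent_config, c(list(profile = profile), agent_over))
  seeds <- seq_len(n_seeds) - 1L
  result <- switch(name,
    sim1a = ,
    sim1b = ,
    sim1c = ,
    sim1d = {
      v <- sub("sim", "", name)
      cfg <- do.call(occlusion_config, occ_over)
      per_run <- occlusion_battery(v, cfg, agent, seeds, out_dir, name)
      list(
        per_run = per_run,
        aggregate = aggregate_summaries(
          per_run, "variant",
          c("mean_speed", "min_speed", "final_speed", "max_abs_y",
            "resolution_time", "conflict_count")
        )
      )
    },
    saliency = {
      cfg <- do.call(occlusion_config, occ_over)
      x_grid <- seq(0, 34, by = 2)
      y_grid <- seq(-1.4, 1.4, by = 0.35)
      list(
        x_grid = x_grid, y_grid = y_grid,
        map_belief = epistemic_saliency_map(y_grid, x_grid, 0.2, cfg, agent),
        map_certain = epistemic_saliency_map(y_grid, x_grid, 0, cfg, agent)
      )
    },
    sim2a = {
      conds <- data.frame(
        lane_width = 3, log_p_on = c(0, -7),
        speed_sigma = 2
      )
      per_run <- timesharing_battery(conds, agent, seeds, out_dir, name)
      list(
        per_run = per_run,
        aggregate = aggregate_summaries(
          per_run, "log_p_on",
          c("mean_speed", "sdlp", "reversals", "mean_offroad_duration",
            "offroad_count")
        )
      )
    },
    sim2b = {
      conds <- data.frame(
        lane_width = c(3, 2.5), log_p_on = -7,
        speed_sigma = 2
      )
      per_run <- timesharing_battery(conds, agent, seeds, out_dir, name)
      list(
        per_run = per_run,
        aggregate = aggregate_summaries(
          per_run, "lane_width",
          c("mean_speed", "sdlp", "reversals", "mean_offroad_duration",
            "offroad_count")
        )
      )
    },
    value_curves = {
      cfg <- do.call(timesharing_config, ts_over)
      grid <- exp(seq(log(0.002), log(1.0), length.out = 36))
      list(
        pref_m7 = value_curves(grid, -7, cfg, agent),
        pref_m10 = value_curves(grid, -10, cfg, agent)
      )
    },
    pref_sweep = {
      conds <- expand.grid(
        lane_width = 3, log_p_on = c(-5, -7, -10), speed_sigma = c(0.5, 2.0)
      )
      per_run <- timesharing_battery(conds, agent, seeds, out_dir, name)
      list(
        per_run = per_run,
        aggregate = aggregate_summaries(
          per_run, c("log_p_on", "speed_sigma"),
          c("mean_speed", "sdlp", "mean_offroad_duration", "offroad_count")
        )
      )
    }
  )
  if (!is.null(out_dir) && !is.null(result$per_run)) {
    utils::write.csv(result$per_run,
      file.path(out_dir, paste0(name, "_per_run.csv")),
      row.names = FALSE
    )
    utils::write.csv(result$aggregate,
      file.path(out_dir, paste0(name, "_summary.csv")),
      row.names = FALSE
    )
  }
  result
}
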