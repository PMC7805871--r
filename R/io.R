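#' Path to the shipped default configuration
#'
#' @return File path of the packaged `default.yaml` (published muscle
#'   constants, geometry and the two subject activation profiles).
#' @export
default_config_path <- function() {
  system.file("config", "default.yaml", package = "wfhankle",
              mustWork = TRUE)
}

check_keys <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    wfh_abort(sprintf("unknown configuration key(s) at '%s': %s", path,
                      paste(extra, collapse = ", ")), "wfh_config_error")
  missing <- setdiff(allowed, names(x))
  if (length(missing))
    wfh_abort(sprintf("missing configuration key(s) at '%s': %s", path,
                      paste(missing, collapse = ", ")), "wfh_config_error")
}

#' Load and validate a controller configuration
#'
#' Reads a YAML configuration with sections `muscle.anterior`,
#' `muscle.posterior`, `geometry`, `schedule.profile1`, `schedule.profile2`
#' and `controller`, validates every value and assembles the model
#' objects. `L0` of each virtual muscle is derived from the geometry as
#' the muscle-tendon length at the neutral ankle angle. Unknown or missing
#' keys are rejected with their key path.
#'
#' @param path Configuration file; defaults to the shipped
#'   [default_config_path()].
#' @return A list of class `wfh_config`: `params_A`, `params_P`, `geom`,
#'   `schedules` (list of two [activation_schedule()]s), `controller`
#'   options and the source `path`.
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path))
    wfh_abort(sprintf("configuration file not found: %s", path),
              "wfh_config_error")
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("muscle", "geometry", "schedule", "controller"), "(top)")
  check_keys(raw$muscle, c("anterior", "posterior"), "muscle")
  mus_keys <- c("P0", "kts", "kss", "Cce_l", "Cce_s", "fl_width")
  check_keys(raw$muscle$anterior, mus_keys, "muscle.anterior")
  check_keys(raw$muscle$posterior, mus_keys, "muscle.posterior")
  geo_keys <- c("SAL_A", "SAL_P", "FMA_A", "FMA_P", "gamma0_A", "gamma0_P")
  check_keys(raw$geometry, geo_keys, "geometry")
  check_keys(raw$schedule, c("profile1", "profile2"), "schedule")
  check_keys(raw$schedule$profile1, c("act_A", "act_P"), "schedule.profile1")
  check_keys(raw$schedule$profile2, c("act_A", "act_P"), "schedule.profile2")
  ctl_keys <- c("sample_rate_hz", "resistance_gain", "constant_arm",
                "smoothing_window")
  check_keys(raw$controller, ctl_keys, "controller")
  geom <- do.call(ankle_geometry, raw$geometry)
  L <- muscle_lengths(0, geom)
  mk <- function(side, L0) {
    m <- raw$muscle[[side]]
    muscle_params(side, P0 = m$P0, kts = m$kts, kss = m$kss,
                  Cce_l = m$Cce_l, Cce_s = m$Cce_s, L0 = L0,
                  fl_width = m$fl_width)
  }
  schedules <- lapply(1:2, function(i) {
    s <- raw$schedule[[paste0("profile", i)]]
    tryCatch(activation_schedule(s$act_A, s$act_P, profile = as.character(i)),
             wfh_error = function(e)
               wfh_abort(sprintf("schedule.profile%d: %s", i,
                                 conditionMessage(e)), "wfh_config_error"))
  })
  ctl <- raw$controller
  if (ctl$sample_rate_hz <= 0)
    wfh_abort("controller.sample_rate_hz must be > 0", "wfh_config_error")
  structure(list(params_A = mk("anterior", L[["Lm_A"]]),
                 params_P = mk("posterior", L[["Lm_P"]]),
                 geom = geom,
                 schedules = stats::setNames(schedules,
                                             c("profile1", "profile2")),
                 controller = ctl, path = path),
            class = "wfh_config")
}

#' @export
print.wfh_config <- function(x, ...) {
  cat(sprintf("<wfh_config from %s>\n", x$path))
  print(x$params_A); print(x$params_P); print(x$geom)
  invisible(x)
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg, f))`
#' reproduces the same object graph.
#'
#' @param cfg A `wfh_config` from [load_config()].
#' @param path Output file.
#' @export
dump_config <- function(cfg, path) {
  mus <- function(p) list(P0 = p$P0, kts = p$kts, kss = p$kss,
                          Cce_l = p$Cce_l, Cce_s = p$Cce_s,
                          fl_width = p$fl_width)
  raw <- list(
    muscle = list(anterior = mus(cfg$params_A),
                  posterior = mus(cfg$params_P)),
    geometry = unclass(cfg$geom),
    schedule = list(
      profile1 = list(act_A = unname(cfg$schedules$profile1$act_A),
                      act_P = unname(cfg$schedules$profile1$act_P)),
      profile2 = list(act_A = unname(cfg$schedules$profile2$act_A),
                      act_P = unname(cfg$schedules$profile2$act_P))),
    controller = cfg$controller)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Write a gait trajectory to CSV
#'
#' Columns `time_s, theta_deg, stage`; body mass, when present, is stored
#' in a leading metadata comment line `# mass_kg=<value>`.
#'
#' @param traj A [gait_trajectory()].
#' @param path Output file.
#' @export
write_gait_csv <- function(traj, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  mass <- attr(traj, "mass_kg")
  if (!is.null(mass) && !is.na(mass))
    writeLines(sprintf("# mass_kg=%g", mass), con)
  utils::write.csv(as.data.frame(traj)[c("time_s", "theta_deg", "stage")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gait trajectory from CSV
#'
#' @param path File written by [write_gait_csv()] (or any CSV with columns
#'   `time_s, theta_deg, stage` and an optional `# mass_kg=` header line).
#' @return A [gait_trajectory()].
#' @export
read_gait_csv <- function(path) {
  first <- readLines(path, n = 1L)
  mass <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("mass_kg=([0-9.eE+-]+)", first))[[1L]]
    if (length(m) == 2L) mass <- as.numeric(m[2L])
  }
  df <- utils::read.csv(path, comment.char = "#")
  gait_trajectory(df$time_s, df$theta_deg, df$stage, mass_kg = mass)
}

moment_csv_columns <- c("time_s", "theta_deg", "stage", "moment_Nm",
                        "moment_Nm_per_kg", "power_W_per_kg",
                        "Fss_A_N", "Fss_P_N")

#' Write a controller moment trace to CSV
#'
#' Columns `time_s, theta_deg, stage, moment_Nm, moment_Nm_per_kg,
#' power_W_per_kg, Fss_A_N, Fss_P_N`; the body mass travels in a
#' `# mass_kg=` header line as for gait CSVs.
#'
#' @param trace A `moment_trace` from [run_controller()].
#' @param path Output file.
#' @export
write_moment_csv <- function(trace, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  mass <- attr(trace, "mass_kg")
  if (!is.null(mass) && !is.na(mass))
    writeLines(sprintf("# mass_kg=%g", mass), con)
  utils::write.csv(as.data.frame(trace)[moment_csv_columns], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a controller moment trace from CSV
#'
#' @param path File written by [write_moment_csv()].
#' @return A `moment_trace` data frame.
#' @export
read_moment_csv <- function(path) {
  first <- readLines(path, n = 1L)
  mass <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("mass_kg=([0-9.eE+-]+)", first))[[1L]]
    if (length(m) == 2L) mass <- as.numeric(m[2L])
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(moment_csv_columns %in% names(df)))
    wfh_abort("missing moment-trace columns", "wfh_input_error")
  structure(df[moment_csv_columns], mass_kg = mass,
            class = c("moment_trace", "data.frame"))
}
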