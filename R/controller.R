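#' Gait trajectory container
#'
#' The controller's only real-time input: a uniformly sampled ankle-angle
#' stream (degrees; plantarflexion negative, dorsiflexion positive, 0 =
#' foot perpendicular to shank) with a per-sample gait-stage label in
#' `{2, 3, 4, 5, 6}`.
#'
#' @param time_s Strictly increasing sample times, s.
#' @param theta_deg Ankle angle per sample, degrees, `|theta| < 90`.
#' @param stage Gait-stage label per sample.
#' @param mass_kg Optional body mass for mass-normalised outputs, kg.
#' @return A `data.frame` of class `gait_trajectory` with attribute
#'   `mass_kg`.
#' @export
gait_trajectory <- function(time_s, theta_deg, stage, mass_kg = NA_real_) {
  n <- length(time_s)
  if (n < 2L || length(theta_deg) != n || length(stage) != n)
    wfh_abort("time, angle and stage channels must have equal length >= 2",
              "wfh_input_error")
  if (any(diff(time_s) <= 0))
    wfh_abort("'time_s' must be strictly increasing", "wfh_input_error")
  if (any(abs(theta_deg) >= 90) || any(!is.finite(theta_deg)))
    wfh_abort("ankle angle must satisfy |theta| < 90 degrees",
              "wfh_input_error")
  if (any(!stage %in% 2:6))
    wfh_abort("stage labels must be in {2, 3, 4, 5, 6}", "wfh_input_error")
  if (!is.na(mass_kg) && mass_kg <= 0)
    wfh_abort("'mass_kg' must be positive", "wfh_input_error")
  structure(data.frame(time_s = time_s, theta_deg = theta_deg,
                       stage = as.integer(stage)),
            mass_kg = mass_kg,
            class = c("gait_trajectory", "data.frame"))
}

#' @export
print.gait_trajectory <- function(x, ...) {
  cat(sprintf("<gait_trajectory: %d samples, %.2f s, mass %s kg>\n",
              nrow(x), x$time_s[nrow(x)] - x$time_s[1L],
              format(attr(x, "mass_kg"))))
  cat(sprintf("  theta range [%.1f, %.1f] deg; stages %s\n",
              min(x$theta_deg), max(x$theta_deg),
              paste(sort(unique(x$stage)), collapse = ",")))
  invisible(x)
}

#' Run the two-muscle ankle controller over a gait trajectory
#'
#' The adaptive torque command of the prosthesis: at every sample the ankle
#' angle is mapped to the two virtual muscle lengths (law of cosines), the
#' gait-stage label selects the square-wave activations, each
#' winding-filament muscle is advanced one Euler step, and the net ankle
#' moment is the difference of the two muscle forces times their geometric
#' moment arms (plantarflexion positive), plus an optional viscous
#' resistance-compensation term. One parameter set serves every terrain:
#' nothing in the controller depends on whether the trajectory is level
#' walking, stair ascent or a transition.
#'
#' @param traj A [gait_trajectory()].
#' @param params_A,params_P [muscle_params()] for the anterior and posterior
#'   muscles.
#' @param geom An [ankle_geometry()] object.
#' @param schedule An [activation_schedule()] object.
#' @param resistance_gain Additive compensation gain on the ankle angular
#'   velocity, N·m·s/deg (default 0 = pure model output).
#' @param constant_arm Use constant foot moment arms instead of the
#'   geometric (virtual-work) arms.
#' @param smoothing_window Optional trailing-mean window (samples) applied
#'   to the square-wave activation channels; 0 or 1 disables (default).
#' @return A `data.frame` of class `moment_trace` with columns `time_s,
#'   theta_deg, stage, moment_Nm, moment_Nm_per_kg, power_W_per_kg, Fss_A_N,
#'   Fss_P_N` (the normalised columns are `NA` when the trajectory carries
#'   no body mass).
#' @export
run_controller <- function(traj, params_A, params_P, geom, schedule,
                           resistance_gain = 0, constant_arm = FALSE,
                           smoothing_window = 0L) {
  stopifnot(inherits(traj, "gait_trajectory"))
  dt <- stats::median(diff(traj$time_s))
  L <- muscle_lengths(traj$theta_deg, geom)
  acts <- activation_at(traj$stage, schedule)
  act_A <- acts[, "act_A"]; act_P <- acts[, "act_P"]
  if (smoothing_window > 1L) {
    act_A <- smooth_activation(act_A, as.integer(smoothing_window))
    act_P <- smooth_activation(act_P, as.integer(smoothing_window))
  }
  mA <- simulate_muscle(params_A, L[, "Lm_A"], act_A, dt)
  mP <- simulate_muscle(params_P, L[, "Lm_P"], act_P, dt)
  r <- moment_arms(traj$theta_deg, geom, constant_arm = constant_arm)
  moment_A <- -mA$Fss_N * r[, "r_A"] / 100
  moment_P <- mP$Fss_N * r[, "r_P"] / 100
  theta_dot <- finite_diff(traj$theta_deg, traj$time_s)   # deg/s
  moment <- moment_A + moment_P + resistance_gain * theta_dot
  mass <- attr(traj, "mass_kg")
  if (is.na(mass)) {
    m_kg <- rep(NA_real_, nrow(traj)); pw <- rep(NA_real_, nrow(traj))
  } else {
    m_kg <- moment / mass
    # plantarflexion-positive angular velocity, rad/s
    pw <- m_kg * (-deg2rad(theta_dot))
  }
  structure(data.frame(time_s = traj$time_s, theta_deg = traj$theta_deg,
                       stage = traj$stage, moment_Nm = moment,
                       moment_Nm_per_kg = m_kg, power_W_per_kg = pw,
                       Fss_A_N = mA$Fss_N, Fss_P_N = mP$Fss_N,
                       moment_A_Nm = moment_A, moment_P_Nm = moment_P),
            mass_kg = mass,
            class = c("moment_trace", "data.frame"))
}

#' @export
print.moment_trace <- function(x, ...) {
  cat(sprintf("<moment_trace: %d samples, peak net moment %.2f N.m>\n",
              nrow(x), max(x$moment_Nm)))
  invisible(x)
}

# Central finite differences, one-sided at the ends.
finite_diff <- function(y, t) {
  n <- length(y)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    d[i] <- (y[i + 1L] - y[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  d
}
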