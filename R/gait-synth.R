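#' Shape parameters for the synthetic gait generator
#'
#' The generator draws each gait cycle as a monotone cubic spline through a
#' small set of named control points (heel-strike angle, mid-stance
#' dorsiflexion, late-stance plantarflexion peak, swing return), with
#' per-stride Gaussian perturbation of the interior control points. Stage
#' labels are assigned by cycle fraction: early stance (4, controlled
#' plantarflexion) covers the first fifth of stance after heel strike,
#' late stance (5, controlled dorsiflexion) runs to three quarters of
#' stance, powered plantarflexion (6) covers the remainder of stance
#' starting near peak dorsiflexion, and swing splits evenly into early (2)
#' and late (3).
#'
#' Stair cycles carry an extra controlled-dorsiflexion/plantarflexion
#' sub-cycle: a first dorsiflexion excursion pulls the centre of mass up
#' from the previous stair, a relief dip follows, then a second, deeper
#' dorsiflexion precedes a plantarflexion peak that is larger and later
#' than in level walking.
#'
#' @param stride_duration_s Cycle duration, s.
#' @param stance_fraction Fraction of the cycle in stance (default 0.60).
#' @param peak_pf_deg Late-stance plantarflexion peak, degrees (negative,
#'   in `[-30, 0]`).
#' @param peak_pf_frac Cycle fraction of the plantarflexion peak.
#' @param midstance_df_deg Mid-stance dorsiflexion peak, degrees.
#' @param stair_mode Logical: add the stair pull-up sub-cycle.
#' @param stair_pullup_df_deg First (pull-up) dorsiflexion excursion for
#'   stair cycles, degrees.
#' @param stair_dip_df_deg Angle of the relief dip between the two stair
#'   dorsiflexion excursions, degrees.
#' @param noise_sd_deg Per-stride SD of the control-point perturbation,
#'   degrees (>= 0).
#' @param fs Sample rate, Hz.
#' @return An object of class `gait_shape_params`.
#' @export
gait_shape_params <- function(stride_duration_s = 1.15,
                              stance_fraction = 0.60,
                              peak_pf_deg = -13,
                              peak_pf_frac = 0.60,
                              midstance_df_deg = 10,
                              stair_mode = FALSE,
                              stair_pullup_df_deg = 12,
                              stair_dip_df_deg = 3,
                              noise_sd_deg = 0.25,
                              fs = 500) {
  if (stance_fraction <= 0 || stance_fraction >= 1)
    wfh_abort("'stance_fraction' must lie in (0, 1)", "wfh_validation_error")
  if (peak_pf_deg < -30 || peak_pf_deg > 0)
    wfh_abort("'peak_pf_deg' must lie in [-30, 0] degrees",
              "wfh_validation_error")
  if (noise_sd_deg < 0)
    wfh_abort("'noise_sd_deg' must be >= 0", "wfh_validation_error")
  if (stride_duration_s <= 0 || fs <= 0)
    wfh_abort("durations and sample rate must be positive",
              "wfh_validation_error")
  structure(list(stride_duration_s = stride_duration_s,
                 stance_fraction = stance_fraction,
                 peak_pf_deg = peak_pf_deg, peak_pf_frac = peak_pf_frac,
                 midstance_df_deg = midstance_df_deg,
                 stair_mode = stair_mode,
                 stair_pullup_df_deg = stair_pullup_df_deg,
                 stair_dip_df_deg = stair_dip_df_deg,
                 noise_sd_deg = noise_sd_deg, fs = fs),
            class = "gait_shape_params")
}

# Control points (cycle fraction, angle in degrees) of one cycle. The
# boundary points at fractions 0 and 1 are pinned to 0 degrees so that
# concatenated cycles join continuously.
cycle_control_points <- function(shape) {
  if (shape$stair_mode) {
    data.frame(
      frac = c(0, 0.15, 0.28, 0.48, shape$peak_pf_frac, 0.88, 1),
      theta = c(0, shape$stair_pullup_df_deg, shape$stair_dip_df_deg,
                shape$midstance_df_deg, shape$peak_pf_deg, 1, 0),
      interior = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  } else {
    data.frame(
      frac = c(0, 0.07, 0.47, shape$peak_pf_frac, 0.82, 1),
      theta = c(0, -4, shape$midstance_df_deg, shape$peak_pf_deg, 3, 0),
      interior = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  }
}

# Stage label for each cycle fraction. Within stance, early stance (4) is
# the controlled-plantarflexion phase after heel strike (~first fifth of
# stance), late stance (5) the controlled-dorsiflexion phase, and powered
# plantarflexion (6) begins near peak dorsiflexion (~75% of stance); swing
# splits evenly into early (2) and late (3).
stage_for_fraction <- function(frac, stance) {
  b <- c(0, 0.2 * stance, 0.75 * stance, stance, stance + 0.5 * (1 - stance))
  lab <- c(4L, 5L, 6L, 2L, 3L)
  lab[findInterval(frac, b, rightmost.closed = FALSE)]
}

# Monotone cubic Hermite interpolant (Fritsch-Carlson). Knot slopes are
# zeroed where the data has a local extremum, so the control points are the
# exact waveform extremes (stats::splinefun's "monoH.FC" over- and
# undershoots past extremum knots), and the curve is C1 everywhere.
mono_spline <- function(x, y) {
  n <- length(x)
  d <- diff(y) / diff(x)
  m <- c(d[1L], ifelse(d[-(n - 1L)] * d[-1L] <= 0, 0,
                       (d[-(n - 1L)] + d[-1L]) / 2), d[n - 1L])
  for (i in seq_len(n - 1L)) {
    if (d[i] == 0) {
      m[i] <- m[i + 1L] <- 0
    } else {
      if (m[i] / d[i] < 0) m[i] <- 0
      else if (m[i] / d[i] > 3) m[i] <- 3 * d[i]
      if (m[i + 1L] / d[i] < 0) m[i + 1L] <- 0
      else if (m[i + 1L] / d[i] > 3) m[i + 1L] <- 3 * d[i]
    }
  }
  function(xx) {
    k <- pmin(pmax(findInterval(xx, x), 1L), n - 1L)
    h <- x[k + 1L] - x[k]
    t <- (xx - x[k]) / h
    (1 + 2 * t) * (1 - t)^2 * y[k] + t * (1 - t)^2 * h * m[k] +
      t^2 * (3 - 2 * t) * y[k + 1L] + t^2 * (t - 1) * h * m[k + 1L]
  }
}

# One sampled cycle: theta values and stage labels (no time base).
synth_cycle <- function(shape, noise) {
  cp <- cycle_control_points(shape)
  th <- cp$theta
  if (length(noise)) th[cp$interior] <- th[cp$interior] + noise
  f <- mono_spline(cp$frac, th)
  n <- max(4L, as.integer(round(shape$stride_duration_s * shape$fs)))
  frac <- (seq_len(n) - 1L) / n
  list(theta = f(frac), stage = stage_for_fraction(frac, shape$stance_fraction))
}

build_bout <- function(shapes, seed, mass_kg = 82) {
  set.seed(as.integer(seed))
  th <- integer(0); st <- integer(0)
  theta <- numeric(0)
  for (shape in shapes) {
    k <- sum(cycle_control_points(shape)$interior)
    noise <- if (shape$noise_sd_deg > 0)
      stats::rnorm(k, 0, shape$noise_sd_deg) else numeric(0)
    cyc <- synth_cycle(shape, noise)
    theta <- c(theta, cyc$theta)
    st <- c(st, cyc$stage)
  }
  fs <- shapes[[1L]]$fs
  gait_trajectory(time_s = (seq_along(theta) - 1L) / fs, theta_deg = theta,
                  stage = st, mass_kg = mass_kg)
}

level_shape_for_speed <- function(speed_class, shape = NULL) {
  preset <- switch(speed_class,
    slow = list(stride_duration_s = 1.40, peak_pf_deg = -8,
                midstance_df_deg = 8),
    medium = list(stride_duration_s = 1.15, peak_pf_deg = -13,
                  midstance_df_deg = 10),
    fast = list(stride_duration_s = 0.95, peak_pf_deg = -19,
                midstance_df_deg = 12))
  if (is.null(shape)) shape <- do.call(gait_shape_params, preset)
  shape
}

#' Synthetic level-walking bout
#'
#' Generates a seeded ankle-angle trajectory for level walking: heel strike
#' at 0% cycle, a brief controlled-plantarflexion dip, mid-stance
#' dorsiflexion, a late-stance plantarflexion peak near 60% of the cycle
#' and a swing return, with stage labels 4-5-6-2-3 and stride-to-stride
#' variability. Speed classes map to stride durations of 1.40/1.15/0.95 s
#' and plantarflexion peaks of -8/-13/-19 degrees (slow/medium/fast).
#'
#' @param speed_class `"slow"`, `"medium"` or `"fast"`.
#' @param n_strides Number of strides (>= 1).
#' @param shape Optional [gait_shape_params()] overriding the speed preset.
#' @param seed RNG seed for the stride-to-stride variability.
#' @param mass_kg Body mass attached to the trajectory, kg.
#' @return A [gait_trajectory()].
#' @export
make_level_walking <- function(speed_class = c("medium", "slow", "fast"),
                               n_strides = 8, shape = NULL, seed = 1,
                               mass_kg = 82) {
  speed_class <- match.arg(speed_class)
  if (n_strides < 1) wfh_abort("'n_strides' must be >= 1",
                               "wfh_validation_error")
  shape <- level_shape_for_speed(speed_class, shape)
  build_bout(rep(list(shape), n_strides), seed, mass_kg)
}

#' Synthetic stair-ascent bout
#'
#' Generates a seeded stair-ascent trajectory: each step cycle contains two
#' controlled-dorsiflexion/plantarflexion excursions (pull-up then push-off)
#' and a plantarflexion peak that is both deeper (default -17 degrees) and
#' later in the cycle than the level-walking defaults. The step-cycle
#' duration on one side is `120 / cadence` seconds (step-over-step gait).
#'
#' @param cadence Steps per minute (> 0), counting both sides.
#' @param n_steps Number of step cycles on the prosthesis side (>= 1).
#' @param shape Optional [gait_shape_params()] with `stair_mode = TRUE`.
#' @param seed RNG seed.
#' @param mass_kg Body mass, kg.
#' @return A [gait_trajectory()].
#' @export
make_stair_ascent <- function(cadence = 80, n_steps = 4, shape = NULL,
                              seed = 1, mass_kg = 82) {
  if (cadence <= 0) wfh_abort("'cadence' must be > 0", "wfh_validation_error")
  if (n_steps < 1) wfh_abort("'n_steps' must be >= 1", "wfh_validation_error")
  if (is.null(shape))
    shape <- gait_shape_params(stride_duration_s = 120 / cadence,
                               stance_fraction = 0.65, peak_pf_deg = -17,
                               peak_pf_frac = 0.68, midstance_df_deg = 17,
                               stair_mode = TRUE)
  if (!shape$stair_mode)
    wfh_abort("stair shape must have stair_mode = TRUE",
              "wfh_validation_error")
  build_bout(rep(list(shape), n_steps), seed, mass_kg)
}

#' Synthetic level-to-stairs transition bout
#'
#' Two level strides, four stair steps and two closing level strides (eight
#' cycles in total), concatenated continuously; every cycle is driven by
#' the same controller parameters downstream -- the only thing that changes
#' at the transitions is the ankle-angle input itself.
#'
#' @param seed RNG seed.
#' @param shape Optional level-walking [gait_shape_params()]; the stair
#'   segment uses the default stair shape with a matched sample rate.
#' @param cadence Stair cadence, steps/min.
#' @param mass_kg Body mass, kg.
#' @return A [gait_trajectory()] of eight cycles.
#' @export
make_transition_bout <- function(seed = 1, shape = NULL, cadence = 80,
                                 mass_kg = 82) {
  level <- level_shape_for_speed("medium", shape)
  stair <- gait_shape_params(stride_duration_s = 120 / cadence,
                             stance_fraction = 0.65, peak_pf_deg = -17,
                             peak_pf_frac = 0.68, midstance_df_deg = 17,
                             stair_mode = TRUE,
                             noise_sd_deg = level$noise_sd_deg,
                             fs = level$fs)
  build_bout(c(rep(list(level), 2), rep(list(stair), 4), rep(list(level), 2)),
             seed, mass_kg)
}
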