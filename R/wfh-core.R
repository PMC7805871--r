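#' Active force-length scaling factor
#'
#' Parabolic approximation to the sarcomere-overlap force-length relation:
#' equals 1 at the optimal length `L0`, falls off symmetrically and reaches
#' zero at `L0 * (1 +/- fl_width)`, clipped below at zero.
#'
#' @param Xm Muscle-tendon length, cm (> 0). Vectorised.
#' @param params A [muscle_params()] object.
#' @return Dimensionless factor in `[0, 1]`, same length as `Xm`.
#' @export
force_length <- function(Xm, params) {
  if (any(!is.finite(Xm)) || any(Xm <= 0))
    wfh_abort("'Xm' must be positive and finite", "wfh_domain_error")
  z <- (Xm - params$L0) / (params$fl_width * params$L0)
  pmax(0, 1 - z^2)
}

#' Contractile element force
#'
#' `Fce = act * fl(Xm) * P0`: the active force of the contractile element at
#' activation `act` and length `Xm`.
#'
#' @param act Activation fraction in `[0, 1]`.
#' @param Xm Muscle-tendon length, cm.
#' @param params A [muscle_params()] object.
#' @return Force in N, in `[0, P0]`.
#' @export
contractile_force <- function(act, Xm, params) {
  if (any(!is.finite(act)) || any(act < 0) || any(act > 1))
    wfh_abort("activation must lie in [0, 1]", "wfh_parameter_error")
  act * force_length(Xm, params) * params$P0
}

#' Directional CE damping coefficient
#'
#' The damper in parallel with the contractile element is a linear
#' approximation to the two limbs of the force-velocity relation, so its
#' coefficient depends on the direction of CE motion: `Cce_l` while the CE
#' lengthens, `Cce_s` while it shortens. The direction is judged on the
#' previous step's CE velocity; an exact tie (`vce = 0`) takes the
#' lengthening coefficient.
#'
#' @param prev_vce CE velocity at the previous step, cm/s.
#' @param params A [muscle_params()] object.
#' @return Damping coefficient, N·s/cm.
#' @export
select_damping <- function(prev_vce, params) {
  if (prev_vce < 0) params$Cce_s else params$Cce_l
}

#' Contractile-element velocity by superposition
#'
#' Sums the rotational and translational force balances about the
#' thin-filament pulley:
#' `vce = (kts*Xts - Fce)/Cce + (kss*(Xm - Xp) - Fce - kts*Xts)/Cce`.
#' The titin terms cancel algebraically, so the result equals
#' `(kss*(Xm - Xp) - 2*Fce)/Cce`.
#'
#' @param state A [muscle_state()].
#' @param Fce Contractile force, N.
#' @param Cce Damping coefficient, N·s/cm (> 0).
#' @param params A [muscle_params()] object.
#' @return CE velocity, cm/s.
#' @export
ce_velocity <- function(state, Fce, Cce, params) {
  if (!is.finite(Cce) || Cce <= 0)
    wfh_abort("'Cce' must be positive", "wfh_parameter_error")
  rot <- (params$kts * state$Xts - Fce) / Cce
  trans <- (params$kss * (state$Xm - state$Xp) - Fce -
              params$kts * state$Xts) / Cce
  rot + trans
}

# One explicit Euler step on the raw numeric state. Pulley equilibrium is
# imposed at all times: combining the rotational balance (Fce + Cce*vce =
# kts*Xts) with the translational balance (Fce + Cce*vce + kts*Xts =
# kss*(Xm - Xp)) gives kss*(Xm - Xp) = 2*kts*Xts, so the pulley position is
# quasi-static and the superposition velocity reads vce =
# 2*(kts*Xts - Fce)/Cce. Differentiating the translational constraint with
# the winding kinematics xts_dot = xp_dot - xce_dot closes the system:
# xts_dot = kss*(xm_dot - vce)/(kss + 2*kts), clipped at Xts >= 0 (the
# cable unwinds slack rather than pushing).
step_kernel <- function(Xts, Xce, Xm_prev, vce_prev, Xm_next, act_next, dt,
                        P0, kts, kss, Cce_l, Cce_s, L0, flw) {
  z <- (Xm_next - L0) / (flw * L0)
  Fce <- act_next * max(0, 1 - z * z) * P0
  Cce <- if (vce_prev < 0) Cce_s else Cce_l
  vce <- 2 * (kts * Xts - Fce) / Cce
  xm_dot <- (Xm_next - Xm_prev) / dt
  Xts_new <- Xts + dt * kss * (xm_dot - vce) / (kss + 2 * kts)
  if (Xts_new < 0) Xts_new <- 0
  c(Xts = Xts_new, Xce = Xce + vce * dt, vce = vce, Fce = Fce)
}

#' Advance a muscle state by one time step
#'
#' One explicit Euler update at the controller rate (default 500 Hz): the
#' contractile force is evaluated at the new length and activation, the
#' damping direction is taken from the previous step's CE velocity, the CE
#' velocity follows from the superposition of the pulley force balances, the
#' titin elongation is integrated from the winding kinematics (clipped at
#' zero), and the pulley position is placed by quasi-static force balance.
#'
#' @param state A [muscle_state()].
#' @param Xm_next Muscle-tendon length at the end of the step, cm.
#' @param act_next Activation over the step, in `[0, 1]`.
#' @param dt Time step, s (> 0; default `1/500`).
#' @param params A [muscle_params()] object.
#' @return The updated [muscle_state()].
#' @export
advance_state <- function(state, Xm_next, act_next, dt = 1 / 500, params) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    wfh_abort("'dt' must be a single positive time step", "wfh_parameter_error")
  if (!is.finite(act_next) || act_next < 0 || act_next > 1)
    wfh_abort("activation must lie in [0, 1]", "wfh_parameter_error")
  if (!is.finite(Xm_next) || Xm_next <= 0)
    wfh_abort("'Xm_next' must be positive", "wfh_domain_error")
  k <- step_kernel(state$Xts, state$Xce, state$Xm, state$vce,
                   Xm_next, act_next, dt,
                   params$P0, params$kts, params$kss,
                   params$Cce_l, params$Cce_s, params$L0, params$fl_width)
  Fts <- params$kts * k[["Xts"]]
  Xp <- Xm_next - 2 * Fts / params$kss
  Fss <- params$kss * (Xm_next - Xp)
  out <- c(k, Xp = Xp, Fts = Fts, Fss = Fss)
  bad <- names(out)[!is.finite(out)]
  if (length(bad))
    wfh_abort(paste0("non-finite state after step: ",
                     paste(bad, collapse = ", ")), "wfh_numerical_error")
  muscle_state(t = state$t + dt, Xm = Xm_next, Xce = k[["Xce"]], Xp = Xp,
               Xts = k[["Xts"]], vce = k[["vce"]], Fce = k[["Fce"]],
               Fts = Fts, Fss = Fss, act = act_next)
}

#' Sub-stepped reference update (verification oracle)
#'
#' Identical contract to [advance_state()] but splits the interval into
#' `refinement` Euler sub-steps with linearly interpolated length and
#' activation. `refinement = 1` reproduces [advance_state()] bit-for-bit;
#' large refinements serve as an integration-accuracy reference.
#'
#' @inheritParams advance_state
#' @param refinement Integer number of sub-steps (>= 1).
#' @return The updated [muscle_state()].
#' @export
oracle_advance <- function(state, Xm_next, act_next, dt = 1 / 500, params,
                           refinement = 1L) {
  refinement <- as.integer(refinement)
  if (is.na(refinement) || refinement < 1L)
    wfh_abort("'refinement' must be an integer >= 1", "wfh_parameter_error")
  if (refinement == 1L)
    return(advance_state(state, Xm_next, act_next, dt, params))
  s <- state
  for (j in seq_len(refinement)) {
    f <- j / refinement
    s <- advance_state(s,
                       Xm_next = state$Xm + f * (Xm_next - state$Xm),
                       act_next = state$act + f * (act_next - state$act),
                       dt = dt / refinement, params = params)
  }
  s
}

# Fast trajectory-level simulation: same arithmetic as advance_state, inlined
# over full input vectors. Xm and act are per-sample (length n); row 1 is the
# passive rest state at Xm[1].
simulate_muscle <- function(params, Xm, act, dt = 1 / 500) {
  n <- length(Xm)
  stopifnot(length(act) == n, n >= 1L)
  P0 <- params$P0; kts <- params$kts; kss <- params$kss
  Cl <- params$Cce_l; Cs <- params$Cce_s
  L0 <- params$L0; flw <- params$fl_width
  wfrac <- kss / (kss + 2 * kts)
  Xts <- numeric(n); Xce <- numeric(n); vce <- numeric(n)
  Fce <- numeric(n); Fss <- numeric(n)
  xts <- 0; xce <- 0; v <- 0
  if (n >= 2L) for (i in 2:n) {
    z <- (Xm[i] - L0) / (flw * L0)
    fl <- 1 - z * z
    if (fl < 0) fl <- 0
    fce <- act[i] * fl * P0
    cce <- if (v < 0) Cs else Cl
    v <- 2 * (kts * xts - fce) / cce
    xts <- xts + dt * wfrac * ((Xm[i] - Xm[i - 1]) / dt - v)
    if (xts < 0) xts <- 0
    xce <- xce + v * dt
    Xts[i] <- xts; Xce[i] <- xce; vce[i] <- v
    Fce[i] <- fce; Fss[i] <- 2 * kts * xts
  }
  if (!all(is.finite(Xts)))
    wfh_abort(sprintf("non-finite titin state at sample %d",
                      which(!is.finite(Xts))[1L]), "wfh_numerical_error")
  data.frame(time_s = (seq_len(n) - 1L) * dt, Xm_cm = Xm, act = act,
             Fce_N = Fce, Fts_N = kts * Xts, Fss_N = Fss,
             Xce_cm = Xce, Xp_cm = Xm - 2 * kts * Xts / kss, Xts_cm = Xts)
}

#' Isometric force-development protocol
#'
#' Activates a muscle from rest at constant length and activation and
#' records the output (series-spring) force at 500 Hz. Under constant
#' drive the force rises monotonically and settles at `2 * Fce`.
#'
#' @param params A [muscle_params()] object.
#' @param act Constant activation in `[0, 1]`.
#' @param Xm Constant muscle-tendon length, cm.
#' @param duration Protocol duration, s (> 0).
#' @param dt Time step, s.
#' @return A `data.frame` force trace with columns `time_s, Xm_cm, act,
#'   Fce_N, Fts_N, Fss_N, Xce_cm, Xp_cm, Xts_cm`.
#' @export
run_isometric <- function(params, act, Xm, duration, dt = 1 / 500) {
  if (!is.finite(duration) || duration <= 0)
    wfh_abort("'duration' must be positive", "wfh_parameter_error")
  n <- max(2L, as.integer(round(duration / dt)) + 1L)
  simulate_muscle(params, rep(Xm, n), rep(act, n), dt)
}

#' Ramp-and-hold stretch/shortening protocol
#'
#' The classic history-dependence protocol: the muscle is activated at
#' length `Xm0`, allowed to develop force for `settle` seconds, stretched
#' (`amplitude > 0`) or shortened (`amplitude < 0`) at constant speed, and
#' held at the final length. The force read `measure_offset` seconds after
#' the ramp ends is compared against a purely isometric contraction at the
#' same final length: active stretch leaves it elevated (residual force
#' enhancement), active shortening leaves it depressed.
#'
#' @param params A [muscle_params()] object.
#' @param act Constant activation in `[0, 1]`.
#' @param Xm0 Initial length, cm.
#' @param velocity Ramp speed magnitude, cm/s (> 0 when `amplitude != 0`).
#' @param amplitude Signed length change, cm (positive = stretch; 0 is
#'   allowed and degenerates to an isometric run).
#' @param hold Hold duration after the ramp, s (>= `measure_offset`).
#' @param settle Activation period before the ramp, s.
#' @param measure_offset Time after ramp end at which the post-hold force is
#'   read, s.
#' @param dt Time step, s.
#' @return A list with `trace` (the full force trace), `post_hold_force`
#'   (N), `t_measure` (s) and the ramp timing, class `ramp_hold_result`.
#' @export
run_ramp_hold <- function(params, act, Xm0, velocity, amplitude, hold,
                          settle = 3, measure_offset = 1, dt = 1 / 500) {
  if (amplitude != 0 && (!is.finite(velocity) || velocity <= 0))
    wfh_abort("'velocity' must be positive for a nonzero ramp",
              "wfh_parameter_error")
  if (!is.finite(hold) || hold <= 0 || hold < measure_offset)
    wfh_abort("'hold' must be positive and at least 'measure_offset'",
              "wfh_parameter_error")
  n1 <- as.integer(round(settle / dt))
  n2 <- if (amplitude == 0) 0L else as.integer(round(abs(amplitude) / velocity / dt))
  n3 <- as.integer(round(hold / dt))
  Xm <- c(rep(Xm0, n1),
          Xm0 + seq_len(n2) * (amplitude / max(n2, 1L)),
          rep(Xm0 + amplitude, n3 + 1L))
  trace <- simulate_muscle(params, Xm, rep(act, length(Xm)), dt)
  t_ramp_end <- (n1 + n2) * dt
  t_measure <- t_ramp_end + measure_offset
  i <- which.min(abs(trace$time_s - t_measure))
  structure(list(trace = trace, post_hold_force = trace$Fss_N[i],
                 t_measure = trace$time_s[i], t_ramp_end = t_ramp_end),
            class = "ramp_hold_result")
}

#' @export
print.ramp_hold_result <- function(x, ...) {
  cat(sprintf("<ramp_hold_result: Fss = %.2f N at t = %.3f s (ramp ended %.3f s)>\n",
              x$post_hold_force, x$t_measure, x$t_ramp_end))
  invisible(x)
}

#' Write a force trace to CSV
#'
#' @param trace Force trace `data.frame` from [run_isometric()] or
#'   [run_ramp_hold()].
#' @param path Output file path.
#' @export
write_force_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
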