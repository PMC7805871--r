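#' Stage-based activation schedule
#'
#' Square-wave activation levels for the two virtual muscles in each stage
#' of the gait cycle: early swing (2), late swing (3), early stance (4),
#' late stance (5) and powered plantarflexion (6). The anterior muscle is
#' active from early swing through early stance (dorsiflexor activity), the
#' posterior muscle only during powered plantarflexion; at most one muscle
#' is active at a time and late stance is a passive gap.
#'
#' @param act_A Named or positional numeric vector of anterior activations
#'   for stages 2..6, each in `[0, 1]`; stages 5 and 6 must be 0.
#' @param act_P Posterior activations for stages 2..6; stages 2..5 must
#'   be 0.
#' @param profile Text label for the preset.
#' @return An object of class `activation_schedule`.
#' @export
activation_schedule <- function(act_A, act_P, profile = "custom") {
  if (length(act_A) != 5L || length(act_P) != 5L)
    wfh_abort("activation vectors must cover stages 2..6 (length 5)",
              "wfh_parameter_error")
  if (any(!is.finite(c(act_A, act_P))) ||
      any(c(act_A, act_P) < 0) || any(c(act_A, act_P) > 1))
    wfh_abort("activations must lie in [0, 1] (schedule)",
              "wfh_parameter_error")
  if (any(act_A[4:5] != 0))
    wfh_abort("anterior activation must be 0 in stages 5 and 6 (schedule)",
              "wfh_parameter_error")
  if (any(act_P[1:4] != 0))
    wfh_abort("posterior activation must be 0 in stages 2..5 (schedule)",
              "wfh_parameter_error")
  structure(list(act_A = stats::setNames(as.numeric(act_A), 2:6),
                 act_P = stats::setNames(as.numeric(act_P), 2:6),
                 profile = profile),
            class = "activation_schedule")
}

#' @export
print.activation_schedule <- function(x, ...) {
  cat(sprintf("<activation_schedule: profile %s>\n", x$profile))
  m <- rbind(anterior = x$act_A, posterior = x$act_P)
  colnames(m) <- paste0("stage", 2:6)
  print(m)
  invisible(x)
}

#' Shipped subject activation presets
#'
#' The two tuned activation profiles (one per subject). Profile 1: anterior
#' 0.93/0.28/0.31 in stages 2/3/4, posterior 0.44 in stage 6. Profile 2:
#' anterior 0.63/0.48/0.51, posterior 0.69.
#'
#' @param profile 1 or 2.
#' @return An [activation_schedule()] object.
#' @export
default_activation_schedule <- function(profile = 1) {
  if (profile == 1) {
    activation_schedule(act_A = c(0.93, 0.28, 0.31, 0, 0),
                        act_P = c(0, 0, 0, 0, 0.44), profile = "1")
  } else if (profile == 2) {
    activation_schedule(act_A = c(0.63, 0.48, 0.51, 0, 0),
                        act_P = c(0, 0, 0, 0, 0.69), profile = "2")
  } else {
    wfh_abort("profile must be 1 or 2", "wfh_parameter_error")
  }
}

#' Activation lookup for a gait stage
#'
#' @param stage Gait-stage label(s) in `{2, 3, 4, 5, 6}`. Vectorised.
#' @param schedule An [activation_schedule()] object.
#' @return For scalar input a named vector `c(act_A, act_P)`; for vector
#'   input a matrix with columns `act_A`, `act_P`.
#' @export
activation_at <- function(stage, schedule) {
  if (any(!stage %in% 2:6))
    wfh_abort("unknown gait stage label (allowed: 2..6)", "wfh_input_error")
  key <- as.character(stage)
  out <- cbind(act_A = schedule$act_A[key], act_P = schedule$act_P[key])
  rownames(out) <- NULL
  if (length(stage) == 1L)
    c(act_A = unname(out[1L, 1L]), act_P = unname(out[1L, 2L]))
  else out
}

# Optional linear ramp smoothing of a square-wave activation channel:
# each sample becomes the mean of the raw channel over a trailing window.
smooth_activation <- function(act, window_samples) {
  if (window_samples <= 1L) return(act)
  stats::filter(c(rep(act[1L], window_samples - 1L), act),
                rep(1 / window_samples, window_samples),
                sides = 1)[window_samples - 1L + seq_along(act)]
}
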