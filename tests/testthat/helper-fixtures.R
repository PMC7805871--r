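# Shared fixtures: shipped defaults, built once per test run.
default_cfg <- load_config()
pA <- default_cfg$params_A
pP <- default_cfg$params_P
geom0 <- default_cfg$geom
sched1 <- default_cfg$schedules$profile1

# Step a muscle along (Xm, act) vectors with advance_state, returning the
# Fss trace. Used as the slow reference for the vectorised simulator.
step_trace <- function(params, Xm, act, dt = 1 / 500, refinement = 1L) {
  s <- init_state(params, Xm[1L])
  Fss <- numeric(length(Xm))
  for (i in seq_along(Xm)[-1L]) {
    s <- oracle_advance(s, Xm[i], act[i], dt, params, refinement)
    Fss[i] <- s$Fss
  }
  Fss
}

# Dominant net-moment peaks within stance of a 100-point normalised stride:
# local maxima with prominence of at least 10% of the cycle's moment range.
stance_moment_peaks <- function(stride100) {
  pk <- find_peaks(stride100$moment_Nm, min_height = -Inf,
                   min_prominence = 0.10)
  pk[stride100$stage[pk] %in% c(4L, 5L, 6L)]
}

zero_schedule <- activation_schedule(rep(0, 5), rep(0, 5), profile = "off")
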