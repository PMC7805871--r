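test_that("stride segmentation cuts at stage 3 -> 4 transitions", {
  traj <- make_transition_bout(seed = 2)
  strides <- segment_strides(traj)
  expect_length(strides, 8)
  st <- traj$stage
  interior <- which(st[-1L] == 4L & st[-length(st)] == 3L) + 1L
  expect_equal(attr(strides, "boundaries"), c(1L, interior))
  # a trace without any heel strike yields zero strides with a warning
  flat <- data.frame(time_s = seq(0, 1, by = 0.01),
                     stage = rep(5L, 101), theta_deg = 0)
  expect_warning(out <- segment_strides(flat), "heel-strike")
  expect_length(out, 0)
})

test_that("cycle normalisation keeps endpoints, affine signals and idempotence", {
  traj <- make_level_walking("medium", n_strides = 2, seed = 8)
  s <- segment_strides(traj)[[1]]
  r <- resample_stride(s)
  expect_equal(nrow(r), 100)
  expect_equal(r$theta_deg[1], s$theta_deg[1])
  expect_equal(r$theta_deg[100], s$theta_deg[nrow(s)])
  # linear ramp in, linear ramp out (linear interpolation is exact)
  ramp <- data.frame(time_s = seq(0, 1, length.out = 37),
                     theta_deg = seq(-5, 10, length.out = 37),
                     stage = rep(4L, 37))
  rr <- resample_stride(ramp)
  expect_equal(rr$theta_deg, seq(-5, 10, length.out = 100), tolerance = 1e-12)
  # already-uniform 100-sample stride is reproduced exactly
  u <- data.frame(time_s = seq(0, 1, length.out = 100),
                  theta_deg = sin(seq(0, 2 * pi, length.out = 100)),
                  stage = rep(4L, 100))
  expect_equal(resample_stride(u)$theta_deg, u$theta_deg, tolerance = 1e-12)
  expect_error(resample_stride(u[1, ]), class = "wfh_input_error")
})

test_that("ankle power matches the analytic product for a known angle waveform", {
  t <- seq(0, 2, by = 1 / 500)
  A <- 10; f <- 1
  trace <- structure(
    data.frame(time_s = t, theta_deg = A * sin(2 * pi * f * t),
               stage = rep(5L, length(t)), moment_Nm = 0.8 * 82,
               moment_Nm_per_kg = 0.8, power_W_per_kg = NA,
               Fss_A_N = 0, Fss_P_N = 0),
    mass_kg = 82, class = c("moment_trace", "data.frame"))
  pw <- ankle_power(trace)
  analytic <- 0.8 * (-(A * pi / 180) * 2 * pi * f * cos(2 * pi * f * t))
  i <- 2:(length(t) - 1L)
  expect_equal(pw[i], analytic[i], tolerance = 1e-3)
  # constant angle: zero power everywhere
  trace$theta_deg <- 5
  expect_equal(ankle_power(trace), rep(0, length(t)))
  attr(trace, "mass_kg") <- NA_real_
  trace$moment_Nm_per_kg <- NA_real_
  expect_error(ankle_power(trace), class = "wfh_config_error")
})

test_that("power is generated during powered plantarflexion of a level stride", {
  traj <- make_level_walking("medium", n_strides = 3, seed = 3)
  out <- run_controller(traj, pA, pP, geom0, sched1)
  s <- resample_stride(segment_strides(out)[[2]])
  pp <- s$stage == 6L
  expect_gt(max(s$power_W_per_kg[pp]), 0)
  expect_equal(max(s$power_W_per_kg[pp]), max(s$power_W_per_kg))
})

test_that("stride summaries aggregate with SEM and honour the generator peaks", {
  traj <- make_level_walking("fast", n_strides = 5,
                             shape = gait_shape_params(
                               stride_duration_s = 0.95, peak_pf_deg = -19,
                               midstance_df_deg = 12, noise_sd_deg = 0),
                             seed = 1)
  out <- run_controller(traj, pA, pP, geom0, sched1)
  strides <- segment_strides(out)
  sm <- stride_summary(strides)
  expect_equal(nrow(sm$per_stride), 5)
  # identical repeated strides: SEM exactly zero
  sm_same <- stride_summary(strides[c(3, 3, 3)])
  expect_equal(unname(sm_same$sem), rep(0, 4))
  # noise-free bout: the angle waveform repeats exactly, so the kinematic
  # metrics have zero spread (muscle-state carryover only affects kinetics)
  expect_equal(unname(sm$sem[["peak_plantarflexion_deg"]]), 0)
  expect_equal(unname(sm$sem[["duration_s"]]), 0, tolerance = 1e-10)
  # generator round-trip: stance plantarflexion peak equals the configured one
  expect_equal(unname(sm$mean[["peak_plantarflexion_deg"]]), -19,
               tolerance = 0.1 / 19)
  # single stride: mean is that stride, SEM flagged zero
  one <- stride_summary(strides[1])
  expect_true(one$single_stride)
  expect_equal(unname(one$sem), rep(0, 4))
  expect_equal(one$mean, unlist(sm$per_stride[1, -1]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # aggregates are invariant to stride order
  sm_rev <- stride_summary(rev(strides))
  expect_equal(sm_rev$mean, sm$mean)
  expect_equal(sm_rev$sem, sm$sem)
  expect_error(stride_summary(list()), class = "wfh_input_error")
})

test_that("a passive cycle absorbs net energy", {
  traj <- make_level_walking("medium", n_strides = 4,
                             shape = gait_shape_params(noise_sd_deg = 0),
                             seed = 1)
  out <- run_controller(traj, pA, pP, geom0, zero_schedule)
  s <- segment_strides(out)[[3]]
  work <- sum(s$power_W_per_kg) * stats::median(diff(s$time_s))
  expect_lte(work, 1e-6)
})
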