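test_that("law-of-cosines lengths match hand-computed triangles and the collinear limit", {
  L <- muscle_lengths(0, geom0)   # both included angles are 90 degrees
  expect_equal(L[["Lm_A"]], sqrt(29^2 + 4^2), tolerance = 1e-12)
  expect_equal(L[["Lm_P"]], sqrt(33^2 + 5.5^2), tolerance = 1e-12)
  expect_equal(L[["Lm_A"]], 29.2746, tolerance = 1e-4)
  # near-collinear: length approaches SAL + FMA
  g <- ankle_geometry(29, 33, 4, 5.5, gamma0_A = 179.999, gamma0_P = 90)
  expect_equal(muscle_lengths(0, g)[["Lm_A"]], 33, tolerance = 1e-6)
  expect_error(muscle_lengths(95, geom0), class = "wfh_domain_error")
  g2 <- ankle_geometry(29, 33, 4, 5.5, gamma0_A = 30, gamma0_P = 90)
  expect_error(muscle_lengths(40, g2), class = "wfh_geometry_error")
})

test_that("anterior and posterior lengths change in strictly opposite directions", {
  th <- seq(-25, 15, length.out = 400)
  L <- muscle_lengths(th, geom0)
  dA <- diff(L[, "Lm_A"]); dP <- diff(L[, "Lm_P"])
  expect_true(all(dA < 0))  # dorsiflexion shortens the anterior muscle
  expect_true(all(dP > 0))  # and lengthens the posterior muscle
  expect_true(all(dA * dP < 0))
})

test_that("moment arms equal the analytic and numerical dL/dtheta", {
  r0 <- moment_arms(0, geom0)
  expect_equal(r0[["r_A"]], 29 * 4 / sqrt(857), tolerance = 1e-12)
  expect_equal(r0[["r_A"]], 3.9625, tolerance = 1e-4)
  expect_equal(r0[["r_P"]], 33 * 5.5 / sqrt(1119.25), tolerance = 1e-12)
  expect_equal(r0[["r_P"]], 5.4252, tolerance = 1e-4)
  th <- seq(-25, 15, length.out = 1000)
  r <- moment_arms(th, geom0)
  h <- 1e-5 * 180 / pi   # 1e-5 rad expressed in degrees
  num_A <- (muscle_lengths(th + h, geom0)[, "Lm_A"] -
              muscle_lengths(th - h, geom0)[, "Lm_A"]) / (2e-5)
  num_P <- (muscle_lengths(th + h, geom0)[, "Lm_P"] -
              muscle_lengths(th - h, geom0)[, "Lm_P"]) / (2e-5)
  expect_lt(max(abs(abs(num_A) - r[, "r_A"]) / r[, "r_A"]), 1e-6)
  expect_lt(max(abs(abs(num_P) - r[, "r_P"]) / r[, "r_P"]), 1e-6)
  # constant-arm mode returns the tabulated foot moment arms
  rc <- moment_arms(th, geom0, constant_arm = TRUE)
  expect_true(all(rc[, "r_A"] == 4) && all(rc[, "r_P"] == 5.5))
})

test_that("attachment angles close each triangle to 180 degrees", {
  a <- attachment_angles(0, geom0)
  expect_equal(a$angle_shank_deg[1], atan(4 / 29) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(a$angle_shank_deg[1], 7.855, tolerance = 1e-3)
  sums <- a$angle_shank_deg + a$angle_foot_deg + a$gamma_deg
  expect_equal(sums, c(180, 180), tolerance = 1e-9)
  # isosceles triangle: the two non-included angles are equal
  gi <- ankle_geometry(10, 10, 10, 10)
  ai <- attachment_angles(7, gi)
  expect_equal(ai$angle_shank_deg, ai$angle_foot_deg, tolerance = 1e-9)
})

test_that("stage activation lookup reproduces the tuned profiles exclusively", {
  expect_equal(activation_at(6, sched1), c(act_A = 0, act_P = 0.44))
  expect_equal(activation_at(5, sched1), c(act_A = 0, act_P = 0))
  expect_equal(activation_at(2, sched1), c(act_A = 0.93, act_P = 0))
  s2 <- default_activation_schedule(2)
  expect_equal(activation_at(6, s2), c(act_A = 0, act_P = 0.69))
  expect_equal(activation_at(2, s2), c(act_A = 0.63, act_P = 0))
  expect_error(activation_at(1, sched1), class = "wfh_input_error")
  expect_error(activation_at(7, sched1), class = "wfh_input_error")
  # at most one muscle may be active in any stage, for both profiles
  for (s in list(sched1, s2)) {
    acts <- activation_at(2:6, s)
    expect_true(all(rowSums(acts > 0) <= 1))
  }
  expect_error(activation_schedule(c(0.9, 0.3, 0.3, 0.1, 0), rep(0, 5)),
               class = "wfh_parameter_error")
  expect_error(activation_schedule(rep(0, 5), c(0, 0, 0, 0, 1.2)),
               class = "wfh_parameter_error")
})

test_that("net moment combines antagonist pulls with plantarflexion positive", {
  expect_equal(net_ankle_moment(0, 0, 0, geom0), 0)
  expect_equal(net_ankle_moment(0, 1200, 0, geom0, constant_arm = TRUE), 66)
  # balanced antagonists cancel exactly
  r <- moment_arms(5, geom0)
  expect_equal(net_ankle_moment(1000, 1000 * r[["r_A"]] / r[["r_P"]], 5,
                                geom0), 0, tolerance = 1e-12)
  # anterior pull alone gives a dorsiflexion (negative) moment
  expect_lt(net_ankle_moment(500, 0, 0, geom0), 0)
  expect_error(net_ankle_moment(-1, 0, 0, geom0), class = "wfh_domain_error")
})

test_that("controller output is passive without activation and bit-reproducible", {
  t <- seq(0, 2, by = 1 / 500)
  traj <- gait_trajectory(t, 2 * sin(2 * pi * t / 2), rep(5L, length(t)),
                          mass_kg = 82)
  out <- run_controller(traj, pA, pP, geom0, zero_schedule)
  expect_lt(max(abs(out$moment_Nm)), 3)  # small passive viscous transients
  traj2 <- make_level_walking("medium", n_strides = 2, seed = 4)
  a <- run_controller(traj2, pA, pP, geom0, sched1)
  b <- run_controller(traj2, pA, pP, geom0, sched1)
  expect_identical(a, b)
  expect_equal(nrow(a), nrow(traj2))
  expect_true(all(is.finite(a$moment_Nm_per_kg)))
  expect_true(all(is.finite(a$power_W_per_kg)))
})
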