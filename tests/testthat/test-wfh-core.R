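test_that("force-length relation is a clipped symmetric parabola with unit plateau", {
  expect_equal(force_length(pP$L0, pP), 1)
  expect_equal(force_length(pP$L0 * (1 + pP$fl_width), pP), 0)
  expect_equal(force_length(pP$L0 * (1 + pP$fl_width / 2), pP), 0.75)
  # symmetry about L0 and non-negativity
  d <- seq(0.05, 0.9, by = 0.05)
  expect_equal(force_length(pP$L0 * (1 + d), pP),
               force_length(pP$L0 * (1 - d), pP))
  expect_true(all(force_length(pP$L0 * seq(0.1, 3, by = 0.1), pP) >= 0))
  expect_error(force_length(0, pP), class = "wfh_domain_error")
  expect_error(force_length(-1, pP), class = "wfh_domain_error")
})

test_that("contractile force is act * fl * P0 with the published posterior peak", {
  expect_equal(contractile_force(0, 17, pP), 0)
  expect_equal(contractile_force(1, pP$L0, pP), 1654)
  expect_equal(contractile_force(0.44, pP$L0, pP), 727.76)
  expect_true(all(contractile_force(runif(20), pP$L0 * runif(20, 0.6, 1.4),
                                    pP) <= pP$P0))
  expect_error(contractile_force(1.2, pP$L0, pP),
               class = "wfh_parameter_error")
  expect_error(contractile_force(-0.1, pP$L0, pP),
               class = "wfh_parameter_error")
})

test_that("superposition velocity cancels the titin term and matches direct evaluation", {
  mk_state <- function(Xm, Xp, Xts) {
    muscle_state(t = 0, Xm = Xm, Xce = 0, Xp = Xp, Xts = Xts, vce = 0,
                 Fce = 0, Fts = pP$kts * Xts, Fss = pP$kss * (Xm - Xp),
                 act = 0.5)
  }
  # zero-force worked value: kss*(Xm - Xp)/Cce = 1559*0.1/57
  s <- mk_state(33.5, 33.4, 0.3)
  expect_equal(ce_velocity(s, Fce = 0, Cce = 57, pP), 1559 * 0.1 / 57,
               tolerance = 1e-12)
  # balanced: kss*(Xm - Xp) = 2*Fce
  Fb <- pP$kss * 0.1 / 2
  expect_equal(ce_velocity(s, Fce = Fb, Cce = 57, pP), 0, tolerance = 1e-12)
  # changing Xts alone never changes the output (exact cancellation)
  s2 <- mk_state(33.5, 33.4, 0.3 + 0.123)
  expect_identical(ce_velocity(s, 100, 57, pP), ce_velocity(s2, 100, 57, pP))
  expect_error(ce_velocity(s, 0, 0, pP), class = "wfh_parameter_error")
  expect_error(ce_velocity(s, 0, -5, pP), class = "wfh_parameter_error")
})

test_that("damping coefficient follows the CE direction with a lengthening tie-break", {
  expect_equal(select_damping(+1, pA), 97)
  expect_equal(select_damping(-1, pP), 57)
  expect_equal(select_damping(0, pA), pA$Cce_l)
  expect_equal(select_damping(0, pP), pP$Cce_l)
})

test_that("rest state is passive and is an exact fixed point of the update", {
  s0 <- init_state(pP, pP$L0)
  expect_equal(s0$Fss, 0)
  expect_equal(s0$Fts, 0)
  expect_equal(s0$Xts, 0)
  expect_equal(s0$Xp, s0$Xm)
  expect_error(init_state(pP, 0), class = "wfh_domain_error")
  expect_error(init_state(pP, -2), class = "wfh_domain_error")
  s <- s0
  for (i in 1:1000) s <- advance_state(s, pP$L0, 0, 1 / 500, pP)
  for (nm in c("Xce", "Xp", "Xts", "vce", "Fce", "Fts", "Fss"))
    expect_equal(s[[nm]], s0[[nm]], tolerance = 1e-12)
})

test_that("advance_state rejects invalid steps and activations", {
  s <- init_state(pP, pP$L0)
  expect_error(advance_state(s, pP$L0, 0.5, dt = 0, params = pP),
               class = "wfh_parameter_error")
  expect_error(advance_state(s, pP$L0, 0.5, dt = -1 / 500, params = pP),
               class = "wfh_parameter_error")
  expect_error(advance_state(s, pP$L0, 1.7, params = pP),
               class = "wfh_parameter_error")
  expect_error(advance_state(s, -3, 0.5, params = pP),
               class = "wfh_domain_error")
})

test_that("activation step at optimal length converges to Fss = 2 Fce with vanishing rotational residual", {
  # the anterior muscle's titin spring is softer relative to its damping,
  # so its development time constant is ~4x the posterior's
  for (p in list(pA, pP)) {
    dur <- if (identical(p, pA)) 15 else 5
    s <- init_state(p, p$L0)
    for (i in seq_len(dur * 500)) s <- advance_state(s, p$L0, 1, 1 / 500, p)
    Fce <- contractile_force(1, p$L0, p)
    expect_equal(s$Fss / (2 * Fce), 1, tolerance = 1e-3)
    Cce <- select_damping(s$vce, p)
    residual <- abs(p$kts * s$Xts - s$Fce - Cce * s$vce)
    expect_lt(residual, 1e-6 * p$P0)
  }
})

test_that("isometric protocol develops force monotonically and scales linearly in activation", {
  tr0 <- run_isometric(pP, 0, pP$L0, 1)
  expect_true(all(tr0$Fss_N == 0))
  tr1 <- run_isometric(pP, 1, pP$L0, 5)
  expect_false(is.unsorted(tr1$Fss_N))
  expect_equal(tr1$Fss_N[nrow(tr1)] / (2 * pP$P0), 1, tolerance = 1e-3)
  trA <- run_isometric(pP, 0.3, pP$L0, 6)
  trB <- run_isometric(pP, 0.6, pP$L0, 6)
  expect_equal(trB$Fss_N[nrow(trB)] / trA$Fss_N[nrow(trA)], 2,
               tolerance = 1e-6)
  expect_true(all(tr1$Xts_cm >= 0))
})

test_that("active stretch enhances and shortening depresses the post-hold force", {
  act <- 0.5
  for (p in list(pA, pP)) {
    iso <- function(L, t_total) {
      tr <- run_isometric(p, act, L, t_total)
      tr$Fss_N[nrow(tr)]
    }
    A <- 0.05 * p$L0
    up <- run_ramp_hold(p, act, p$L0 - A, velocity = 2, amplitude = A,
                        hold = 1.5)
    dn <- run_ramp_hold(p, act, p$L0 + A, velocity = 2, amplitude = -A,
                        hold = 1.5)
    ref <- iso(p$L0, up$t_measure)
    expect_gt(up$post_hold_force, ref)
    expect_lt(dn$post_hold_force, ref)
  }
  # zero amplitude degenerates to the isometric trace
  rh0 <- run_ramp_hold(pP, act, pP$L0, velocity = 2, amplitude = 0, hold = 1.5)
  iso_tr <- run_isometric(pP, act, pP$L0, max(rh0$trace$time_s))
  expect_equal(rh0$trace$Fss_N, iso_tr$Fss_N[seq_len(nrow(rh0$trace))],
               tolerance = 1e-12)
  expect_error(run_ramp_hold(pP, act, pP$L0, velocity = 0, amplitude = 1,
                             hold = 1.5), class = "wfh_parameter_error")
})

test_that("sub-stepped oracle reproduces the Euler step exactly at refinement 1", {
  traj <- make_level_walking("medium", n_strides = 1, seed = 2)
  Xm <- muscle_lengths(traj$theta_deg, geom0)[, "Lm_P"]
  act <- activation_at(traj$stage, sched1)[, "act_P"]
  idx <- seq(1, length(Xm), by = 5)[1:40]
  s1 <- init_state(pP, Xm[idx[1]]); s2 <- s1
  for (i in idx[-1L]) {
    s1 <- advance_state(s1, Xm[i], act[i], 1 / 100, pP)
    s2 <- oracle_advance(s2, Xm[i], act[i], 1 / 100, pP, refinement = 1L)
  }
  expect_identical(s1, s2)
  expect_error(oracle_advance(s1, Xm[2], 0.5, 1 / 500, pP, refinement = 0L),
               class = "wfh_parameter_error")
})

test_that("vectorised trajectory simulation matches the per-step public update", {
  traj <- make_level_walking("fast", n_strides = 1, seed = 9)
  Xm <- muscle_lengths(traj$theta_deg, geom0)[, "Lm_P"]
  act <- activation_at(traj$stage, sched1)[, "act_P"]
  fast <- wfhankle:::simulate_muscle(pP, Xm, act, 1 / 500)
  slow <- step_trace(pP, Xm, act, 1 / 500)
  expect_equal(fast$Fss_N, slow, tolerance = 1e-12)
})
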