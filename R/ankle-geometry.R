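#' Ankle-joint musculoskeletal geometry
#'
#' Describes the simplified hinge-ankle model: each virtual muscle is a
#' straight line from a shank attachment (at distance `SAL` from the joint
#' centre) to a foot attachment (at distance `FMA` from the joint centre).
#' The included angle between the shank and foot segments is `gamma0` at the
#' neutral ankle angle (theta = 0, foot perpendicular to shank) and changes
#' one-for-one with theta: dorsiflexion (theta > 0) closes the posterior
#' triangle and opens the anterior one.
#'
#' @param SAL_A,SAL_P Shank attachment lengths, anterior/posterior, cm.
#' @param FMA_A,FMA_P Foot moment arms, anterior/posterior, cm.
#' @param gamma0_A,gamma0_P Included shank-foot angle at theta = 0, degrees.
#' @return An object of class `ankle_geometry`.
#' @export
ankle_geometry <- function(SAL_A, SAL_P, FMA_A, FMA_P,
                           gamma0_A = 90, gamma0_P = 90) {
  for (nm in c("SAL_A", "SAL_P", "FMA_A", "FMA_P")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      wfh_abort(sprintf("'%s' must be a positive length in cm", nm),
                "wfh_parameter_error")
  }
  for (nm in c("gamma0_A", "gamma0_P")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v >= 180)
      wfh_abort(sprintf("'%s' must lie in (0, 180) degrees", nm),
                "wfh_parameter_error")
  }
  structure(list(SAL_A = SAL_A, SAL_P = SAL_P, FMA_A = FMA_A, FMA_P = FMA_P,
                 gamma0_A = gamma0_A, gamma0_P = gamma0_P),
            class = "ankle_geometry")
}

#' @export
print.ankle_geometry <- function(x, ...) {
  cat("<ankle_geometry>\n")
  cat(sprintf("  anterior : SAL = %g cm, FMA = %g cm, gamma0 = %g deg\n",
              x$SAL_A, x$FMA_A, x$gamma0_A))
  cat(sprintf("  posterior: SAL = %g cm, FMA = %g cm, gamma0 = %g deg\n",
              x$SAL_P, x$FMA_P, x$gamma0_P))
  invisible(x)
}

#' Published default ankle geometry
#'
#' Anterior: 29 cm shank attachment, 4 cm foot moment arm. Posterior: 33 cm
#' shank attachment, 5.5 cm foot moment arm. Neutral included angles of 90
#' degrees (foot perpendicular to shank at theta = 0).
#'
#' @return An [ankle_geometry()] object.
#' @export
default_ankle_geometry <- function() {
  ankle_geometry(SAL_A = 29, SAL_P = 33, FMA_A = 4, FMA_P = 5.5)
}

included_angles <- function(theta, geom) {
  gA <- geom$gamma0_A - theta
  gP <- geom$gamma0_P + theta
  if (any(gA <= 0 | gA >= 180 | gP <= 0 | gP >= 180))
    wfh_abort("included shank-foot angle outside (0, 180) degrees",
              "wfh_geometry_error")
  list(gA = gA, gP = gP)
}

check_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(abs(theta) >= 90))
    wfh_abort("'theta' must satisfy |theta| < 90 degrees", "wfh_domain_error")
}

#' Virtual muscle lengths from the ankle angle
#'
#' Law of cosines on each shank-foot triangle:
#' `Lm = sqrt(SAL^2 + FMA^2 - 2*SAL*FMA*cos(gamma))` with included angles
#' `gamma_A = gamma0_A - theta` and `gamma_P = gamma0_P + theta`.
#' Plantarflexion (theta decreasing) lengthens the anterior muscle and
#' shortens the posterior one; the two lengths always change in opposite
#' directions.
#'
#' @param theta Ankle angle, degrees (plantarflexion negative). Vectorised.
#' @param geom An [ankle_geometry()] object.
#' @return For scalar `theta` a named vector `c(Lm_A, Lm_P)` in cm; for
#'   vector input a matrix with columns `Lm_A`, `Lm_P`.
#' @export
muscle_lengths <- function(theta, geom) {
  check_theta(theta)
  g <- included_angles(theta, geom)
  LA <- sqrt(geom$SAL_A^2 + geom$FMA_A^2 -
               2 * geom$SAL_A * geom$FMA_A * cos(deg2rad(g$gA)))
  LP <- sqrt(geom$SAL_P^2 + geom$FMA_P^2 -
               2 * geom$SAL_P * geom$FMA_P * cos(deg2rad(g$gP)))
  if (length(theta) == 1L) c(Lm_A = LA, Lm_P = LP)
  else cbind(Lm_A = LA, Lm_P = LP)
}

#' Muscle moment arms about the ankle
#'
#' Virtual-work moment arm `r = |dLm/dtheta|` (theta in radians), which for
#' the straight-line muscle equals `SAL * FMA * sin(gamma) / Lm` -- the
#' perpendicular distance from the joint centre to the muscle's line of
#' action. Near gamma = 90 degrees this is approximately the constant foot
#' moment arm `FMA`.
#'
#' @inheritParams muscle_lengths
#' @param constant_arm If `TRUE`, return the constant foot moment arms
#'   (`FMA_A`, `FMA_P`) instead of the geometric arms.
#' @return For scalar `theta` a named vector `c(r_A, r_P)` in cm; for vector
#'   input a matrix with columns `r_A`, `r_P`.
#' @export
moment_arms <- function(theta, geom, constant_arm = FALSE) {
  check_theta(theta)
  if (constant_arm) {
    rA <- rep(geom$FMA_A, length(theta))
    rP <- rep(geom$FMA_P, length(theta))
  } else {
    g <- included_angles(theta, geom)
    L <- muscle_lengths(theta, geom)
    if (length(theta) == 1L) L <- rbind(L)
    rA <- geom$SAL_A * geom$FMA_A * sin(deg2rad(g$gA)) / L[, "Lm_A"]
    rP <- geom$SAL_P * geom$FMA_P * sin(deg2rad(g$gP)) / L[, "Lm_P"]
  }
  if (length(theta) == 1L) c(r_A = rA[[1L]], r_P = rP[[1L]])
  else cbind(r_A = rA, r_P = rP)
}

#' Muscle attachment angles from the law of sines
#'
#' Interior angles of each shank-foot-muscle triangle at the shank and foot
#' attachment points. The angle sum of each triangle (shank angle + foot
#' angle + included angle gamma) is 180 degrees.
#'
#' @inheritParams muscle_lengths
#' @param theta Scalar ankle angle, degrees.
#' @return A `data.frame` with rows `anterior` (alpha) and `posterior`
#'   (beta) and columns `angle_shank_deg`, `angle_foot_deg`, `gamma_deg`.
#' @export
attachment_angles <- function(theta, geom) {
  stopifnot(length(theta) == 1L)
  check_theta(theta)
  g <- included_angles(theta, geom)
  L <- muscle_lengths(theta, geom)
  shank_A <- rad2deg(asin(geom$FMA_A * sin(deg2rad(g$gA)) / L[["Lm_A"]]))
  shank_P <- rad2deg(asin(geom$FMA_P * sin(deg2rad(g$gP)) / L[["Lm_P"]]))
  data.frame(muscle = c("anterior", "posterior"),
             angle_shank_deg = c(shank_A, shank_P),
             angle_foot_deg = c(180 - g$gA - shank_A, 180 - g$gP - shank_P),
             gamma_deg = c(g$gA, g$gP))
}

#' Net ankle moment from the two muscle forces
#'
#' `M = (Fss_P * r_P - Fss_A * r_A) / 100` in N·m (the division converts the
#' cm moment arms to m). Plantarflexion moment is positive: the posterior
#' muscle plantarflexes, the anterior muscle dorsiflexes.
#'
#' @param Fss_A,Fss_P Series-spring (output) forces of the anterior and
#'   posterior muscles, N (>= 0; muscles pull only). Vectorised.
#' @param theta Ankle angle, degrees (same length as the forces or scalar).
#' @param geom An [ankle_geometry()] object.
#' @param constant_arm Passed to [moment_arms()].
#' @return Net ankle moment, N·m.
#' @export
net_ankle_moment <- function(Fss_A, Fss_P, theta, geom,
                             constant_arm = FALSE) {
  if (any(Fss_A < 0) || any(Fss_P < 0))
    wfh_abort("muscle forces must be non-negative (muscles pull only)",
              "wfh_domain_error")
  r <- moment_arms(theta, geom, constant_arm = constant_arm)
  if (length(theta) == 1L) r <- rbind(r)
  (Fss_P * r[, "r_P"] - Fss_A * r[, "r_A"]) / 100
}
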