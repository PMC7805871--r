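#' Winding-filament muscle parameters
#'
#' Constructs the constant parameter set of one virtual muscle-tendon unit:
#' a contractile element (CE) with peak isometric force `P0` and a parabolic
#' active force-length relation, a directional viscous damper in parallel
#' with the CE (`Cce_l` while the CE lengthens, `Cce_s` while it shortens),
#' a linear titin spring `kts` wound onto the thin-filament pulley by
#' activation, and a linear series spring `kss` (tendon and aponeurosis)
#' attached at the pulley axle.
#'
#' @param name Text label, e.g. `"anterior"` or `"posterior"`.
#' @param P0 Peak isometric force of the contractile element, N.
#' @param kts Titin spring constant, N/cm.
#' @param kss Series (tendon) spring constant, N/cm.
#' @param Cce_l CE damping constant during lengthening, N·s/cm.
#' @param Cce_s CE damping constant during shortening, N·s/cm.
#' @param L0 Optimal muscle-tendon length (force-length plateau), cm.
#' @param fl_width Half-width of the force-length parabola as a fraction of
#'   `L0`; active force reaches zero at `L0 * (1 +/- fl_width)`.
#'
#' @return An object of class `muscle_params`.
#' @seealso [default_muscle_params()] for the shipped anterior/posterior
#'   constants, [force_length()], [contractile_force()].
#' @export
muscle_params <- function(name, P0, kts, kss, Cce_l, Cce_s, L0,
                          fl_width = 0.5) {
  for (nm in c("P0", "kts", "kss", "Cce_l", "Cce_s", "L0", "fl_width")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      wfh_abort(sprintf("'%s' must be a single finite number", nm),
                "wfh_parameter_error")
    if (v <= 0)
      wfh_abort(sprintf("'%s' must be positive (got %g)", nm, v),
                "wfh_parameter_error")
  }
  if (fl_width > 1)
    wfh_abort("'fl_width' must lie in (0, 1]", "wfh_parameter_error")
  structure(
    list(name = as.character(name)[1L], P0 = P0, kts = kts, kss = kss,
         Cce_l = Cce_l, Cce_s = Cce_s, L0 = L0, fl_width = fl_width),
    class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf("<muscle_params: %s>\n", x$name))
  cat(sprintf("  P0 = %g N   L0 = %g cm   fl_width = %g\n",
              x$P0, x$L0, x$fl_width))
  cat(sprintf("  kts = %g N/cm   kss = %g N/cm\n", x$kts, x$kss))
  cat(sprintf("  Cce_l = %g N.s/cm   Cce_s = %g N.s/cm\n", x$Cce_l, x$Cce_s))
  invisible(x)
}

#' Published default parameters for the two virtual shank muscle groups
#'
#' Returns the parameter set used on the prosthesis for the anterior
#' (tibialis anterior + synergists) or posterior (soleus, gastrocnemius,
#' plantaris) virtual muscle group. Spring and damping constants come from
#' local optimisation against recorded ankle torque; `P0` is scaled from
#' published human shank muscle cross-sectional areas.
#'
#' `L0` is not tabulated for the virtual muscles; by convention it is the
#' muscle-tendon length at the neutral ankle angle (theta = 0) computed from
#' the default ankle geometry, which places the operating point on the
#' force-length plateau at neutral stance.
#'
#' @param muscle `"anterior"` or `"posterior"`.
#' @param geom Ankle geometry used to derive `L0`; defaults to
#'   [default_ankle_geometry()].
#' @return A [muscle_params()] object.
#' @export
default_muscle_params <- function(muscle = c("anterior", "posterior"),
                                  geom = default_ankle_geometry()) {
  muscle <- match.arg(muscle)
  L <- muscle_lengths(0, geom)
  if (muscle == "anterior") {
    muscle_params("anterior", P0 = 1799, kts = 159, kss = 1499,
                  Cce_l = 97, Cce_s = 182, L0 = L[["Lm_A"]])
  } else {
    muscle_params("posterior", P0 = 1654, kts = 205, kss = 1559,
                  Cce_l = 102, Cce_s = 57, L0 = L[["Lm_P"]])
  }
}

#' Evolving state of a winding-filament muscle
#'
#' Bundles the time-varying quantities of one muscle-tendon unit. Created by
#' [init_state()] and advanced by [advance_state()]; not usually constructed
#' directly.
#'
#' Fields: `t` time (s); `Xm` muscle-tendon length input (cm); `Xce`
#' accumulated contractile-element displacement (cm); `Xp` pulley position
#' (cm); `Xts` titin spring elongation (cm, never negative); `vce` CE
#' velocity (cm/s); `act` activation in `[0, 1]`; derived forces `Fce`,
#' `Fts = kts * Xts` and `Fss = kss * (Xm - Xp)` (N).
#'
#' @param t,Xm,Xce,Xp,Xts,vce,Fce,Fts,Fss,act See description.
#' @return An object of class `muscle_state`.
#' @export
muscle_state <- function(t, Xm, Xce, Xp, Xts, vce, Fce, Fts, Fss, act) {
  if (Xts < 0)
    wfh_abort("titin elongation Xts must be >= 0", "wfh_state_error")
  if (act < 0 || act > 1)
    wfh_abort("activation must lie in [0, 1]", "wfh_state_error")
  structure(list(t = t, Xm = Xm, Xce = Xce, Xp = Xp, Xts = Xts, vce = vce,
                 Fce = Fce, Fts = Fts, Fss = Fss, act = act),
            class = "muscle_state")
}

#' @export
print.muscle_state <- function(x, ...) {
  cat(sprintf("<muscle_state t = %.4f s>\n", x$t))
  cat(sprintf("  Xm = %.4f  Xce = %.4f  Xp = %.4f  Xts = %.4f cm\n",
              x$Xm, x$Xce, x$Xp, x$Xts))
  cat(sprintf("  vce = %.4f cm/s  act = %.2f\n", x$vce, x$act))
  cat(sprintf("  Fce = %.2f  Fts = %.2f  Fss = %.2f N\n",
              x$Fce, x$Fts, x$Fss))
  invisible(x)
}

#' Initial passive rest state
#'
#' Builds the state of a fully relaxed muscle at length `Xm0`: no CE
#' displacement, titin unwound (`Xts = 0`), series spring slack
#' (`Xp = Xm0`), all forces zero.
#'
#' @param params A [muscle_params()] object.
#' @param Xm0 Initial muscle-tendon length, cm (> 0).
#' @return A [muscle_state()] at `t = 0`.
#' @export
init_state <- function(params, Xm0) {
  stopifnot(inherits(params, "muscle_params"))
  if (!is.numeric(Xm0) || length(Xm0) != 1L || !is.finite(Xm0) || Xm0 <= 0)
    wfh_abort("'Xm0' must be a single positive length in cm",
              "wfh_domain_error")
  muscle_state(t = 0, Xm = Xm0, Xce = 0, Xp = Xm0, Xts = 0, vce = 0,
               Fce = 0, Fts = 0, Fss = 0, act = 0)
}
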