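#' Coefficient of determination of a moment prediction
#'
#' `R^2 = 1 - SSE/SST` with the total sum of squares taken about the
#' reference mean. Can be negative for predictions worse than the
#' reference mean; equals 1 only for a perfect match.
#'
#' @param predicted,reference Equal-length numeric series (length >= 2);
#'   the reference must not be constant.
#' @return Dimensionless scalar `<= 1`.
#' @export
rsquared <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(reference) < 2L)
    wfh_abort("series must have equal length >= 2", "wfh_input_error")
  sst <- sum((reference - mean(reference))^2)
  if (sst == 0)
    wfh_abort("R^2 is undefined for a constant reference series",
              "wfh_input_error")
  1 - sum((predicted - reference)^2) / sst
}

# Tunable scalar parameters of the controller, as (object, field) pairs.
# Suffixes: _A anterior muscle, _P posterior.
tunable_parameters <- function() {
  c(P0_A = "muscle", kts_A = "muscle", kss_A = "muscle",
    Cce_l_A = "muscle", Cce_s_A = "muscle",
    P0_P = "muscle", kts_P = "muscle", kss_P = "muscle",
    Cce_l_P = "muscle", Cce_s_P = "muscle",
    SAL_A = "geometry", SAL_P = "geometry",
    FMA_A = "geometry", FMA_P = "geometry",
    act_A2 = "schedule", act_A3 = "schedule", act_A4 = "schedule",
    act_P6 = "schedule")
}

get_parameter <- function(name, params_A, params_P, geom, schedule) {
  kind <- tunable_parameters()[[name]]
  if (kind == "muscle") {
    side <- sub(".*_", "", name)
    field <- sub("_[AP]$", "", name)
    (if (side == "A") params_A else params_P)[[field]]
  } else if (kind == "geometry") {
    geom[[name]]
  } else {
    side <- substr(name, 5, 5)
    stg <- substr(name, 6, 6)
    (if (side == "A") schedule$act_A else schedule$act_P)[[stg]]
  }
}

set_parameter <- function(name, value, params_A, params_P, geom, schedule) {
  kind <- tunable_parameters()[[name]]
  if (kind == "muscle") {
    side <- sub(".*_", "", name)
    field <- sub("_[AP]$", "", name)
    p <- if (side == "A") params_A else params_P
    args <- list(name = p$name, P0 = p$P0, kts = p$kts, kss = p$kss,
                 Cce_l = p$Cce_l, Cce_s = p$Cce_s, L0 = p$L0,
                 fl_width = p$fl_width)
    args[[field]] <- value
    p <- do.call(muscle_params, args)
    if (side == "A") params_A <- p else params_P <- p
  } else if (kind == "geometry") {
    geom[[name]] <- value
    geom <- do.call(ankle_geometry, unclass(geom))
  } else {
    side <- substr(name, 5, 5)
    stg <- substr(name, 6, 6)
    aA <- schedule$act_A; aP <- schedule$act_P
    if (side == "A") aA[[stg]] <- value else aP[[stg]] <- value
    schedule <- activation_schedule(aA, aP, profile = schedule$profile)
  }
  list(params_A = params_A, params_P = params_P, geom = geom,
       schedule = schedule)
}

#' Fit controller parameters to a reference moment trace
#'
#' Bounded local optimisation (quasi-Newton, `stats::optim` method
#' `"L-BFGS-B"`) of the controller's `R^2` against a reference ankle-moment
#' series, over a chosen free-parameter list. Mirrors the tuning procedure
#' used on the prosthesis: peak isometric forces and spring/damping
#' constants are optimised; activation levels are user-tuned, not fitted,
#' and are therefore absent from the default free list.
#'
#' @param reference A `moment_trace` (or any data frame with `moment_Nm`)
#'   to fit against.
#' @param traj The driving [gait_trajectory()].
#' @param free Character vector of free parameter names, a subset of
#'   `names(tunable_parameters())` restricted to muscle parameters
#'   (`P0_*`, `kts_*`, `kss_*`, `Cce_l_*`, `Cce_s_*`).
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults to `[0.25x, 4x]` of the start value.
#' @param start_A,start_P Starting [muscle_params()] pair.
#' @param geom,schedule Fixed geometry and activation schedule.
#' @param seed Integer seed (recorded; the local search itself is
#'   deterministic given the start).
#' @param control Passed to [stats::optim()].
#' @return A list of class `fit_result`: fitted `params_A`/`params_P`,
#'   `r_squared`, `iterations`, `converged`, `seed`, `free`.
#' @export
fit_parameters <- function(reference, traj, free, bounds = NULL,
                           start_A, start_P, geom = default_ankle_geometry(),
                           schedule = default_activation_schedule(1),
                           seed = 1L, control = list()) {
  muscle_names <- names(tunable_parameters())[tunable_parameters() == "muscle"]
  if (!all(free %in% muscle_names))
    wfh_abort("free parameters must be muscle parameters (P0/kts/kss/Cce per muscle)",
              "wfh_parameter_error")
  set.seed(as.integer(seed))
  ref <- reference$moment_Nm
  objective_r2 <- function(pars) {
    st <- list(params_A = start_A, params_P = start_P, geom = geom,
               schedule = schedule)
    for (nm in names(pars))
      st <- set_parameter(nm, pars[[nm]], st$params_A, st$params_P,
                          st$geom, st$schedule)
    out <- run_controller(traj, st$params_A, st$params_P, st$geom,
                          st$schedule)
    rsquared(out$moment_Nm, ref)
  }
  start_vals <- vapply(free, get_parameter, numeric(1),
                       params_A = start_A, params_P = start_P,
                       geom = geom, schedule = schedule)
  if (!length(free)) {
    r2 <- objective_r2(stats::setNames(numeric(0), character(0)))
    return(structure(list(params_A = start_A, params_P = start_P,
                          r_squared = r2, iterations = 0L, converged = TRUE,
                          seed = seed, free = character(0)),
                     class = "fit_result"))
  }
  if (is.null(bounds))
    bounds <- stats::setNames(lapply(start_vals, function(v) c(v / 4, v * 4)),
                              free)
  lower <- vapply(free, function(nm) bounds[[nm]][1L], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2L], numeric(1))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    wfh_abort("parameter bounds must be finite", "wfh_parameter_error")
  best <- list(pars = start_vals, value = Inf)
  fn <- function(p) {
    names(p) <- free
    v <- tryCatch(-objective_r2(p), error = function(e) NA_real_)
    if (!is.finite(v)) return(1e6)  # search continues from feasible points
    if (v < best$value) best <<- list(pars = p, value = v)
    v
  }
  ctl <- utils::modifyList(list(parscale = abs(start_vals), maxit = 500L,
                                factr = 1e4, pgtol = 0), control)
  opt <- stats::optim(start_vals, fn, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctl)
  pars <- if (opt$value <= best$value) opt$par else best$pars
  names(pars) <- free
  st <- list(params_A = start_A, params_P = start_P, geom = geom,
             schedule = schedule)
  for (nm in free)
    st <- set_parameter(nm, pars[[nm]], st$params_A, st$params_P,
                        st$geom, st$schedule)
  structure(list(params_A = st$params_A, params_P = st$params_P,
                 r_squared = objective_r2(pars),
                 iterations = opt$counts[["function"]],
                 converged = opt$convergence == 0, seed = seed, free = free),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: R^2 = %.6f, %d evaluations, converged = %s>\n",
              x$r_squared, x$iterations, x$converged))
  if (length(x$free)) {
    vals <- vapply(x$free, get_parameter, numeric(1),
                   params_A = x$params_A, params_P = x$params_P,
                   geom = default_ankle_geometry(),
                   schedule = default_activation_schedule(1))
    print(round(vals, 4))
  }
  invisible(x)
}

#' One-at-a-time parameter sensitivity scan
#'
#' Each tunable controller parameter (muscle constants, geometry lengths
#' and activation levels) is scaled in turn over a grid of fractions of its
#' nominal value (default spanning 0.5% to 250%) while everything else is
#' held fixed; the perturbed controller output is compared to the reference
#' moment trace by `R^2`. A perturbed value that violates a model
#' invariant (e.g. an activation scaled above 1) or a failed simulation is
#' recorded as a missing `R^2` and the scan continues.
#'
#' @param params_A,params_P Nominal [muscle_params()] pair.
#' @param schedule Nominal [activation_schedule()].
#' @param traj Driving [gait_trajectory()].
#' @param reference Reference `moment_trace` (typically the nominal model's
#'   own output, in which case the fraction-1 rows have `R^2 = 1`).
#' @param grid Fractions in `(0, 2.5]`, must include 1.
#' @param geom Nominal [ankle_geometry()].
#' @param parameters Names to scan; default all of
#'   `names(tunable_parameters())`.
#' @return A data frame `parameter, fraction, r_squared` with exactly
#'   `length(parameters) * length(grid)` rows.
#' @export
sensitivity_scan <- function(params_A, params_P, schedule, traj, reference,
                             grid = c(0.005, 0.1, 0.25, 0.5, 0.75, 1,
                                      1.25, 1.5, 2, 2.5),
                             geom = default_ankle_geometry(),
                             parameters = names(tunable_parameters())) {
  if (any(grid <= 0) || any(grid > 2.5) || !any(grid == 1))
    wfh_abort("grid fractions must lie in (0, 2.5] and include 1.0",
              "wfh_parameter_error")
  ref <- reference$moment_Nm
  rows <- expand.grid(parameter = parameters, fraction = grid,
                      stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$parameter, parameters), rows$fraction), ]
  rows$r_squared <- vapply(seq_len(nrow(rows)), function(i) {
    nm <- rows$parameter[i]
    val <- get_parameter(nm, params_A, params_P, geom, schedule) *
      rows$fraction[i]
    tryCatch({
      st <- set_parameter(nm, val, params_A, params_P, geom, schedule)
      out <- run_controller(traj, st$params_A, st$params_P, st$geom,
                            st$schedule)
      rsquared(out$moment_Nm, ref)
    }, error = function(e) NA_real_)
  }, numeric(1))
  rownames(rows) <- NULL
  rows
}
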