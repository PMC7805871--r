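#' Segment a trace into strides at heel strike
#'
#' Heel strike is taken as the late-swing to early-stance (stage 3 -> 4)
#' label transition, the 0% point of the gait cycle. The bout start counts
#' as a heel strike when the trace begins in early stance; the trailing
#' segment is kept only when it ends in late swing (a complete cycle).
#' Partial leading/trailing cycles are dropped. When no stage 3 -> 4
#' transition exists at all, an empty list is returned with a warning.
#'
#' @param trace A [gait_trajectory()] or `moment_trace` (any data frame
#'   with `time_s` and `stage` columns).
#' @return A list of stride slices (data frames); attribute `boundaries`
#'   holds the heel-strike sample indices.
#' @export
segment_strides <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("time_s", "stage") %in% names(trace)))
  st <- trace$stage
  n <- length(st)
  hs <- which(st[-1L] == 4L & st[-n] == 3L) + 1L
  if (!length(hs)) {
    warning("no heel-strike (stage 3 -> 4) transition found; 0 strides")
    return(structure(list(), boundaries = integer(0)))
  }
  if (st[1L] == 4L) hs <- c(1L, hs)
  ends <- c(hs[-1L] - 1L, if (st[n] == 3L) n)
  starts <- hs[seq_along(ends)]
  out <- Map(function(a, b) trace[a:b, , drop = FALSE], starts, ends)
  structure(out, boundaries = starts)
}

#' Normalise a stride to the 0-100% gait cycle
#'
#' Linearly interpolates every numeric channel of a stride onto `n_points`
#' equally spaced cycle fractions over the stride duration, preserving the
#' endpoint samples. Label columns (`stage`) are carried by
#' nearest-neighbour lookup.
#'
#' @param stride One stride slice from [segment_strides()] (>= 2 samples).
#' @param n_points Number of output samples (default 100).
#' @return A data frame with `n_points` rows and an added `cycle_pct`
#'   column.
#' @export
resample_stride <- function(stride, n_points = 100) {
  if (!is.data.frame(stride) || nrow(stride) < 2L)
    wfh_abort("stride must have at least 2 samples", "wfh_input_error")
  t <- stride$time_s
  tt <- seq(t[1L], t[length(t)], length.out = n_points)
  out <- data.frame(cycle_pct = seq(0, 100, length.out = n_points))
  for (nm in setdiff(names(stride), "time_s")) {
    col <- stride[[nm]]
    if (nm == "stage") {
      out[[nm]] <- col[pmax(1L, findInterval(tt, t))]
    } else if (is.numeric(col)) {
      out[[nm]] <- stats::approx(t, col, xout = tt)$y
    }
  }
  cbind(time_s = tt, out)
}

#' Ankle power from a moment trace
#'
#' `power = moment (N·m/kg) x angular velocity (rad/s)`, with the angular
#' velocity taken in the plantarflexion-positive sense (`-dtheta/dt`) so
#' that power is positive (generation) during powered plantarflexion.
#' The angular velocity uses central finite differences with one-sided
#' differences at the ends.
#'
#' @param trace A `moment_trace` from [run_controller()].
#' @param mass_kg Body mass; defaults to the mass carried by the trace.
#' @return Power series, W/kg, one value per sample.
#' @export
ankle_power <- function(trace, mass_kg = attr(trace, "mass_kg")) {
  stopifnot(is.data.frame(trace))
  if (is.null(mass_kg) || is.na(mass_kg))
    wfh_abort("body mass is required to compute ankle power (W/kg)",
              "wfh_config_error")
  m <- if (!all(is.na(trace$moment_Nm_per_kg))) trace$moment_Nm_per_kg
       else trace$moment_Nm / mass_kg
  omega_pf <- -deg2rad(finite_diff(trace$theta_deg, trace$time_s))
  m * omega_pf
}

#' Per-stride summary metrics and their aggregate
#'
#' For each stride: peak ankle moment (N·m/kg), peak plantarflexion angle
#' during stance (degrees, negative), peak ankle power (W/kg, signed
#' maximum by default) and stride duration (s); plus the mean and standard
#' error of the mean over strides. With a single stride the SEM is
#' reported as 0 and flagged.
#'
#' @param strides List of stride slices from [segment_strides()] on a
#'   `moment_trace`.
#' @param mass_kg Body mass used when the slices carry only raw moments.
#' @param power_peak `"signed"` (default) takes the signed maximum of the
#'   power series; `"magnitude"` takes the maximum absolute value.
#' @return A list with `per_stride` (data frame, one row per stride),
#'   `mean`, `sem` (named vectors) and `single_stride` flag; class
#'   `stride_metrics`.
#' @export
stride_summary <- function(strides, mass_kg = NULL,
                           power_peak = c("signed", "magnitude")) {
  power_peak <- match.arg(power_peak)
  if (!length(strides))
    wfh_abort("at least one stride is required", "wfh_input_error")
  rows <- lapply(seq_along(strides), function(i) {
    s <- strides[[i]]
    mass <- if (!is.null(mass_kg)) mass_kg else attr(s, "mass_kg")
    stance <- s$stage %in% c(4L, 5L, 6L)
    has_moment <- "moment_Nm" %in% names(s)
    if (has_moment) {
      mkg <- if (!all(is.na(s$moment_Nm_per_kg))) s$moment_Nm_per_kg
             else if (!is.null(mass) && !is.na(mass)) s$moment_Nm / mass
             else rep(NA_real_, nrow(s))
      pw <- if (!all(is.na(mkg)))
        mkg * (-deg2rad(finite_diff(s$theta_deg, s$time_s)))
      else rep(NA_real_, nrow(s))
      pk_pw <- if (power_peak == "signed") max(pw) else max(abs(pw))
    } else {
      mkg <- NA_real_; pk_pw <- NA_real_
    }
    data.frame(stride = i,
               peak_moment_Nm_per_kg = if (has_moment) max(mkg) else NA_real_,
               peak_plantarflexion_deg = min(s$theta_deg[stance]),
               peak_power_W_per_kg = pk_pw,
               duration_s = s$time_s[nrow(s)] - s$time_s[1L] +
                 stats::median(diff(s$time_s)))
  })
  per_stride <- do.call(rbind, rows)
  vals <- per_stride[, -1L, drop = FALSE]
  structure(list(per_stride = per_stride,
                 mean = colMeans(vals),
                 sem = vapply(vals, function(x) as.numeric(sem(x)),
                              numeric(1)),
                 single_stride = nrow(per_stride) == 1L),
            class = "stride_metrics")
}

#' @export
print.stride_metrics <- function(x, ...) {
  cat(sprintf("<stride_metrics: %d stride(s)%s>\n", nrow(x$per_stride),
              if (x$single_stride) " [single stride: SEM reported as 0]"
              else ""))
  agg <- rbind(mean = x$mean, sem = x$sem)
  print(round(agg, 4))
  invisible(x)
}

#' Locate dominant peaks in a periodic signal
#'
#' Local maxima filtered by height and prominence, used to count
#' net-moment peaks per gait cycle (one for level walking, two for stair
#' ascent) and, on the negated angle, plantarflexion excursions.
#'
#' @param y Signal values over one cycle.
#' @param min_height Minimum peak height as a fraction of the cycle
#'   maximum (default 0.25).
#' @param min_prominence Minimum drop on both sides, as a fraction of the
#'   cycle range (default 0.10).
#' @return Integer indices of the detected peaks.
#' @export
find_peaks <- function(y, min_height = 0.25, min_prominence = 0.10) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] >= min_height * max(y)]
  if (length(cand) < 2L) return(cand)
  prom <- min_prominence * diff(range(y))
  # Iteratively merge a peak into its neighbour when the valley between
  # them does not drop at least `prom` below the lower of the two peaks.
  repeat {
    if (length(cand) < 2L) break
    drops <- vapply(seq_len(length(cand) - 1L), function(j) {
      valley <- min(y[cand[j]:cand[j + 1L]])
      min(y[cand[j]], y[cand[j + 1L]]) - valley
    }, numeric(1))
    j <- which.min(drops)
    if (drops[j] >= prom) break
    pair <- c(j, j + 1L)
    cand <- cand[-pair[which.min(y[cand[pair]])]]
  }
  cand
}
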