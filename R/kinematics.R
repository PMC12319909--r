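#' Cross-sectional area versus depth of a flow compartment
#'
#' Tabulates `A(x)` (cm^2) against depth `x` (cm), with `x = 0` at the bottom
#' of the first imaging slice and positive `x` pointing into the imaging
#' volume. Areas are linearly interpolated within the tabulated range and
#' clamped from below; outside the range the floor area is used, so the
#' velocity field is defined everywhere spins can travel.
#'
#' @param positions Strictly increasing depths in cm.
#' @param areas Areas in cm^2, same length as `positions`.
#' @param area_floor Minimum usable area in cm^2 (default 0.05); areas below
#'   it, and all positions outside the tabulated range, evaluate to it.
#' @return An object of class `area_profile`. The tabulated range must cover
#'   `x = 0`, where the reference area `A_slc1` is taken.
#' @export
area_profile <- function(positions, areas, area_floor = 0.05) {
  positions <- as.numeric(positions)
  areas <- as.numeric(areas)
  stopifnot(length(positions) == length(areas), length(positions) >= 2L,
            all(is.finite(positions)), all(is.finite(areas)),
            area_floor > 0)
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (positions[1L] > 0 || positions[length(positions)] < 0) {
    stop("tabulated positions must cover x = 0 (bottom of slice 1), ",
         "where the reference area is defined", call. = FALSE)
  }
  a_slc1 <- max(stats::approx(positions, areas, xout = 0)$y, area_floor)
  structure(list(positions = positions, areas = areas,
                 area_floor = area_floor, a_slc1 = a_slc1),
            class = "area_profile")
}

#' Straight-tube area profile
#'
#' Constant-area compartment (so the anatomy factor F(x) is 1 everywhere),
#' as used for flow-phantom analyses.
#'
#' @param area Tube cross-section in cm^2.
#' @param span Tabulated range in cm, covering 0.
#' @param area_floor Passed to [area_profile()].
#' @export
straight_tube <- function(area = 0.5, span = c(-50, 50), area_floor = 0.05) {
  area_profile(span, rep(area, 2L), area_floor = area_floor)
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf(
    "<area_profile> %d points over [%.3g, %.3g] cm, A(0)=%.3g cm^2, floor=%.3g\n",
    length(x$positions), min(x$positions), max(x$positions),
    x$a_slc1, x$area_floor))
  invisible(x)
}

#' Evaluate the (clamped) cross-sectional area
#'
#' @param profile An `area_profile`.
#' @param x Depths in cm (vectorized).
#' @return Areas in cm^2, never below `area_floor`.
#' @export
area_at <- function(profile, x) {
  a <- stats::approx(profile$positions, profile$areas, xout = x,
                     yleft = profile$area_floor,
                     yright = profile$area_floor)$y
  pmax(a, profile$area_floor)
}

#' Anatomy velocity factor F(x) = A_slc1 / A(x)
#'
#' Non-dimensional factor by which the entrance velocity at the bottom of
#' slice 1 is scaled at depth `x`, expressing incompressible plug flow
#' through a compartment of varying cross-section.
#'
#' @param x Depths in cm (vectorized).
#' @param profile An `area_profile`.
#' @export
f_factor <- function(x, profile) {
  profile$a_slc1 / area_at(profile, x)
}

# Volume coordinate s(x) = int_0^x A(u)/A_slc1 du, strictly increasing in x.
# Along any trajectory ds/dt = V(t), so s(x(t)) = s(x0) + int_0^t V dt: the
# separable ODE is solved exactly by composing these two monotone maps.
# The map is tabulated on a fine grid (trapezoid rule) with exact linear
# tails where the area is the constant floor.
build_s_map <- function(profile, dx = 0.002) {
  xs <- seq(profile$positions[1L], profile$positions[length(profile$positions)],
            by = dx)
  if (xs[length(xs)] < profile$positions[length(profile$positions)]) {
    xs <- c(xs, profile$positions[length(profile$positions)])
  }
  a <- area_at(profile, xs) / profile$a_slc1
  ds <- diff(xs) * (a[-1L] + a[-length(a)]) / 2
  s <- c(0, cumsum(ds))
  s <- s - stats::approx(xs, s, xout = 0)$y   # s(0) = 0
  slope_tail <- profile$area_floor / profile$a_slc1
  list(x = xs, s = s, slope_tail = slope_tail)
}

s_of_x <- function(smap, x) {
  n <- length(smap$x)
  out <- stats::approx(smap$x, smap$s, xout = x, rule = 2)$y
  lo <- x < smap$x[1L]
  hi <- x > smap$x[n]
  out[lo] <- smap$s[1L] + (x[lo] - smap$x[1L]) * smap$slope_tail
  out[hi] <- smap$s[n] + (x[hi] - smap$x[n]) * smap$slope_tail
  out
}

x_of_s <- function(smap, s) {
  n <- length(smap$x)
  out <- stats::approx(smap$s, smap$x, xout = s, rule = 2)$y
  lo <- s < smap$s[1L]
  hi <- s > smap$s[n]
  out[lo] <- smap$x[1L] + (s[lo] - smap$s[1L]) / smap$slope_tail
  out[hi] <- smap$x[n] + (s[hi] - smap$s[n]) / smap$slope_tail
  out
}

#' Velocity waveform at the entrance of the imaging volume
#'
#' Velocity (cm/s, signed, positive into the volume) at the bottom of the
#' first slice, on a uniform time grid.
#'
#' @param times Uniformly spaced times in seconds.
#' @param values Velocities in cm/s.
#' @return An object of class `velocity_waveform`, carrying the cumulative
#'   displacement integral used by the trajectory solver.
#' @export
velocity_waveform <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  stopifnot(length(times) == length(values), length(times) >= 2L,
            all(is.finite(times)), all(is.finite(values)))
  dt <- diff(times)
  if (any(abs(dt - dt[1L]) > 1e-9 * max(dt[1L], 1))) {
    stop("velocity waveform requires a uniform time grid", call. = FALSE)
  }
  disp <- c(0, cumsum(dt * (values[-1L] + values[-length(values)]) / 2))
  structure(list(times = times, values = values, displacement = disp),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf(
    "<velocity_waveform> %d samples over [%.4g, %.4g] s, range [%.3g, %.3g] cm/s\n",
    length(x$times), x$times[1L], x$times[length(x$times)],
    min(x$values), max(x$values)))
  invisible(x)
}

velocity_at <- function(waveform, t) {
  stats::approx(waveform$times, waveform$values, xout = t, rule = 2)$y
}

displacement_at <- function(waveform, t) {
  stats::approx(waveform$times, waveform$displacement, xout = t, rule = 2)$y
}

#' Integrate spin-ensemble trajectories through the velocity field
#'
#' Solves `dx/dt = F(x) V(t)` for each initial position. The default method
#' exploits that the equation is separable: in the volume coordinate
#' `s(x) = int_0^x A/A_slc1 du` every trajectory is
#' `s(x(t)) = s(x0) + int V dt`, which is evaluated exactly from the
#' tabulated monotone map (this also conserves mass exactly). An adaptive
#' Runge-Kutta solver (`method = "rk"`, via deSolve's "ode45") is available
#' as an independent numerical route.
#'
#' @param x0s Initial positions in cm.
#' @param waveform A [velocity_waveform()] covering `t_span`.
#' @param profile An [area_profile()].
#' @param t_span Length-2 vector `c(t0, t1)` in seconds.
#' @param method "separable" (default, exact) or "rk".
#' @param rtol,atol Tolerances for the "rk" method.
#' @return An object of class `spin_trajectories` whose positions can be
#'   queried densely at arbitrary times with [trajectory_positions()].
#' @export
integrate_trajectories <- function(x0s, waveform, profile, t_span,
                                   method = c("separable", "rk"),
                                   rtol = 1e-6, atol = 1e-8) {
  method <- match.arg(method)
  stopifnot(length(t_span) == 2L, t_span[2L] > t_span[1L],
            all(is.finite(x0s)))
  if (waveform$times[1L] > t_span[1L] + 1e-9 ||
      waveform$times[length(waveform$times)] < t_span[2L] - 1e-9) {
    stop("waveform does not cover the requested time span", call. = FALSE)
  }
  if (method == "separable") {
    smap <- build_s_map(profile)
    obj <- list(method = "separable", smap = smap, waveform = waveform,
                s0 = s_of_x(smap, x0s), t_span = t_span,
                u0 = displacement_at(waveform, t_span[1L]))
  } else {
    deriv <- function(t, x, parms) {
      list(f_factor(x, profile) * velocity_at(waveform, t))
    }
    tout <- seq(t_span[1L], t_span[2L],
                length.out = max(200L, ceiling(diff(t_span) * 20)))
    sol <- deSolve::ode(y = as.numeric(x0s), times = tout, func = deriv,
                        parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop("trajectory solver failed to converge", call. = FALSE)
    }
    obj <- list(method = "rk", times = sol[, 1L],
                states = sol[, -1L, drop = FALSE], t_span = t_span)
  }
  structure(c(obj, list(n_spins = length(x0s), x0s = as.numeric(x0s))),
            class = "spin_trajectories")
}

#' Query trajectory positions at arbitrary times
#'
#' @param traj A `spin_trajectories` object.
#' @param t Times in seconds within the integrated span.
#' @param spins Optional spin indices to evaluate (default: all).
#' @return A matrix of positions (length(t) rows, one column per requested
#'   spin), cm.
#' @export
trajectory_positions <- function(traj, t, spins = NULL) {
  t <- as.numeric(t)
  if (is.null(spins)) spins <- seq_len(traj$n_spins)
  if (traj$method == "separable") {
    u <- displacement_at(traj$waveform, t) - traj$u0
    out <- vapply(spins, function(j) {
      x_of_s(traj$smap, traj$s0[j] + u)
    }, numeric(length(t)))
  } else {
    out <- vapply(spins, function(j) {
      stats::approx(traj$times, traj$states[, j], xout = t, rule = 2)$y
    }, numeric(length(t)))
  }
  matrix(out, nrow = length(t), ncol = length(spins))
}

#' Seed initial spin positions around the imaging slices
#'
#' Returns uniformly spaced initial positions spanning the imaging slices
#' plus margins wide enough that, given the waveform's cumulative
#' displacement range (amplified by the largest anatomy factor the spins can
#' encounter), every slice stays populated for the whole simulation. The
#' occupancy guarantee is checked post hoc.
#'
#' @param profile An [area_profile()].
#' @param protocol An [protocol()].
#' @param waveform A [velocity_waveform()].
#' @param spacing Seed spacing in cm; default `W / 100`.
#' @param min_count Minimum spins that must occupy each slice at all times.
#' @return Numeric vector of initial positions (cm).
#' @export
seed_positions <- function(profile, protocol, waveform,
                           spacing = protocol$slice_thickness / 100,
                           min_count = 50L) {
  stopifnot(spacing > 0)
  w <- protocol$slice_thickness
  top <- protocol$n_slices * w
  smap <- build_s_map(profile)
  u <- waveform$displacement - waveform$displacement[1L]
  # displacement in s equals the entrance displacement; convert the worst-case
  # s-excursion back to x through the steepest (floor-area) tail slope
  fmax <- profile$a_slc1 / profile$area_floor
  margin <- fmax * max(abs(range(u))) + w
  x0s <- seq(-margin, top + margin, by = spacing)
  # post-hoc occupancy check on a coarse time grid
  tchk <- seq(waveform$times[1L], waveform$times[length(waveform$times)],
              length.out = 25L)
  s_edges <- s_of_x(smap, seq(0, top, by = w))
  s0 <- sort(s_of_x(smap, x0s))
  uchk <- displacement_at(waveform, tchk) - waveform$displacement[1L]
  for (ti in seq_along(tchk)) {
    occ <- findInterval(s_edges - uchk[ti], s0)
    if (any(diff(occ) < min_count)) {
      stop("slice occupancy fell below ", min_count,
           " spins; use smaller spacing or check the waveform margins",
           call. = FALSE)
    }
  }
  x0s
}

#' Detect slice-specific RF excitations along a trajectory
#'
#' A spin at position `x` at an event time receives the pulse iff
#' `k W <= x < (k+1) W` for some excited slice `k` (half-open intervals, so
#' boundary positions are counted once). Spins outside all slices receive
#' nothing and recover.
#'
#' @param traj A single-spin `spin_trajectories` object (or one with several
#'   spins; the first is used unless `spin` is given).
#' @param schedule An [build_schedule()] result covering the trajectory span.
#' @param protocol An [protocol()].
#' @param spin Column index of the spin to analyse.
#' @return A data frame with one row per received pulse: `time`, `slice`
#'   (0-based), `delta_t` (time since the previous received pulse, NA for the
#'   first), plus the final [excitation_history()] as attribute `"history"`
#'   (NULL if no pulse was received).
#' @export
detect_excitations <- function(traj, schedule, protocol, spin = 1L) {
  w <- protocol$slice_thickness
  keep <- schedule$times >= traj$t_span[1L] & schedule$times <= traj$t_span[2L]
  times <- schedule$times[keep]
  slices <- schedule$slices[keep, , drop = FALSE]
  x <- trajectory_positions(traj, times, spins = spin)[, 1L]
  occupied <- floor(x / w)
  hit <- occupied >= 0 & occupied < protocol$n_slices &
    matrixStats_any_row(slices, occupied)
  times_hit <- times[hit]
  df <- data.frame(time = times_hit,
                   slice = as.integer(occupied[hit]),
                   delta_t = if (length(times_hit)) {
                     c(NA_real_, diff(times_hit))
                   } else numeric(0))
  hist <- if (nrow(df) > 0L) {
    excitation_history(nrow(df), df$delta_t[-1L])
  }
  attr(df, "history") <- hist
  df
}

# row-wise membership test: does row i of `slices` contain value[i]?
matrixStats_any_row <- function(slices, values) {
  out <- rep(FALSE, length(values))
  for (j in seq_len(ncol(slices))) {
    out <- out | (slices[, j] == values)
  }
  out
}

#' Read / write area profiles and velocity waveforms as CSV
#'
#' Two-column CSVs: `position_cm, area_cm2` for profiles and
#' `time_s, velocity_cm_s` for waveforms.
#'
#' @param path File path.
#' @param area_floor Passed to [area_profile()].
#' @name flow_csv
NULL

#' @rdname flow_csv
#' @export
read_area_csv <- function(path, area_floor = 0.05) {
  df <- utils::read.csv(path)
  area_profile(df[[1L]], df[[2L]], area_floor = area_floor)
}

#' @rdname flow_csv
#' @param profile An `area_profile`.
#' @export
write_area_csv <- function(profile, path) {
  utils::write.csv(data.frame(position_cm = profile$positions,
                              area_cm2 = profile$areas),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname flow_csv
#' @export
read_velocity_csv <- function(path) {
  df <- utils::read.csv(path)
  velocity_waveform(df[[1L]], df[[2L]])
}

#' @rdname flow_csv
#' @param waveform A `velocity_waveform`.
#' @export
write_velocity_csv <- function(waveform, path) {
  utils::write.csv(data.frame(time_s = waveform$times,
                              velocity_cm_s = waveform$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
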