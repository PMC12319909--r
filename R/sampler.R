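#' Spectral bounds for stochastic velocity sampling
#'
#' Frequency-dependent amplitude envelope built from three Gaussian
#' components describing slow hemodynamic, respiratory (with second and
#' third harmonics at weights 1/3 and 1/6), and cardiac velocity dynamics.
#' The per-frequency sampling bounds are
#' `B_U(f) = 1.4 (g_slow + g_resp + g_card) + 0.01` and
#' `B_L(f) = 0.6 (g_slow + g_resp + g_card)`.
#'
#' @param alpha_slow,alpha_resp,alpha_card Component amplitudes in cm/s.
#' @param mu_slow,mu_resp,mu_card Component center frequencies in Hz.
#' @return An object of class `spectral_bounds`. Component widths are fixed
#'   at 0.015 (slow), 0.002 (respiratory), and 0.0075 Hz (cardiac).
#' @export
spectral_bounds <- function(alpha_slow = 0, mu_slow = 0.05,
                            alpha_resp = 0, mu_resp = 0.167,
                            alpha_card = 0, mu_card = 0.9) {
  stopifnot(alpha_slow >= 0, alpha_resp >= 0, alpha_card >= 0,
            mu_slow > 0, mu_resp > 0, mu_card > 0)
  structure(list(alpha_slow = alpha_slow, mu_slow = mu_slow,
                 alpha_resp = alpha_resp, mu_resp = mu_resp,
                 alpha_card = alpha_card, mu_card = mu_card,
                 sigma_slow = 0.015, sigma_resp = 0.002, sigma_card = 0.0075,
                 kind = "human"),
            class = "spectral_bounds")
}

#' Single-Gaussian spectral bounds for phantom-mode samples
#'
#' @param alpha Amplitude in cm/s.
#' @param mu Center frequency in Hz; the pump frequencies used are 0.05, 0.1,
#'   or 0.2 Hz.
#' @export
phantom_bounds <- function(alpha = 0, mu = 0.1) {
  structure(list(alpha = alpha, mu = mu, sigma = 0.006, kind = "phantom"),
            class = "spectral_bounds")
}

gauss <- function(f, mu, sigma) exp(-0.5 * ((f - mu) / sigma)^2)

g_sum <- function(f, sb) {
  if (sb$kind == "phantom") {
    sb$alpha * gauss(f, sb$mu, sb$sigma)
  } else {
    sb$alpha_slow * gauss(f, sb$mu_slow, sb$sigma_slow) +
      sb$alpha_resp * (gauss(f, sb$mu_resp, sb$sigma_resp) +
                         gauss(f, 2 * sb$mu_resp, sb$sigma_resp) / 3 +
                         gauss(f, 3 * sb$mu_resp, sb$sigma_resp) / 6) +
      sb$alpha_card * gauss(f, sb$mu_card, sb$sigma_card)
  }
}

#' Sinusoid amplitude sampling bounds at given frequencies
#'
#' @param f Frequencies in Hz (> 0, vectorized).
#' @param sb A [spectral_bounds()] or [phantom_bounds()] object.
#' @return A two-column matrix `cbind(lower, upper)` in cm/s, with
#'   `lower <= upper` everywhere.
#' @export
bounds <- function(f, sb) {
  stopifnot(all(f > 0))
  g <- g_sum(f, sb)
  cbind(lower = 0.6 * g, upper = 1.4 * g + 0.01)
}

#' Draw one stochastic velocity specification (and waveform)
#'
#' Samples the training-velocity generative model: a velocity offset plus
#' 100 sinusoids at 0.01, 0.02, ..., 1.00 Hz, each with a random time shift
#' uniform over its own period and an amplitude drawn uniformly between the
#' frequency-dependent lower and upper bounds. Human-mode draws use the
#' three-component bounds with `alpha_slow ~ U(0, 0.1)`,
#' `mu_slow ~ U(0.035, 0.065)`, `alpha_resp ~ U(0, 1)`,
#' `mu_resp ~ U(0.1, 0.3)` (with a 25% chance of forcing `mu_resp = 0.167`,
#' the paced-breathing rate), `alpha_card ~ U(0, 0.2)`,
#' `mu_card ~ U(0.8, 1.0)`, and offset `V0 ~ U(-0.1, 0.1)` cm/s. With
#' probability `phantom_prob` the draw is in phantom mode: a single Gaussian
#' bound with `mu` drawn from {0.05, 0.1, 0.2} Hz, `alpha ~ U(0, 1.2)`, and
#' `V0 = 0` (the pump produces purely bidirectional flow).
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param duration Realized waveform length in seconds.
#' @param dt Waveform sample interval in seconds.
#' @param phantom_prob Probability of phantom mode (default 0.25).
#' @param forced_resp_prob Probability, within human mode, of forcing
#'   `mu_resp = 0.167` Hz (default 0.25).
#' @param n_f Number of sinusoids (default 100; frequencies `(1:n_f)/100`).
#' @param realize If FALSE, skip building the waveform (cheap draws for
#'   distributional checks).
#' @return A list with `mode` ("human"/"phantom"), `v0`, `freqs`,
#'   `amplitudes`, `t_shifts`, `bounds` (the realized spectral bounds
#'   object), and (if realized) `waveform`, a [velocity_waveform()].
#' @export
sample_velocity <- function(duration = 120.96, dt = 0.02,
                            phantom_prob = 0.25, forced_resp_prob = 0.25,
                            n_f = 100L, realize = TRUE) {
  freqs <- seq_len(n_f) / 100
  phantom <- stats::runif(1) < phantom_prob
  if (phantom) {
    sb <- phantom_bounds(alpha = stats::runif(1, 0, 1.2),
                         mu = sample(c(0.05, 0.1, 0.2), 1L))
    v0 <- 0
  } else {
    mu_resp <- if (stats::runif(1) < forced_resp_prob) 0.167 else
      stats::runif(1, 0.1, 0.3)
    sb <- spectral_bounds(alpha_slow = stats::runif(1, 0, 0.1),
                          mu_slow = stats::runif(1, 0.035, 0.065),
                          alpha_resp = stats::runif(1, 0, 1.0),
                          mu_resp = mu_resp,
                          alpha_card = stats::runif(1, 0, 0.2),
                          mu_card = stats::runif(1, 0.8, 1.0))
    v0 <- stats::runif(1, -0.1, 0.1)
  }
  b <- bounds(freqs, sb)
  amps <- stats::runif(n_f, b[, "lower"], b[, "upper"])
  shifts <- stats::runif(n_f, 0, 1 / freqs)
  out <- list(mode = if (phantom) "phantom" else "human",
              v0 = v0, freqs = freqs, amplitudes = amps, t_shifts = shifts,
              bounds = sb)
  if (realize) {
    out$waveform <- realize_velocity(out, duration = duration, dt = dt)
  }
  out
}

#' Realize a velocity specification on a time grid
#'
#' `V(t) = V0 + sum_i V_i cos(2 pi f_i (t - t_shift_i))`.
#'
#' @param spec A list as returned by [sample_velocity()].
#' @param duration Length in seconds.
#' @param dt Sample interval in seconds.
#' @return A [velocity_waveform()].
#' @export
realize_velocity <- function(spec, duration, dt = 0.02) {
  t <- seq(0, duration, by = dt)
  phases <- outer(t, spec$freqs) - rep(spec$freqs * spec$t_shifts,
                                       each = length(t))
  v <- spec$v0 + as.numeric(cos(2 * pi * phases) %*% spec$amplitudes)
  velocity_waveform(t, v)
}

#' Synthetic fourth-ventricle-like area curve
#'
#' Smooth unimodal area-depth curve
#' `A(x) = A_min + (A_peak - A_min) exp(-(x - x_peak)^2 / (2 sigma^2))` with
#' `A_min ~ U(0.1, 0.4)` cm^2, `A_peak ~ U(0.8, 2.0)` cm^2, and
#' `sigma ~ U(0.5, 1.5)` cm, tabulated over an 8 cm span centered on the
#' peak. This is a synthetic stand-in emulating the scale and shape of
#' extracted fourth-ventricle anatomy (whose subject-level curves are not
#' published as data); it is not a reference anatomy.
#'
#' Uses R's global RNG.
#'
#' @param dx Tabulation step in cm.
#' @return A list with `positions`, `areas`, and `x_peak` (the widest
#'   location, here the curve center).
#' @export
synthetic_ventricle_curve <- function(dx = 0.05) {
  a_min <- stats::runif(1, 0.1, 0.4)
  a_peak <- stats::runif(1, 0.8, 2.0)
  sigma <- stats::runif(1, 0.5, 1.5)
  x <- seq(-4, 4, by = dx)
  list(positions = x,
       areas = a_min + (a_peak - a_min) * exp(-(x)^2 / (2 * sigma^2)),
       x_peak = 0)
}

#' Draw a training-sample anatomy
#'
#' Human mode: picks a curve from the library (default: a fresh synthetic
#' ventricle curve), shifts the depth origin so the bottom of the first
#' imaging slice lands within +/- 1 cm of the widest location, and scales
#' all areas by a factor uniform in [0.8, 1.2] (which leaves F(x)
#' unchanged). Phantom mode: a straight tube.
#'
#' Uses R's global RNG.
#'
#' @param mode "human" or "phantom".
#' @param curve_library Optional list of curves (as returned by
#'   [synthetic_ventricle_curve()]) to draw from.
#' @param area_floor Passed to [area_profile()].
#' @return An [area_profile()].
#' @export
sample_anatomy <- function(mode = c("human", "phantom"),
                           curve_library = NULL, area_floor = 0.05) {
  mode <- match.arg(mode)
  if (mode == "phantom") return(straight_tube(area_floor = area_floor))
  curve <- if (is.null(curve_library)) {
    synthetic_ventricle_curve()
  } else {
    curve_library[[sample.int(length(curve_library), 1L)]]
  }
  shift <- stats::runif(1, -1, 1)
  scale <- stats::runif(1, 0.8, 1.2)
  # place x = 0 (slice-1 bottom) at x_peak + shift in curve coordinates
  area_profile(curve$positions - (curve$x_peak + shift),
               curve$areas * scale, area_floor = area_floor)
}

#' Generate one training sample for the inverse model
#'
#' Draws a velocity and an anatomy, simulates the three bottom-slice inflow
#' signals through the forward model (240 TR cycles with the first 40
#' discarded as transient, leaving 200 samples of ~100 s at TR 0.504 s),
#' rescales the three-slice signal set so its maximum amplitude is 1 (human
#' mode) or 0.25 (phantom mode), adds Gaussian noise with standard deviation
#' uniform in [0.01, 0.1], demeans each inflow channel, and appends the
#' anatomy feature channels (areas in cm^2 and their depths in cm, linearly
#' interpolated to length 200). The target is the input velocity resampled
#' to 1,000 points over the same retained window.
#'
#' Uses R's global RNG.
#'
#' @param protocol An [protocol()].
#' @param n_keep Inflow samples kept per channel (default 200).
#' @param trim_trs Transient TR cycles discarded (default 40).
#' @param target_len Velocity target length (default 1000).
#' @param min_occupancy Seeding density control for [simulate_inflow()].
#' @param curve_library Passed to [sample_anatomy()].
#' @return A list with `inputs` (5 x 200 matrix: slice1..3, area, position),
#'   `target` (length 1000, cm/s), and `meta` (mode, noise sd, v0).
#' @export
make_sample <- function(protocol = csfinflow::protocol(), n_keep = 200L,
                        trim_trs = 40L, target_len = 1000L,
                        min_occupancy = 50L, curve_library = NULL) {
  n_trs <- n_keep + trim_trs
  duration <- n_trs * protocol$tr
  draw <- sample_velocity(duration = duration + 2 * protocol$tr)
  prof <- sample_anatomy(draw$mode, curve_library = curve_library)
  ss <- simulate_inflow(draw$waveform, prof, protocol, n_slices_out = 3L,
                        duration = duration, trim_trs = trim_trs,
                        min_occupancy = min_occupancy)
  sig <- ss$signal
  peak <- max(abs(sig))
  target_amp <- if (draw$mode == "phantom") 0.25 else 1
  if (peak > 0) sig <- sig * (target_amp / peak)
  noise_sd <- stats::runif(1, 0.01, 0.1)
  sig <- sig + matrix(stats::rnorm(length(sig), 0, noise_sd), nrow(sig))
  sig <- sweep(sig, 2L, colMeans(sig))
  anat <- anatomy_channels(prof, n_keep)
  inputs <- rbind(t(sig), anat$area, anat$position)
  rownames(inputs) <- c("slice1", "slice2", "slice3", "area", "position")
  # target: velocity over the retained window, resampled to target_len
  t_lo <- trim_trs * protocol$tr
  t_target <- seq(t_lo, duration, length.out = target_len)
  target <- velocity_at(draw$waveform, t_target)
  list(inputs = inputs, target = target,
       meta = list(mode = draw$mode, noise_sd = noise_sd, v0 = draw$v0))
}

#' Anatomy feature channels for the network input
#'
#' Linearly interpolates the tabulated area curve to `len` points over its
#' span; positions are depths relative to the bottom of the first imaging
#' slice (the profile's native origin).
#'
#' @param profile An [area_profile()].
#' @param len Channel length (default 200).
#' @return List with `area` (cm^2) and `position` (cm) vectors.
#' @export
anatomy_channels <- function(profile, len = 200L) {
  pos <- seq(profile$positions[1L], profile$positions[length(profile$positions)],
             length.out = len)
  list(area = stats::approx(profile$positions, profile$areas, xout = pos)$y,
       position = pos)
}

#' Generate a training dataset
#'
#' Repeated [make_sample()] under a master seed: `(seed, n)` determines the
#' dataset bit-for-bit.
#'
#' @param n Number of samples.
#' @param seed Master RNG seed.
#' @param protocol An [protocol()].
#' @param verbose Print progress every 500 samples.
#' @param ... Passed to [make_sample()].
#' @return A list with `inputs` (array 5 x 200 x n), `targets` (matrix
#'   target_len x n), and `meta` (data frame with mode, noise sd, v0).
#' @export
make_training_set <- function(n, seed = 1L, protocol = csfinflow::protocol(),
                              verbose = FALSE, ...) {
  set.seed(seed)
  first <- make_sample(protocol = protocol, ...)
  inputs <- array(NA_real_, c(nrow(first$inputs), ncol(first$inputs), n))
  targets <- matrix(NA_real_, length(first$target), n)
  meta <- vector("list", n)
  inputs[, , 1L] <- first$inputs
  targets[, 1L] <- first$target
  meta[[1L]] <- first$meta
  if (n > 1L) for (i in 2:n) {
    s <- make_sample(protocol = protocol, ...)
    inputs[, , i] <- s$inputs
    targets[, i] <- s$target
    meta[[i]] <- s$meta
    if (verbose && i %% 500L == 0L) message("generated ", i, "/", n)
  }
  list(inputs = inputs, targets = targets,
       meta = data.frame(mode = vapply(meta, `[[`, "", "mode"),
                         noise_sd = vapply(meta, `[[`, 0, "noise_sd"),
                         v0 = vapply(meta, `[[`, 0, "v0")))
}
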