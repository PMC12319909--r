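#' Partial-volume scaling factor
#'
#' Linear-interpolation scaling between a pure-tissue and the most CSF-filled
#' voxel intensity on the T1-weighted anatomical image:
#' `m = T1Wvox * (T1Wtiss / T1Wcsf - 1) / (T1Wtiss - T1Wcsf)`.
#' A pure-CSF voxel (`T1Wvox = T1Wcsf`) gets `m = 1`; the more tissue a voxel
#' contains (the brighter it is), the larger the scale-up.
#'
#' @param t1w_tiss Reference tissue intensity (> `t1w_csf`).
#' @param t1w_csf Reference CSF intensity (> 0; CSF is dark on T1-weighted
#'   images).
#' @param t1w_voxel Voxel intensities (vectorized).
#' @return Dimensionless scaling factors, always >= 1 for voxel intensities
#'   in `[t1w_csf, t1w_tiss]`.
#' @export
pv_scale <- function(t1w_tiss, t1w_csf, t1w_voxel) {
  if (!(t1w_tiss > t1w_csf && t1w_csf > 0)) {
    stop("need t1w_tiss > t1w_csf > 0", call. = FALSE)
  }
  t1w_voxel * (t1w_tiss / t1w_csf - 1) / (t1w_tiss - t1w_csf)
}

#' Preprocess an fMRI inflow ROI time series
#'
#' Drops the first `trim` samples (initial transient of high signal),
#' subtracts the mean of the lowest-decile values to set the baseline near
#' zero, and (optionally) low-pass filters below `lowpass` Hz with a
#' zero-phase fifth-order Butterworth filter. The network input path uses
#' `lowpass = NULL`.
#'
#' @param values Signal samples (one per TR).
#' @param tr Repetition time in seconds.
#' @param trim Samples to drop from the start (default 40).
#' @param lowpass Cutoff in Hz, or NULL to skip filtering.
#' @param baseline_quantile Fraction of lowest values averaged for the
#'   baseline (default 0.1).
#' @return Numeric vector of preprocessed samples.
#' @export
preprocess_fmri <- function(values, tr, trim = 40L, lowpass = 0.5,
                            baseline_quantile = 0.1) {
  values <- as.numeric(values)
  if (length(values) <= trim) {
    stop("time series shorter than the trim length", call. = FALSE)
  }
  x <- values[-seq_len(trim)]
  k <- max(1L, ceiling(baseline_quantile * length(x)))
  x <- x - mean(sort(x)[seq_len(k)])
  if (!is.null(lowpass)) {
    x <- butter_lowpass(x, fs = 1 / tr, cutoff = lowpass)
  }
  x
}

# zero-phase (forward-backward) Butterworth low-pass, order 5
butter_lowpass <- function(x, fs, cutoff, order = 5L) {
  wn <- cutoff / (fs / 2)
  if (wn >= 1) return(x)
  bf <- signal::butter(order, wn, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Convert phase-contrast phase to velocity
#'
#' Subtracts the stationary-tissue offset phase and scales by the velocity
#' encoding limit, `v = VENC * (phi_flow - phi_stationary) / pi` (a phase of
#' pi maps to VENC).
#'
#' @param phase_flow Flow-ROI phase time series (radians).
#' @param phase_stationary Stationary-ROI phase time series (radians), same
#'   length.
#' @param venc Velocity encoding limit in cm/s.
#' @return Velocity in cm/s.
#' @export
phase_to_velocity <- function(phase_flow, phase_stationary, venc) {
  if (length(phase_flow) != length(phase_stationary)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  venc * (phase_flow - phase_stationary) / pi
}

#' Detect peaks with minimum separation and prominence
#'
#' Local maxima filtered by topographic prominence (height above the higher
#' of the two flanking minima, searched out to the nearest higher sample) and
#' then by minimum separation, keeping the larger peak of any conflicting
#' pair.
#'
#' @param x Numeric series.
#' @param distance Minimum index separation between kept peaks.
#' @param prominence Minimum prominence.
#' @return Integer vector of peak indices (sorted).
#' @export
find_signal_peaks <- function(x, distance = 1L, prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  prom <- vapply(idx, function(i) {
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > x[i])
    lmin <- min(x[(if (length(higher_l)) max(higher_l) else 1L):i])
    right <- x[i:n]
    higher_r <- which(right > x[i])
    rmin <- min(x[i:(if (length(higher_r)) i - 1L + min(higher_r) else n)])
    x[i] - max(lmin, rmin)
  }, 0)
  idx <- idx[prom >= prominence]
  if (!length(idx)) return(integer(0))
  # enforce separation, greedily keeping higher peaks
  ord <- idx[order(x[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= distance)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Cycle-locked average of an oscillatory time series
#'
#' Upsamples by a factor of 4 (linear interpolation), detects peaks with a
#' minimum separation of `expected_period - 1` seconds and prominence 0.1 (in
#' the units of the input: cm/s for velocities, normalized units for inflow
#' signals), and averages the inter-peak segments after resampling each to a
#' common length.
#'
#' @param values Signal samples.
#' @param dt Sample interval in seconds.
#' @param expected_period Nominal oscillation period in seconds.
#' @param prominence Peak prominence threshold (default 0.1).
#' @return An object of class `cycle_average`: list with `cycle` (mean cycle
#'   waveform), `dt` (upsampled interval), `n_cycles`, `period_estimate`.
#' @export
cycle_average <- function(values, dt, expected_period, prominence = 0.1) {
  values <- as.numeric(values)
  if (length(values) * dt < 2 * expected_period) {
    stop("need at least two expected periods of data", call. = FALSE)
  }
  up <- 4L
  n_up <- (length(values) - 1L) * up + 1L
  t_up <- seq(0, (length(values) - 1L) * dt, length.out = n_up)
  x <- stats::approx(seq(0, by = dt, length.out = length(values)), values,
                     xout = t_up)$y
  dt_up <- dt / up
  min_sep <- max(1L, round((expected_period - 1) / dt_up))
  peaks <- find_signal_peaks(x, distance = min_sep, prominence = prominence)
  if (length(peaks) < 2L) {
    stop("fewer than two peaks detected; cannot form cycles", call. = FALSE)
  }
  len <- max(2L, round(expected_period / dt_up))
  segs <- vapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- x[peaks[i]:peaks[i + 1L]]
    stats::approx(seq(0, 1, length.out = length(seg)), seg,
                  xout = seq(0, 1, length.out = len))$y
  }, numeric(len))
  structure(list(cycle = rowMeans(segs), dt = dt_up,
                 n_cycles = length(peaks) - 1L,
                 period_estimate = mean(diff(peaks)) * dt_up),
            class = "cycle_average")
}

#' @export
print.cycle_average <- function(x, ...) {
  cat(sprintf("<cycle_average> %d cycles, period ~ %.3g s, %d points\n",
              x$n_cycles, x$period_estimate, length(x$cycle)))
  invisible(x)
}

#' Mean absolute difference between two cycle averages
#'
#' Resamples both mean cycles to a common length and returns the mean
#' absolute difference; both should be normalized by the same convention
#' (see [normalize_top5()]).
#'
#' @param measured,simulated `cycle_average` objects (or plain vectors).
#' @return Mean absolute difference (same units as the inputs).
#' @export
cycle_error <- function(measured, simulated) {
  a <- if (inherits(measured, "cycle_average")) measured$cycle else measured
  b <- if (inherits(simulated, "cycle_average")) simulated$cycle else simulated
  len <- max(length(a), length(b))
  ra <- stats::approx(seq(0, 1, length.out = length(a)), a,
                      xout = seq(0, 1, length.out = len))$y
  rb <- stats::approx(seq(0, 1, length.out = length(b)), b,
                      xout = seq(0, 1, length.out = len))$y
  mean(abs(ra - rb))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann window, 50% overlap, one-sided,
#' density scaling (so `sum(psd) * df` approximates the signal variance for
#' a demeaned input).
#'
#' @param x Numeric series.
#' @param fs Sampling frequency in Hz.
#' @param nperseg Segment length (default: `length(x) / 4`, at least 16).
#' @param demean Subtract the series mean first (default TRUE).
#' @return List with `freqs` (Hz) and `psd` (power per Hz).
#' @export
spectral_density <- function(x, fs, nperseg = NULL, demean = TRUE) {
  x <- as.numeric(x)
  if (demean) x <- x - mean(x)
  n <- length(x)
  if (is.null(nperseg)) nperseg <- max(16L, floor(n / 4))
  nperseg <- min(as.integer(round(nperseg)), n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1L)) / nperseg)  # periodic Hann
  scale <- fs * sum(win^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * win
    p <- abs(stats::fft(seg))^2 / scale
    acc <- acc + p[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  if (nperseg %% 2L == 0L) {
    psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]
  } else if (nfreq > 1L) {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  list(freqs = (seq_len(nfreq) - 1L) * fs / nperseg, psd = psd)
}

#' Power-law exponent of a spectrum
#'
#' Least-squares slope of `log(psd)` versus `log(f)` on a frequency band;
#' with the convention `psd ~ f^gamma`, flow-attenuated spectra have more
#' negative `gamma`.
#'
#' @param freqs Frequencies in Hz.
#' @param psd Power spectral density (must be positive on the band).
#' @param fit_band Length-2 vector `c(f_lo, f_hi)` in Hz.
#' @return The exponent gamma.
#' @export
power_law_fit <- function(freqs, psd, fit_band) {
  keep <- freqs >= fit_band[1L] & freqs <= fit_band[2L] & freqs > 0
  if (sum(keep) < 2L) stop("fit band contains fewer than two points", call. = FALSE)
  if (any(psd[keep] <= 0)) stop("psd must be positive on the fit band", call. = FALSE)
  unname(stats::coef(stats::lm(log(psd[keep]) ~ log(freqs[keep])))[2L])
}

#' Relative bandpower
#'
#' Fraction of total spectral power lying inside a frequency band (default
#' 0.14-0.19 Hz, around a 0.167 Hz paced-breathing rate).
#'
#' @param x Numeric series.
#' @param fs Sampling frequency in Hz.
#' @param band Length-2 band in Hz.
#' @return Fraction in [0, 1].
#' @export
relative_bandpower <- function(x, fs, band = c(0.14, 0.19)) {
  ps <- spectral_density(x, fs, nperseg = min(length(x), round(fs * 60)))
  tot <- sum(ps$psd)
  if (tot <= 0) stop("zero total power", call. = FALSE)
  inb <- ps$freqs >= band[1L] & ps$freqs <= band[2L]
  sum(ps$psd[inb]) / tot
}

#' Cross-sectional area profile from a labeled anatomical volume
#'
#' For each anatomical slice (third array dimension), sums the in-plane area
#' of labeled voxels, scaling each voxel by `T1W_ref / T1W_voxel` where
#' `T1W_ref` is the slice minimum over labeled voxels (the most CSF-filled
#' voxel); partial-volume tissue brightens a voxel, shrinking its
#' contribution. Slices without labeled voxels are skipped.
#'
#' @param label_volume 3D logical/0-1 array marking compartment voxels.
#' @param t1w_volume 3D intensity array, same dimensions.
#' @param voxel_dims Voxel dimensions `c(dx, dy, dz)` in cm.
#' @param x0_slice Index of the anatomical slice mapped to depth 0 (bottom of
#'   the first imaging slice); defaults to the first labeled slice.
#' @param area_floor Passed to [area_profile()].
#' @return An [area_profile()] ordered by depth.
#' @export
area_from_labels <- function(label_volume, t1w_volume, voxel_dims,
                             x0_slice = NULL, area_floor = 0.05) {
  stopifnot(identical(dim(label_volume), dim(t1w_volume)),
            length(dim(label_volume)) == 3L, length(voxel_dims) == 3L)
  inplane <- voxel_dims[1L] * voxel_dims[2L]
  nz <- dim(label_volume)[3L]
  areas <- rep(NA_real_, nz)
  for (k in seq_len(nz)) {
    lab <- label_volume[, , k] > 0
    if (!any(lab)) next
    ints <- t1w_volume[, , k][lab]
    ref <- min(ints)
    areas[k] <- sum(inplane * ref / ints)
  }
  keep <- which(!is.na(areas))
  if (length(keep) < 2L) {
    stop("fewer than two labeled slices", call. = FALSE)
  }
  if (is.null(x0_slice)) x0_slice <- keep[1L]
  positions <- (keep - x0_slice) * voxel_dims[3L]
  area_profile(positions, areas[keep], area_floor = area_floor)
}
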