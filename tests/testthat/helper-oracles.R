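# Independent oracles used across the test files.

# Brute-force longitudinal recursion: iterate
#   Mz <- Mz * cos(theta) * E + Meq * (1 - E),  E = exp(-dt / T1)
# from equilibrium, then read out the transverse signal at the last pulse.
# Disambiguates the closed-form signal expression by construction.
recursion_oracle <- function(deltas, protocol) {
  mz <- protocol$m_eq
  for (d in deltas) {
    e <- exp(-d / protocol$t1)
    mz <- mz * cos(protocol$flip_angle) * e + protocol$m_eq * (1 - e)
  }
  mz * sin(protocol$flip_angle) * exp(-protocol$te / protocol$t2)
}

# Independent constant-plug-flow enumeration: spins move as x(t) = x0 + V t
# (straight tube); walk the schedule event list in time order, accumulate
# each spin's pulse history directly, and average the closed-recursion
# contrast over the spins inside the sampled slice at its excitation
# instants. Shares no code path with the s-coordinate simulator core.
plug_flow_oracle <- function(v, protocol, n_slices_out, duration,
                             trim_trs = 40L, spacing = NULL) {
  sched <- build_schedule(protocol, duration)
  w <- protocol$slice_thickness
  if (is.null(spacing)) spacing <- w / 60
  x0 <- seq(-v * duration - w, protocol$n_slices * w + w, by = spacing)
  mz <- rep(protocol$m_eq, length(x0))
  last_t <- rep(0, length(x0))
  np <- integer(length(x0))
  ctheta <- cos(protocol$flip_angle)
  te_f <- sin(protocol$flip_angle) * exp(-protocol$te / protocol$t2)
  ssig <- steady_state_signal(protocol$tr, protocol)
  n_cyc <- ceiling(max(sched$times) / protocol$tr)
  out <- matrix(NA_real_, n_cyc, n_slices_out)
  for (e in seq_along(sched$times)) {
    t <- sched$times[e]
    x <- x0 + v * t
    k <- floor(x / w)
    for (sl in sched$slices[e, ]) {
      if (sl < 0 || sl >= protocol$n_slices) next
      sel <- which(k == sl)
      if (!length(sel)) next
      ee <- exp(-(t - last_t[sel]) / protocol$t1)
      mzb <- ifelse(np[sel] == 0L, protocol$m_eq,
                    mz[sel] * ee + protocol$m_eq * (1 - ee))
      if (sl < n_slices_out) {
        cyc <- floor(t / protocol$tr + 1e-9) + 1L
        out[cyc, sl + 1L] <- mean(mzb) * te_f - ssig
      }
      mz[sel] <- mzb * ctheta
      last_t[sel] <- t
      np[sel] <- np[sel] + 1L
    }
  }
  out[-seq_len(trim_trs), , drop = FALSE]
}

# Small helpers reused by several files.
test_protocol <- function(...) protocol(...)

constant_waveform <- function(v, duration, dt = 0.05) {
  t <- seq(0, duration, by = dt)
  velocity_waveform(t, rep(v, length(t)))
}
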