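#' Define a multislice gradient-echo imaging protocol
#'
#' Bundles the acquisition and relaxation parameters that determine both the
#' slice excitation timing and the spoiled gradient-echo signal constants.
#' Defaults correspond to a fast fMRI CSF-flow protocol (TR 0.504 s, TE 30 ms,
#' 45 degree flip, 2.5 mm slices, 21 slices with multiband factor 3) with
#' CSF-like relaxation times (T1 = 4 s, T2 = 1.5 s).
#'
#' @param tr Repetition time in seconds (> 0).
#' @param te Echo time in seconds (>= 0).
#' @param flip_angle Excitation flip angle; degrees by default.
#' @param flip_units Either "degrees" or "radians".
#' @param slice_thickness Slice thickness W in cm (> 0).
#' @param n_slices Number of slices (>= 1).
#' @param mb_factor Multiband (simultaneous multislice) factor; `n_slices`
#'   must be divisible by it.
#' @param slice_order Within-TR ordering of the `n_slices / mb_factor`
#'   excitation groups: "interleaved" (even group indices then odd),
#'   "sequential", or an explicit 0-based permutation of the group indices.
#' @param t1,t2 Longitudinal / transverse relaxation times of the fluid (s).
#' @param m_eq Equilibrium longitudinal magnetization (arbitrary units).
#' @return An object of class `inflow_protocol`.
#' @examples
#' p <- protocol()
#' critical_velocity(p)
#' @export
protocol <- function(tr = 0.504, te = 0.03,
                     flip_angle = 45, flip_units = c("degrees", "radians"),
                     slice_thickness = 0.25, n_slices = 21L, mb_factor = 3L,
                     slice_order = "interleaved",
                     t1 = 4, t2 = 1.5, m_eq = 1) {
  flip_units <- match.arg(flip_units)
  theta <- if (flip_units == "degrees") flip_angle * pi / 180 else flip_angle
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0)
  stopifnot(is.numeric(te), length(te) == 1L, te >= 0)
  if (!(theta > 0 && theta <= pi / 2)) {
    stop("flip angle must lie in (0, 90] degrees", call. = FALSE)
  }
  stopifnot(slice_thickness > 0, t1 > 0, t2 > 0)
  n_slices <- as.integer(n_slices)
  mb_factor <- as.integer(mb_factor)
  stopifnot(n_slices >= 1L, mb_factor >= 1L)
  if (n_slices %% mb_factor != 0L) {
    stop("n_slices must be divisible by mb_factor", call. = FALSE)
  }
  n_groups <- n_slices %/% mb_factor
  if (is.character(slice_order)) {
    slice_order <- match.arg(slice_order, c("interleaved", "sequential"))
  } else {
    slice_order <- as.integer(slice_order)
    if (!identical(sort(slice_order), seq_len(n_groups) - 1L)) {
      stop("explicit slice_order must be a 0-based permutation of the ",
           n_groups, " excitation groups", call. = FALSE)
    }
  }
  structure(
    list(tr = tr, te = te, flip_angle = theta,
         slice_thickness = slice_thickness, n_slices = n_slices,
         mb_factor = mb_factor, slice_order = slice_order,
         t1 = t1, t2 = t2, m_eq = m_eq),
    class = "inflow_protocol")
}

#' @export
print.inflow_protocol <- function(x, ...) {
  cat(sprintf(
    "<inflow_protocol> TR=%.4g s, TE=%.4g s, flip=%.3g deg, W=%.3g cm,\n",
    x$tr, x$te, x$flip_angle * 180 / pi, x$slice_thickness))
  cat(sprintf("  %d slices (MB=%d), T1=%.3g s, T2=%.3g s, Meq=%.3g\n",
              x$n_slices, x$mb_factor, x$t1, x$t2, x$m_eq))
  cat(sprintf("  critical velocity W/TR = %.4g cm/s\n", critical_velocity(x)))
  invisible(x)
}

#' Read a protocol from a YAML or JSON configuration file
#'
#' Field names match the arguments of [protocol()]. Flip angle is taken in
#' degrees unless the file sets `flip_units: radians`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `inflow_protocol`.
#' @export
read_protocol <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported protocol config extension: ", ext, call. = FALSE))
  do.call(protocol, cfg)
}

#' Critical velocity of a protocol
#'
#' The speed `W / TR` at which fluid traverses one slice thickness per
#' repetition: at or above it, every spin sampled in the first slice has
#' received exactly one pulse and the first-slice inflow signal saturates.
#'
#' @param protocol An `inflow_protocol`.
#' @return Speed in cm/s.
#' @export
critical_velocity <- function(protocol) {
  protocol$slice_thickness / protocol$tr
}

group_order <- function(protocol) {
  n_groups <- protocol$n_slices %/% protocol$mb_factor
  ord <- protocol$slice_order
  if (is.character(ord)) {
    idx <- seq_len(n_groups) - 1L
    ord <- switch(ord,
      sequential = idx,
      interleaved = c(idx[idx %% 2L == 0L], idx[idx %% 2L == 1L]))
  }
  ord
}

#' Build the slice-specific RF excitation schedule
#'
#' The `n_slices / mb_factor` excitation groups are spread uniformly over one
#' TR at offsets `j * TR / n_groups`, in the protocol's configured group
#' order, and the pattern repeats every TR until `duration`. Multiband group
#' `k` excites slices `{k, k + n_groups, k + 2 n_groups, ...}` (0-based
#' arithmetic-stride grouping, the standard SMS convention).
#'
#' @param protocol An `inflow_protocol`.
#' @param duration Schedule span in seconds (>= TR); events cover
#'   `[0, duration)`.
#' @return An object of class `excitation_schedule`: a list with `times`
#'   (event times, s), `slices` (integer matrix, one row per event, 0-based
#'   slice indices excited simultaneously), and `tr`.
#' @export
build_schedule <- function(protocol, duration) {
  stopifnot(duration >= protocol$tr)
  n_groups <- protocol$n_slices %/% protocol$mb_factor
  ord <- group_order(protocol)
  offsets <- (seq_len(n_groups) - 1L) * protocol$tr / n_groups
  n_cycles <- ceiling(duration / protocol$tr - 1e-9)
  cycle_starts <- (seq_len(n_cycles) - 1L) * protocol$tr
  times <- rep(cycle_starts, each = n_groups) + rep(offsets, n_cycles)
  groups <- rep(ord, n_cycles)
  keep <- times < duration - 1e-12
  times <- times[keep]
  groups <- groups[keep]
  slices <- outer(groups, (seq_len(protocol$mb_factor) - 1L) * n_groups, `+`)
  structure(list(times = times, slices = slices, tr = protocol$tr,
                 n_slices = protocol$n_slices),
            class = "excitation_schedule")
}

#' @export
print.excitation_schedule <- function(x, ...) {
  cat(sprintf("<excitation_schedule> %d events over [0, %.4g) s, TR=%.4g s\n",
              length(x$times), max(x$times) + x$tr, x$tr))
  invisible(x)
}

#' Export an excitation schedule as CSV
#'
#' Writes columns `time_s` and `slice_indices` (0-based, semicolon-separated
#' for simultaneous multiband excitations).
#'
#' @param schedule An `excitation_schedule`.
#' @param path Output file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- data.frame(
    time_s = schedule$times,
    slice_indices = apply(schedule$slices, 1L, paste, collapse = ";"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
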