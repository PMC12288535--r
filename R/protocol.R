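#' Acquisition protocol
#'
#' Describes one free-running CMR acquisition: a continuously running 3D
#' cine scan, a pulse-oximeter-gated multi-TI delayed-enhancement (DE)
#' scan, or a low-resolution prescan. All timing is in milliseconds,
#' geometry in millimeters. The field of view is an isotropic cube sampled
#' on a Cartesian grid; the readout axis (x) is always fully sampled and
#' undersampling happens on the ky-kz plane.
#'
#' @param mode one of `"cine"`, `"de"`, `"prescan"`.
#' @param tr_ms,te_ms repetition and echo time in ms.
#' @param flip_deg excitation flip angle in degrees.
#' @param fov_mm isotropic field of view in mm.
#' @param matrix_size voxels per axis (grid is `matrix_size^3`).
#' @param sg_interval number of imaging lines between successive
#'   self-gating (SG) lines during cine; ignored for DE where one SG line
#'   is acquired per heartbeat.
#' @param duration_s cine scan duration in seconds.
#' @param n_heartbeats number of gated heartbeats for DE.
#' @param trigger_delay_ms delay from pulse trigger to inversion pulse.
#' @param acq_window_ms duration of the acquisition window after each
#'   inversion.
#' @param ti_centers_ms nominal inversion-time window centers in ms,
#'   strictly increasing.
#' @param ti_window_ms width of each TI bin in ms.
#' @param seed integer seed controlling every random choice the simulator
#'   makes for this protocol (sampling pattern, noise).
#'
#' @return An object of class `acq_protocol`. `resolution_mm` is derived
#'   as `fov_mm / matrix_size`.
#' @export
acq_protocol <- function(mode = c("cine", "de", "prescan"),
                         tr_ms = 4.0, te_ms = 2.9, flip_deg = 12,
                         fov_mm = 307, matrix_size = 192,
                         sg_interval = 10,
                         duration_s = 600, n_heartbeats = 900,
                         trigger_delay_ms = 100, acq_window_ms = 400,
                         ti_centers_ms = seq(80, 340, by = 10),
                         ti_window_ms = 80,
                         seed = 1L) {
  mode <- match.arg(mode)
  timings <- c(tr_ms = tr_ms, te_ms = te_ms, fov_mm = fov_mm,
               trigger_delay_ms = trigger_delay_ms,
               acq_window_ms = acq_window_ms, ti_window_ms = ti_window_ms)
  if (any(!is.finite(timings)) || any(timings <= 0))
    stop("all protocol timings and geometry must be positive: ",
         paste(names(timings)[timings <= 0], collapse = ", "))
  if (matrix_size < 2 || matrix_size != round(matrix_size))
    stop("matrix_size must be an integer >= 2")
  if (mode == "cine" && duration_s <= 0)
    stop("cine duration_s must be positive")
  if (mode == "de") {
    if (n_heartbeats < 1) stop("n_heartbeats must be >= 1")
    if (is.unsorted(ti_centers_ms, strictly = TRUE))
      stop("ti_centers_ms must be strictly increasing")
    if (any(ti_centers_ms <= 0)) stop("ti_centers_ms must be positive")
  }
  if (sg_interval < 1) stop("sg_interval must be >= 1")
  structure(list(
    mode = mode, tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
    fov_mm = fov_mm, matrix_size = as.integer(matrix_size),
    resolution_mm = fov_mm / matrix_size,
    sg_interval = as.integer(sg_interval),
    duration_s = duration_s, n_heartbeats = as.integer(n_heartbeats),
    trigger_delay_ms = trigger_delay_ms, acq_window_ms = acq_window_ms,
    ti_centers_ms = ti_centers_ms, ti_window_ms = ti_window_ms,
    seed = as.integer(seed)
  ), class = "acq_protocol")
}

#' Published default protocols
#'
#' Convenience constructors mirroring the published free-running exam:
#' 10 minutes of continuously acquired 3D isotropic cine at 1.6 mm /
#' 307 mm FOV with an SG line after every 10th imaging line, and a
#' pulse-oximeter-gated DE scan of 900 heartbeats with 100 ms trigger
#' delay, 400 ms acquisition window and reconstructed TI windows centered
#' 80--340 ms in 10 ms steps (80 ms wide).
#'
#' @param ... overrides passed on to [acq_protocol()].
#' @return An `acq_protocol`.
#' @export
cine_protocol <- function(...) {
  args <- list(mode = "cine", tr_ms = 4.0, te_ms = 2.9, flip_deg = 12,
               fov_mm = 307, matrix_size = 192, sg_interval = 10,
               duration_s = 600)
  do.call(acq_protocol, utils::modifyList(args, list(...)))
}

#' @rdname cine_protocol
#' @export
de_protocol <- function(...) {
  args <- list(mode = "de", tr_ms = 3.7, te_ms = 2.6, flip_deg = 10,
               fov_mm = 307, matrix_size = 192, n_heartbeats = 900,
               trigger_delay_ms = 100, acq_window_ms = 400,
               ti_centers_ms = seq(80, 340, by = 10), ti_window_ms = 80)
  do.call(acq_protocol, utils::modifyList(args, list(...)))
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf("<acq_protocol> mode=%s  %dx%dx%d @ %.2f mm (FOV %.0f mm)\n",
              x$mode, x$matrix_size, x$matrix_size, x$matrix_size,
              x$resolution_mm, x$fov_mm))
  cat(sprintf("  TR/TE = %.1f/%.1f ms, FA = %.0f deg\n",
              x$tr_ms, x$te_ms, x$flip_deg))
  if (x$mode == "cine")
    cat(sprintf("  duration %.0f s, SG every %d imaging lines\n",
                x$duration_s, x$sg_interval))
  if (x$mode == "de")
    cat(sprintf("  %d heartbeats, TD %.0f ms, window %.0f ms, %d TI bins (%.0f-%.0f ms)\n",
                x$n_heartbeats, x$trigger_delay_ms, x$acq_window_ms,
                length(x$ti_centers_ms), min(x$ti_centers_ms),
                max(x$ti_centers_ms)))
  invisible(x)
}
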