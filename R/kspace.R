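#' Timestamped multi-coil Cartesian k-space container
#'
#' Holds the raw lines of a simulated acquisition: for every line a
#' timestamp, a type (imaging or self-gating), 0-based ky/kz grid indices
#' (the readout axis kx is always fully sampled), the inversion time for
#' DE lines, and the complex readout samples of every coil.
#'
#' @param data complex array `[n_lines, n_samples, n_coils]`.
#' @param timestamp_ms numeric, strictly increasing, one per line.
#' @param line_type character, `"imaging"` or `"self_gating"` per line.
#' @param ky_index,kz_index integer 0-based phase/slice-encode indices;
#'   self-gating lines must sit at the grid center (`n %/% 2`).
#' @param protocol the [acq_protocol()] the data was acquired with.
#' @param ti_ms per-line inversion time (ms since the inversion pulse)
#'   for DE imaging lines, `NA` otherwise.
#' @param trigger_times_ms reference trigger time series (ground truth
#'   heartbeat times for cine, pulse-oximeter triggers for DE).
#' @param fov_mm field of view of the encoded volume.
#' @return object of class `kspace_data`.
#' @export
kspace_data <- function(data, timestamp_ms, line_type, ky_index, kz_index,
                        protocol, ti_ms = NULL, trigger_times_ms = numeric(0),
                        fov_mm = protocol$fov_mm) {
  stopifnot(length(dim(data)) == 3)
  n <- dim(data)[1]
  if (length(timestamp_ms) != n || length(line_type) != n ||
      length(ky_index) != n || length(kz_index) != n)
    stop("per-line metadata length must equal the number of lines")
  if (any(diff(timestamp_ms) <= 0))
    stop("timestamps must be strictly increasing")
  if (!all(line_type %in% c("imaging", "self_gating")))
    stop("line_type must be 'imaging' or 'self_gating'")
  ctr <- grid_center(dim(data)[2])
  sg <- line_type == "self_gating"
  if (any(sg) && (any(ky_index[sg] != ctr) || any(kz_index[sg] != ctr)))
    stop("self-gating lines must pass through the k-space center")
  if (is.null(ti_ms)) ti_ms <- rep(NA_real_, n)
  structure(list(
    data = data, timestamp_ms = timestamp_ms, line_type = line_type,
    ky_index = as.integer(ky_index), kz_index = as.integer(kz_index),
    ti_ms = ti_ms, trigger_times_ms = trigger_times_ms,
    header = list(protocol = protocol, n_coils = dim(data)[3],
                  grid = rep(dim(data)[2], 3), fov_mm = fov_mm)
  ), class = "kspace_data")
}

#' 0-based index of the k-space center on an axis of length `n`
#' @param n grid size.
#' @export
grid_center <- function(n) as.integer(n %/% 2)

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data> %d lines (%d self-gating), %d coils, grid %d, %s\n",
              length(x$timestamp_ms), sum(x$line_type == "self_gating"),
              x$header$n_coils, x$header$grid[1], x$header$protocol$mode))
  cat(sprintf("  span %.1f s, %d reference triggers\n",
              diff(range(x$timestamp_ms)) / 1000, length(x$trigger_times_ms)))
  invisible(x)
}
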