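#' TI bin membership of delayed-enhancement lines
#'
#' A line with inversion time `ti` belongs to every reconstructed TI bin
#' whose window `[center - w/2, center + w/2]` contains it; with the
#' default 80 ms windows spaced 10 ms apart the windows overlap and one
#' line feeds several bins.
#'
#' @param ti_ms inversion time of one line (ms).
#' @param ti_centers_ms nominal window centers.
#' @param ti_window_ms window width.
#' @return integer indices of the member bins (possibly empty).
#' @export
ti_bins_for <- function(ti_ms, ti_centers_ms, ti_window_ms = 80) {
  which(abs(ti_ms - ti_centers_ms) <= ti_window_ms / 2)
}

#' Sort DE readouts into overlapping TI bins and grid them
#'
#' Applies the respiratory acceptance of a gating result first, then
#' assigns every accepted imaging line to all TI windows containing its
#' inversion time and grids each bin's lines onto the Cartesian grid
#' (repeated cells averaged).
#'
#' @param raw DE [kspace_data()] with per-line `ti_ms`.
#' @param gating matching `gating_result` (respiratory acceptance);
#'   `NULL` accepts every line.
#' @param ti_centers_ms TI window centers; default from the protocol.
#' @param ti_window_ms window width in ms.
#' @return list with `ksp` `[kx, ky, kz, ti, coil]`, `mask`
#'   `[ky, kz, ti]`, `ti_values_ms`, per-bin line counts `n_lines`, and
#'   logical `empty` flags (empty bins are excluded from reconstruction).
#' @export
bin_de_by_ti <- function(raw, gating = NULL,
                         ti_centers_ms = raw$header$protocol$ti_centers_ms,
                         ti_window_ms = raw$header$protocol$ti_window_ms) {
  img <- which(raw$line_type == "imaging")
  acc <- rep(TRUE, length(img))
  if (!is.null(gating)) acc <- gating$resp_accepted
  idx <- img[acc]
  N <- raw$header$grid[1]; nc <- raw$header$n_coils
  nb <- length(ti_centers_ms)
  ksp <- array(0 + 0i, c(N, N, N, nb, nc))
  cnt <- array(0L, c(N, N, nb))
  for (l in idx) {
    bins <- ti_bins_for(raw$ti_ms[l], ti_centers_ms, ti_window_ms)
    if (length(bins) == 0) next
    iy <- raw$ky_index[l] + 1L; iz <- raw$kz_index[l] + 1L
    for (b in bins) {
      ksp[, iy, iz, b, ] <- ksp[, iy, iz, b, ] + raw$data[l, , ]
      cnt[iy, iz, b] <- cnt[iy, iz, b] + 1L
    }
  }
  for (b in seq_len(nb)) {
    w <- ifelse(cnt[, , b] > 0, 1 / pmax(cnt[, , b], 1L), 0)
    for (c in seq_len(nc))
      ksp[, , , b, c] <- ksp[, , , b, c] * rep(w, each = N)
  }
  n_lines <- apply(cnt, 3, function(m) sum(m))
  list(ksp = ksp, mask = cnt > 0, ti_values_ms = ti_centers_ms,
       n_lines = n_lines, empty = n_lines == 0)
}

#' Per-voxel inversion-recovery null-point detection
#'
#' Finds the minimum of the magnitude-vs-TI curve for every voxel,
#' refines it by 3-point parabolic interpolation around the discrete
#' argmin (ties broken toward the lower TI), and converts the null TI to
#' T1 via `T1 = null / log(2 * efficiency)` (perfect-inversion
#' assumption by default). Voxels whose minimum lies at the boundary of
#' the TI range are flagged out-of-range and get no T1; a monotone
#' magnitude curve is such a case, not an error.
#'
#' @param mag magnitude data: a numeric vector (one voxel), a
#'   `[voxels, ti]` matrix, or a 4D `[x, y, z, ti]` array.
#' @param ti_values_ms TI sample positions (>= 3).
#' @param efficiency assumed inversion efficiency.
#' @return for a vector input a list with `null_ti_ms`, `t1_ms`,
#'   `out_of_range`; for array input the same fields as arrays/vectors.
#' @export
detect_null_point <- function(mag, ti_values_ms, efficiency = 1) {
  if (length(ti_values_ms) < 3) stop("need at least 3 TI samples")
  vec_in <- is.null(dim(mag))
  arr_in <- !vec_in && length(dim(mag)) == 4
  M <- if (vec_in) matrix(mag, nrow = 1)
       else if (arr_in) matrix(mag, ncol = dim(mag)[4])
       else mag
  M <- abs(M)
  nt <- length(ti_values_ms)
  stopifnot(ncol(M) == nt)
  imin <- max.col(-M, ties.method = "first")    # ties -> lower TI
  oob <- imin == 1L | imin == nt
  null_ti <- ti_values_ms[imin]
  inner <- which(!oob)
  if (length(inner) > 0) {
    i <- imin[inner]
    v0 <- M[cbind(inner, i - 1L)]
    v1 <- M[cbind(inner, i)]
    v2 <- M[cbind(inner, i + 1L)]
    t0 <- ti_values_ms[i - 1L]; t1v <- ti_values_ms[i]
    t2 <- ti_values_ms[i + 1L]
    # parabola vertex through three (t, v) points
    denom <- (t0 - t1v) * (t0 - t2) * (t1v - t2)
    a <- (t2 * (v1 - v0) + t1v * (v0 - v2) + t0 * (v2 - v1)) / denom
    b <- (t2^2 * (v0 - v1) + t1v^2 * (v2 - v0) + t0^2 * (v1 - v2)) / denom
    vert <- ifelse(a > 0, -b / (2 * a), t1v)
    null_ti[inner] <- pmin(pmax(vert, t0), t2)
  }
  null_ti[oob] <- NA_real_
  t1 <- null_ti / log(2 * efficiency)
  # sign convention for PSIR in out-of-range voxels: argmin at the first
  # TI means every sample is past the null (positive), at the last TI the
  # curve is still approaching it (negative)
  oob_sign <- ifelse(imin == 1L, 1, -1)
  shape <- function(v) {
    if (vec_in) v[1]
    else if (arr_in) array(v, dim(mag)[1:3])
    else v
  }
  list(null_ti_ms = shape(null_ti), t1_ms = shape(t1),
       out_of_range = shape(oob), oob_sign = shape(oob_sign))
}

#' Phase-sensitive inversion-recovery (PSIR) contrast
#'
#' Restores the polarity of magnitude DE images using the per-voxel null
#' map: a voxel's value at inversion time TI is `-|m|` below its null
#' point and `+|m|` at or above it. Out-of-range voxels take the sign of
#' their longest-TI trend. Every TI volume is normalized to `[-1, 1]`.
#'
#' @param mag 4D magnitude array `[x, y, z, ti]` (an `image_series`
#'   `data` is also accepted), or complex data whose phase is removed
#'   against `reference_phase` first.
#' @param null result of [detect_null_point()] on the same data (or a
#'   compatible list with `null_ti_ms`, `out_of_range`, `oob_sign`).
#' @param ti_values_ms TI of each volume.
#' @param reference_phase optional 3D phase reference (radians) used to
#'   rephase complex input before taking magnitudes.
#' @return object of class `ti_series` with signed `data`, `contrast =
#'   "PSIR"`, `ti_values_ms`, `null_map_ms`, `t1_map_ms`.
#' @export
make_psir <- function(mag, null, ti_values_ms, reference_phase = NULL) {
  if (inherits(mag, "image_series")) mag <- mag$data
  if (is.complex(mag)) {
    if (!is.null(reference_phase))
      mag <- mag * exp(-1i * array(reference_phase, dim(mag)))
    mag <- abs(mag)
  }
  d <- dim(mag)
  stopifnot(length(d) == 4, d[4] == length(ti_values_ms))
  nullmap <- array(null$null_ti_ms, d[1:3])
  oob <- array(null$out_of_range, d[1:3])
  osgn <- array(null$oob_sign, d[1:3])
  out <- array(0, d)
  for (t in seq_len(d[4])) {
    sgn <- ifelse(oob, osgn,
                  ifelse(ti_values_ms[t] < nullmap, -1, 1))
    v <- sgn * abs(mag[, , , t])
    mx <- max(abs(v))
    out[, , , t] <- if (mx > 0) v / mx else v
  }
  structure(list(data = out, ti_values_ms = ti_values_ms,
                 contrast = "PSIR",
                 null_map_ms = nullmap, t1_map_ms = array(null$t1_ms, d[1:3]),
                 out_of_range = oob),
            class = "ti_series")
}

#' Smallest resolved bar-grid pitch
#'
#' Draws a line profile through each post grid of a reconstructed
#' resolution phantom (after Fourier up-sampling of the central slice,
#' mirroring the interpolation used when the physical phantom is read
#' out), computes the modulation `(max - min) / (max + min)` over the
#' grid span, and declares a grid resolved when the modulation reaches
#' the threshold.
#'
#' @param recon reconstructed volume carrying `voxel_mm` and `grids`
#'   attributes (see [make_resolution_phantom()] / [acquire_static()]).
#' @param grid_sizes_mm pitches to assess; default: all grids present.
#' @param modulation_threshold minimum modulation for "resolved".
#' @param upsample Fourier interpolation factor for the profile.
#' @return list with a per-grid data.frame (`pitch_mm`, `modulation`,
#'   `resolved`) and `smallest_resolved_mm` (NA if none).
#' @export
resolve_resolution <- function(recon, grid_sizes_mm = NULL,
                               modulation_threshold = 0.5, upsample = 4) {
  info <- attr(recon, "grids")
  vx <- attr(recon, "voxel_mm")
  if (is.null(info) || is.null(vx))
    stop("recon must carry 'grids' and 'voxel_mm' attributes")
  if (!is.null(grid_sizes_mm))
    info <- info[info$pitch_mm %in% grid_sizes_mm, , drop = FALSE]
  d <- dim(recon)
  fov <- d * rep(vx, length.out = 3)
  zc <- max(1L, round(d[3] / 2))
  slice <- Re(recon[, , zc])
  # Fourier up-sampling of the slice
  K <- fftshiftn(stats::fft(slice))
  du <- d[1:2] * upsample
  Ku <- matrix(0 + 0i, du[1], du[2])
  off <- (du - d[1:2]) %/% 2
  Ku[(off[1] + 1):(off[1] + d[1]), (off[2] + 1):(off[2] + d[2])] <- K
  su <- Re(stats::fft(ifftshiftn(Ku), inverse = TRUE)) / length(K)
  vxu <- fov[1:2] / du
  xs <- ((seq_len(du[1]) - 1) + 0.5) * vxu[1] - fov[1] / 2
  ys <- ((seq_len(du[2]) - 1) + 0.5) * vxu[2] - fov[2] / 2
  res <- do.call(rbind, lapply(seq_len(nrow(info)), function(g) {
    row <- info[g, ]
    iy <- which.min(abs(ys - row$cy_mm))
    inx <- abs(xs - row$cx_mm) <= row$half_span_mm
    prof <- su[inx, iy]
    mx <- max(prof); mn <- min(prof)
    mod <- if (mx + mn <= 1e-12) 0 else (mx - mn) / (mx + mn)
    data.frame(pitch_mm = row$pitch_mm, modulation = mod,
               resolved = mod >= modulation_threshold)
  }))
  res <- res[order(res$pitch_mm), ]
  smallest <- if (any(res$resolved)) min(res$pitch_mm[res$resolved]) else NA_real_
  list(grids = res, smallest_resolved_mm = smallest)
}
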