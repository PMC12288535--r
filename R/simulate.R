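#' Simulate a free-running acquisition into raw k-space
#'
#' Samples the dynamic phantom line by line. In cine mode imaging lines
#' are drawn Gaussian-randomly on the ky-kz grid and a self-gating (SG)
#' line through the k-space center is inserted after every
#' `protocol$sg_interval` imaging lines; every line is sampled from the
#' phantom at the motion state of its timestamp. In DE mode each
#' simulated heartbeat consists of a trigger, one SG line, a wait of
#' `trigger_delay_ms`, an inversion pulse, and `acq_window_ms` of imaging
#' lines whose per-line inversion time is the time since the inversion;
#' the longitudinal signal follows [ir_signal()]. The readout axis is
#' always fully sampled.
#'
#' Motion is discretized: per-cardiac-cycle and per-respiratory-cycle
#' phases are quantized to `phantom$n_card_states` / `n_resp_states`
#' states and each state's coil-weighted 3D FFT is computed once and
#' cached, so runtime scales with the number of distinct motion states
#' rather than the number of lines.
#'
#' All randomness (sampling pattern, complex Gaussian noise) derives from
#' `protocol$seed`: identical protocols give bit-identical k-space.
#'
#' @param phantom a [phantom_state()].
#' @param protocol an [acq_protocol()]; `matrix_size` sets the simulation
#'   grid and `fov_mm` the rasterization FOV.
#' @param n_coils number of receive coils (>= 2).
#' @param snr image-domain signal-to-noise ratio (mean phantom magnitude
#'   over the noise standard deviation); `Inf` disables noise.
#' @return A [kspace_data()] whose `trigger_times_ms` holds the reference
#'   trigger series (ground-truth beat times for cine, pulse-oximeter
#'   triggers for DE).
#' @export
simulate_acquisition <- function(phantom, protocol, n_coils = 4, snr = Inf) {
  stopifnot(inherits(phantom, "phantom_state"),
            inherits(protocol, "acq_protocol"))
  if (protocol$mode == "prescan") {
    protocol$mode <- "cine"            # prescan is a short, coarse cine
    if (is.null(protocol$duration_s) || protocol$duration_s > 30)
      protocol$duration_s <- 30
  }
  set.seed(protocol$seed)
  if (protocol$mode == "cine") .simulate_cine(phantom, protocol, n_coils, snr)
  else .simulate_de(phantom, protocol, n_coils, snr)
}

# quantized respiratory shift (mm) for a state index 0..n_resp-1
.resp_shift <- function(state, n_resp, amp)
  amp * sin(2 * pi * (state + 0.5) / n_resp)

.gauss_kindex <- function(n_lines, N) {
  ctr <- grid_center(N)
  idx <- round(stats::rnorm(n_lines, mean = ctr, sd = N / 6))
  pmin(pmax(idx, 0), N - 1)
}

.noise_sd <- function(phantom, grid, fov_mm, snr) {
  if (!is.finite(snr)) return(0)
  ref <- make_cardiac_phantom(phantom, grid, 0, fov_mm)
  supp <- abs(ref$image) > 0
  if (!any(supp)) return(0)
  mu <- mean(abs(ref$image[supp]))
  mu / snr * sqrt(prod(rep(grid, length.out = 3)))
}

.add_noise <- function(data, sd) {
  if (sd <= 0) return(data)
  n <- length(data)
  data + complex(real = stats::rnorm(n, 0, sd / sqrt(2)),
                 imaginary = stats::rnorm(n, 0, sd / sqrt(2)))
}

.simulate_cine <- function(phantom, protocol, n_coils, snr) {
  N <- protocol$matrix_size
  fov <- protocol$fov_mm
  sens <- coil_sensitivities(N, fov, n_coils)
  fc <- phantom$cardiac_freq_hz
  fr <- phantom$resp_freq_hz
  nc_states <- phantom$n_card_states
  nr_states <- max(1L, if (phantom$resp_amp_mm > 0) phantom$n_resp_states else 1L)

  total_ms <- protocol$duration_s * 1000
  n_total <- floor(total_ms / protocol$tr_ms)
  i <- seq_len(n_total)
  t_ms <- (i - 1) * protocol$tr_ms
  is_sg <- (i %% (protocol$sg_interval + 1L)) == 0L
  ctr <- grid_center(N)
  ky <- integer(n_total); kz <- integer(n_total)
  n_img <- sum(!is_sg)
  ky[!is_sg] <- .gauss_kindex(n_img, N)
  kz[!is_sg] <- .gauss_kindex(n_img, N)
  ky[is_sg] <- ctr; kz[is_sg] <- ctr

  card_state <- floor(((t_ms / 1000 * fc) %% 1) * nc_states)
  resp_state <- if (nr_states > 1)
    floor(((t_ms / 1000 * fr) %% 1) * nr_states) else rep(0L, n_total)

  cache <- new.env(parent = emptyenv())
  get_state_fft <- function(ic, ir) {
    key <- paste0("c", ic, "r", ir)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ph <- make_cardiac_phantom(
      phantom, N, frame_phase = (ic + 0.5) / nc_states, fov_mm = fov,
      resp_shift_mm = .resp_shift(ir, nr_states, phantom$resp_amp_mm))
    K <- array(0 + 0i, c(N, N, N, n_coils))
    for (c in seq_len(n_coils))
      K[, , , c] <- kfwd(ph$image * sens[, , , c])
    cache[[key]] <- K
    K
  }

  data <- array(0 + 0i, c(n_total, N, n_coils))
  for (l in seq_len(n_total)) {
    K <- get_state_fft(card_state[l], resp_state[l])
    data[l, , ] <- K[, ky[l] + 1L, kz[l] + 1L, ]
  }
  data <- .add_noise(data, .noise_sd(phantom, N, fov, snr))

  n_trig <- ceiling(total_ms * fc / 1000 - 1e-9)   # beats starting in [0, T)
  triggers <- (seq_len(n_trig) - 1) * 1000 / fc
  kspace_data(data, t_ms, ifelse(is_sg, "self_gating", "imaging"),
              ky, kz, protocol, trigger_times_ms = triggers)
}

.simulate_de <- function(phantom, protocol, n_coils, snr) {
  N <- protocol$matrix_size
  fov <- protocol$fov_mm
  sens <- coil_sensitivities(N, fov, n_coils)
  rr_ms <- 1000 / phantom$cardiac_freq_hz
  window_ms <- protocol$acq_window_ms
  if (window_ms >= rr_ms) {
    warning("acquisition window >= RR interval: acquisition overlaps ",
            "beats; truncating the window to fit the rhythm")
    window_ms <- rr_ms - protocol$trigger_delay_ms - protocol$tr_ms
    if (window_ms < protocol$tr_ms)
      stop("RR interval too short for the trigger delay")
  }
  nr_states <- max(1L, if (phantom$resp_amp_mm > 0) phantom$n_resp_states else 1L)
  fr <- phantom$resp_freq_hz
  eff <- phantom$inversion_efficiency
  ctr <- grid_center(N)

  # cache: per (structure, respiratory state) coil-weighted FFT of the
  # structure's indicator volume; line = sum_s w_s(TI) * column_s
  cache <- new.env(parent = emptyenv())
  struct_names <- names(phantom$structures)
  get_struct_fft <- function(ir) {
    key <- paste0("r", ir)
    if (!is.null(cache[[key]])) return(cache[[key]])
    masks <- .phantom_masks(phantom, N, fov, frame_phase = 0,
                            resp_shift_mm = .resp_shift(ir, nr_states,
                                                        phantom$resp_amp_mm))
    Ks <- lapply(struct_names, function(nm) {
      K <- array(0 + 0i, c(N, N, N, n_coils))
      m <- masks[[nm]] + 0
      for (c in seq_len(n_coils)) K[, , , c] <- kfwd(m * sens[, , , c])
      K
    })
    names(Ks) <- struct_names
    cache[[key]] <- Ks
    Ks
  }
  pd <- vapply(phantom$structures, `[[`, numeric(1), "pd")
  t1 <- vapply(phantom$structures, `[[`, numeric(1), "t1_ms")

  lines_per_beat <- floor(window_ms / protocol$tr_ms)
  nb <- protocol$n_heartbeats
  n_total <- nb * (1L + lines_per_beat)
  data <- array(0 + 0i, c(n_total, N, n_coils))
  t_ms <- numeric(n_total); ti_ms <- rep(NA_real_, n_total)
  line_type <- character(n_total)
  ky <- integer(n_total); kz <- integer(n_total)
  triggers <- (seq_len(nb) - 1) * rr_ms

  ky_img <- .gauss_kindex(nb * lines_per_beat, N)
  kz_img <- .gauss_kindex(nb * lines_per_beat, N)
  img_ctr <- 0L
  row <- 0L
  for (b in seq_len(nb)) {
    tb <- triggers[b]
    resp_state <- if (nr_states > 1)
      floor(((tb / 1000 * fr) %% 1) * nr_states) else 0L
    Ks <- get_struct_fft(resp_state)
    # SG line at the trigger (pre-inversion, proton-density weighted)
    row <- row + 1L
    t_ms[row] <- tb; line_type[row] <- "self_gating"
    ky[row] <- ctr; kz[row] <- ctr
    for (s in seq_along(struct_names))
      data[row, , ] <- data[row, , ] +
        pd[s] * Ks[[s]][, ctr + 1L, ctr + 1L, ]
    t_inv <- tb + protocol$trigger_delay_ms
    for (j in seq_len(lines_per_beat)) {
      row <- row + 1L; img_ctr <- img_ctr + 1L
      ti <- j * protocol$tr_ms
      t_ms[row] <- t_inv + ti; ti_ms[row] <- ti
      line_type[row] <- "imaging"
      ky[row] <- ky_img[img_ctr]; kz[row] <- kz_img[img_ctr]
      w <- pd * ir_signal(ti, t1, efficiency = eff)
      acc <- matrix(0 + 0i, N, n_coils)
      for (s in seq_along(struct_names))
        if (w[s] != 0)
          acc <- acc + w[s] * Ks[[s]][, ky[row] + 1L, kz[row] + 1L, ]
      data[row, , ] <- acc
    }
  }
  data <- .add_noise(data, .noise_sd(phantom, N, fov, snr))
  kspace_data(data, t_ms, line_type, ky, kz, protocol, ti_ms = ti_ms,
              trigger_times_ms = triggers)
}

#' Total simulated scan span of a gated DE schedule
#'
#' Span from the first trigger to the end of the last acquisition window
#' for a pulse-oximeter-gated DE protocol at a steady heart rate.
#'
#' @param protocol a DE [acq_protocol()].
#' @param heart_rate_bpm steady rhythm in beats per minute.
#' @return span in minutes.
#' @export
de_scan_duration_min <- function(protocol, heart_rate_bpm = 60) {
  stopifnot(protocol$mode == "de")
  rr_ms <- 60000 / heart_rate_bpm
  last_trigger <- (protocol$n_heartbeats - 1) * rr_ms
  (last_trigger + protocol$trigger_delay_ms + protocol$acq_window_ms) / 60000
}

#' Band-limited static acquisition of a finely rasterized volume
#'
#' Emulates scanning a static phantom at a coarser acquisition
#' resolution: the fine volume's centered k-space is cropped to the
#' acquisition band and inverse transformed onto the acquisition grid.
#' The band is symmetric-inclusive: the positive-edge Nyquist bin is
#' folded onto its negative-edge partner so a real-valued object keeps
#' its full modulation at the band edge.
#'
#' @param volume complex 3D array with a `voxel_mm` attribute (e.g. from
#'   [make_resolution_phantom()]).
#' @param res_acq_mm acquisition voxel size in mm (scalar or length 3),
#'   must be a coarsening of the simulation grid.
#' @return complex 3D array at the acquisition resolution with
#'   `voxel_mm`, `fov_mm` (and, if present, `grids`) attributes.
#' @export
acquire_static <- function(volume, res_acq_mm) {
  vx <- attr(volume, "voxel_mm")
  if (is.null(vx)) stop("volume must carry a 'voxel_mm' attribute")
  d <- dim(volume)
  fov <- d * rep(vx, length.out = 3)
  n_acq <- round(fov / rep(res_acq_mm, length.out = 3))
  if (any(n_acq > d)) stop("acquisition resolution finer than the simulation")
  K <- kfwd(volume)
  sel <- lapply(seq_len(3), function(ax) {
    ctr <- grid_center(d[ax])               # 0-based DC position
    lo <- ctr - n_acq[ax] %/% 2
    (lo + 1):(lo + n_acq[ax])               # 1-based crop range
  })
  Kc <- do.call(`[`, c(list(K), sel, list(drop = FALSE)))
  # fold the excluded positive Nyquist bin onto the kept negative edge
  for (ax in seq_len(3)) {
    hi0 <- sel[[ax]][length(sel[[ax]])] + 1   # first excluded index
    if (hi0 <= d[ax] && n_acq[ax] < d[ax]) {
      idx <- sel; idx[[ax]] <- hi0
      slab <- do.call(`[`, c(list(K), idx, list(drop = FALSE)))
      tgt <- lapply(seq_len(3), function(a)
        if (a == ax) 1L else seq_len(n_acq[a]))
      ref <- do.call(`[`, c(list(Kc), tgt, list(drop = FALSE)))
      Kc <- .assign_slab(Kc, tgt, ref + array(slab, dim(ref)))
    }
  }
  # normalize so image intensities (and the mean) are preserved
  out <- kinv(Kc) * prod(n_acq) / prod(d)
  attr(out, "voxel_mm") <- fov / n_acq
  attr(out, "fov_mm") <- fov
  attr(out, "grids") <- attr(volume, "grids")
  out
}

.assign_slab <- function(x, idx, value) {
  do.call(`[<-`, c(list(x), idx, list(value = value)))
}
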