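#' Stack self-gating readouts into a channel matrix
#'
#' Collects every self-gating (SG) line of a raw acquisition and stacks
#' the central readout samples of every coil channel-wise, real and
#' imaginary parts as separate channels, with the per-channel mean
#' removed. Optional coil weights (e.g. derived from a heart ROI) scale
#' each coil's channels before stacking.
#'
#' @param raw a [kspace_data()] containing at least 2 SG lines.
#' @param roi_coil_weights optional numeric weight per coil.
#' @param n_center number of central readout samples kept per coil.
#' @return list with `mat` (SG samples x channels) and `times_ms`.
#' @export
extract_sg_matrix <- function(raw, roi_coil_weights = NULL, n_center = 16) {
  sg <- which(raw$line_type == "self_gating")
  if (length(sg) < 2)
    stop("raw data contains fewer than 2 self-gating lines; ",
         "wrong acquisition mode?")
  ns <- dim(raw$data)[2]; nc <- dim(raw$data)[3]
  keep <- min(n_center, ns)
  ctr <- grid_center(ns)
  lo <- max(1L, ctr + 1L - keep %/% 2)
  cols <- lo:min(ns, lo + keep - 1L)
  if (is.null(roi_coil_weights)) roi_coil_weights <- rep(1, nc)
  if (length(roi_coil_weights) != nc)
    stop("roi_coil_weights must have one entry per coil")
  blocks <- lapply(seq_len(nc), function(c) {
    x <- raw$data[sg, cols, c, drop = FALSE]
    dim(x) <- c(length(sg), length(cols))
    roi_coil_weights[c] * cbind(Re(x), Im(x))
  })
  mat <- do.call(cbind, blocks)
  mat <- sweep(mat, 2, colMeans(mat))
  list(mat = mat, times_ms = raw$timestamp_ms[sg])
}

# spectral energy fraction at or below `split_hz`, DC excluded
.low_band_fraction <- function(x, fs_hz, split_hz = 0.6) {
  n <- length(x)
  p <- abs(stats::fft(x - mean(x)))^2
  half <- seq(2, floor(n / 2) + 1)           # positive frequencies
  f <- (half - 1) * fs_hz / n
  tot <- sum(p[half])
  if (tot == 0) return(NA_real_)
  sum(p[half][f <= split_hz]) / tot
}

# dominant (highest-power) frequency, DC excluded
.dominant_freq <- function(x, fs_hz) {
  n <- length(x)
  p <- abs(stats::fft(x - mean(x)))^2
  half <- seq(2, floor(n / 2) + 1)
  (which.max(p[half])) * fs_hz / n
}

#' Separate cardiac and respiratory navigators by PCA + band energy
#'
#' Resamples the SG channel matrix to a uniform time grid, computes
#' principal components, and classifies each component by its spectral
#' energy split at 0.6 Hz: the highest-variance component whose energy is
#' dominantly (>= 60%) below 0.6 Hz becomes the respiratory signal, the
#' highest-variance component dominantly above becomes the cardiac
#' signal. Energy exactly at 0.6 Hz counts as respiratory.
#'
#' @param sg either the list returned by [extract_sg_matrix()] or a
#'   numeric matrix (samples x channels).
#' @param fs_hz sampling rate, required when `sg` is a plain matrix
#'   sampled uniformly; otherwise derived from the SG timestamps.
#' @param require_resp,require_cardiac raise an error if the band has no
#'   dominant component (maps to a failed automated self-gating exam).
#' @return list with `cardiac` and `resp` data.frames (`time_ms`,
#'   `value`; `NULL` when not required and absent), `fs_hz`, and the
#'   per-component `low_fraction` diagnostics.
#' @export
decompose_and_classify <- function(sg, fs_hz = NULL,
                                   require_resp = TRUE,
                                   require_cardiac = TRUE) {
  if (is.list(sg) && !is.null(sg$mat)) {
    times <- sg$times_ms
    dt <- stats::median(diff(times))
    fs_hz <- 1000 / dt
    grid <- seq(min(times), max(times), by = dt)
    mat <- apply(sg$mat, 2, function(col)
      stats::approx(times, col, xout = grid, rule = 2)$y)
    time_ms <- grid
  } else {
    if (is.null(fs_hz)) stop("fs_hz is required for a plain matrix input")
    mat <- as.matrix(sg)
    time_ms <- (seq_len(nrow(mat)) - 1) * 1000 / fs_hz
  }
  if (ncol(mat) < 2) stop("need at least 2 SG channels")
  keep <- apply(mat, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("all SG channels are constant")
  pc <- stats::prcomp(mat[, keep, drop = FALSE], center = TRUE)
  nkeep <- min(ncol(pc$x), 8L)
  lowfrac <- vapply(seq_len(nkeep), function(j)
    .low_band_fraction(pc$x[, j], fs_hz), numeric(1))
  resp_j <- which(!is.na(lowfrac) & lowfrac >= 0.6)[1]
  card_cand <- which(!is.na(lowfrac) & (1 - lowfrac) >= 0.6)
  # respiratory motion couples nonlinearly into the SG channels, so its
  # harmonics can dominate a high-band component; prefer the first
  # candidate whose dominant frequency is not a respiratory harmonic,
  # falling back to plain variance order when all are (e.g. when the two
  # rhythms happen to be commensurate)
  card_j <- card_cand[1]
  if (!is.na(resp_j) && length(card_cand) > 0) {
    f_resp <- .dominant_freq(pc$x[, resp_j], fs_hz)
    if (f_resp > 0) {
      # power of each candidate in the cardiac band with narrow bands
      # around the respiratory harmonics (k * f_resp +/- 6% of f_resp)
      # removed; prefer the candidate with the most non-harmonic power
      clean_power <- vapply(card_cand, function(j) {
        x <- pc$x[, j]
        n <- length(x)
        p <- abs(stats::fft(x - mean(x)))^2
        half <- seq(2, floor(n / 2) + 1)
        f <- (half - 1) * fs_hz / n
        k <- round(f / f_resp)
        harmonic <- k >= 1 & abs(f - k * f_resp) <= 0.06 * f_resp
        sum(p[half][f > 0.6 & !harmonic])
      }, numeric(1))
      if (any(clean_power > 0)) card_j <- card_cand[which.max(clean_power)]
    }
  }
  if (length(card_cand) == 0) card_j <- NA_integer_
  if (require_resp && is.na(resp_j))
    stop("no principal component with dominant energy below 0.6 Hz: ",
         "respiratory signal not found (failed automated self-gating)")
  if (require_cardiac && is.na(card_j))
    stop("no principal component with dominant energy above 0.6 Hz: ",
         "cardiac signal not found (failed automated self-gating)")
  mk <- function(j) if (is.na(j)) NULL else
    data.frame(time_ms = time_ms, value = pc$x[, j])
  list(cardiac = mk(card_j), resp = mk(resp_j), fs_hz = fs_hz,
       low_fraction = lowfrac)
}

#' Detect heartbeats on the cardiac navigator
#'
#' Applies a Savitzky-Golay filter to the cardiac signal, then finds
#' local maxima with a minimum separation of 0.6 times a naive RR
#' estimate (the period of the dominant spectral peak of the smoothed
#' signal). Because the sign of a principal component is arbitrary,
#' both polarities are tried and the one yielding the lower RR
#' coefficient of variation is kept.
#'
#' @param cardiac_signal data.frame with `time_ms` and `value`, sampled
#'   uniformly (as returned by [decompose_and_classify()]).
#' @param smoothing list with `window` (odd, > `polyorder`) and
#'   `polyorder` for the Savitzky-Golay filter.
#' @return numeric vector of peak times in ms.
#' @export
detect_peaks <- function(cardiac_signal, smoothing = list(window = 9,
                                                          polyorder = 3)) {
  w <- smoothing$window; p <- smoothing$polyorder
  if (w %% 2 == 0 || w <= p)
    stop("Savitzky-Golay window must be odd and larger than polyorder")
  x <- cardiac_signal$value
  t <- cardiac_signal$time_ms
  if (length(x) <= w) stop("cardiac signal shorter than the smoothing window")
  if (stats::sd(x) == 0) stop("constant cardiac signal: no peaks")
  xs <- signal::sgolayfilt(x, p = p, n = w)

  # naive RR estimate: period of the dominant spectral peak (DC excluded)
  n <- length(xs)
  pw <- abs(stats::fft(xs - mean(xs)))^2
  half <- 2:(floor(n / 2) + 1)
  f_dom <- which.max(pw[half])               # cycles per record
  naive_rr_samples <- n / f_dom
  # 0.6 x naive RR: wide enough to reject the secondary intra-beat bump
  # produced by atrial counter-motion, while the 2-SD rule still sees
  # genuinely short arrhythmic intervals as missing/rejected data
  minsep <- max(1L, floor(0.6 * naive_rr_samples))

  find_one <- function(s) {
    pk <- pracma::findpeaks(s, minpeakdistance = minsep,
                            minpeakheight = stats::median(s))
    if (is.null(pk) || nrow(pk) < 2) return(NULL)
    sort(pk[, 2])
  }
  cand <- list(pos = find_one(xs), neg = find_one(-xs))
  cv <- vapply(cand, function(idx) {
    if (is.null(idx)) return(Inf)
    rr <- diff(t[idx])
    stats::sd(rr) / mean(rr)
  }, numeric(1))
  if (all(!is.finite(cv))) stop("fewer than 2 peaks detected")
  t[cand[[which.min(cv)]]]
}

#' Reject arrhythmic RR intervals (two-standard-deviation rule)
#'
#' An interval is accepted iff its duration differs from the mean RR by
#' at most two standard deviations. Mean and SD are computed once over
#' all intervals (single pass).
#'
#' @param peak_times_ms at least 2 peak times in ms.
#' @return list with `rr_intervals_ms`, `accepted_mask`, `rr_mean_ms`,
#'   `rr_sd_ms`.
#' @export
reject_arrhythmic <- function(peak_times_ms) {
  if (length(peak_times_ms) < 2) stop("need at least 2 peaks")
  rr <- diff(peak_times_ms)
  m <- mean(rr)
  s <- stats::sd(rr)
  if (is.na(s)) s <- 0
  list(rr_intervals_ms = rr,
       accepted_mask = abs(rr - m) <= 2 * s,
       rr_mean_ms = m, rr_sd_ms = s)
}

#' Assign readouts to cardiac frames
#'
#' Cardiac phase is defined peak-to-peak with a linear stretch per
#' interval: a readout at time `t` inside the accepted interval
#' `[p_k, p_k+1)` gets bin `floor(n_bins * (t - p_k) / (p_k+1 - p_k))`.
#' Readouts inside rejected intervals or outside the peak span are
#' flagged rejected (`NA`).
#'
#' @param readout_times_ms readout timestamps.
#' @param peak_times_ms detected peak times.
#' @param accepted_mask logical per interval (from
#'   [reject_arrhythmic()]).
#' @param n_bins number of cardiac frames (default 30).
#' @return integer vector of bins in `[0, n_bins)`, `NA` for rejected.
#' @export
assign_cardiac_bins <- function(readout_times_ms, peak_times_ms,
                                accepted_mask, n_bins = 30) {
  k <- findInterval(readout_times_ms, peak_times_ms)
  out <- rep(NA_integer_, length(readout_times_ms))
  inside <- k >= 1 & readout_times_ms < peak_times_ms[length(peak_times_ms)]
  ok <- inside & accepted_mask[pmax(k, 1L)]
  kk <- k[ok]
  frac <- (readout_times_ms[ok] - peak_times_ms[kk]) /
    (peak_times_ms[kk + 1L] - peak_times_ms[kk])
  out[ok] <- pmin(as.integer(floor(n_bins * frac)), n_bins - 1L)
  out
}

#' Mode respiratory phase acceptance window
#'
#' Interpolates the respiratory navigator to the readout times, builds an
#' equal-width amplitude histogram and keeps readouts falling in the
#' modal bin (the most frequently occupied respiratory amplitude,
#' typically end-expiration).
#'
#' @param resp_signal data.frame with `time_ms` and `value`.
#' @param readout_times_ms readout timestamps.
#' @param n_hist_bins number of histogram bins (default 10).
#' @return list with `window` (amplitude lo/hi), `accepted` (logical per
#'   readout), `fraction` accepted, `amplitude` (interpolated values).
#' @export
respiratory_mode_window <- function(resp_signal, readout_times_ms,
                                    n_hist_bins = 10) {
  amp <- stats::approx(resp_signal$time_ms, resp_signal$value,
                       xout = readout_times_ms, rule = 2)$y
  rng <- range(amp)
  if (diff(rng) == 0) {
    return(list(window = rng, accepted = rep(TRUE, length(amp)),
                fraction = 1, amplitude = amp))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_hist_bins + 1)
  counts <- tabulate(pmin(findInterval(amp, breaks), n_hist_bins),
                     nbins = n_hist_bins)
  mode_bin <- which.max(counts)
  win <- c(breaks[mode_bin], breaks[mode_bin + 1])
  acc <- amp >= win[1] & amp <= win[2]
  list(window = win, accepted = acc, fraction = mean(acc), amplitude = amp)
}

#' Heart rate from accepted RR intervals
#'
#' @param rr_intervals_ms RR intervals in ms, or a `gating_result`.
#' @param accepted_mask logical per interval (ignored for a
#'   `gating_result`).
#' @return heart rate in beats per minute, `60000 / mean(accepted RR)`.
#' @export
heart_rate <- function(rr_intervals_ms, accepted_mask = NULL) {
  if (inherits(rr_intervals_ms, "gating_result")) {
    g <- rr_intervals_ms
    rr_intervals_ms <- g$rr_intervals_ms
    accepted_mask <- g$accepted_rr_mask
  }
  if (is.null(accepted_mask)) accepted_mask <- rep(TRUE, length(rr_intervals_ms))
  rr <- rr_intervals_ms[accepted_mask]
  if (length(rr) == 0) stop("no accepted RR intervals")
  60000 / mean(rr)
}

#' Compare detected beats to a reference trigger series
#'
#' Matches detected peaks to reference triggers by nearest-neighbor
#' pairing within half the median reference RR and summarizes counts,
#' rates and per-beat time offsets.
#'
#' @param peak_times_ms detected peak times (or a `gating_result`).
#' @param reference_trigger_times_ms reference beat times.
#' @return list with counts, mean heart rates, matched-beat `offsets_ms`
#'   (detected minus reference) and unmatched counts.
#' @export
compare_to_reference <- function(peak_times_ms, reference_trigger_times_ms) {
  if (inherits(peak_times_ms, "gating_result"))
    peak_times_ms <- peak_times_ms$peak_times_ms
  pk <- sort(peak_times_ms); ref <- sort(reference_trigger_times_ms)
  if (length(pk) == 0 || length(ref) == 0)
    stop("both series must be non-empty")
  tol <- if (length(ref) > 1) stats::median(diff(ref)) / 2 else Inf
  used <- rep(FALSE, length(pk))
  offsets <- rep(NA_real_, length(ref))
  for (i in seq_along(ref)) {
    d <- abs(pk - ref[i]); d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      offsets[i] <- pk[j] - ref[i]
    }
  }
  hr <- function(t) if (length(t) > 1) 60000 / mean(diff(t)) else NA_real_
  list(n_detected = length(pk), n_reference = length(ref),
       n_matched = sum(!is.na(offsets)),
       hr_detected_bpm = hr(pk), hr_reference_bpm = hr(ref),
       offsets_ms = offsets[!is.na(offsets)],
       n_unmatched_detected = sum(!used),
       n_unmatched_reference = sum(is.na(offsets)))
}

#' Run the full self-gating chain on a raw acquisition
#'
#' For cine data: SG matrix extraction, PCA band classification,
#' Savitzky-Golay peak detection, 2-SD RR rejection, 30-frame cardiac
#' binning of every imaging readout, and mode-respiratory-phase
#' acceptance. For DE data only the respiratory chain applies (the
#' acquisition is already trigger-gated).
#'
#' @param raw a [kspace_data()].
#' @param n_bins number of cardiac frames.
#' @param sg_window,sg_order Savitzky-Golay smoothing parameters.
#' @param n_hist_bins respiratory histogram bins.
#' @param roi_coil_weights optional per-coil weights for SG extraction.
#' @return object of class `gating_result` holding the navigator
#'   signals, peaks, RR statistics and per-imaging-readout assignments
#'   (`cardiac_bin` with `NA` = rejected, `resp_accepted`).
#' @export
self_gate <- function(raw, n_bins = 30, sg_window = 9, sg_order = 3,
                      n_hist_bins = 10, roi_coil_weights = NULL) {
  mode <- raw$header$protocol$mode
  sg <- extract_sg_matrix(raw, roi_coil_weights)
  img <- which(raw$line_type == "imaging")
  t_img <- raw$timestamp_ms[img]
  if (mode == "cine") {
    dec <- decompose_and_classify(sg)
    peaks <- detect_peaks(dec$cardiac,
                          smoothing = list(window = sg_window,
                                           polyorder = sg_order))
    rej <- reject_arrhythmic(peaks)
    bins <- assign_cardiac_bins(t_img, peaks, rej$accepted_mask, n_bins)
    resp <- respiratory_mode_window(dec$resp, t_img, n_hist_bins)
    hr <- heart_rate(rej$rr_intervals_ms, rej$accepted_mask)
  } else {
    if (all(apply(sg$mat, 2, stats::sd) == 0)) {
      # motionless acquisition (e.g. a stationary calibration phantom):
      # nothing to gate on, accept everything
      dec <- list(cardiac = NULL, resp = NULL)
      rsig <- data.frame(time_ms = sg$times_ms,
                         value = rep(0, length(sg$times_ms)))
    } else {
      dec <- decompose_and_classify(sg, require_cardiac = FALSE)
      rsig <- if (!is.null(dec$resp)) dec$resp else
        data.frame(time_ms = sg$times_ms, value = sg$mat[, 1])
    }
    resp <- respiratory_mode_window(rsig, t_img, n_hist_bins)
    peaks <- raw$trigger_times_ms
    rej <- if (length(peaks) >= 2) reject_arrhythmic(peaks) else
      list(rr_intervals_ms = numeric(0), accepted_mask = logical(0),
           rr_mean_ms = NA_real_, rr_sd_ms = NA_real_)
    bins <- rep(NA_integer_, length(img))
    hr <- if (length(rej$rr_intervals_ms) > 0)
      heart_rate(rej$rr_intervals_ms, rej$accepted_mask) else NA_real_
    dec$cardiac <- NULL
  }
  structure(list(
    cardiac_signal = dec$cardiac, resp_signal = dec$resp,
    peak_times_ms = peaks,
    rr_intervals_ms = rej$rr_intervals_ms,
    accepted_rr_mask = rej$accepted_mask,
    rr_mean_ms = rej$rr_mean_ms, rr_sd_ms = rej$rr_sd_ms,
    readout_index = img, readout_times_ms = t_img,
    cardiac_bin = bins, resp_accepted = resp$accepted,
    resp_window = resp$window, resp_fraction = resp$fraction,
    heart_rate_bpm = hr, n_bins = as.integer(n_bins)
  ), class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result> %d peaks, HR %.1f bpm, %d/%d RR accepted\n",
              length(x$peak_times_ms), x$heart_rate_bpm,
              sum(x$accepted_rr_mask), length(x$accepted_rr_mask)))
  cat(sprintf("  readouts: %d assigned / %d rejected (cardiac), %.0f%% in respiratory window\n",
              sum(!is.na(x$cardiac_bin)), sum(is.na(x$cardiac_bin)),
              100 * x$resp_fraction))
  invisible(x)
}
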