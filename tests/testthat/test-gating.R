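test_that("SG matrix has one row per SG line and zero column means", {
  raw <- shared_cine_raw()
  sg <- extract_sg_matrix(raw)
  expect_equal(nrow(sg$mat), sum(raw$line_type == "self_gating"))
  expect_lt(max(abs(colMeans(sg$mat))), 1e-10)
  # DE: one SG row per heartbeat
  de <- shared_de_raw()
  sgde <- extract_sg_matrix(de)
  expect_equal(nrow(sgde$mat), de$header$protocol$n_heartbeats)
  # no SG lines -> error naming the acquisition mode
  img_only <- raw
  keep <- raw$line_type == "imaging"
  img_only$data <- raw$data[keep, , , drop = FALSE]
  img_only$timestamp_ms <- raw$timestamp_ms[keep]
  img_only$line_type <- raw$line_type[keep]
  img_only$ky_index <- raw$ky_index[keep]
  img_only$kz_index <- raw$kz_index[keep]
  img_only$ti_ms <- raw$ti_ms[keep]
  expect_error(extract_sg_matrix(img_only), "acquisition mode")
})

test_that("0.6 Hz band rule assigns sinusoid components to the right bands", {
  set.seed(2)
  fs <- 10; t <- seq(0, 120, by = 1 / fs)
  # distinct source variances so the principal axes align with the
  # sources rather than an arbitrary rotation of their span
  resp_src <- 1.6 * sin(2 * pi * 0.25 * t)
  card_src <- 0.8 * sin(2 * pi * 1.2 * t)
  # rotate the two orthogonal sources into 4 mixed channels (orthonormal
  # mixing: a rotation, which PCA can undo given distinct variances)
  mix <- t(qr.Q(qr(matrix(rnorm(8), 4, 2))))
  mat <- cbind(resp_src, card_src) %*% mix
  dec <- decompose_and_classify(mat, fs_hz = fs)
  r_card <- abs(cor(dec$cardiac$value, card_src))
  r_resp <- abs(cor(dec$resp$value, resp_src))
  expect_gt(r_card, 0.99)
  expect_gt(r_resp, 0.99)
})

test_that("a missing band raises an error naming that band", {
  fs <- 10; t <- seq(0, 60, by = 1 / fs)
  only_cardiac <- cbind(sin(2 * pi * 1.0 * t), cos(2 * pi * 1.0 * t))
  expect_error(decompose_and_classify(only_cardiac, fs_hz = fs),
               "respiratory")
  only_resp <- cbind(sin(2 * pi * 0.2 * t), cos(2 * pi * 0.2 * t))
  expect_error(decompose_and_classify(only_resp, fs_hz = fs), "cardiac")
})

test_that("peak detection counts beats of a 1 Hz signal, with and without noise", {
  # noiseless: 600 s at 1 Hz -> 600 peaks, 60 bpm
  clean <- sine_signal(1, fs_hz = 20, dur_s = 600)
  pk <- detect_peaks(clean)
  expect_length(pk, 600)
  rr <- diff(pk)
  expect_equal(60000 / mean(rr), 60, tolerance = 0.01)
  # 20% amplitude Gaussian noise, fixed seed: count within +/- 1
  noisy <- sine_signal(1, fs_hz = 20, dur_s = 600, noise_sd = 0.2, seed = 1)
  pkn <- detect_peaks(noisy)
  expect_lte(abs(length(pkn) - 600), 1)
  # constant signal: error
  flat <- data.frame(time_ms = clean$time_ms, value = rep(1, nrow(clean)))
  expect_error(detect_peaks(flat), "constant|peaks")
  expect_error(detect_peaks(clean, smoothing = list(window = 8, polyorder = 3)),
               "odd")
})

test_that("2-SD rejection reproduces hand-computed masks", {
  # 18 x 1000 ms, one 2000 ms ectopic, one 1000 ms
  peaks <- cumsum(c(0, rep(1000, 18), 2000, 1000))
  r <- reject_arrhythmic(peaks)
  expect_equal(r$rr_mean_ms, 1050)
  expect_equal(r$rr_sd_ms, sqrt(50000), tolerance = 1e-9)   # ~223.6
  expect_equal(which(!r$accepted_mask), 19L)                # only the ectopic
  # all equal: sd 0, all accepted (<= comparison)
  r2 <- reject_arrhythmic(seq(0, 5000, by = 1000))
  expect_equal(r2$rr_sd_ms, 0)
  expect_true(all(r2$accepted_mask))
  # two intervals 800/1200: both within 2 SD
  r3 <- reject_arrhythmic(c(0, 800, 2000))
  expect_true(all(r3$accepted_mask))
})

test_that("cardiac bins follow the linear peak-to-peak phase stretch", {
  peaks <- c(0, 1000, 2000)
  acc <- c(TRUE, TRUE)
  expect_equal(assign_cardiac_bins(0, peaks, acc), 0L)       # t = p_k
  expect_equal(assign_cardiac_bins(500, peaks, acc), 15L)    # 50% -> bin 15
  expect_equal(assign_cardiac_bins(1999.9, peaks, acc), 29L)
  # readout in a rejected interval or outside the span -> NA
  expect_true(is.na(assign_cardiac_bins(500, peaks, c(FALSE, TRUE))))
  expect_true(is.na(assign_cardiac_bins(2500, peaks, acc)))
  expect_true(is.na(assign_cardiac_bins(-10, peaks, acc)))
})

test_that("binning conserves readouts and occupancy is near-uniform", {
  g <- shared_gating()
  n_assigned <- sum(!is.na(g$cardiac_bin))
  n_rejected <- sum(is.na(g$cardiac_bin))
  expect_equal(n_assigned + n_rejected, length(g$readout_times_ms))
  occ <- tabulate(g$cardiac_bin + 1L, nbins = 30)
  expect_lt(max(occ) / min(occ), 1.5)
  expect_true(all(g$cardiac_bin >= 0 & g$cardiac_bin < 30, na.rm = TRUE))
})

test_that("mode respiratory window picks the most occupied amplitude bin", {
  # constant amplitude: everything accepted
  flat <- data.frame(time_ms = 0:100 * 100, value = rep(2, 101))
  r <- respiratory_mode_window(flat, seq(0, 10000, by = 50))
  expect_equal(r$fraction, 1)
  # sinusoid: arcsine density -> modal bin at an extreme, fraction > 1/10
  t <- seq(0, 100, by = 0.05)
  sig <- data.frame(time_ms = t * 1000, value = sin(2 * pi * 0.25 * t))
  rs <- respiratory_mode_window(sig, t * 1000)
  expect_gt(rs$fraction, 1 / 10)
  extreme <- max(abs(rs$window))
  expect_gt(extreme, 0.75)                   # window touches an extreme
  # bimodal 70/30: window covers the dominant mode
  amp <- c(rnorm(700, 10, 0.1), rnorm(300, 0, 0.1))
  sig2 <- data.frame(time_ms = seq_along(amp) * 10, value = amp)
  rb <- respiratory_mode_window(sig2, seq_along(amp) * 10)
  expect_gt(mean(rb$window), 5)              # around the 70% mode at 10
  expect_gt(rb$fraction, 0.5)
})

test_that("heart rate is 60000 over the mean accepted RR", {
  expect_equal(heart_rate(rep(1000, 10)), 60)
  expect_equal(heart_rate(rep(500, 4)), 120)
  expect_equal(heart_rate(c(800, 1200)), 60)
  expect_equal(heart_rate(c(800, 1200, 5000), c(TRUE, TRUE, FALSE)), 60)
  expect_error(heart_rate(c(1000), FALSE), "no accepted")
})

test_that("reference comparison matches beats and reports offsets", {
  ref <- seq(0, 59000, by = 1000)
  same <- compare_to_reference(ref, ref)
  expect_equal(same$n_matched, 60)
  expect_true(all(same$offsets_ms == 0))
  lag <- compare_to_reference(ref + 50, ref)
  expect_true(all(lag$offsets_ms == 50))
  spur <- compare_to_reference(sort(c(ref, 500.1)), ref)
  expect_equal(spur$n_detected - spur$n_reference, 1)
  expect_equal(spur$n_unmatched_detected, 1)
})

test_that("self-gating recovers rate and beat count across physiologic ranges", {
  # end-to-end parameter recovery on short seeded acquisitions
  cases <- list(c(cardiac = 50 / 60, resp = 0.1, seed = 21),
                c(cardiac = 75 / 60, resp = 0.3, seed = 23),
                c(cardiac = 100 / 60, resp = 0.4, seed = 22))
  for (cs in cases) {
    ph <- default_heart_phantom(cardiac_freq_hz = cs[["cardiac"]],
                                resp_freq_hz = cs[["resp"]])
    raw <- simulate_acquisition(
      ph, test_cine_protocol(duration_s = 60, seed = cs[["seed"]]),
      n_coils = 4, snr = 20)
    g <- self_gate(raw)
    expect_lt(abs(g$heart_rate_bpm - 60 * cs[["cardiac"]]), 1)
    expect_lte(abs(length(g$peak_times_ms) -
                     length(raw$trigger_times_ms)), 1)
  }
})
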