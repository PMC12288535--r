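# shared fixtures, built in code at test time

test_phantom <- function(...) default_heart_phantom(...)

test_cine_protocol <- function(duration_s = 60, seed = 1, ...) {
  cine_protocol(fov_mm = 160, matrix_size = 32, tr_ms = 5,
                duration_s = duration_s, seed = seed, ...)
}

test_de_protocol <- function(n_heartbeats = 40, seed = 1, ...) {
  de_protocol(fov_mm = 160, matrix_size = 32, tr_ms = 4,
              n_heartbeats = n_heartbeats, seed = seed, ...)
}

# cached simulated cine acquisition shared across tests (built once)
.sim_env <- new.env()
shared_cine_raw <- function() {
  if (is.null(.sim_env$raw)) {
    ph <- test_phantom()
    proto <- test_cine_protocol(duration_s = 120, seed = 42)
    .sim_env$raw <- simulate_acquisition(ph, proto, n_coils = 4, snr = 20)
    .sim_env$phantom <- ph
  }
  .sim_env$raw
}
shared_cine_phantom <- function() {
  shared_cine_raw()
  .sim_env$phantom
}
shared_gating <- function() {
  if (is.null(.sim_env$gating)) .sim_env$gating <- self_gate(shared_cine_raw())
  .sim_env$gating
}

shared_de_raw <- function() {
  if (is.null(.sim_env$de_raw)) {
    ph <- make_t1mes_phantom()
    proto <- test_de_protocol(n_heartbeats = 60, seed = 3)
    .sim_env$de_raw <- simulate_acquisition(ph, proto, n_coils = 2,
                                            snr = Inf)
    .sim_env$de_phantom <- ph
  }
  .sim_env$de_raw
}
shared_de_phantom <- function() {
  shared_de_raw()
  .sim_env$de_phantom
}

# synthetic uniformly sampled sinusoid navigator
sine_signal <- function(freq_hz, fs_hz = 20, dur_s = 60, noise_sd = 0,
                        seed = 1) {
  set.seed(seed)
  t <- seq(0, dur_s - 1 / fs_hz, by = 1 / fs_hz)
  data.frame(time_ms = t * 1000,
             value = sin(2 * pi * freq_hz * t) +
               stats::rnorm(length(t), 0, noise_sd))
}

# independent (test-local) centered FFT pair, for round-trip oracles
oracle_kfwd <- function(img) {
  K <- stats::fft(img)
  d <- dim(K)
  idx <- lapply(d, function(n) {
    h <- floor(n / 2); c(seq_len(n)[-seq_len(h)], seq_len(h))
  })
  do.call(`[`, c(list(K), idx))
}

# inverse fftshift for the oracle pair
ifftshift_oracle <- function(K) {
  d <- dim(K)
  idx <- lapply(d, function(n) {
    h <- ceiling(n / 2); c(seq_len(n)[-seq_len(h)], seq_len(h))
  })
  do.call(`[`, c(list(K), idx))
}
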