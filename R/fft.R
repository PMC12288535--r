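# Centered FFT conventions used package-wide:
#   forward (image -> k-space):  K = fftshift(fft(img))     [negative exponent]
#   inverse (k-space -> image):  img = ifft(ifftshift(K)) / prod(dim)
# After fftshift the DC sample sits at 0-based index N %/% 2 on every axis,
# which is where the simulator places self-gating lines.

.shift_idx <- function(n, inverse = FALSE) {
  # fftshift rotates by ceiling(n/2), ifftshift by floor(n/2); they only
  # differ for odd n (e.g. odd band-limited crops)
  h <- if (inverse) floor(n / 2) else ceiling(n / 2)
  c(seq_len(n)[-seq_len(h)], seq_len(h))
}

# circular shift along every dimension (fftshift) or its inverse
fftshiftn <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) return(x[.shift_idx(length(x), inverse)])
  idx <- lapply(d, .shift_idx, inverse = inverse)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftshiftn <- function(x) fftshiftn(x, inverse = TRUE)

# centered forward/inverse n-dimensional FFT
kfwd <- function(img) fftshiftn(stats::fft(img))
kinv <- function(ksp) stats::fft(ifftshiftn(ksp), inverse = TRUE) / length(ksp)

# centered unitary 2D FFT applied to a [nx, ny] matrix (used by the CS solver)
fft2c <- function(x) fftshiftn(stats::fft(x)) / sqrt(length(x))
ifft2c <- function(k) stats::fft(ifftshiftn(k), inverse = TRUE) / sqrt(length(k))
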