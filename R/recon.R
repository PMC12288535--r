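#' Average image from all cine data
#'
#' Grids every line onto the Cartesian grid (samples repeated at the same
#' ky-kz location are averaged), inverse Fourier transforms, and combines
#' coils by root-sum-of-squares. This motion-averaged volume seeds heart
#' localization and ROVir.
#'
#' @param raw a cine [kspace_data()].
#' @return real 3D array (RSS magnitude) with `voxel_mm` attribute.
#' @export
average_image <- function(raw) {
  n <- length(raw$timestamp_ms)
  if (n == 0) stop("empty raw data")
  N <- raw$header$grid[1]; nc <- raw$header$n_coils
  acc <- array(0 + 0i, c(N, N, N, nc))
  cnt <- matrix(0L, N, N)
  for (l in seq_len(n)) {
    iy <- raw$ky_index[l] + 1L; iz <- raw$kz_index[l] + 1L
    acc[, iy, iz, ] <- acc[, iy, iz, ] + raw$data[l, , ]
    cnt[iy, iz] <- cnt[iy, iz] + 1L
  }
  w <- ifelse(cnt > 0, 1 / pmax(cnt, 1L), 0)
  out <- array(0, c(N, N, N))
  for (c in seq_len(nc)) {
    K <- acc[, , , c] * rep(w, each = N)
    out <- out + abs(kinv(K))^2
  }
  out <- sqrt(out)
  attr(out, "voxel_mm") <- rep(raw$header$fov_mm / N, 3)
  out
}

# binary dilation by r steps of the 6-neighborhood
.dilate3 <- function(mask, r = 1) {
  d <- dim(mask)
  for (i in seq_len(r)) {
    m <- mask
    m[-1, , ] <- m[-1, , ] | mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] | mask[-1, , ]
    m[, -1, ] <- m[, -1, ] | mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] | mask[, -1, ]
    m[, , -1] <- m[, , -1] | mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] | mask[, , -1]
    mask <- m
  }
  mask
}

# largest 6-connected component of a logical array
.largest_component <- function(mask) {
  remaining <- mask
  best <- NULL; best_size <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- .dilate3(seed, 1) & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    if (sum(seed) > best_size) { best <- seed; best_size <- sum(seed) }
    remaining <- remaining & !seed
  }
  best
}

#' Localize the heart on the average image
#'
#' Builds the region-of-interest mask either from ground-truth labels
#' (dilated union of all cardiac structures) or by intensity thresholding
#' with a largest-connected-component fallback. The interference region
#' is the FOV minus a further-dilated ROI.
#'
#' @param average 3D volume from [average_image()].
#' @param labels_or_threshold integer label array (labels mode) or a
#'   numeric scalar absolute intensity threshold (threshold mode).
#' @param roi_dilate,interference_gap dilation radii (voxels) for the ROI
#'   and for the guard band separating ROI from interference region.
#' @return list with logical `roi` and `interference` masks.
#' @export
heart_roi <- function(average, labels_or_threshold, roi_dilate = 2,
                      interference_gap = 4) {
  if (any(!is.finite(average))) stop("average volume must be finite")
  if (is.array(labels_or_threshold) || is.integer(labels_or_threshold)) {
    core <- labels_or_threshold > 0
  } else {
    if (diff(range(average)) == 0)
      stop("uniform image: no connected component to segment")
    bin <- average > labels_or_threshold
    if (!any(bin)) stop("empty ROI: threshold above image maximum")
    core <- .largest_component(bin)
  }
  if (!any(core)) stop("empty ROI")
  roi <- .dilate3(core, roi_dilate)
  interference <- !.dilate3(roi, interference_gap)
  list(roi = roi, interference = interference)
}

#' Region-optimized virtual coil basis
#'
#' Forms signal Gram matrices over the ROI voxels (A) and interference
#' voxels (B) from per-coil images and solves the generalized
#' eigenproblem `A w = lambda B w`. The leading eigenvectors maximize
#' ROI-to-interference signal energy; enough are kept to retain the
#' requested fraction of ROI energy (or exactly `n_virtual`). Weights
#' are orthonormalized and eigenvalues sorted descending.
#'
#' @param coil_images complex array `[x, y, z, coil]`.
#' @param roi_mask,interference_mask disjoint, non-empty logical masks.
#' @param n_virtual number of virtual coils to keep (overrides
#'   `energy_fraction`).
#' @param energy_fraction fraction of ROI energy to retain (default
#'   0.95).
#' @return object of class `virtual_coil_basis` with `weights`
#'   (coils x virtual, orthonormal), `eigenvalues`, `roi_energy`, and
#'   the masks used.
#' @export
rovir_basis <- function(coil_images, roi_mask, interference_mask,
                        n_virtual = NULL, energy_fraction = 0.95) {
  if (!any(roi_mask) || !any(interference_mask))
    stop("ROI and interference masks must both be non-empty")
  if (any(roi_mask & interference_mask))
    stop("ROI and interference masks must be disjoint")
  nc <- dim(coil_images)[4]
  S <- matrix(coil_images, ncol = nc)
  Sa <- S[as.vector(roi_mask), , drop = FALSE]
  Sb <- S[as.vector(interference_mask), , drop = FALSE]
  A <- Conj(t(Sa)) %*% Sa
  B <- Conj(t(Sb)) %*% Sb
  trB <- Re(sum(diag(B)))
  eps <- 1e-9 * max(trB / nc, Re(sum(diag(A))) / nc, 1e-30)
  eb <- eigen(B, symmetric = TRUE)
  if (min(eb$values) < eps) {
    message("rovir_basis: near-singular interference Gram matrix, ",
            "adding ridge")
    B <- B + diag(eps * trB / nc + eps, nc)
    eb <- eigen(B, symmetric = TRUE)
  }
  Winv_sqrt <- eb$vectors %*% diag(1 / sqrt(pmax(eb$values, eps)), nc) %*%
    Conj(t(eb$vectors))
  M <- Winv_sqrt %*% A %*% Winv_sqrt
  M <- (M + Conj(t(M))) / 2
  em <- eigen(M, symmetric = TRUE)
  Wfull <- Winv_sqrt %*% em$vectors          # generalized eigenvectors
  roi_energy <- Re(diag(Conj(t(Wfull)) %*% A %*% Wfull)) /
    colSums(abs(Wfull)^2)                    # per unit weight norm
  if (is.null(n_virtual)) {
    cum <- cumsum(roi_energy) / sum(roi_energy)
    n_virtual <- which(cum >= energy_fraction)[1]
  }
  n_virtual <- min(n_virtual, nc)
  W <- Wfull[, seq_len(n_virtual), drop = FALSE]
  W <- qr.Q(qr(W))                           # orthonormalize
  structure(list(weights = W, eigenvalues = em$values,
                 roi_energy = roi_energy,
                 n_virtual = n_virtual,
                 roi_mask = roi_mask, interference_mask = interference_mask),
            class = "virtual_coil_basis")
}

#' Project multi-coil data through a virtual coil basis
#'
#' @param x complex array whose last dimension indexes physical coils
#'   (k-space lines, coil images, or sensitivities).
#' @param basis a [rovir_basis()].
#' @return array with the last dimension replaced by virtual coils.
#' @export
rovir_project <- function(x, basis) {
  d <- dim(x)
  nc <- d[length(d)]
  stopifnot(nc == nrow(basis$weights))
  m <- matrix(x, ncol = nc) %*% basis$weights
  array(m, c(d[-length(d)], ncol(basis$weights)))
}

# ---- cyclic temporal total-variation proximal operator -------------------

# prox of  min_x 0.5*||x - z||^2 + lam_v * sum_t |x_{t+1} - x_t| (cyclic),
# rows of z are voxels, columns time frames; lam is a per-row weight.
# Solved in the dual by projected gradient (step 1/4 since ||D||^2 <= 4).
.tv_prox_rows <- function(z, lam, n_dual_iter = 40) {
  Tn <- ncol(z)
  Dop <- function(x) x[, c(2:Tn, 1), drop = FALSE] - x
  Dt <- function(p) p[, c(Tn, 1:(Tn - 1)), drop = FALSE] - p
  p <- matrix(0, nrow(z), Tn)
  for (i in seq_len(n_dual_iter)) {
    g <- Dop(z - Dt(p))
    p <- p + 0.25 * g
    p <- pmin(pmax(p, -lam), lam)
  }
  z - Dt(p)
}

.tv_prox_complex <- function(z, lam, n_dual_iter = 40) {
  .tv_prox_rows(Re(z), lam, n_dual_iter) +
    1i * .tv_prox_rows(Im(z), lam, n_dual_iter)
}

# anisotropic (real+imag) cyclic temporal TV of a [V, T] complex matrix
.tv_value <- function(x) {
  Tn <- ncol(x)
  d <- x[, c(2:Tn, 1), drop = FALSE] - x
  sum(abs(Re(d))) + sum(abs(Im(d)))
}

# centered unitary 2D FFT of a [n1, n2, ...] stack, transforming dims 1:2.
# Convention matches kfwd/kinv: forward shifts after the transform,
# inverse un-shifts before it (no symmetric pre-shift).
.fft1c_axis <- function(x, inverse) {
  d <- dim(x); n <- d[1]
  m <- matrix(x, nrow = n)
  if (inverse) {
    m <- m[.shift_idx(n, inverse = TRUE), , drop = FALSE]
    m <- stats::mvfft(m, inverse = TRUE) / sqrt(n)
  } else {
    m <- stats::mvfft(m) / sqrt(n)
    m <- m[.shift_idx(n), , drop = FALSE]
  }
  array(m, d)
}

.fft2c_stack <- function(x, inverse = FALSE) {
  d <- dim(x)
  x <- .fft1c_axis(x, inverse)
  perm <- c(2, 1, seq_along(d)[-(1:2)])
  x <- aperm(x, perm)
  x <- .fft1c_axis(x, inverse)
  aperm(x, perm)
}

#' Slice-wise compressed-sensing SENSE reconstruction with temporal TV
#'
#' After an inverse FFT along the fully sampled readout axis, every axial
#' slice is solved as an independent 2D+time inverse problem
#' `min_x 0.5 * ||E x - y||^2 + lambda_tv * sum |x_(t+1) - x_t|` with
#' `E` = per-frame ky-kz sampling o centered unitary 2D FFT o coil
#' sensitivity multiplication, the temporal difference cyclic over the
#' frames, and the TV applied anisotropically to real and imaginary
#' parts. The solver is a Jacobi-preconditioned proximal gradient descent
#' with objective-based backtracking, so the logged objective is
#' non-increasing by construction.
#'
#' @param ksp complex array `[kx, ky, kz, frame, coil]` of gridded binned
#'   k-space (unsampled cells zero).
#' @param mask logical array `[ky, kz, frame]` of sampled cells.
#' @param sens complex sensitivity array `[x, y, z, coil]`.
#' @param lambda_tv temporal TV weight; `NULL` (default) uses
#'   `0.01 * max |adjoint image|`.
#' @param n_iter number of outer iterations.
#' @param voxel_mm voxel size recorded in the output.
#' @param verbose print per-iteration objective.
#' @return an `image_series`: list with complex `data`
#'   `[x, y, z, frame]`, `voxel_mm`, `frame_semantic`, and attribute
#'   `objective` (the per-iteration objective trace).
#' @export
cs_reconstruct <- function(ksp, mask, sens, lambda_tv = NULL, n_iter = 20,
                           voxel_mm = c(1, 1, 1), verbose = FALSE) {
  d <- dim(ksp)
  N <- d[1]; Tn <- d[4]; nc <- d[5]
  stopifnot(all(dim(mask) == c(d[2], d[3], Tn)),
            all(dim(sens)[1:3] == d[1:3]), dim(sens)[4] == nc)
  # hybrid space: centered inverse FFT along the readout axis (same
  # convention as kinv: un-shift, then inverse transform)
  m <- matrix(ksp, nrow = N)
  m <- m[.shift_idx(N, inverse = TRUE), , drop = FALSE]
  m <- stats::mvfft(m, inverse = TRUE) / N
  hyb <- array(m, d)

  maskT <- mask
  storage.mode(maskT) <- "double"
  out <- array(0 + 0i, c(d[1], d[2], d[3], Tn))
  obj_trace <- matrix(NA_real_, N, n_iter + 1)

  for (sl in seq_len(N)) {
    y <- array(hyb[sl, , , , ], c(d[2], d[3], Tn, nc))
    s <- array(sens[sl, , , ], c(d[2], d[3], nc))
    Dsos <- apply(abs(s)^2, c(1, 2), sum)
    pre <- 1 / (Dsos + 1e-8 * max(Dsos, 1e-30))
    Eop <- function(x) {              # x: [y, z, T] -> k: [y, z, T, coil]
      k <- array(0 + 0i, c(d[2], d[3], Tn, nc))
      for (c in seq_len(nc))
        k[, , , c] <- .fft2c_stack(x * as.vector(s[, , c])) * maskT
      k
    }
    Eadj <- function(k) {
      x <- array(0 + 0i, c(d[2], d[3], Tn))
      for (c in seq_len(nc))
        x <- x + Conj(as.vector(s[, , c])) *
          .fft2c_stack(array(k[, , , c], c(d[2], d[3], Tn)) * maskT,
                       inverse = TRUE)
      x
    }
    adj <- Eadj(y)
    lam <- if (is.null(lambda_tv)) 0.01 * max(abs(adj)) else lambda_tv
    x <- adj * as.vector(pre)
    objective <- function(x) {
      r <- Eop(x) - y
      0.5 * sum(abs(r)^2) +
        if (lam > 0) lam * .tv_value(matrix(x, ncol = Tn)) else 0
    }
    fx <- objective(x)
    obj_trace[sl, 1] <- fx
    alpha <- 1
    for (it in seq_len(n_iter)) {
      g <- Eadj(Eop(x) - y)
      accepted <- FALSE
      a <- alpha
      for (bt in 1:12) {
        z <- x - a * as.vector(pre) * g
        xn <- if (lam > 0) {
          lamv <- lam * a * as.vector(pre)
          array(.tv_prox_complex(matrix(z, ncol = Tn),
                                 matrix(lamv, nrow = d[2] * d[3],
                                        ncol = Tn)),
                c(d[2], d[3], Tn))
        } else z
        fn <- objective(xn)
        if (fn <= fx + 1e-12 * abs(fx)) { accepted <- TRUE; break }
        a <- a / 2
      }
      if (accepted && fn < fx) { x <- xn; fx <- fn; alpha <- min(a * 2, 1) }
      obj_trace[sl, it + 1] <- fx
      if (verbose)
        message(sprintf("slice %d iter %d objective %.6g (step %.3g)",
                        sl, it, fx, a))
    }
    out[sl, , , ] <- x
  }
  # input k-space uses the unnormalized forward FFT (kfwd); the slice
  # solver works with unitary 2D transforms, so rescale to image units
  out <- out / sqrt(d[2] * d[3])
  res <- structure(list(data = out, voxel_mm = rep(voxel_mm, length.out = 3),
                        frame_semantic = "cardiac_phase",
                        n_frames = Tn),
                   class = "image_series")
  attr(res, "objective") <- colSums(obj_trace)
  res
}

#' Locally-low-rank (multi-scale) denoising
#'
#' For each spatial block size, tiles the volume into non-overlapping
#' blocks, forms block-by-frame Casorati matrices, soft-thresholds their
#' singular values, and averages the reconstructions across scales.
#'
#' @param series an `image_series` or a complex/real 4D array
#'   `[x, y, z, frame]`.
#' @param block_sizes vector of cubic block edge lengths (voxels).
#' @param thresholds non-negative singular-value thresholds, one per
#'   scale (recycled).
#' @return same type as the input, denoised.
#' @export
llr_denoise <- function(series, block_sizes = c(4, 8), thresholds = 0.05) {
  is_series <- inherits(series, "image_series")
  x <- if (is_series) series$data else series
  if (any(thresholds < 0)) stop("thresholds must be non-negative")
  thresholds <- rep(thresholds, length.out = length(block_sizes))
  d <- dim(x); Tn <- d[4]
  accum <- array(0 + 0i, d)
  for (si in seq_along(block_sizes)) {
    b <- block_sizes[si]; tau <- thresholds[si]
    dp <- ceiling(d[1:3] / b) * b
    xp <- array(0 + 0i, c(dp, Tn))
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
    for (i in seq(1, dp[1], by = b)) for (j in seq(1, dp[2], by = b))
      for (k in seq(1, dp[3], by = b)) {
        blk <- xp[i:(i + b - 1), j:(j + b - 1), k:(k + b - 1), , drop = FALSE]
        M <- matrix(blk, ncol = Tn)
        if (tau > 0) {
          sv <- svd(M)
          ds <- pmax(sv$d - tau, 0)
          M <- sv$u %*% (ds * Conj(t(sv$v)))
        }
        xp[i:(i + b - 1), j:(j + b - 1), k:(k + b - 1), ] <-
          array(M, c(b, b, b, Tn))
      }
    accum <- accum + xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ,
                        drop = FALSE]
  }
  out <- accum / length(block_sizes)
  if (!is.complex(x)) out <- Re(out)
  if (is_series) { series$data <- out; series } else out
}

#' Grid accepted cine readouts into per-frame k-space
#'
#' Applies the respiratory acceptance window and cardiac frame
#' assignment of a [self_gate()] result, accumulating accepted imaging
#' lines onto the `[kx, ky, kz, frame, coil]` grid with averaging of
#' repeated cells.
#'
#' @param raw cine [kspace_data()].
#' @param gating matching `gating_result`.
#' @return list with `ksp`, logical `mask` `[ky, kz, frame]`, and
#'   per-frame accepted line counts `n_lines`.
#' @export
bin_cine_kspace <- function(raw, gating) {
  N <- raw$header$grid[1]; nc <- raw$header$n_coils
  Tn <- gating$n_bins
  keep <- !is.na(gating$cardiac_bin) & gating$resp_accepted
  idx <- gating$readout_index[keep]
  bins <- gating$cardiac_bin[keep] + 1L
  ksp <- array(0 + 0i, c(N, N, N, Tn, nc))
  cnt <- array(0L, c(N, N, Tn))
  for (r in seq_along(idx)) {
    l <- idx[r]
    iy <- raw$ky_index[l] + 1L; iz <- raw$kz_index[l] + 1L; f <- bins[r]
    ksp[, iy, iz, f, ] <- ksp[, iy, iz, f, ] + raw$data[l, , ]
    cnt[iy, iz, f] <- cnt[iy, iz, f] + 1L
  }
  for (f in seq_len(Tn)) {
    w <- ifelse(cnt[, , f] > 0, 1 / pmax(cnt[, , f], 1L), 0)
    for (c in seq_len(nc))
      ksp[, , , f, c] <- ksp[, , , f, c] * rep(w, each = N)
  }
  list(ksp = ksp, mask = cnt > 0,
       n_lines = apply(cnt, 3, sum))
}
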