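# small synthetic 2D+time problems exercise the solver; the heavier
# end-to-end cine case lives in test-acceptance.R

make_dynamic_disc <- function(N = 16, Tn = 10, nc = 3, accel = 4,
                              seed = 5) {
  set.seed(seed)
  xs <- (1:N) - N / 2 - 0.5
  truth <- array(0 + 0i, c(N, N, N, Tn))
  for (f in 1:Tn) {
    r <- 4 + 1.5 * sin(2 * pi * (f - 1) / Tn)
    truth[, , , f] <- (outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= r^2) + 0i
  }
  sens <- coil_sensitivities(N, 160, nc)
  ksp <- array(0 + 0i, c(N, N, N, Tn, nc))
  mask <- array(FALSE, c(N, N, Tn))
  for (f in 1:Tn) {
    sel <- sample(N * N, round(N * N / accel))
    iy <- (sel - 1) %% N + 1; iz <- (sel - 1) %/% N + 1
    for (c in 1:nc) {
      K <- oracle_kfwd(truth[, , , f] * sens[, , , c])
      for (s in seq_along(iy)) ksp[, iy[s], iz[s], f, c] <- K[, iy[s], iz[s]]
    }
    mask[cbind(iy, iz, f)] <- TRUE
  }
  # SENSE-combined zero-filled baseline (inverse FFT of zero-filled data)
  den <- apply(abs(sens)^2, 1:3, sum)
  zf <- array(0 + 0i, dim(truth))
  for (f in 1:Tn) {
    num <- array(0 + 0i, c(N, N, N))
    for (c in 1:nc)
      num <- num + Conj(sens[, , , c]) *
        (stats::fft(ifftshift_oracle(ksp[, , , f, c]), inverse = TRUE) /
           N^3)
    zf[, , , f] <- num / (den + 1e-8)
  }
  list(truth = truth, sens = sens, ksp = ksp, mask = mask, zf = zf)
}

test_that("average image of a static fully-sampled phantom matches rasterization", {
  ph <- default_heart_phantom(contraction_amplitude = 0,
                              atrial_amplitude = 0, resp_amp_mm = 0)
  proto <- test_cine_protocol(duration_s = 60, seed = 2)
  raw <- simulate_acquisition(ph, proto, n_coils = 2, snr = Inf)
  avg <- average_image(raw)
  p <- make_cardiac_phantom(ph, 32, 0, 160)
  sens <- coil_sensitivities(32, 160, 2)
  rss <- sqrt(abs(p$image * sens[, , , 1])^2 + abs(p$image * sens[, , , 2])^2)
  # Gaussian sampling covers the center densely; compare where sampled
  nrmse <- sqrt(mean((avg - rss)^2)) / sqrt(mean(rss^2))
  expect_lt(nrmse, 0.15)
  # moving phantom blurs edges: gradient energy drops
  mov <- average_image(shared_cine_raw())
  grad_energy <- function(x) sum(diff(x)^2)
  # compare along the superior-inferior axis through the heart
  expect_gt(grad_energy(rss[, 16, 16]), grad_energy(mov[, 16, 16]))
  expect_error(average_image(structure(list(timestamp_ms = numeric(0)),
                                       class = "kspace_data")), "empty")
})

test_that("zero k-space gives a zero average volume", {
  ph <- test_phantom()
  for (nm in names(ph$structures)) ph$structures[[nm]]$pd <- 0
  raw <- simulate_acquisition(ph, test_cine_protocol(duration_s = 5),
                              n_coils = 2, snr = Inf)
  expect_true(all(average_image(raw) == 0))
})

test_that("heart ROI localizes the phantom heart", {
  ph <- default_heart_phantom(resp_amp_mm = 0)
  p <- make_cardiac_phantom(ph, 32, 0, 160)
  avg <- abs(p$image)
  roi <- heart_roi(avg, 0.2 * max(avg))
  expect_true(any(roi$roi)); expect_true(any(roi$interference))
  expect_false(any(roi$roi & roi$interference))
  # centroid within 5 voxels of the true heart centroid
  w <- which(roi$roi, arr.ind = TRUE)
  truth <- which(p$labels > 0, arr.ind = TRUE)
  expect_lt(sqrt(sum((colMeans(w) - colMeans(truth))^2)), 5)
  # labels mode covers every labeled voxel
  roi2 <- heart_roi(avg, p$labels)
  expect_true(all(roi2$roi[p$labels > 0]))
  expect_error(heart_roi(array(1, c(8, 8, 8)), 0.5), "uniform")
})

test_that("ROVir recovers the analytic eigenvector for a diagonal 2-coil pencil", {
  dims <- c(16, 16, 16)
  roi <- array(FALSE, dims); roi[4:8, 4:8, 4:8] <- TRUE
  intf <- array(FALSE, dims); intf[13:16, , ] <- TRUE
  ci <- array(0 + 0i, c(dims, 2))
  ci[, , , 1][roi] <- 1 + 0i
  ci[, , , 2][intf] <- 1 + 0i
  suppressMessages(b <- rovir_basis(ci, roi, intf, n_virtual = 1))
  w <- abs(b$weights[, 1])
  expect_equal(w / max(w), c(1, 0), tolerance = 1e-6)
  # ROI/interference energy ratio improves vs the RSS combination
  proj <- rovir_project(ci, b)
  rss <- sqrt(abs(ci[, , , 1])^2 + abs(ci[, , , 2])^2)
  ratio_proj <- sum(abs(proj[, , , 1][roi])^2) /
    (sum(abs(proj[, , , 1][intf])^2) + 1e-12)
  ratio_rss <- sum(rss[roi]^2) / (sum(rss[intf]^2) + 1e-12)
  expect_gt(ratio_proj, ratio_rss)
})

test_that("keeping all virtual coils preserves the data (basis completeness)", {
  set.seed(2)
  dims <- c(12, 12, 12)
  roi <- array(FALSE, dims); roi[3:6, 3:6, 3:6] <- TRUE
  intf <- array(FALSE, dims); intf[9:12, , ] <- TRUE
  ci <- array(complex(real = rnorm(prod(dims) * 4),
                      imaginary = rnorm(prod(dims) * 4)), c(dims, 4))
  b <- rovir_basis(ci, roi, intf, n_virtual = 4)
  W <- b$weights
  expect_lt(max(abs(Conj(t(W)) %*% W - diag(4))), 1e-10)
  expect_true(all(diff(b$eigenvalues) <= 1e-9))      # sorted descending
  proj <- rovir_project(ci, b)
  # W is square unitary, so projecting onto W^H inverts the combination
  back <- rovir_project(proj, structure(list(weights = Conj(t(W))),
                                        class = "virtual_coil_basis"))
  expect_lt(max(abs(back - ci)) / max(abs(ci)), 1e-10)
})

test_that("ROVir improves the ROI energy fraction on seeded phantom trials", {
  for (seed in 1:3) {
    set.seed(seed)
    ph <- default_heart_phantom(resp_amp_mm = 0)
    p <- make_cardiac_phantom(ph, 32, 0, 160)
    sens <- coil_sensitivities(32, 160, 4)
    # off-center interference source near the FOV edge
    intf_src <- array(0, c(32, 32, 32)); intf_src[30:32, , ] <- 2
    img <- p$image + intf_src
    ci <- array(0 + 0i, c(32, 32, 32, 4))
    for (c in 1:4) ci[, , , c] <- img * sens[, , , c]
    roi <- p$labels > 0
    intf <- array(FALSE, c(32, 32, 32)); intf[29:32, , ] <- TRUE
    b <- rovir_basis(ci, roi, intf, n_virtual = 2)
    proj <- rovir_project(ci, b)
    frac <- function(x, nc) {
      e_roi <- sum(vapply(1:nc, function(c) sum(abs(x[, , , c][roi])^2),
                          numeric(1)))
      e_int <- sum(vapply(1:nc, function(c) sum(abs(x[, , , c][intf])^2),
                          numeric(1)))
      e_roi / (e_roi + e_int)
    }
    expect_gt(frac(proj, 2), frac(ci, 4))
  }
})

test_that("lambda=0 full sampling equals the least-squares inverse transform", {
  set.seed(7)
  N <- 12; Tn <- 4; nc <- 3
  img <- array(complex(real = rnorm(N^3 * Tn), imaginary = rnorm(N^3 * Tn)),
               c(N, N, N, Tn))
  sens <- array(complex(real = rnorm(N^3 * nc, 1, 0.2),
                        imaginary = rnorm(N^3 * nc, 0, 0.2)), c(N, N, N, nc))
  ksp <- array(0 + 0i, c(N, N, N, Tn, nc))
  for (f in 1:Tn) for (c in 1:nc)
    ksp[, , , f, c] <- oracle_kfwd(img[, , , f] * sens[, , , c])
  mask <- array(TRUE, c(N, N, Tn))
  rec <- cs_reconstruct(ksp, mask, sens, lambda_tv = 0, n_iter = 2,
                        voxel_mm = 1)
  # independent oracle: per-voxel least squares  sum(conj(s) x_c) / sum|s|^2
  den <- apply(abs(sens)^2, 1:3, sum)
  for (f in 1:Tn) {
    num <- array(0 + 0i, c(N, N, N))
    for (c in 1:nc)
      num <- num + Conj(sens[, , , c]) *
        (stats::fft(ifftshift_oracle(ksp[, , , f, c]), inverse = TRUE) / N^3)
    oracle <- num / den
    rel <- sqrt(mean(abs(rec$data[, , , f] - oracle)^2)) /
      sqrt(mean(abs(oracle)^2))
    expect_lt(rel, 1e-6)
  }
})

test_that("reconstruction is linear in the data at lambda = 0", {
  pr <- make_dynamic_disc(N = 12, Tn = 4, nc = 2, accel = 2, seed = 8)
  r1 <- cs_reconstruct(pr$ksp, pr$mask, pr$sens, lambda_tv = 0, n_iter = 4,
                       voxel_mm = 1)
  r2 <- cs_reconstruct(3 * pr$ksp, pr$mask, pr$sens, lambda_tv = 0,
                       n_iter = 4, voxel_mm = 1)
  expect_lt(max(abs(r2$data - 3 * r1$data)) / max(abs(r1$data)), 1e-8)
})

test_that("CS objective is non-increasing and beats zero-filling frame-wise", {
  pr <- make_dynamic_disc(N = 16, Tn = 10, nc = 3, accel = 4, seed = 5)
  rec <- cs_reconstruct(pr$ksp, pr$mask, pr$sens, lambda_tv = 0.35,
                        n_iter = 30, voxel_mm = 1)
  ob <- attr(rec, "objective")
  expect_true(all(diff(ob) <= 1e-9 * abs(ob[1])))
  rmse <- function(x) sqrt(apply(abs(x - pr$truth)^2, 4, mean))
  expect_true(all(rmse(rec$data) < rmse(pr$zf)))
})

test_that("LLR denoising: identity at zero threshold, shrinkage helps, rank collapse", {
  set.seed(3)
  u <- rnorm(8^3); vt <- sin(2 * pi * (1:10) / 10)
  clean <- array(outer(u, vt), c(8, 8, 8, 10))
  noisy <- clean + array(rnorm(length(clean), 0, 0.3), dim(clean))
  expect_identical(llr_denoise(noisy, block_sizes = 4, thresholds = 0), noisy)
  den <- llr_denoise(noisy, block_sizes = c(4, 8), thresholds = c(2, 2))
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
  # threshold -> infinity: temporal structure collapses toward zero rank
  flat <- llr_denoise(noisy, block_sizes = 4, thresholds = 1e6)
  expect_lt(max(abs(flat)), 1e-6)
  expect_error(llr_denoise(noisy, block_sizes = 4, thresholds = -1),
               "non-negative")
})
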