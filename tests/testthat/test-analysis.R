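test_that("chamber volumes are voxel counts times voxel volume", {
  labels <- array(0L, c(32, 32, 32, 1))
  labels[1:10, 1:10, 1:10, 1] <- 1L          # 1000 LV voxels
  v <- chamber_volumes(labels, 1.6)
  expect_equal(v$lv_blood, 1000 * 1.6^3 / 1000)   # 4.096 mL
  expect_equal(v$rv_blood, 0)
  labels[1, 1, 11, 1] <- 99L
  expect_warning(chamber_volumes(labels, 1.6), "unknown label")
  # rasterized ellipsoid vs closed form, within a surface-voxel bound
  ph <- test_phantom()
  p <- make_cardiac_phantom(ph, 64, 0, 160)
  vol <- chamber_volumes(array(p$labels, c(dim(p$labels), 1)),
                         p$voxel_mm)$lv_blood
  s <- ph$structures$lv_blood$semi
  analytic_ml <- 4 / 3 * pi * prod(s) / 1000
  # bound: one voxel-volume per surface voxel of the rasterized pool
  surface <- p$labels == 1L & freecmr:::.dilate3(p$labels != 1L, 1)
  bound_ml <- sum(surface) * prod(p$voxel_mm) / 1000
  expect_lt(abs(vol - analytic_ml), bound_ml)
})

test_that("ED/ES frames are the volume-curve argmax/argmin with low-index ties", {
  v <- cos(2 * pi * (0:29) / 30)             # max at frame 1, min at 16
  expect_equal(find_ed_es(v), list(lved_frame = 1L, lves_frame = 16L))
  expect_equal(find_ed_es(rep(3, 30)), list(lved_frame = 1L, lves_frame = 1L))
  # phantom with known contraction phase
  ph <- test_phantom()
  vol <- vapply(1:30, function(f)
    sum(make_cardiac_phantom(ph, 32, (f - 0.5) / 30, 160)$labels == 1L),
    numeric(1))
  ee <- find_ed_es(vol)
  expect_true(ee$lved_frame %in% c(1L, 30L))
  expect_true(abs(ee$lves_frame - 15.5) <= 1)
})

test_that("EF, CO, LVM and the atrial formulas match their printed forms", {
  expect_equal(ejection_fraction(100, 40), 60)
  expect_equal(cardiac_output(100, 40, 60), 3.6)
  expect_equal(lv_mass(100), 105)
  expect_warning(ef <- ejection_fraction(50, 60), "negative")
  expect_lt(ef, 0)
  expect_error(ejection_fraction(0, 0), "positive")
  expect_equal(atrial_ef(60, 30), 50)
  expect_equal(atrial_ef(42, 42), 0)
  expect_error(atrial_ef(0, 10), "positive")
  expect_equal(fac(24, 12), 50)
  expect_equal(fac(7, 7), 0)
  expect_error(fac(0, 0), "positive")
})

test_that("phantom atria peak at ventricular systole, giving positive atrial EF", {
  ph <- test_phantom()
  l_ed <- make_cardiac_phantom(ph, 32, 0, 160)$labels
  l_es <- make_cardiac_phantom(ph, 32, 0.5, 160)$labels
  la_ed <- sum(l_ed == 4L); la_es <- sum(l_es == 4L)
  expect_gt(la_es, la_ed)
  expect_gt(atrial_ef(la_es * 1, la_ed * 1), 0)
})

test_that("valve planes come from label interfaces; stacked boxes give the exact plane", {
  labels <- array(0L, c(32, 32, 32))
  labels[10:20, 10:20, 5:14] <- 1L           # LV blood below
  labels[10:20, 10:20, 15:22] <- 4L          # LA stacked on top (z)
  labels[22:26, 10:20, 5:14] <- 3L           # RV
  labels[22:26, 10:20, 15:20] <- 5L          # RA above RV
  labels[10:20, 22:26, 5:14] <- 2L           # a myocardium slab
  labels[10:14, 10:20, 1:4] <- 6L            # aorta touching LV bottom
  lm <- detect_landmarks(labels, 1)
  # mitral plane: centroid of the LV voxels facing LA -> z at slice 14
  expect_equal(unname(lm$mitral$center[3]), 13.5, tolerance = 1e-9)
  expect_equal(abs(lm$mitral$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(unname(lm$mitral$center[1:2]), c(14.5, 14.5),
               tolerance = 1e-9)
  # missing LA: error names the absent interface
  no_la <- labels; no_la[no_la == 4L] <- 0L
  expect_error(detect_landmarks(no_la, 1), "la")
})

test_that("default phantom apex lies at the LV tip", {
  ph <- test_phantom()
  p <- make_cardiac_phantom(ph, 64, 0, 160)
  lm <- detect_landmarks(p$labels, p$voxel_mm)
  # true apex: bottom of the epicardial ellipsoid, world (-18, 0, -47),
  # corner-origin coordinates (62, 80, 33)
  expect_lt(sqrt(sum((lm$apex - c(62, 80, 33))^2)), 2 * max(p$voxel_mm))
})

test_that("prescribed views satisfy the geometric invariants", {
  # analytic landmark triangle
  lm <- structure(list(
    apex = c(0, 0, 0),
    mitral = list(center = c(0, 0, 10), normal = c(0, 0, 1)),
    tricuspid = list(center = c(5, 0, 10), normal = c(0, 0, 1)),
    com = NULL), class = "landmark_set")
  vw <- prescribe_views(lm)
  expect_equal(abs(vw$ch4$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(vw$sax$normal^2)), 1, tolerance = 1e-12)
  expect_equal(abs(sum(vw$sax$normal * c(0, 0, -1))), 1, tolerance = 1e-12)
  # 4CH plane contains all three defining landmarks
  for (pt in list(lm$apex, lm$mitral$center, lm$tricuspid$center))
    expect_lt(abs(sum((pt - vw$ch4$origin) * vw$ch4$normal)), 1e-9)
  # 2CH orthogonal to 4CH and containing the long axis
  expect_lt(abs(sum(vw$ch2$normal * vw$ch4$normal)), 1e-12)
  expect_lt(abs(sum(vw$ch2$normal * vw$sax$normal)), 1e-12)
  # collinear landmarks: degenerate
  lm$tricuspid$center <- c(0, 0, 5)
  expect_error(prescribe_views(lm), "collinear|degenerate")
})

test_that("view-normal angles are sign-invariant and bounded", {
  n <- c(0, 0, 1)
  expect_equal(view_angle_difference(n, n), 0)
  expect_equal(view_angle_difference(n, -n), 0)
  expect_equal(view_angle_difference(n, c(1, 0, 0)), 90)
  expect_equal(view_angle_difference(n, c(1, 0, 1)), 45, tolerance = 1e-9)
  expect_error(view_angle_difference(n, c(0, 0, 0)), "zero")
})

test_that("scar percent: label arithmetic and threshold mode agree with truth", {
  labels <- array(0L, c(20, 20, 4))
  labels[1:10, 1:18, 1] <- 2L                # 180 myocardium voxels
  labels[1:10, 19:20, 1] <- 7L               # 20 scar voxels
  sp <- scar_percent(labels = labels)
  expect_equal(sp, 10)                       # 20 / (20 + 180)
  no_scar <- labels; no_scar[no_scar == 7L] <- 2L
  expect_equal(scar_percent(labels = no_scar), 0)
  # complement closes to 100 exactly
  expect_equal(sp + 100 * sum(labels == 2) /
                 (sum(labels == 7) + sum(labels == 2)), 100)
  # threshold mode on a configured ~15% enhancing patch at high CNR
  ph <- default_heart_phantom(with_scar = TRUE)
  ph$structures$scar$semi <- c(7, 12, 16)     # enlarge to ~15% of the wall
  p <- make_cardiac_phantom(ph, 64, 0, 160)
  true_pct <- scar_percent(labels = p$labels)
  myo_all <- p$labels == 2L | p$labels == 7L
  psir <- array(0, dim(p$labels))
  psir[p$labels == 2L] <- 0.2; psir[p$labels == 7L] <- 0.9
  set.seed(4)
  psir <- psir + array(rnorm(length(psir), 0, 0.02), dim(psir))
  est <- scar_percent(psir = psir, myo_mask = myo_all,
                      remote_mask = p$labels == 2L, n_sd = 5)
  expect_lt(abs(est - true_pct), 2)
  expect_error(scar_percent(psir = psir, myo_mask = myo_all,
                            remote_mask = array(FALSE, dim(psir))),
               "remote")
})

test_that("4CH atrial areas track the analytic in-plane ellipse area", {
  ph <- test_phantom()
  p_es <- make_cardiac_phantom(ph, 64, 0.5, 160)  # atria at full size
  lm <- detect_landmarks(make_cardiac_phantom(ph, 64, 0, 160)$labels,
                         p_es$voxel_mm)
  vw <- prescribe_views(lm)
  a <- plane_area(p_es$labels, p_es$voxel_mm, vw$ch4, LABEL_CODES["la"])
  expect_gt(a, 0)
  # the 4CH section passes near the LA center; its area is bounded by the
  # maximal cross-section pi * a * b of the (full-size) LA ellipsoid
  s <- ph$structures$la$semi
  expect_lt(a, pi * s[1] * s[2] / 100 * 1.2)
  expect_gt(a, pi * s[1] * s[2] / 100 * 0.2)
})

test_that("summary flags metrics against reference ranges deterministically", {
  labels <- array(0L, c(32, 32, 32, 2))
  labels[10:20, 10:20, 5:14, 1] <- 1L
  labels[12:18, 12:18, 6:12, 2] <- 1L
  labels[10:20, 22:26, 5:14, 1:2] <- 2L
  labels[22:26, 10:20, 5:14, 1:2] <- 3L
  labels[10:20, 10:20, 15:20, 1:2] <- 4L
  labels[22:26, 10:20, 15:18, 1:2] <- 5L
  rep <- biomarker_report(labels, 2, hr_bpm = 60, compute_areas = FALSE)
  s1 <- generate_summary(rep, ranges = list(lv_ef_percent = c(52, 72)))
  row <- s1$table[s1$table$metric == "lv_ef_percent", ]
  expect_true(row$flag %in% c("LOW", "NORMAL", "HIGH"))
  ef <- rep$metrics$lv_ef_percent
  expected <- if (ef < 52) "LOW" else if (ef > 72) "HIGH" else "NORMAL"
  expect_equal(row$flag, expected)
  # metrics without a configured range flag N/A, no error
  expect_true(all(s1$table$flag[s1$table$metric != "lv_ef_percent"] == "N/A"))
  # deterministic field order
  s2 <- generate_summary(rep, ranges = list(lv_ef_percent = c(52, 72)))
  expect_identical(s1$table, s2$table)
  expect_identical(s1$text, s2$text)
  # explicit LOW / NORMAL cases
  r_lo <- list(lv_ef_percent = c(95, 99))
  expect_equal(generate_summary(rep, r_lo)$table[
    generate_summary(rep, r_lo)$table$metric == "lv_ef_percent", "flag"],
    "LOW")
})
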