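#' Per-frame chamber volumes from 4D label maps
#'
#' Volume = voxel count x voxel volume, reported in mL, for every known
#' structure code in every cardiac frame. Unknown codes trigger a
#' warning and are ignored.
#'
#' @param labels integer array `[x, y, z]` or `[x, y, z, frame]`.
#' @param voxel_mm voxel edge lengths in mm (scalar or length 3).
#' @return data.frame with `frame` (1-based), one column per structure
#'   name in [LABEL_CODES] (mL).
#' @export
chamber_volumes <- function(labels, voxel_mm) {
  if (length(dim(labels)) == 3) dim(labels) <- c(dim(labels), 1)
  nf <- dim(labels)[4]
  vox_ml <- prod(rep(voxel_mm, length.out = 3)) / 1000
  codes <- sort(unique(as.vector(labels)))
  codes <- codes[codes != 0]
  unknown <- setdiff(codes, LABEL_CODES)
  if (length(unknown) > 0)
    warning("ignoring unknown label codes: ", paste(unknown, collapse = ", "))
  out <- data.frame(frame = seq_len(nf))
  for (nm in names(LABEL_CODES)) {
    code <- LABEL_CODES[[nm]]
    out[[nm]] <- vapply(seq_len(nf), function(f)
      sum(labels[, , , f] == code) * vox_ml, numeric(1))
  }
  out
}

#' Detect end-diastolic and end-systolic frames
#'
#' LVED is the frame maximizing, LVES the frame minimizing, the LV blood
#' pool volume; ties go to the lowest frame index.
#'
#' @param lv_volume_ml per-frame LV blood volume.
#' @return list with 1-based `lved_frame`, `lves_frame`.
#' @export
find_ed_es <- function(lv_volume_ml) {
  list(lved_frame = which.max(lv_volume_ml),
       lves_frame = which.min(lv_volume_ml))
}

#' Ventricular function metrics
#'
#' `EF = 100 * (EDV - ESV) / EDV` (percent); `CO = (EDV - ESV) * HR /
#' 1000` (L/min); `LVM = myocardial volume x 1.05 g/mL` (standard
#' myocardial tissue density).
#'
#' @param edv,esv end-diastolic / end-systolic volume in mL.
#' @return EF in percent. A negative EF (ESV > EDV) signals a
#'   frame-selection failure and raises a warning.
#' @export
ejection_fraction <- function(edv, esv) {
  if (edv <= 0) stop("EDV must be positive")
  ef <- 100 * (edv - esv) / edv
  if (ef < 0) warning("negative ejection fraction: ESV exceeds EDV")
  ef
}

#' @rdname ejection_fraction
#' @param hr_bpm heart rate in beats per minute.
#' @export
cardiac_output <- function(edv, esv, hr_bpm) (edv - esv) * hr_bpm / 1000

#' @rdname ejection_fraction
#' @param myo_volume_ml myocardial volume at LVED in mL.
#' @param density_g_per_ml myocardial density (default 1.05 g/mL).
#' @export
lv_mass <- function(myo_volume_ml, density_g_per_ml = 1.05)
  myo_volume_ml * density_g_per_ml

#' Atrial ejection fraction
#'
#' Computed from atrial volumes at the ventricular end-systolic and
#' end-diastolic frames: `100 * (V_LVES - V_LVED) / V_LVES` (atria are
#' fullest at ventricular end-systole).
#'
#' @param vol_at_lves,vol_at_lved atrial volume (mL) at the LVES / LVED
#'   frame.
#' @return percent.
#' @export
atrial_ef <- function(vol_at_lves, vol_at_lved) {
  if (vol_at_lves <= 0) stop("atrial volume at LVES must be positive")
  100 * (vol_at_lves - vol_at_lved) / vol_at_lves
}

#' Fractional area change
#'
#' `FAC = 100 * (max area - min area) / max area`.
#'
#' @param area_max_cm2,area_min_cm2 maximal / minimal in-plane area.
#' @return percent.
#' @export
fac <- function(area_max_cm2, area_min_cm2) {
  if (area_max_cm2 <= 0) stop("maximum area must be positive")
  100 * (area_max_cm2 - area_min_cm2) / area_max_cm2
}

#' In-plane cross-sectional area of a labeled structure
#'
#' Resamples the label map onto a view plane with a 1 mm in-plane grid
#' (nearest-neighbor) and counts pixels of the requested code.
#'
#' @param labels 3D integer array.
#' @param voxel_mm voxel size (scalar or length 3).
#' @param plane a `view_plane` (see [prescribe_views()]).
#' @param code structure code to count.
#' @param half_extent_mm half-size of the sampled square patch.
#' @param step_mm in-plane sampling pitch.
#' @return area in cm^2.
#' @export
plane_area <- function(labels, voxel_mm, plane, code,
                       half_extent_mm = 60, step_mm = 1) {
  vx <- rep(voxel_mm, length.out = 3)
  g <- seq(-half_extent_mm, half_extent_mm, by = step_mm)
  uv <- as.matrix(expand.grid(u = g, v = g))
  pts <- matrix(plane$origin, nrow(uv), 3, byrow = TRUE) +
    uv[, 1] %*% t(plane$basis[, 1]) + uv[, 2] %*% t(plane$basis[, 2])
  idx <- sweep(pts, 2, vx, "/") + 0.5       # voxel centers at (i-0.5)*vx
  idx <- round(idx)
  d <- dim(labels)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  hit <- labels[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])] == code
  sum(hit) * step_mm^2 / 100                 # mm^2 -> cm^2
}

# world-mm coordinates (corner-origin) of voxels where mask is TRUE
.mask_coords <- function(mask, voxel_mm) {
  vx <- rep(voxel_mm, length.out = 3)
  ij <- which(mask, arr.ind = TRUE)
  sweep(ij - 0.5, 2, vx, "*")
}

# least-squares plane through points: centroid + unit normal
.fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  n <- ev$vectors[, 3]
  list(center = ctr, normal = n / sqrt(sum(n^2)))
}

#' Cardiac landmarks from a segmented end-diastolic frame
#'
#' Computes per-structure centers of mass, the valve planes as
#' least-squares plane fits to the blood-pool voxels 6-adjacent to the
#' neighboring chamber (mitral: LV/LA, aortic: LV/aorta, tricuspid:
#' RV/RA), and the apex as the LV (blood + myocardium) voxel with the
#' largest projection onto the direction from the mitral center through
#' the LV center of mass.
#'
#' @param labels 3D integer label array at LVED.
#' @param voxel_mm voxel size in mm.
#' @return object of class `landmark_set` with `com` (matrix,
#'   structures x xyz mm), `apex`, and `mitral`, `aortic`, `tricuspid`
#'   valve plane centers/normals.
#' @export
detect_landmarks <- function(labels, voxel_mm) {
  vx <- rep(voxel_mm, length.out = 3)
  need <- c("lv_blood", "myocardium", "rv_blood", "la", "ra", "aorta")
  present <- vapply(need, function(nm) any(labels == LABEL_CODES[[nm]]),
                    logical(1))
  if (!all(present))
    stop("missing structures: ", paste(need[!present], collapse = ", "))
  com <- t(vapply(need, function(nm)
    colMeans(.mask_coords(labels == LABEL_CODES[[nm]], vx)), numeric(3)))
  interface_plane <- function(code_a, code_b, what) {
    a <- labels == code_a
    touch <- a & .dilate3(labels == code_b, 1)
    if (!any(touch))
      stop("no ", what, " interface found between the labeled structures")
    .fit_plane(.mask_coords(touch, vx))
  }
  mitral <- interface_plane(LABEL_CODES["lv_blood"], LABEL_CODES["la"],
                            "mitral (LV/LA)")
  aortic <- interface_plane(LABEL_CODES["lv_blood"], LABEL_CODES["aorta"],
                            "aortic (LV/aorta)")
  tricuspid <- interface_plane(LABEL_CODES["rv_blood"], LABEL_CODES["ra"],
                               "tricuspid (RV/RA)")
  lv_all <- labels == LABEL_CODES["lv_blood"] |
    labels == LABEL_CODES["myocardium"]
  dirv <- com["lv_blood", ] - mitral$center
  dirv <- dirv / sqrt(sum(dirv^2))
  pts <- .mask_coords(lv_all, vx)
  proj <- as.vector(sweep(pts, 2, mitral$center) %*% dirv)
  apex <- pts[which.max(proj), ]
  structure(list(com = com, apex = apex, mitral = mitral,
                 aortic = aortic, tricuspid = tricuspid,
                 long_axis = dirv),
            class = "landmark_set")
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector")
  v / n
}

.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

.view_plane <- function(name, origin, normal, long_axis = NULL,
                        sax_positions = NULL) {
  normal <- .unit(normal)
  seed <- if (!is.null(long_axis)) long_axis else
    if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- .unit(seed - sum(seed * normal) * normal)
  b2 <- .cross(normal, b1)
  structure(list(name = name, origin = origin, normal = normal,
                 basis = cbind(b1, b2), sax_positions = sax_positions),
            class = "view_plane")
}

#' Prescribe standard cardiac views from landmarks
#'
#' The long axis runs from the mitral valve center to the apex. The
#' four-chamber (4CH) plane contains apex, mitral and tricuspid centers;
#' the short-axis (SAX) stack is normal to the long axis with positions
#' from the mitral plane to the apex at 8 mm spacing; the two-chamber
#' (2CH) plane contains the long axis and is orthogonal to the 4CH
#' plane.
#'
#' @param landmarks a [detect_landmarks()] result.
#' @param sax_spacing_mm spacing of the SAX stack.
#' @return list of `view_plane`s named `ch2`, `ch4`, `sax`.
#' @export
prescribe_views <- function(landmarks, sax_spacing_mm = 8) {
  apex <- landmarks$apex
  mv <- landmarks$mitral$center
  tv <- landmarks$tricuspid$center
  long_axis <- .unit(apex - mv)
  n4 <- .cross(apex - mv, tv - mv)
  if (sqrt(sum(n4^2)) < 1e-9)
    stop("degenerate view geometry: apex, mitral and tricuspid centers ",
         "are collinear")
  n4 <- .unit(n4)
  dist <- sqrt(sum((apex - mv)^2))
  sax_pos <- seq(0, dist, by = sax_spacing_mm)
  ch4 <- .view_plane("4CH", origin = mv, normal = n4, long_axis = long_axis)
  n2 <- .unit(.cross(long_axis, n4))
  ch2 <- .view_plane("2CH", origin = mv, normal = n2, long_axis = long_axis)
  sax <- .view_plane("SAX", origin = mv, normal = long_axis,
                     sax_positions = sax_pos)
  list(ch2 = ch2, ch4 = ch4, sax = sax)
}

#' Angular difference between two view normals
#'
#' Sign-invariant angle `acos(|n1 . n2| / (|n1| |n2|))` in degrees,
#' in `[0, 90]`.
#'
#' @param n1,n2 non-zero direction vectors.
#' @return degrees.
#' @export
view_angle_difference <- function(n1, n2) {
  a <- sqrt(sum(n1^2)); b <- sqrt(sum(n2^2))
  if (a == 0 || b == 0) stop("zero vector")
  acos(pmin(abs(sum(n1 * n2)) / (a * b), 1)) * 180 / pi
}

#' Scar burden as percent of LV myocardium
#'
#' Labels mode: `100 * scar voxels / (scar + myocardium voxels)`.
#' Threshold mode: scar = myocardial voxels whose PSIR intensity exceeds
#' `mean + n * SD` of a supplied remote (non-enhancing) myocardium
#' region.
#'
#' @param labels 3D integer array (labels mode) or `NULL`.
#' @param psir 3D PSIR intensity array (threshold mode).
#' @param myo_mask,remote_mask logical arrays for threshold mode.
#' @param n_sd threshold multiplier (default 5).
#' @return percent scar.
#' @export
scar_percent <- function(labels = NULL, psir = NULL, myo_mask = NULL,
                         remote_mask = NULL, n_sd = 5) {
  if (!is.null(labels)) {
    scar <- sum(labels == LABEL_CODES["scar"])
    myo <- sum(labels == LABEL_CODES["myocardium"])
    if (scar + myo == 0) stop("no myocardium in label map")
    return(100 * scar / (scar + myo))
  }
  stopifnot(!is.null(psir), !is.null(myo_mask), !is.null(remote_mask))
  if (!any(myo_mask)) stop("empty myocardium mask")
  if (!any(remote_mask)) stop("empty remote-myocardium region")
  thr <- mean(psir[remote_mask]) + n_sd * stats::sd(psir[remote_mask])
  scar <- sum(psir[myo_mask] > thr)
  100 * scar / sum(myo_mask)
}

#' Intraclass correlation, two-way mixed, single measure, consistency
#'
#' ICC(3,1): `(MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)` with
#' `k = 2` raters rating each target (fixed raters). A constant offset
#' between raters does not reduce this consistency form.
#'
#' @param x,y paired measurements (n >= 3).
#' @return ICC value.
#' @export
icc_fixed_raters <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need >= 3 complete pairs")
  k <- 2
  dat <- cbind(x, y)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= 0)
    stop("zero between-target variance: ICC undefined")
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; bias = mean(d); 95% limits of agreement =
#' bias +/- 1.96 sd(d) (sample SD).
#'
#' @param x,y paired measurements (n >= 2).
#' @return list with `bias`, `loa_lower`, `loa_upper`, `sd_diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) < 2 || length(y) != length(x))
    stop("need >= 2 complete pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_diff = s)
}
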