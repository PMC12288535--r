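#' Dynamic digital heart phantom
#'
#' A `phantom_state` describes an analytic thorax stand-in made of
#' ellipsoidal cardiac structures plus the motion and relaxation physics
#' the scanner sees implicitly: periodic cardiac contraction (radial
#' scaling of the chamber ellipsoids), slower rigid superior-inferior
#' respiratory translation, per-structure proton density and T1.
#'
#' Structure geometry is given in millimeters in a world frame centered on
#' the field of view (x right, y anterior, z superior). Ventricular blood
#' pools scale by `1 - contraction_amplitude * (1 - cos(2*pi*phase))/2`
#' (maximal at phase 0, end-diastole convention); atria move in
#' counter-phase so their volume peaks at ventricular systole. The LV
#' myocardium is the shell between a fixed epicardial ellipsoid and the
#' instantaneous LV blood pool, so the wall thickens in systole.
#'
#' @param structures named list of structures; each a list with `code`
#'   (integer label), `center` (length-3 mm), `semi` (length-3 semi-axes
#'   mm), `pd` (proton density), `t1_ms`, and `dynamic` (one of
#'   `"ventricle"`, `"atrium"`, `"static"`).
#' @param cardiac_freq_hz cardiac frequency, must exceed 0.6 Hz so the
#'   spectral band classifier applies.
#' @param resp_freq_hz respiratory frequency, must be below 0.6 Hz. The
#'   default (0.22 Hz, about 13 breaths/min) is deliberately
#'   incommensurate with the 1 Hz default heart rate: real breathing is
#'   not phase-locked to the heartbeat, and a rational frequency ratio
#'   would lock the mode-respiratory acceptance window to a fixed subset
#'   of cardiac phases.
#' @param resp_amp_mm peak-to-zero respiratory translation along z.
#' @param contraction_amplitude fractional radial contraction of the
#'   ventricular semi-axes at end-systole.
#' @param atrial_amplitude fractional radial contraction of the atria at
#'   ventricular end-diastole.
#' @param inversion_efficiency inversion pulse efficiency in `[0, 1]`;
#'   1 is a perfect 180 degree inversion.
#' @param n_card_states,n_resp_states number of quantized motion states
#'   the k-space simulator caches per cardiac / respiratory cycle.
#' @return An object of class `phantom_state`.
#' @seealso [default_heart_phantom()], [make_cardiac_phantom()],
#'   [simulate_acquisition()]
#' @export
phantom_state <- function(structures,
                          cardiac_freq_hz = 1.0,
                          resp_freq_hz = 0.22,
                          resp_amp_mm = 8,
                          contraction_amplitude = 0.26,
                          atrial_amplitude = 0.25,
                          inversion_efficiency = 1.0,
                          n_card_states = 24,
                          n_resp_states = 7) {
  if (cardiac_freq_hz <= 0.6)
    stop("cardiac_freq_hz must exceed 0.6 Hz (band classifier assumption)")
  if (resp_freq_hz >= 0.6)
    stop("resp_freq_hz must be below 0.6 Hz (band classifier assumption)")
  if (contraction_amplitude < 0 || contraction_amplitude >= 1)
    stop("contraction_amplitude must be in [0, 1)")
  stopifnot(is.list(structures), length(structures) >= 1)
  for (nm in names(structures)) {
    s <- structures[[nm]]
    if (!all(c("code", "center", "semi", "pd", "t1_ms", "dynamic") %in% names(s)))
      stop("structure '", nm, "' is missing required fields")
    if (any(s$semi <= 0)) stop("structure '", nm, "' has non-positive semi-axes")
    if (s$t1_ms <= 0) stop("structure '", nm, "' has non-positive T1")
  }
  structure(list(
    structures = structures,
    cardiac_freq_hz = cardiac_freq_hz,
    resp_freq_hz = resp_freq_hz,
    resp_amp_mm = resp_amp_mm,
    contraction_amplitude = contraction_amplitude,
    atrial_amplitude = atrial_amplitude,
    inversion_efficiency = inversion_efficiency,
    n_card_states = as.integer(n_card_states),
    n_resp_states = as.integer(n_resp_states)
  ), class = "phantom_state")
}

#' Label codes used throughout the package
#' @export
LABEL_CODES <- c(lv_blood = 1L, myocardium = 2L, rv_blood = 3L,
                 la = 4L, ra = 5L, aorta = 6L, scar = 7L)

#' Default whole-heart phantom
#'
#' Seven-structure heart (LV blood pool, LV myocardium, RV, LA, RA,
#' ascending aorta, optional scar patch in the lateral LV wall) with
#' geometry sized for a real heart inside a 160 mm simulation FOV.
#' Default post-contrast T1 values: blood 300 ms, remote myocardium
#' 450 ms, enhancing scar 250 ms.
#'
#' @param with_scar include a transmural scar patch (label 7) occupying
#'   part of the lateral wall.
#' @param ... overrides forwarded to [phantom_state()].
#' @return A `phantom_state`.
#' @export
default_heart_phantom <- function(with_scar = FALSE, ...) {
  # chambers are tangent/slightly overlapping where valves sit (LV-LA,
  # LV-aorta, RV-RA); listed-order precedence carves the overlap so label
  # maps are disjoint while the structures remain voxel-adjacent, which is
  # what the valve-plane landmark detector needs. The myocardial shell is
  # cut open above the basal plane (z = 16 mm) like a real LV.
  st <- list(
    lv_blood   = list(code = 1L, center = c(-18, 0, -10), semi = c(20, 20, 30),
                      pd = 1.00, t1_ms = 300, dynamic = "ventricle"),
    myocardium = list(code = 2L, center = c(-18, 0, -10), semi = c(27, 27, 37),
                      pd = 0.45, t1_ms = 450, dynamic = "epicardium",
                      base_cut_mm = 16),
    rv_blood   = list(code = 3L, center = c(24, 0, -8), semi = c(12, 17, 25),
                      pd = 0.95, t1_ms = 300, dynamic = "ventricle"),
    la         = list(code = 4L, center = c(-18, 6, 26), semi = c(14, 14, 12),
                      pd = 0.90, t1_ms = 300, dynamic = "atrium"),
    ra         = list(code = 5L, center = c(24, 0, 22), semi = c(11, 13, 11),
                      pd = 0.90, t1_ms = 300, dynamic = "atrium"),
    aorta      = list(code = 6L, center = c(-12, -10, 26), semi = c(7, 7, 16),
                      pd = 0.85, t1_ms = 300, dynamic = "static")
  )
  if (with_scar)
    st$scar <- list(code = 7L, center = c(5.5, 0, -10), semi = c(4.5, 8, 10),
                    pd = 0.80, t1_ms = 250, dynamic = "scar")
  phantom_state(structures = st, ...)
}

# radial scale factor of a structure at cardiac phase p in [0, 1)
.structure_scale <- function(dynamic, phase, ca, aa) {
  switch(dynamic,
         ventricle = 1 - ca * (1 - cos(2 * pi * phase)) / 2,
         atrium    = 1 - aa * (1 + cos(2 * pi * phase)) / 2,
         1)
}

# logical ellipsoid mask on the voxel grid; coords are per-axis center
# coordinate vectors (mm)
.ellipsoid_mask <- function(coords, center, semi) {
  qx <- ((coords$x - center[1]) / semi[1])^2
  qy <- ((coords$y - center[2]) / semi[2])^2
  qz <- ((coords$z - center[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

.grid_coords <- function(grid, fov_mm) {
  grid <- rep(as.integer(grid), length.out = 3)
  fov <- rep(fov_mm, length.out = 3)
  res <- fov / grid
  list(x = ((seq_len(grid[1]) - 1) + 0.5) * res[1] - fov[1] / 2,
       y = ((seq_len(grid[2]) - 1) + 0.5) * res[2] - fov[2] / 2,
       z = ((seq_len(grid[3]) - 1) + 0.5) * res[3] - fov[3] / 2,
       res = res, grid = grid)
}

#' Rasterize the heart phantom at one cardiac phase
#'
#' Evaluates the analytic ellipsoids at a cardiac phase (and optional
#' respiratory shift) on a voxel grid, returning the complex-valued
#' proton-density image and the matching integer label map. LV blood
#' volume varies smoothly and periodically with phase; phase 0 is
#' end-diastole.
#'
#' @param phantom a [phantom_state()].
#' @param grid voxels per axis (scalar or length 3), each >= 32.
#' @param frame_phase cardiac phase in `[0, 1)`.
#' @param fov_mm rasterization field of view in mm.
#' @param resp_shift_mm rigid translation along the readout
#'   (superior-inferior, x) axis applied to all structures.
#' @return list with `image` (complex 3D array), `labels` (integer 3D
#'   array using [LABEL_CODES]), `voxel_mm`, `fov_mm`.
#' @export
make_cardiac_phantom <- function(phantom, grid = 64, frame_phase = 0,
                                 fov_mm = 160, resp_shift_mm = 0) {
  stopifnot(inherits(phantom, "phantom_state"))
  if (any(rep(grid, length.out = 3) < 32))
    stop("grid must be >= 32 voxels per axis")
  masks <- .phantom_masks(phantom, grid, fov_mm, frame_phase, resp_shift_mm,
                          check_overlap = (frame_phase == 0 &&
                                           resp_shift_mm == 0))
  co <- .grid_coords(grid, fov_mm)
  dims <- co$grid
  labels <- array(0L, dims)
  image <- array(0 + 0i, dims)
  for (nm in names(masks)) {
    s <- phantom$structures[[nm]]
    labels[masks[[nm]]] <- s$code
    image[masks[[nm]]] <- s$pd + 0i
  }
  list(image = image, labels = labels,
       voxel_mm = co$res, fov_mm = rep(fov_mm, length.out = 3))
}

# per-structure logical masks (in structure order, shell/scar logic applied)
.phantom_masks <- function(phantom, grid, fov_mm, frame_phase,
                           resp_shift_mm = 0, check_overlap = FALSE) {
  if (frame_phase < 0 || frame_phase >= 1)
    stop("frame_phase must lie in [0, 1)")
  co <- .grid_coords(grid, fov_mm)
  ca <- phantom$contraction_amplitude
  aa <- phantom$atrial_amplitude
  # respiratory translation is along the fully sampled readout axis (x,
  # superior-inferior): the k-space-center SG line integrates over the
  # phase-encode plane, so only motion along the readout projects onto it
  shift <- c(resp_shift_mm, 0, 0)
  masks <- list()
  lv_mask <- NULL
  claimed <- array(FALSE, co$grid)
  for (nm in names(phantom$structures)) {
    s <- phantom$structures[[nm]]
    sc <- .structure_scale(s$dynamic, frame_phase, ca, aa)
    m <- .ellipsoid_mask(co, s$center + shift, s$semi * sc)
    if (s$dynamic == "epicardium") {
      if (is.null(lv_mask))
        stop("epicardium structure must follow the LV blood pool")
      m <- m & !lv_mask            # shell: epicardial ellipsoid minus cavity
      if (!is.null(s$base_cut_mm)) {
        zmask <- outer(outer(rep(TRUE, co$grid[1]), rep(TRUE, co$grid[2]),
                             "&"), co$z <= s$base_cut_mm, "&")
        m <- m & zmask             # open the shell at the basal plane
      }
    }
    if (s$dynamic == "scar") {
      myo <- masks[["myocardium"]]
      if (is.null(myo)) stop("scar requires a myocardium structure")
      m <- m & myo                 # scar confined to the myocardial wall
      masks[["myocardium"]] <- myo & !m
      masks[[nm]] <- m
      next
    }
    # precedence carving: earlier-listed structures keep contested voxels
    # (models valve-plane contact); gross overlap is a configuration error
    n_raw <- sum(m)
    lost <- sum(m & claimed)
    if (check_overlap && n_raw > 0 && lost > 0.25 * n_raw)
      stop("phantom structures overlap excessively at the reference ",
           "phase ('", nm, "' loses ", round(100 * lost / n_raw),
           "% of its volume); adjust centers/semi-axes")
    m <- m & !claimed
    claimed <- claimed | m
    if (s$dynamic == "ventricle" && s$code == 1L) lv_mask <- m
    masks[[nm]] <- m
  }
  masks
}

#' Analytic ejection fraction of a phantom
#'
#' The ventricular blood pools scale radially, so volume scales with the
#' cube of the contraction factor and the configured ejection fraction is
#' `1 - (1 - contraction_amplitude)^3` (in percent).
#' @param phantom a `phantom_state`.
#' @return EF in percent.
#' @export
analytic_ef <- function(phantom) {
  100 * (1 - (1 - phantom$contraction_amplitude)^3)
}

#' Smooth analytic coil sensitivity maps
#'
#' Complex Gaussian profiles centered on coil positions arranged on a
#' circle around the FOV in the x-y plane, with a gentle per-coil linear
#' phase. Enough spatial structure for SENSE and region-optimized virtual
#' coil combination to be nontrivial.
#'
#' @param grid voxels per axis (scalar or length 3).
#' @param fov_mm field of view in mm.
#' @param n_coils number of receive coils (>= 2).
#' @return complex array `[grid, n_coils]`.
#' @export
coil_sensitivities <- function(grid, fov_mm = 160, n_coils = 4) {
  if (n_coils < 2) stop("need at least 2 coils")
  co <- .grid_coords(grid, fov_mm)
  dims <- co$grid
  sens <- array(0 + 0i, c(dims, n_coils))
  sigma <- 0.55 * max(rep(fov_mm, length.out = 3))
  radius <- 0.65 * max(rep(fov_mm, length.out = 3))
  X <- array(rep(co$x, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(co$y, each = dims[1]), times = dims[3]), dims)
  for (k in seq_len(n_coils)) {
    ang <- 2 * pi * (k - 1) / n_coils
    cx <- radius * cos(ang); cy <- radius * sin(ang)
    d2 <- (X - cx)^2 + (Y - cy)^2
    mag <- exp(-d2 / (2 * sigma^2))
    ph <- 0.6 * pi * (cos(ang) * X + sin(ang) * Y) / max(fov_mm)
    sens[, , , k] <- mag * exp(1i * ph)
  }
  sens
}

#' Resolution bar-grid phantom
#'
#' A water bath (intensity 1) containing four 3x3 grids of square resin
#' posts (intensity 0), one quadrant per requested pitch. Post side and
#' gap both equal the pitch, so the bar pattern period is twice the pitch
#' and a grid is at the Nyquist limit of an acquisition whose voxel size
#' equals its pitch.
#'
#' @param grid_sizes_mm pitches (mm) of the post grids; up to 4. The
#'   published phantom uses `c(2.4, 2.0, 1.6, 1.0)`.
#' @param grid simulation voxels per axis (scalar or length 3).
#' @param voxel_mm simulation voxel size in mm; every pitch must be at
#'   least one simulation voxel.
#' @return complex 3D array with attributes `voxel_mm`, `fov_mm` and
#'   `grids` (a data.frame of per-quadrant geometry used by
#'   [resolve_resolution()]).
#' @export
make_resolution_phantom <- function(grid_sizes_mm = c(2.4, 2.0, 1.6, 1.0),
                                    grid = c(192, 192, 32),
                                    voxel_mm = 0.4) {
  if (length(grid_sizes_mm) > 4) stop("at most 4 quadrants supported")
  if (any(grid_sizes_mm <= 0)) stop("grid pitches must be positive")
  if (any(grid_sizes_mm < voxel_mm))
    stop("pitch smaller than the simulation voxel size cannot be rasterized")
  co <- .grid_coords(grid, voxel_mm * rep(grid, length.out = 3))
  dims <- co$grid
  fov <- dims * co$res
  vol <- array(1 + 0i, dims)     # water bath
  qcent <- list(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  zslab <- abs(co$z) <= fov[3] / 4
  info <- NULL
  for (g in seq_along(grid_sizes_mm)) {
    pitch <- grid_sizes_mm[g]
    qc <- qcent[[g]] * fov[1:2] / 4
    post_centers <- (-1:1) * 2 * pitch
    inx <- rep(FALSE, dims[1]); iny <- rep(FALSE, dims[2])
    for (pc in post_centers) {
      inx <- inx | abs(co$x - (qc[1] + pc)) <= pitch / 2
      iny <- iny | abs(co$y - (qc[2] + pc)) <= pitch / 2
    }
    post <- outer(outer(inx, iny, "&"), zslab, "&")
    vol[post] <- 0 + 0i
    info <- rbind(info, data.frame(
      pitch_mm = pitch, cx_mm = qc[1], cy_mm = qc[2],
      half_span_mm = 2.5 * pitch))
  }
  attr(vol, "voxel_mm") <- co$res
  attr(vol, "fov_mm") <- fov
  attr(vol, "grids") <- info
  vol
}

#' T1 calibration phantom
#'
#' Nine (or fewer) static cylindrical compartments arranged on a 3x3 grid
#' in the x-y plane, one per requested T1, mimicking a standard
#' cardiac-T1 calibration phantom. No cardiac or respiratory motion is
#' simulated (amplitudes zero); proton density is 1 in every compartment.
#'
#' @param t1_list_ms compartment T1 values in ms; default is the
#'   published 9-vial set.
#' @return A `phantom_state` whose structures are the compartments.
#' @export
make_t1mes_phantom <- function(t1_list_ms = c(250, 294, 424, 451, 555,
                                              1010, 1260, 1499, 1872)) {
  if (any(t1_list_ms <= 0)) stop("all T1 values must be positive")
  if (length(t1_list_ms) > 9) stop("at most 9 compartments supported")
  st <- list()
  spacing <- 40
  for (k in seq_along(t1_list_ms)) {
    row <- (k - 1) %/% 3; col <- (k - 1) %% 3
    st[[paste0("vial", k)]] <- list(
      code = as.integer(k),
      center = c((col - 1) * spacing, (row - 1) * spacing, 0),
      semi = c(12, 12, 25), pd = 1.0, t1_ms = t1_list_ms[k],
      dynamic = "static")
  }
  phantom_state(structures = st, cardiac_freq_hz = 1.0,
                resp_freq_hz = 0.25, resp_amp_mm = 0,
                contraction_amplitude = 0, atrial_amplitude = 0)
}

#' Inversion-recovery longitudinal signal
#'
#' Standard inversion-recovery model
#' `M(TI) = M0 * (1 - 2 * eff * exp(-TI / T1))` with inversion
#' efficiency `eff` (1 = perfect inversion). The signal crosses zero at
#' `TI = T1 * log(2 * eff)`.
#'
#' @param ti_ms inversion time(s) in ms.
#' @param t1_ms longitudinal relaxation time in ms.
#' @param m0 equilibrium magnetization.
#' @param efficiency inversion efficiency in `(0, 1]`.
#' @return signed longitudinal magnetization, same length as `ti_ms`.
#' @export
ir_signal <- function(ti_ms, t1_ms, m0 = 1, efficiency = 1) {
  m0 * (1 - 2 * efficiency * exp(-ti_ms / t1_ms))
}
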