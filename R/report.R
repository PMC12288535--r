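#' Whole-heart biomarker report from 4D label maps
#'
#' Runs the automated biomarker engine: per-frame chamber volumes, LVED
#' and LVES detection from the LV volume curve, ventricular EF and
#' cardiac output at those frames, LV mass at LVED, atrial EF from the
#' printed formula (volumes at the LVES/LVED frames) plus atrial max/min
#' volumes over all frames, four-chamber atrial areas and fractional
#' area change, and scar burden when a scar label is present.
#'
#' @param labels 4D integer array `[x, y, z, frame]`.
#' @param voxel_mm voxel size in mm (scalar or length 3).
#' @param hr_bpm heart rate during scanning (from the gating result).
#' @param compute_areas compute 4CH areas / FAC (needs landmarks; set
#'   `FALSE` to skip the most expensive step).
#' @return object of class `biomarker_report` (a named list of metrics,
#'   the per-frame volume table, landmarks and views).
#' @export
biomarker_report <- function(labels, voxel_mm, hr_bpm,
                             compute_areas = TRUE) {
  stopifnot(length(dim(labels)) == 4)
  vols <- chamber_volumes(labels, voxel_mm)
  ed_es <- find_ed_es(vols$lv_blood)
  ed <- ed_es$lved_frame; es <- ed_es$lves_frame
  lv_edv <- vols$lv_blood[ed]; lv_esv <- vols$lv_blood[es]
  rv_edv <- vols$rv_blood[ed]; rv_esv <- vols$rv_blood[es]
  rep_list <- list(
    lved_frame = ed, lves_frame = es, heart_rate_bpm = hr_bpm,
    lv_edv_ml = lv_edv, lv_esv_ml = lv_esv,
    lv_ef_percent = ejection_fraction(lv_edv, lv_esv),
    lv_co_l_min = cardiac_output(lv_edv, lv_esv, hr_bpm),
    lvm_g = lv_mass(vols$myocardium[ed]),
    rv_edv_ml = rv_edv, rv_esv_ml = rv_esv,
    rv_ef_percent = ejection_fraction(rv_edv, rv_esv),
    rv_co_l_min = cardiac_output(rv_edv, rv_esv, hr_bpm),
    la_vol_lved_ml = vols$la[ed], la_vol_lves_ml = vols$la[es],
    la_ef_percent = atrial_ef(vols$la[es], vols$la[ed]),
    la_max_ml = max(vols$la), la_min_ml = min(vols$la),
    ra_vol_lved_ml = vols$ra[ed], ra_vol_lves_ml = vols$ra[es],
    ra_ef_percent = atrial_ef(vols$ra[es], vols$ra[ed]),
    ra_max_ml = max(vols$ra), ra_min_ml = min(vols$ra)
  )
  if (any(labels == LABEL_CODES["scar"]))
    rep_list$scar_percent <- scar_percent(labels = labels[, , , ed])
  landmarks <- NULL; views <- NULL
  if (compute_areas) {
    landmarks <- detect_landmarks(labels[, , , ed], voxel_mm)
    views <- prescribe_views(landmarks)
    nf <- dim(labels)[4]
    la_area <- ra_area <- numeric(nf)
    for (f in seq_len(nf)) {
      la_area[f] <- plane_area(labels[, , , f], voxel_mm, views$ch4,
                               LABEL_CODES["la"])
      ra_area[f] <- plane_area(labels[, , , f], voxel_mm, views$ch4,
                               LABEL_CODES["ra"])
    }
    rep_list$la_area_max_cm2 <- max(la_area)
    rep_list$la_area_min_cm2 <- min(la_area)
    rep_list$la_fac_percent <- fac(max(la_area), min(la_area))
    rep_list$ra_area_max_cm2 <- max(ra_area)
    rep_list$ra_area_min_cm2 <- min(ra_area)
    rep_list$ra_fac_percent <- fac(max(ra_area), min(ra_area))
  }
  structure(list(metrics = rep_list, volumes = vols,
                 landmarks = landmarks, views = views),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<biomarker_report> LVEF %.1f%%  RVEF %.1f%%  HR %.0f bpm\n",
              m$lv_ef_percent, m$rv_ef_percent, m$heart_rate_bpm))
  cat(sprintf("  LV EDV/ESV %.1f/%.1f mL, CO %.2f L/min, LVM %.0f g\n",
              m$lv_edv_ml, m$lv_esv_ml, m$lv_co_l_min, m$lvm_g))
  invisible(x)
}

#' Default normal-range table
#'
#' Reads the editable YAML table shipped with the package. The shipped
#' values are generic adult placeholder ranges meant to be replaced with
#' site-specific reference values.
#'
#' @param path optional path to a user YAML file.
#' @return named list of `c(lo, hi)` ranges.
#' @export
normal_ranges <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "normal_ranges.yaml", package = "freecmr")
  yaml::read_yaml(path)
}

.metric_units <- c(
  lv_edv_ml = "mL", lv_esv_ml = "mL", lv_ef_percent = "%",
  lv_co_l_min = "L/min", lvm_g = "g",
  rv_edv_ml = "mL", rv_esv_ml = "mL", rv_ef_percent = "%",
  rv_co_l_min = "L/min",
  la_ef_percent = "%", ra_ef_percent = "%",
  la_max_ml = "mL", la_min_ml = "mL", ra_max_ml = "mL", ra_min_ml = "mL",
  la_fac_percent = "%", ra_fac_percent = "%",
  scar_percent = "%", heart_rate_bpm = "bpm")

#' Automated volumetric and functional summary
#'
#' Tabulates every metric of a biomarker report with its units, value,
#' reference range and a LOW / NORMAL / HIGH flag (N/A when no range is
#' configured), in a deterministic field order, as plain text and as a
#' JSON-ready list.
#'
#' @param report a [biomarker_report()].
#' @param ranges named list of `c(lo, hi)` reference ranges (see
#'   [normal_ranges()]).
#' @return list with `table` (data.frame), `text` (character vector of
#'   report lines), and `json` (list ready for serialization).
#' @export
generate_summary <- function(report, ranges = normal_ranges()) {
  m <- report$metrics
  keys <- names(.metric_units)[names(.metric_units) %in% names(m)]
  rows <- lapply(keys, function(k) {
    val <- m[[k]]
    rng <- ranges[[k]]
    flag <- if (is.null(rng)) "N/A"
      else if (val < rng[1]) "LOW"
      else if (val > rng[2]) "HIGH"
      else "NORMAL"
    data.frame(metric = k, value = round(val, 2),
               units = .metric_units[[k]],
               ref_lo = if (is.null(rng)) NA_real_ else rng[1],
               ref_hi = if (is.null(rng)) NA_real_ else rng[2],
               flag = flag, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  txt <- c("AUTOMATED VOLUMETRIC AND FUNCTIONAL SUMMARY",
           sprintf("%-18s %10s %-7s %-15s %s", "metric", "value", "units",
                   "reference", "flag"),
           vapply(seq_len(nrow(tab)), function(i) {
             r <- tab[i, ]
             ref <- if (is.na(r$ref_lo)) "-" else
               sprintf("[%.1f, %.1f]", r$ref_lo, r$ref_hi)
             sprintf("%-18s %10.2f %-7s %-15s %s", r$metric, r$value,
                     r$units, ref, r$flag)
           }, character(1)))
  json <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    list(metric = r$metric, value = r$value, units = r$units,
         reference = if (is.na(r$ref_lo)) NULL else c(r$ref_lo, r$ref_hi),
         flag = r$flag)
  })
  list(table = tab, text = txt, json = json)
}
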