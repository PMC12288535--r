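.config_schema <- list(
  seed = NULL, out_dir = NULL,
  protocol = c("tr_ms", "te_ms", "flip_deg", "fov_mm", "matrix_size",
               "sg_interval", "duration_s"),
  phantom = c("with_scar", "cardiac_freq_hz", "resp_freq_hz", "resp_amp_mm",
              "contraction_amplitude", "atrial_amplitude",
              "n_card_states", "n_resp_states"),
  acquisition = c("n_coils", "snr"),
  recon = c("lambda_tv", "n_iter", "n_bins", "rovir",
            "rovir_energy_fraction", "llr", "llr_block_sizes",
            "llr_thresholds"),
  analysis = c("normal_ranges", "compute_areas")
)

#' Load and validate a pipeline configuration
#'
#' Configurations are YAML (or an equivalent nested list) with blocks
#' `protocol`, `phantom`, `acquisition`, `recon`, `analysis` plus a
#' mandatory integer `seed`. Unknown keys are rejected with the
#' offending path named; the structure round-trips losslessly through
#' YAML.
#'
#' @param x path to a YAML file or a named list.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  bad <- setdiff(names(cfg), names(.config_schema))
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (blk in names(.config_schema)) {
    allowed <- .config_schema[[blk]]
    if (is.null(allowed) || is.null(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad) > 0)
      stop("unknown configuration key(s): ",
           paste(paste0(blk, ".", bad), collapse = ", "))
  }
  if (is.null(cfg$seed))
    stop("configuration must set an explicit integer 'seed' ",
         "(no wall-clock seeding)")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the end-to-end pipeline: simulate, gate, reconstruct, analyze
#'
#' Executes every stage in order and writes all intermediates to the
#' output directory: `raw.h5` (simulated cine k-space), `gating.json`,
#' `cine_mag.nii.gz` (reconstructed magnitude series), `labels.nii.gz`
#' (ground-truth label maps at the 30 frame centers, standing in for the
#' segmentation interface), `volumes.csv`, `report.json`, `report.txt`,
#' `views.json`, and a `manifest.json` listing paths and MD5 checksums.
#' Identical configuration and seed give identical manifest checksums.
#' Stage failures propagate with the stage name; partial outputs are
#' retained for debugging.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return list with `status` (0 on success) and the `manifest`
#'   data.frame, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  out <- out_dir %||% cfg$out_dir
  if (is.null(out)) stop("no output directory configured")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(out, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out)
  unlink(probe)

  g <- function(blk, key, default) {
    v <- cfg[[blk]][[key]]
    if (is.null(v)) default else v
  }
  paths <- character(0)
  add <- function(p) { paths[[length(paths) + 1]] <<- p; p }

  ## stage 1: simulate -----------------------------------------------------
  raw <- .stage("simulate", {
    proto_args <- cfg$protocol %||% list()
    proto_args$seed <- cfg$seed
    protocol <- do.call(cine_protocol, proto_args)
    ph_args <- cfg$phantom %||% list()
    phantom <- do.call(default_heart_phantom, ph_args)
    r <- simulate_acquisition(phantom, protocol,
                              n_coils = g("acquisition", "n_coils", 4),
                              snr = g("acquisition", "snr", Inf))
    write_raw(r, add(file.path(out, "raw.h5")))
    attr(r, "phantom") <- phantom
    r
  })
  protocol <- raw$header$protocol
  phantom <- attr(raw, "phantom")

  ## stage 2: gate ---------------------------------------------------------
  gating <- .stage("gate", {
    gt <- self_gate(raw, n_bins = g("recon", "n_bins", 30))
    write_gating(gt, add(file.path(out, "gating.json")))
    gt
  })

  ## stage 3: reconstruct --------------------------------------------------
  series <- .stage("recon", {
    N <- protocol$matrix_size
    sens <- coil_sensitivities(N, protocol$fov_mm,
                               g("acquisition", "n_coils", 4))
    binned <- bin_cine_kspace(raw, gating)
    ksp <- binned$ksp
    if (isTRUE(g("recon", "rovir", TRUE))) {
      avg <- average_image(raw)
      roi <- heart_roi(avg, 0.25 * max(avg))
      coil_imgs <- array(0 + 0i, c(N, N, N, dim(sens)[4]))
      pha <- make_cardiac_phantom(phantom, N, 0, protocol$fov_mm)
      for (c in seq_len(dim(sens)[4]))
        coil_imgs[, , , c] <- pha$image * sens[, , , c]
      basis <- rovir_basis(coil_imgs, roi$roi, roi$interference,
                           energy_fraction = g("recon",
                                               "rovir_energy_fraction", 0.95))
      ksp <- rovir_project(ksp, basis)
      sens <- rovir_project(sens, basis)
    }
    ser <- cs_reconstruct(ksp, binned$mask, sens,
                          lambda_tv = g("recon", "lambda_tv", NULL),
                          n_iter = g("recon", "n_iter", 15),
                          voxel_mm = protocol$resolution_mm)
    if (isTRUE(g("recon", "llr", FALSE)))
      ser <- llr_denoise(ser,
                         block_sizes = g("recon", "llr_block_sizes", c(4, 8)),
                         thresholds = g("recon", "llr_thresholds", 0.05))
    write_images(abs(ser$data), add(file.path(out, "cine_mag.nii.gz")),
                 ser$voxel_mm)
    ser
  })

  ## stage 4: analyze ------------------------------------------------------
  report <- .stage("analyze", {
    N <- protocol$matrix_size
    nb <- gating$n_bins
    labels <- array(0L, c(N, N, N, nb))
    for (f in seq_len(nb))
      labels[, , , f] <- make_cardiac_phantom(
        phantom, N, frame_phase = (f - 0.5) / nb,
        fov_mm = protocol$fov_mm)$labels
    write_labels(labels, add(file.path(out, "labels.nii.gz")),
                 protocol$resolution_mm)
    rep <- biomarker_report(labels, protocol$resolution_mm,
                            hr_bpm = gating$heart_rate_bpm,
                            compute_areas = isTRUE(g("analysis",
                                                     "compute_areas", TRUE)))
    utils::write.csv(rep$volumes, add(file.path(out, "volumes.csv")),
                     row.names = FALSE)
    rep
  })

  ## stage 5: report -------------------------------------------------------
  .stage("report", {
    rng_path <- g("analysis", "normal_ranges", NULL)
    rng <- if (is.null(rng_path)) normal_ranges() else normal_ranges(rng_path)
    summ <- generate_summary(report, rng)
    jsonlite::write_json(summ$json, add(file.path(out, "report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(summ$text, add(file.path(out, "report.txt")))
    if (!is.null(report$views)) {
      vw <- lapply(report$views, function(v)
        list(name = v$name, origin = v$origin, normal = v$normal,
             basis = list(v$basis[, 1], v$basis[, 2]),
             sax_positions = v$sax_positions))
      jsonlite::write_json(vw, add(file.path(out, "views.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    NULL
  })

  manifest <- data.frame(path = unlist(paths),
                         md5 = unname(tools::md5sum(unlist(paths))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
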