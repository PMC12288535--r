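#' Write / read raw k-space containers (HDF5)
#'
#' The raw container uses HDF5 with ISMRMRD-style named datasets:
#' `data_real` / `data_imag` (`lines x samples x coils`; HDF5 has no
#' native complex type), `timestamps` (ms), `line_type` (0 = imaging,
#' 1 = self-gating), `ky`, `kz` (0-based), `ti` (ms, NaN for non-DE
#' lines), `trigger_times` and a `header` dataset holding the protocol
#' and geometry as JSON. Round trips are bit-exact for the complex data.
#'
#' @param raw a [kspace_data()].
#' @param path output `.h5` file.
#' @return `path`, invisibly; `read_raw()` returns a `kspace_data`.
#' @export
write_raw <- function(raw, path) {
  stopifnot(inherits(raw, "kspace_data"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(raw$data), path, "data_real")
  rhdf5::h5write(Im(raw$data), path, "data_imag")
  rhdf5::h5write(raw$timestamp_ms, path, "timestamps")
  rhdf5::h5write(as.integer(raw$line_type == "self_gating"), path,
                 "line_type")
  rhdf5::h5write(raw$ky_index, path, "ky")
  rhdf5::h5write(raw$kz_index, path, "kz")
  rhdf5::h5write(raw$ti_ms, path, "ti")
  rhdf5::h5write(raw$trigger_times_ms, path, "trigger_times")
  hdr <- raw$header
  hdr$protocol <- unclass(hdr$protocol)
  rhdf5::h5write(as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE,
                                               digits = NA)),
                 path, "header")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_raw
#' @export
read_raw <- function(path) {
  need <- c("data_real", "data_imag", "timestamps", "line_type", "ky",
            "kz", "ti", "trigger_times", "header")
  have <- rhdf5::h5ls(path)$name
  missing <- setdiff(need, have)
  if (length(missing) > 0)
    stop("raw container is missing dataset(s): ",
         paste(missing, collapse = ", "))
  re <- rhdf5::h5read(path, "data_real")
  im <- rhdf5::h5read(path, "data_imag")
  hdr <- jsonlite::fromJSON(rhdf5::h5read(path, "header")[1])
  proto <- hdr$protocol
  class(proto) <- "acq_protocol"
  lt <- as.vector(rhdf5::h5read(path, "line_type"))
  out <- kspace_data(
    data = array(complex(real = re, imaginary = im), dim(re)),
    timestamp_ms = as.vector(rhdf5::h5read(path, "timestamps")),
    line_type = ifelse(lt == 1L, "self_gating", "imaging"),
    ky_index = as.vector(rhdf5::h5read(path, "ky")),
    kz_index = as.vector(rhdf5::h5read(path, "kz")),
    protocol = proto,
    ti_ms = as.vector(rhdf5::h5read(path, "ti")),
    trigger_times_ms = as.vector(rhdf5::h5read(path, "trigger_times")),
    fov_mm = hdr$fov_mm)
  rhdf5::h5closeAll()
  out
}

#' Write / read integer label maps (NIfTI-1)
#'
#' Labels are stored as integer NIfTI volumes (3D or 4D with the cardiac
#' frame as the fourth dimension), voxel size in the header, RAS affine.
#' `read_labels()` refuses non-integer data.
#'
#' @param labels integer array (3D or 4D).
#' @param path output `.nii` / `.nii.gz` file.
#' @param voxel_mm voxel size in mm.
#' @return `path` invisibly; `read_labels()` returns a list with
#'   `labels` and `voxel_mm`.
#' @export
write_labels <- function(labels, path, voxel_mm) {
  storage.mode(labels) <- "integer"
  vx <- rep(voxel_mm, length.out = 3)
  RNifti::pixdim(labels) <- c(vx, rep(1, length(dim(labels)) - 3))
  RNifti::writeNifti(RNifti::asNifti(labels, datatype = "int16"), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (any(arr != round(arr)))
    stop("label NIfTI contains non-integer values: integer codes required")
  storage.mode(arr) <- "integer"
  list(labels = arr, voxel_mm = RNifti::pixdim(img)[1:3])
}

#' Write / read image volumes (NIfTI-1)
#'
#' Real arrays are written as a single float NIfTI; complex arrays are
#' split into `<stem>_real` and `<stem>_imag` volumes so round trips are
#' bit-exact. Cine series must be 4D with the frame dimension fourth.
#'
#' @param img numeric or complex array (3D or 4D).
#' @param path output file.
#' @param voxel_mm voxel size in mm.
#' @param expect_4d for `read_images()`: raise an error if the volume is
#'   not 4D (e.g. a cine series missing its frame dimension).
#' @return `path` invisibly; `read_images()` returns a list with `data`
#'   and `voxel_mm`.
#' @export
write_images <- function(img, path, voxel_mm) {
  vx <- rep(voxel_mm, length.out = 3)
  put <- function(arr, p) {
    RNifti::pixdim(arr) <- c(vx, rep(1, length(dim(arr)) - 3))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), p)
  }
  if (is.complex(img)) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    ext <- substr(path, nchar(stem) + 1, nchar(path))
    put(Re(img), paste0(stem, "_real", ext))
    put(Im(img), paste0(stem, "_imag", ext))
  } else {
    put(img, path)
  }
  invisible(path)
}

#' @rdname write_labels
#' @export
read_images <- function(path, expect_4d = FALSE) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  ext <- substr(path, nchar(stem) + 1, nchar(path))
  re_path <- paste0(stem, "_real", ext)
  if (!file.exists(path) && file.exists(re_path)) {
    re <- RNifti::readNifti(re_path)
    im <- RNifti::readNifti(paste0(stem, "_imag", ext))
    arr <- array(complex(real = as.vector(re), imaginary = as.vector(im)),
                 dim(re))
    vx <- RNifti::pixdim(re)[1:3]
  } else {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))
    vx <- RNifti::pixdim(img)[1:3]
  }
  if (expect_4d && length(dim(arr)) != 4)
    stop("expected a 4D volume (x, y, z, frame); got ",
         length(dim(arr)), "D")
  list(data = arr, voxel_mm = vx)
}

#' Serialize / restore a gating result (JSON)
#'
#' @param gating a `gating_result`.
#' @param path output `.json` file.
#' @return `path` invisibly; `read_gating()` returns a `gating_result`.
#' @export
write_gating <- function(gating, path) {
  x <- unclass(gating)
  x$cardiac_signal <- as.list(x$cardiac_signal)
  x$resp_signal <- as.list(x$resp_signal)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_gating
#' @export
read_gating <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (nm in c("cardiac_signal", "resp_signal"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.data.frame(x[[nm]])
  x$cardiac_bin <- as.integer(x$cardiac_bin)
  structure(x, class = "gating_result")
}
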