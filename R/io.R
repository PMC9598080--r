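## File formats. Complex dual-echo images travel either as a single-file
## archive (an RDS file holding named real/imag arrays plus scalar metadata,
## with pinned key names) or as two pairs of real/imag NIfTI volumes with a
## YAML metadata sidecar. NIfTI has no universally supported complex dialect,
## so complex maps are always stored as real/imag float pairs.

ARCHIVE_KEYS <- c(
  "s1_real", "s1_imag", "s2_real", "s2_imag",
  "te1_ms", "te2_ms", "b0_tesla", "fat_shift_ppm", "pixel_spacing_mm"
)

#' Write a dual-echo image to a single-file archive
#'
#' @param img a [DualEchoImage-class]
#' @param path output file path (conventionally `.rds`)
#' @return `path`, invisibly
#' @export
writeDualEcho <- function(img, path) {
  p <- img@params
  obj <- list(
    s1_real = Re(img@s1), s1_imag = Im(img@s1),
    s2_real = Re(img@s2), s2_imag = Im(img@s2),
    te1_ms = p@te1, te2_ms = p@te2, b0_tesla = p@fieldStrength,
    fat_shift_ppm = p@fatShiftPpm, pixel_spacing_mm = p@pixelSpacing
  )
  saveRDS(obj, path)
  invisible(path)
}

archiveToImage <- function(obj, what = "archive") {
  missing <- setdiff(ARCHIVE_KEYS, names(obj))
  if (length(missing)) {
    stop(sprintf(
      "%s is missing required key(s): %s", what,
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  s1 <- complex(real = obj$s1_real, imaginary = obj$s1_imag)
  s2 <- complex(real = obj$s2_real, imaginary = obj$s2_imag)
  if (!identical(dim(obj$s1_real), dim(obj$s2_real))) {
    stop("echo arrays have mismatched shapes", call. = FALSE)
  }
  d <- dim(obj$s1_real)
  dualEchoImage(
    matrix(s1, d[1], d[2]), matrix(s2, d[1], d[2]),
    acquisitionParams(
      te1 = obj$te1_ms, te2 = obj$te2_ms, fieldStrength = obj$b0_tesla,
      fatShiftPpm = obj$fat_shift_ppm, pixelSpacing = obj$pixel_spacing_mm
    )
  )
}

#' Read a dual-echo image
#'
#' Accepts either the single-file archive written by [writeDualEcho()] or a
#' YAML sidecar describing a NIfTI real/imag pair per echo (see
#' [writeDualEchoNifti()]).
#'
#' @param path archive path (`.rds`) or YAML sidecar path (`.yaml`/`.yml`)
#' @return a [DualEchoImage-class]
#' @export
readDualEcho <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (grepl("\\.ya?ml$", path)) {
    meta <- yaml::read_yaml(path)
    need <- c("s1_real", "s1_imag", "s2_real", "s2_imag")
    missing <- setdiff(c(need, "te1_ms", "te2_ms", "b0_tesla",
      "fat_shift_ppm", "pixel_spacing_mm"), names(meta))
    if (length(missing)) {
      stop(sprintf(
        "sidecar is missing required key(s): %s",
        paste(missing, collapse = ", ")
      ), call. = FALSE)
    }
    dir <- dirname(path)
    arr <- lapply(meta[need], function(f) {
      m <- RNifti::readNifti(file.path(dir, f))
      matrix(as.numeric(m), dim(m)[1], dim(m)[2])
    })
    obj <- c(arr, meta[c("te1_ms", "te2_ms", "b0_tesla", "fat_shift_ppm",
      "pixel_spacing_mm")])
    obj$pixel_spacing_mm <- as.numeric(obj$pixel_spacing_mm)
    return(archiveToImage(obj, what = "NIfTI sidecar"))
  }
  archiveToImage(readRDS(path))
}

writeNiftiMap <- function(m, path, pixelSpacing = c(1, 1)) {
  arr <- array(m, dim = c(dim(m), 1L))
  attr(arr, "pixdim") <- c(pixelSpacing, 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}

#' Write a dual-echo image as NIfTI pairs with a YAML sidecar
#'
#' @param img a [DualEchoImage-class]
#' @param prefix output path prefix; writes `<prefix>_s1_real.nii` etc. and
#'   `<prefix>.yaml`
#' @return the sidecar path, invisibly
#' @export
writeDualEchoNifti <- function(img, prefix) {
  p <- img@params
  parts <- list(
    s1_real = Re(img@s1), s1_imag = Im(img@s1),
    s2_real = Re(img@s2), s2_imag = Im(img@s2)
  )
  files <- list()
  for (nm in names(parts)) {
    f <- paste0(basename(prefix), "_", nm, ".nii")
    writeNiftiMap(parts[[nm]], file.path(dirname(prefix), f), p@pixelSpacing)
    files[[nm]] <- f
  }
  sidecar <- paste0(prefix, ".yaml")
  yaml::write_yaml(c(files, list(
    te1_ms = p@te1, te2_ms = p@te2, b0_tesla = p@fieldStrength,
    fat_shift_ppm = p@fatShiftPpm,
    pixel_spacing_mm = as.numeric(p@pixelSpacing)
  )), sidecar)
  invisible(sidecar)
}

#' Write a separation result to disk
#'
#' Writes `water` and `fat` as float32 NIfTI, the selected phasor as a
#' real/imag NIfTI pair, the selection labels as NIfTI, and a provenance
#' JSON with the options used. Uncompressed NIfTI is used so output bytes
#' are deterministic.
#'
#' @param result a [WaterFatResult-class]
#' @param prefix output path prefix
#' @return named character vector of written files, invisibly
#' @export
writeResult <- function(result, prefix) {
  ps <- result@meta$pixelSpacing %||% c(1, 1)
  files <- c(
    water = paste0(prefix, "_water.nii"),
    fat = paste0(prefix, "_fat.nii"),
    phasor_real = paste0(prefix, "_phasor_real.nii"),
    phasor_imag = paste0(prefix, "_phasor_imag.nii"),
    selection = paste0(prefix, "_selection.nii"),
    provenance = paste0(prefix, "_provenance.json")
  )
  writeNiftiMap(result@water, files["water"], ps)
  writeNiftiMap(result@fat, files["fat"], ps)
  ph <- result@phasor
  if (length(ph) == 0L || all(is.na(ph))) {
    ph <- matrix(0 + 0i, nrow(result@water), ncol(result@water))
  }
  writeNiftiMap(Re(ph), files["phasor_real"], ps)
  writeNiftiMap(Im(ph), files["phasor_imag"], ps)
  sel <- result@selection
  if (length(sel) == 0L) {
    sel <- matrix(0L, nrow(result@water), ncol(result@water))
  }
  selIm <- RNifti::asNifti(array(as.integer(sel), dim = c(dim(sel), 1L)),
    datatype = "uint8")
  RNifti::writeNifti(selIm, files["selection"])
  jsonlite::write_json(
    result@meta,
    files["provenance"],
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  invisible(files)
}
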