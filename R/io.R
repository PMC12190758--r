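# Standard-format I/O: NIfTI-1 volumes with JSON sidecars for anything
# carrying acquisition metadata, CSV for cohort tables, JSON for
# configuration. Complex k-space series are persisted as a real/imaginary
# NIfTI pair plus a JSON sidecar of delays and noise parameters.

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file. If a sidecar JSON
#'   (`<path minus extension>.json`) exists it is attached as the
#'   `"sidecar"` attribute; for 4D series with a `times` entry the frame
#'   count is checked against it.
#' @return A numeric array (with `pixdim` available via
#'   [RNifti::pixdim()]).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sc_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    if (!is.null(sc$times) && length(dim(img)) == 4 &&
        dim(img)[4] != length(sc$times)) {
      stop("frame count does not match the sidecar timing vector")
    }
    attr(img, "sidecar") <- sc
  }
  img
}

#' Write a NIfTI-1 volume
#'
#' Data are stored as float32; spatial metadata (voxel spacing) round
#' trips exactly.
#'
#' @param volume Numeric array (3D or 4D).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param pixdim Voxel spacing per dimension (mm, and s/frame for a 4th
#'   dimension).
#' @param sidecar Optional named list written as a JSON sidecar next to
#'   the volume.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, pixdim = NULL, sidecar = NULL) {
  img <- RNifti::asNifti(volume)
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path, datatype = "float")
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Persist an SPI k-space series
#'
#' Writes `<stem>_real.nii` and `<stem>_imag.nii` (4D, delay as the 4th
#' dimension) plus `<stem>.json` with delays, grid and noise metadata.
#'
#' @param kspace A [simulate_spi()] result.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_kspace <- function(kspace, stem) {
  grid <- kspace$grid
  nd <- length(kspace$kspace)
  re <- im <- array(0, c(grid, nd))
  for (j in seq_len(nd)) {
    re[, , , j] <- Re(kspace$kspace[[j]])
    im[, , , j] <- Im(kspace$kspace[[j]])
  }
  write_volume(re, paste0(stem, "_real.nii"))
  write_volume(im, paste0(stem, "_imag.nii"))
  jsonlite::write_json(list(delays = kspace$delays, grid = kspace$grid,
                            noise_sd = kspace$noise_sd,
                            phantom_shape = kspace$phantom_shape,
                            offset = kspace$offset),
                       paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Read back a persisted SPI k-space series
#' @param stem Path stem used by [write_kspace()].
#' @return A list of class `spi_kspace_series`.
#' @export
read_kspace <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  re <- read_volume(paste0(stem, "_real.nii"))
  im <- read_volume(paste0(stem, "_imag.nii"))
  ks <- lapply(seq_along(meta$delays), function(j) {
    array(complex(real = re[, , , j], imaginary = im[, , , j]), meta$grid)
  })
  structure(list(kspace = ks, delays = meta$delays, grid = meta$grid,
                 noise_sd = meta$noise_sd,
                 phantom_shape = meta$phantom_shape, offset = meta$offset),
            class = "spi_kspace_series")
}
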