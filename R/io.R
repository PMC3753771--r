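# Image, mask and k-space persistence.
#
# Images: PNG / TIFF (grayscale, rescaled to [0, 1]) and single-slice NIfTI.
# Masks and complex k-space: a documented flat binary container — IEEE-754
# little-endian doubles in column-major order, complex data as the real
# plane followed by the imaginary plane — with a JSON sidecar (`<path>.json`)
# recording dimensions, storage layout, and acquisition provenance
# (seed, ratio, decay, noise model).

#' Read a grayscale image from PNG, TIFF or NIfTI
#'
#' Multichannel inputs are averaged to one channel; 3-D NIfTI volumes yield
#' the requested slice. Intensities are returned on \[0, 1\] (integer-typed
#' NIfTI data are divided by their maximum).
#'
#' @param path input file; format chosen by extension (`.png`, `.tif(f)`,
#'   `.nii`, `.nii.gz`).
#' @param slice slice index for 3-D NIfTI volumes. Default 1.
#' @return a numeric matrix in \[0, 1\].
#' @export
read_image <- function(path, slice = 1L) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    nii = {
      vol <- RNifti::readNifti(path)
      arr <- as.array(vol)
      if (length(dim(arr)) == 3L) arr <- arr[, , slice]
      if (max(arr) > 1) arr <- arr / max(arr)
      arr
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' Write a grayscale image
#'
#' Values are clipped to \[0, 1\]; PNG is written as 8-bit grayscale, TIFF
#' as 32-bit float, NIfTI as a float volume.
#'
#' @param u numeric image matrix.
#' @param path output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(u, path) {
  check_image(u)
  x <- pmin(pmax(u, 0), 1)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
    png = png::writePNG(x, path, dpi = NULL),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 32L),
    nii = RNifti::writeNifti(RNifti::asNifti(x), path),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

write_array_bin <- function(x, path, meta = list()) {
  is_cplx <- is.complex(x)
  vec <- if (is_cplx) c(as.vector(Re(x)), as.vector(Im(x))) else as.vector(x * 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.double(vec), con, size = 8L, endian = "little")
  side <- c(list(dim = dim(x),
                 storage = "float64-le",
                 order = "column-major",
                 complex = is_cplx,
                 layout = if (is_cplx) "real-plane-then-imag-plane" else "single-plane"),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_array_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim) * (if (isTRUE(meta$complex)) 2L else 1L)
  con <- file(path, "rb")
  on.exit(close(con))
  vec <- readBin(con, "double", n = n, size = 8L, endian = "little")
  x <- if (isTRUE(meta$complex)) {
    half <- length(vec) / 2
    complex(real = vec[seq_len(half)], imaginary = vec[half + seq_len(half)])
  } else vec
  dim(x) <- meta$dim
  list(data = x, meta = meta)
}

#' Persist a sampling mask or k-space measurement
#'
#' Both use the package's flat binary container (column-major little-endian
#' float64, complex data as two planes) plus a JSON sidecar carrying the
#' acquisition parameters.
#'
#' @param mask a `"sampling_mask"`.
#' @param m a `"kspace_meas"`.
#' @param path output path (`<path>.json` sidecar is written next to it).
#' @return the loaded object, or `path` invisibly for the writers.
#' @export
save_mask <- function(mask, path) {
  write_array_bin(matrix(as.double(mask), nrow(mask)), path,
                  meta = list(kind = "sampling_mask",
                              ratio = attr(mask, "ratio"),
                              decay = attr(mask, "decay"),
                              center_fraction = attr(mask, "center_fraction"),
                              seed = attr(mask, "seed"),
                              n_selected = sum(mask)))
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  r <- read_array_bin(path)
  structure(matrix(r$data != 0, r$meta$dim[1]),
            class = c("sampling_mask", "matrix"),
            ratio = r$meta$ratio, decay = r$meta$decay,
            center_fraction = r$meta$center_fraction,
            seed = r$meta$seed)
}

#' @rdname save_mask
#' @export
save_kspace <- function(m, path) {
  stop_if(!inherits(m, "kspace_meas"), "m must be a kspace_meas")
  write_array_bin(m$values, path,
                  meta = list(kind = "kspace",
                              noise_model = m$noise_model,
                              noise_level = m$noise_level,
                              mask_ratio = attr(m$mask, "ratio"),
                              mask_decay = attr(m$mask, "decay"),
                              mask_center_fraction = attr(m$mask, "center_fraction"),
                              mask_seed = attr(m$mask, "seed"),
                              mask_selected = which(m$mask)))
}

#' @rdname save_mask
#' @export
load_kspace <- function(path) {
  r <- read_array_bin(path)
  sel <- matrix(FALSE, r$meta$dim[1], r$meta$dim[2])
  sel[r$meta$mask_selected] <- TRUE
  mask <- structure(sel, class = c("sampling_mask", "matrix"),
                    ratio = r$meta$mask_ratio, decay = r$meta$mask_decay,
                    center_fraction = r$meta$mask_center_fraction,
                    seed = r$meta$mask_seed)
  new_kspace(r$data, mask, r$meta$noise_model, r$meta$noise_level)
}
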