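#' Read a volumetric image into an `image_grid`
#'
#' Dispatches on the path: a directory is read as a DICOM image series
#' (explicit VR little endian), a `.nii`/`.nii.gz` file as NIfTI. Geometry
#' (spacing, origin) is taken from the file header. For DICOM, stored
#' integers are rescaled by the header slope/intercept and the quantity is
#' taken from the units tag (0054,1001) when present; otherwise the image is
#' assumed to be a count-rate map, with a warning.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param quantity optional quantity override (see [image_grid()]).
#' @param reference_time hours since administration that the image refers to.
#' @return an [image_grid()].
#' @export
read_image <- function(path, quantity = NULL, reference_time = 0) {
  if (dir.exists(path))
    return(read_dicom_series(path, quantity = quantity,
                             reference_time = reference_time))
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path))
    return(read_nifti_grid(path, quantity = quantity,
                           reference_time = reference_time))
  stop("unsupported image format: ", path,
       " (supported: NIfTI file, DICOM series directory)", call. = FALSE)
}

# internal NIfTI reader; quantity NULL means "unknown": warn and fall back to
# COUNT_RATE unless `quiet` (used by the mask reader, which binarizes anyway)
read_nifti_grid <- function(path, quantity = NULL, reference_time = 0,
                            quiet = FALSE) {
  im <- RNifti::readNifti(path)
  xf <- RNifti::xform(im)
  vals <- array(as.numeric(im), dim = dim(im))
  spacing <- abs(c(xf[1, 1], xf[2, 2], xf[3, 3]))
  if (any(spacing == 0)) spacing <- RNifti::pixdim(im)[1:3]
  origin <- xf[1:3, 4]
  if (is.null(quantity)) {
    if (!quiet)
      warning("NIfTI carries no dose/activity units; assuming COUNT_RATE",
              call. = FALSE)
    quantity <- "COUNT_RATE"
  }
  image_grid(vals, spacing = spacing, origin = origin, quantity = quantity,
             reference_time = reference_time)
}

#' Write an `image_grid` as NIfTI
#'
#' Geometry is stored in the sform/qform (scaling = spacing, translation =
#' origin). NIfTI has no units field for the pipeline's quantities, so the
#' quantity is not persisted; supply it again on read.
#'
#' @param grid an [image_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_image <- function(grid, path) {
  stopifnot(inherits(grid, "image_grid"))
  im <- RNifti::asNifti(grid$values)
  RNifti::pixdim(im) <- grid$spacing
  m <- diag(4)
  diag(m)[1:3] <- grid$spacing
  m[1:3, 4] <- grid$origin
  im <- RNifti::`sform<-`(im, structure(m, code = 2L))
  im <- RNifti::`qform<-`(im, structure(m, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a binary structure mask from NIfTI
#'
#' Values are binarized with `value > threshold`.
#'
#' @param path NIfTI file.
#' @param name structure label; defaults to the file stem.
#' @param threshold binarization threshold (default 0.5).
#' @return a [structure_mask()].
#' @export
read_mask <- function(path, name = NULL, threshold = 0.5) {
  if (is.null(name))
    name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  g <- read_nifti_grid(path, quantity = NULL, quiet = TRUE)
  vals <- (g$values > threshold) * 1
  structure_mask(name, image_grid(vals, g$spacing, g$origin, quantity = "MASK"))
}
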