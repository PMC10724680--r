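# Volume: a 3D scalar intensity grid with voxel spacing, an aligned binary
# brain mask, and passthrough affine metadata.

#' Create a volume
#'
#' @param data numeric 3D array of intensities (arbitrary units).
#' @param mask logical/numeric 3D array of the same dimensions; nonzero
#'   marks brain. `NULL` means no mask.
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param affine optional 4x4 voxel-to-world matrix, passed through I/O.
#' @return an object of class `volume`.
#' @export
volume <- function(data, mask = NULL, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(data)))
    mask <- array(as.numeric(mask != 0), dim = dim(mask))
  }
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, mask = mask, spacing = as.numeric(spacing),
                 affine = affine), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume> ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "/"),
      " mm", sep = "")
  if (!is.null(x$mask)) cat(", ", sum(x$mask > 0), " brain voxels", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

brain_values <- function(vol) {
  if (is.null(vol$mask)) stop("volume has no brain mask")
  v <- vol$data[vol$mask > 0]
  if (!length(v)) stop("brain mask is empty")
  v
}

#' Read / write a volume as NIfTI-1
#'
#' The intensity grid and the mask are stored as separate NIfTI files; the
#' mask path defaults to the volume path with a `_mask` suffix.
#'
#' @param vol a [volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param mask_path path for the mask image, or `NULL` to skip/derive.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume()].
#' @export
write_volume <- function(vol, path, mask_path = NULL) {
  img <- RNifti::asNifti(vol$data, reference = vol$affine)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  if (!is.null(vol$mask)) {
    if (is.null(mask_path)) mask_path <- default_mask_path(path)
    m <- RNifti::asNifti(vol$mask)
    RNifti::pixdim(m) <- vol$spacing
    RNifti::writeNifti(m, mask_path)
  }
  invisible(path)
}

default_mask_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, mask_path = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(mask_path)) {
    cand <- default_mask_path(path)
    mask_path <- if (file.exists(cand)) cand else NULL
  }
  msk <- if (!is.null(mask_path)) {
    array(as.numeric(as.array(RNifti::readNifti(mask_path)) > 0.5),
          dim = dim(img))
  }
  volume(array(as.numeric(img), dim = dim(img)), mask = msk,
         spacing = RNifti::pixdim(img)[1:3], affine = img)
}
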