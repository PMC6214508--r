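#' Image volume container
#'
#' A 3D scalar grid (typically Hounsfield units) together with its physical
#' voxel spacing in mm. The object is a plain numeric array carrying a
#' `spacing_mm` attribute, so all of base R's array machinery keeps working.
#'
#' @param data 3D numeric array.
#' @param spacing_mm numeric length-3 voxel size (mm) along the array axes.
#' @return An `image_volume`: the array with spacing metadata.
#' @export
image_volume <- function(data, spacing_mm) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three positive numbers")
  }
  structure(data, spacing_mm = spacing_mm,
            class = c("image_volume", "array"))
}

#' Voxel spacing of a volume or mask
#'
#' @param x an `image_volume`, or any array with a `spacing_mm` attribute.
#' @return Numeric length-3 spacing in mm.
#' @export
vol_spacing <- function(x) {
  sp <- attr(x, "spacing_mm")
  if (is.null(sp)) stop("object has no `spacing_mm` attribute")
  sp
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  sp <- vol_spacing(x)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

# strip class/attrs down to a bare array (internal)
as_bare_array <- function(x) {
  a <- as.vector(x)
  dim(a) <- dim(x)
  a
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping the spacing metadata in the NIfTI pixdim
#' fields. Masks are written as 0/1 volumes.
#'
#' @param x an `image_volume` or a logical mask array with `spacing_mm`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns an `image_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(x, path) {
  sp <- vol_spacing(x)
  a <- as_bare_array(x)
  storage.mode(a) <- if (is.logical(x)) "integer" else "double"
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  image_volume(a, RNifti::pixdim(img)[seq_len(3)])
}

# logical mask with spacing attribute (internal constructor)
as_mask <- function(x, spacing_mm) {
  m <- array(as.logical(x), dim = dim(x))
  attr(m, "spacing_mm") <- as.numeric(spacing_mm)
  m
}
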