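#' Euclidean distance to a voxel set
#'
#' Exact voxel-centre-to-voxel-centre Euclidean distance (in mm, honouring
#' anisotropic spacing) from every grid voxel to the nearest `TRUE` voxel of
#' `mask`, computed with a separable lower-envelope distance transform.
#' Voxels inside the set have distance 0.
#'
#' @param mask logical 3D array.
#' @param spacing_mm per-axis voxel size in mm.
#' @return Numeric array of distances (mm), same shape as `mask`.
#' @export
distance_to_mask <- function(mask, spacing_mm = vol_spacing(mask)) {
  if (!any(mask)) stop("mask is empty: distance to the empty set is undefined")
  d2 <- .edt_sq(as.logical(mask), dim(mask), as.numeric(spacing_mm))
  d <- sqrt(array(d2, dim = dim(mask)))
  attr(d, "spacing_mm") <- as.numeric(spacing_mm)
  d
}

#' Peritumoral rim mask
#'
#' The rim spans `inner_mm` inside to `outer_mm` outside the tumor boundary.
#' Morphology is done in physical units by thresholding the exact Euclidean
#' distance transform: the extratumoral shell is `dilate(tumor, outer_mm) \
#' tumor` intersected with the lung mask (only parenchymal tissue is kept
#' outside the tumor), the intratumoral shell is `tumor \ erode(tumor,
#' inner_mm)` and is kept unconditionally. Distances exactly equal to a
#' threshold are included.
#'
#' @param tumor_mask,lung_mask logical 3D arrays on a common grid. Tumor
#'   voxels are assumed excluded from `lung_mask`.
#' @param spacing_mm per-axis voxel size in mm.
#' @param inner_mm,outer_mm band half-widths in mm (defaults 3 and 3).
#' @return Logical mask of the rim with spacing attribute.
#' @export
make_rim <- function(tumor_mask, lung_mask,
                     spacing_mm = vol_spacing(tumor_mask),
                     inner_mm = 3, outer_mm = 3) {
  check_region_inputs(tumor_mask, lung_mask)
  if (inner_mm < 0 || outer_mm < 0) stop("band widths must be >= 0")
  d_out <- distance_to_mask(tumor_mask, spacing_mm)
  d_in <- if (all(tumor_mask)) {
    array(Inf, dim = dim(tumor_mask))
  } else {
    distance_to_mask(!tumor_mask, spacing_mm)
  }
  outer_shell <- !tumor_mask & d_out <= outer_mm & lung_mask
  inner_shell <- tumor_mask & d_in <= inner_mm
  rim <- outer_shell | inner_shell
  if (!any(rim)) warning("rim is empty after lung-mask intersection")
  as_mask(rim, spacing_mm)
}

#' Tumor exterior mask
#'
#' Lung voxels at a distance in `(from_mm, to_mm]` outside the tumor contour:
#' `(dilate(tumor, to_mm) \ dilate(tumor, from_mm))` intersected with the
#' lung mask.
#'
#' @inheritParams make_rim
#' @param from_mm,to_mm band limits in mm, `0 <= from_mm <= to_mm`
#'   (defaults 3 and 9); an empty band (`from_mm == to_mm`) yields an empty
#'   mask.
#' @return Logical mask with spacing attribute.
#' @export
make_exterior <- function(tumor_mask, lung_mask,
                          spacing_mm = vol_spacing(tumor_mask),
                          from_mm = 3, to_mm = 9) {
  check_region_inputs(tumor_mask, lung_mask)
  if (from_mm < 0 || from_mm > to_mm) stop("need 0 <= from_mm <= to_mm")
  d_out <- distance_to_mask(tumor_mask, spacing_mm)
  ext <- !tumor_mask & d_out > from_mm & d_out <= to_mm & lung_mask
  if (!any(ext)) warning("exterior band is empty after lung-mask intersection")
  as_mask(ext, spacing_mm)
}

check_region_inputs <- function(tumor_mask, lung_mask) {
  if (!identical(dim(tumor_mask), dim(lung_mask))) {
    stop("tumor and lung masks must share one grid")
  }
  if (!any(tumor_mask)) stop("tumor mask is empty")
  invisible(TRUE)
}

#' Analysis regions for one case
#'
#' Builds the three analysis masks (tumor, rim, exterior) on the native grid.
#'
#' @inheritParams make_rim
#' @inheritParams make_exterior
#' @return A `region_set`: named list of the three logical masks plus
#'   `spacing_mm`.
#' @export
region_set <- function(tumor_mask, lung_mask,
                       spacing_mm = vol_spacing(tumor_mask),
                       inner_mm = 3, outer_mm = 3,
                       from_mm = 3, to_mm = 9) {
  rim <- make_rim(tumor_mask, lung_mask, spacing_mm, inner_mm, outer_mm)
  ext <- make_exterior(tumor_mask, lung_mask, spacing_mm, from_mm, to_mm)
  structure(
    list(tumor = as_mask(tumor_mask, spacing_mm), rim = rim, exterior = ext,
         spacing_mm = as.numeric(spacing_mm)),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> tumor %d | rim %d | exterior %d voxels\n",
              sum(x$tumor), sum(x$rim), sum(x$exterior)))
  invisible(x)
}

#' Conventional shape features of a mask
#'
#' Volume (voxel count times voxel volume) and the maximal 3D / maximal
#' axial-slice 2D diameters, measured as the largest pairwise distance
#' between surface-voxel centres. Surface voxels are mask voxels with at
#' least one 6-connected neighbour outside the mask (or outside the grid).
#'
#' @param mask nonempty logical 3D array.
#' @param spacing_mm per-axis voxel size in mm.
#' @return A one-row tibble with `volume_mm3`, `max_3d_diameter_mm`,
#'   `max_2d_axial_diameter_mm`.
#' @export
shape_features <- function(mask, spacing_mm = vol_spacing(mask)) {
  if (!any(mask)) stop("mask is empty")
  spacing_mm <- as.numeric(spacing_mm)
  surf <- surface_voxels(mask)
  pts <- which(surf, arr.ind = TRUE)
  xyz <- sweep(pts - 0.5, 2, spacing_mm, `*`)
  max3d <- if (nrow(xyz) < 2) 0 else max(stats::dist(xyz))
  max2d <- 0
  for (z in unique(pts[, 3])) {
    sl <- xyz[pts[, 3] == z, 1:2, drop = FALSE]
    if (nrow(sl) >= 2) max2d <- max(max2d, max(stats::dist(sl)))
  }
  tibble::tibble(
    volume_mm3 = sum(mask) * prod(spacing_mm),
    max_3d_diameter_mm = max3d,
    max_2d_axial_diameter_mm = max2d
  )
}

surface_voxels <- function(mask) {
  d <- dim(mask)
  pad_shift <- function(m, axis, by) {
    # shift with FALSE fill
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) {
      idx_dst[[axis]] <- seq(1 + by, n)
      idx_src[[axis]] <- seq(1, n - by)
    } else {
      idx_dst[[axis]] <- seq(1, n + by)
      idx_src[[axis]] <- seq(1 - by, n)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  inside <- array(TRUE, dim = d)
  for (axis in 1:3) {
    for (by in c(-1, 1)) {
      inside <- inside & pad_shift(mask, axis, by)
    }
  }
  mask & !inside
}
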