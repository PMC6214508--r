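#' Filter specifications
#'
#' A filter spec names one derived image: the unfiltered volume
#' (`original`), a Laplacian-of-Gaussian response at a physical scale
#' (`log`), or one sub-band of a one-level undecimated 3D wavelet
#' decomposition (`wavelet`). The string form used in feature names is
#' `original`, `log-sigma-<x>mm` or `wavelet-<SUB>`, where `<SUB>` is a
#' three-letter L/H code in (x, y, z) array-axis order.
#'
#' @param kind one of `"original"`, `"log"`, `"wavelet"`.
#' @param sigma_mm LoG kernel scale in mm (`log` only).
#' @param subband three-letter code over `{L,H}` (`wavelet` only).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("original", "log", "wavelet"),
                        sigma_mm = NULL, subband = NULL) {
  kind <- match.arg(kind)
  if (kind == "log") {
    if (is.null(sigma_mm) || !is.finite(sigma_mm) || sigma_mm <= 0) {
      stop("`sigma_mm` must be a positive scalar for LoG filters")
    }
  }
  if (kind == "wavelet") {
    if (is.null(subband) || !grepl("^[LH]{3}$", subband)) {
      stop("`subband` must be a 3-letter code over {L,H}")
    }
  }
  structure(list(kind = kind, sigma_mm = sigma_mm, subband = subband),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param x a `filter_spec`.
#' @export
filter_name <- function(x) {
  switch(x$kind,
         original = "original",
         log = sprintf("log-sigma-%gmm", x$sigma_mm),
         wavelet = sprintf("wavelet-%s", x$subband))
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec>", filter_name(x), "\n")
  invisible(x)
}

#' Default filter bank
#'
#' The unfiltered image, LoG responses at 0.5/1.5/2.5/3.0 mm, and all eight
#' wavelet sub-bands.
#'
#' @param log_sigmas_mm LoG scales in mm.
#' @param wavelet include the 8 wavelet sub-bands?
#' @return List of `filter_spec`s.
#' @export
default_filters <- function(log_sigmas_mm = c(0.5, 1.5, 2.5, 3.0),
                            wavelet = TRUE) {
  out <- list(filter_spec("original"))
  for (s in log_sigmas_mm) out <- c(out, list(filter_spec("log", sigma_mm = s)))
  if (wavelet) {
    subs <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")), 1,
                  paste0, collapse = "")
    for (sb in subs) out <- c(out, list(filter_spec("wavelet", subband = sb)))
  }
  out
}

#' Resample to an isotropic grid
#'
#' Resamples the image by trilinear interpolation and each mask by nearest
#' neighbour onto an isotropic grid with spacing `target_mm` covering the
#' original physical extent.
#'
#' @param image an `image_volume`.
#' @param masks a named list of logical masks on the image grid (or a single
#'   mask).
#' @param target_mm isotropic target spacing in mm (default 3).
#' @return List with `image` (an `image_volume`) and `masks` (named list of
#'   logical masks). Errors if any mask is empty after resampling.
#' @export
resample_isotropic <- function(image, masks, target_mm = 3) {
  if (target_mm <= 0) stop("`target_mm` must be positive")
  sp <- vol_spacing(image)
  d <- dim(image)
  if (!is.list(masks)) masks <- list(mask = masks)
  od <- pmax(1L, as.integer(ceiling(d * sp / target_mm)))
  osp <- rep(target_mm, 3)
  img <- .resample3d(as.numeric(as_bare_array(image)), d, sp, od, osp,
                     c(0, 0, 0), FALSE)
  img <- image_volume(array(img, dim = od), osp)
  rmasks <- lapply(masks, function(m) {
    rm <- .resample3d(as.numeric(m), d, sp, od, osp, c(0, 0, 0), TRUE)
    as_mask(array(rm > 0.5, dim = od), osp)
  })
  empty <- vapply(rmasks, function(m) !any(m), logical(1))
  if (any(empty)) {
    stop("mask(s) empty after resampling (region too thin for ",
         target_mm, " mm grid): ", paste(names(rmasks)[empty], collapse = ", "))
  }
  list(image = img, masks = rmasks)
}

#' Discretize intensities into gray levels
#'
#' Fixed-width binning anchored at absolute multiples of `bin_width`:
#' `g(v) = floor(v / bin_width) - floor(min(values) / bin_width) + 1`. The
#' anchoring makes gray levels comparable across test/retest replicates;
#' shifting all values by an exact multiple of `bin_width` leaves the gray
#' levels unchanged.
#'
#' @param values numeric vector (HU or filtered intensities).
#' @param bin_width bin width in intensity units (default 25 HU).
#' @return Integer vector of consecutive positive gray levels.
#' @export
discretize <- function(values, bin_width = 25) {
  if (length(values) == 0) stop("`values` is empty")
  if (bin_width <= 0) stop("`bin_width` must be positive")
  as.integer(floor(values / bin_width) - floor(min(values) / bin_width) + 1)
}

# 1D Gaussian taps sampled at integer offsets, normalized to sum 1
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D second-derivative-of-Gaussian taps; exact zero DC response
gauss_d2_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  k <- (x^2 - sigma_vox^2) / sigma_vox^4 * g
  k - mean(k)
}

conv_sep <- function(a, kx, ky, kz) {
  d <- dim(a)
  v <- as.numeric(a)
  v <- .conv_axis(v, d, kx, 0L, as.integer((length(kx) - 1) %/% 2))
  v <- .conv_axis(v, d, ky, 1L, as.integer((length(ky) - 1) %/% 2))
  v <- .conv_axis(v, d, kz, 2L, as.integer((length(kz) - 1) %/% 2))
  array(v, dim = d)
}

#' Laplacian-of-Gaussian filtered image
#'
#' Scale-normalized LoG response (`sigma_mm^2 * Laplacian(Gaussian)`),
#' computed separably with per-axis sigma `sigma_mm / spacing` voxels and
#' mirror padding. The kernel has exactly zero DC response, so a constant
#' image maps to zero.
#'
#' @param image an `image_volume`.
#' @param sigma_mm kernel scale in mm.
#' @return An `image_volume` of the same shape.
#' @export
log_filter <- function(image, sigma_mm) {
  if (!is.finite(sigma_mm) || sigma_mm <= 0) stop("`sigma_mm` must be > 0")
  sp <- vol_spacing(image)
  if (sigma_mm < min(sp) / 2) {
    warning("sigma ", sigma_mm, " mm is under-resolved on spacing ",
            paste(signif(sp, 3), collapse = "x"), " mm")
  }
  sv <- sigma_mm / sp
  g <- lapply(sv, gauss_kernel)
  d2 <- lapply(sv, gauss_d2_kernel)
  a <- as_bare_array(image)
  out <- conv_sep(a, d2[[1]], g[[2]], g[[3]]) +
    conv_sep(a, g[[1]], d2[[2]], g[[3]]) +
    conv_sep(a, g[[1]], g[[2]], d2[[3]])
  image_volume(sigma_mm^2 * out, sp)
}

# Coiflet-1 analysis taps; the high-pass is the quadrature mirror of the
# low-pass, so it annihilates constants.
coif1_taps <- function() {
  lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
          0.852572020212255, 0.337897662457809, -0.072732619512854)
  n <- length(lo)
  hi <- (-1)^(seq_len(n) - 1) * rev(lo)
  list(lo = lo, hi = hi)
}

#' One-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) wavelet transform with Coiflet-1
#' analysis filters and mirror padding. Returns the 8 sub-bands labelled by
#' a per-axis L/H letter in (x, y, z) array-axis order; `HLL` is high-pass
#' along x and low-pass along y and z. All sub-bands keep the input grid.
#'
#' @param image an `image_volume` with at least 2 voxels per axis.
#' @return Named list of 8 `image_volume`s (`LLL` ... `HHH`).
#' @export
wavelet_subbands <- function(image) {
  if (any(dim(image) < 2)) stop("grid must have >= 2 voxels per axis")
  sp <- vol_spacing(image)
  taps <- coif1_taps()
  pick <- function(l) if (l == "L") taps$lo else taps$hi
  subs <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")), 1,
                paste0, collapse = "")
  a <- as_bare_array(image)
  out <- lapply(subs, function(code) {
    ltr <- strsplit(code, "")[[1]]
    image_volume(conv_sep(a, pick(ltr[1]), pick(ltr[2]), pick(ltr[3])), sp)
  })
  names(out) <- subs
  out[order(names(out))]
}

#' Apply one filter spec
#'
#' @param image an `image_volume`.
#' @param spec a `filter_spec`.
#' @param subband_cache optional precomputed result of
#'   [wavelet_subbands()] to avoid recomputation across specs.
#' @return The filtered `image_volume`.
#' @export
apply_filter <- function(image, spec, subband_cache = NULL) {
  switch(spec$kind,
         original = image,
         log = log_filter(image, spec$sigma_mm),
         wavelet = {
           if (is.null(subband_cache)) subband_cache <- wavelet_subbands(image)
           subband_cache[[spec$subband]]
         })
}
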