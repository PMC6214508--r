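#' First-order intensity statistics
#'
#' Kurtosis is the Pearson (non-excess) fourth standardized moment
#' `m4 / m2^2`; it is `NA` for zero-variance input. Entropy is computed in
#' bits from the fixed-width discretized histogram (see [discretize()]);
#' standard deviation is the population form.
#'
#' @param values numeric vector of in-region intensities.
#' @param bin_width bin width for the entropy histogram.
#' @return Named list with `median`, `minimum`, `range`, `kurtosis`, `mean`,
#'   `std`, `energy`, `entropy`.
#' @export
first_order <- function(values, bin_width = 25) {
  if (length(values) == 0) stop("`values` is empty")
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m4 <- mean((values - mu)^4)
  p <- tabulate(discretize(values, bin_width))
  p <- p[p > 0] / length(values)
  list(
    median = median(values),
    minimum = min(values),
    range = max(values) - min(values),
    kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    mean = mu,
    std = sqrt(m2),
    energy = sum(values^2),
    entropy = -sum(p * log2(p))
  )
}

# gray-level array: integer array, 0 outside the region, 1..Ng inside
gray_array <- function(image, mask, bin_width) {
  g <- array(0L, dim = dim(mask))
  vals <- as.numeric(image)[mask]
  g[mask] <- discretize(vals, bin_width)
  g
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' GLCM texture features
#'
#' Symmetric gray-level co-occurrence counts over the 13 unique 3D offsets
#' at voxel distance 1, summed over directions before normalization
#' (merged-matrix convention). Difference entropy is the entropy (bits) of
#' the gray-level difference distribution `p_{x-y}`.
#'
#' @param gray integer array of gray levels, 0 outside the region.
#' @return Named list with `difference_entropy` (NA when no voxel pair
#'   exists).
#' @export
glcm_features <- function(gray) {
  ng <- max(gray)
  if (ng < 1) stop("empty region")
  cc <- .glcm_counts(as.integer(gray), dim(gray), ng)
  tot <- sum(cc$diff)
  if (tot == 0) return(list(difference_entropy = NA_real_))
  list(difference_entropy = entropy_bits(cc$diff / tot))
}

#' GLRLM texture features
#'
#' Maximal constant-level runs per direction over the 13 unique 3D
#' directions, with runs broken at out-of-region voxels, aggregated over
#' directions. Run entropy is the entropy (bits) of the normalized run
#' count distribution over (gray level, run length).
#'
#' @inheritParams glcm_features
#' @param directions subset of the 13 scan directions to aggregate
#'   (default all; a single index gives single-offset run statistics).
#' @return Named list with `run_entropy`.
#' @export
glrlm_features <- function(gray, directions = 1:13) {
  ng <- max(gray)
  if (ng < 1) stop("empty region")
  m <- .glrlm_counts(as.integer(gray), dim(gray), ng,
                     as.integer(directions))
  tot <- sum(m)
  if (tot == 0) return(list(run_entropy = NA_real_))
  list(run_entropy = entropy_bits(m / tot))
}

#' NGTDM texture features
#'
#' Neighbouring gray tone difference statistics from the 26-neighbourhood:
#' for every in-region voxel with at least one in-region neighbour, the
#' absolute difference between its level and the mean level of its valid
#' neighbours is accumulated per gray level (`s_i`), with occupancy
#' probabilities `p_i = n_i / N_valid`. Complexity, strength, coarseness,
#' busyness and contrast follow the standardized (IBSI) definitions;
#' strength is 0 when all `s_i` vanish, and coarseness is capped at 1e6 for
#' a homogeneous region.
#'
#' @inheritParams glcm_features
#' @return Named list with `complexity`, `strength`, `coarseness`,
#'   `busyness`, `contrast`.
#' @export
ngtdm_features <- function(gray) {
  ng <- max(gray)
  if (ng < 1) stop("empty region")
  st <- .ngtdm_stats(as.integer(gray), dim(gray), ng)
  nvec <- st$n
  svec <- st$s
  nvalid <- sum(nvec)
  if (nvalid == 0) {
    return(list(complexity = NA_real_, strength = NA_real_,
                coarseness = NA_real_, busyness = NA_real_,
                contrast = NA_real_))
  }
  keep <- which(nvec > 0)
  i <- keep
  p <- nvec[keep] / nvalid
  s <- svec[keep]
  ngp <- length(keep)
  ii <- matrix(i, ngp, ngp)
  jj <- t(ii)
  pi_ <- matrix(p, ngp, ngp)
  pj_ <- t(pi_)
  si_ <- matrix(s, ngp, ngp)
  sj_ <- t(si_)

  contrast <- if (ngp > 1) {
    (sum(pi_ * pj_ * (ii - jj)^2) / (ngp * (ngp - 1))) * (sum(s) / nvalid)
  } else 0
  bus_den <- sum(abs(ii * pi_ - jj * pj_))
  busyness <- if (bus_den > 0) sum(p * s) / bus_den else 0
  coarseness <- if (sum(p * s) > 0) min(1 / sum(p * s), 1e6) else 1e6
  complexity <- sum(abs(ii - jj) * (pi_ * si_ + pj_ * sj_) / (pi_ + pj_)) /
    nvalid
  strength <- if (sum(s) > 0) sum((pi_ + pj_) * (ii - jj)^2) / sum(s) else 0
  list(complexity = complexity, strength = strength, coarseness = coarseness,
       busyness = busyness, contrast = contrast)
}

feature_class_names <- function() {
  list(
    firstorder = c("median", "minimum", "range", "kurtosis", "mean", "std",
                   "energy", "entropy"),
    glcm = "difference_entropy",
    glrlm = "run_entropy",
    ngtdm = c("complexity", "strength", "coarseness", "busyness", "contrast")
  )
}

region_feature_row <- function(filtered, mask, fname, bin_width) {
  nm <- feature_class_names()
  mk <- function(class, vals) {
    setNames(as.numeric(unlist(vals[nm[[class]]])),
             paste(fname, class, nm[[class]], sep = "_"))
  }
  nvox <- sum(mask)
  if (nvox < 2) {
    all_names <- unlist(lapply(names(nm), function(cl)
      paste(fname, cl, nm[[cl]], sep = "_")))
    return(setNames(rep(NA_real_, length(all_names)), all_names))
  }
  vals <- as.numeric(filtered)[mask]
  gray <- gray_array(filtered, mask, bin_width)
  c(mk("firstorder", first_order(vals, bin_width)),
    mk("glcm", glcm_features(gray)),
    mk("glrlm", glrlm_features(gray)),
    mk("ngtdm", ngtdm_features(gray)))
}

#' Extract radiomic features for one region
#'
#' For every filter spec, the filtered image is discretized within the mask
#' (fixed 25 HU-style bin width, edge-anchored) and the implemented feature
#' classes are computed: 8 first-order statistics, GLCM difference entropy,
#' GLRLM run entropy and the 5 NGTDM features. Feature names follow
#' `<filter>_<class>_<feature>`. Degenerate regions (< 2 voxels) yield
#' missing values rather than errors.
#'
#' @param image an `image_volume` (already resampled if desired).
#' @param mask logical region mask on the image grid.
#' @param filters list of [filter_spec()]s.
#' @param bin_width discretization bin width (intensity units).
#' @return One-row tibble of named feature values.
#' @export
extract_features <- function(image, mask, filters = default_filters(),
                             bin_width = 25) {
  if (!identical(dim(image), dim(mask))) stop("image and mask grids differ")
  if (!any(mask)) stop("mask is empty")
  cache <- if (any(vapply(filters, function(f) f$kind == "wavelet",
                          logical(1)))) {
    wavelet_subbands(image)
  } else NULL
  row <- unlist(lapply(filters, function(f) {
    region_feature_row(apply_filter(image, f, cache), mask, filter_name(f),
                       bin_width)
  }))
  tibble::as_tibble(as.list(row))
}

#' Extract features for all regions of a case
#'
#' Resamples the image and the region masks to an isotropic grid, computes
#' every filtered image once, and extracts the feature set per region.
#'
#' @param image native-grid `image_volume`.
#' @param regions a [region_set()] on the native grid.
#' @param filters list of [filter_spec()]s.
#' @param bin_width discretization bin width.
#' @param resample_mm isotropic target spacing in mm.
#' @param which_regions subset of the three region names to compute.
#' @return Tibble with a `region` column and one feature column per name.
#' @export
extract_region_features <- function(image, regions,
                                    filters = default_filters(),
                                    bin_width = 25, resample_mm = 3,
                                    which_regions = c("tumor", "rim",
                                                      "exterior")) {
  masks <- regions[which_regions]
  rs <- resample_isotropic(image, masks, resample_mm)
  img <- rs$image
  cache <- if (any(vapply(filters, function(f) f$kind == "wavelet",
                          logical(1)))) {
    wavelet_subbands(img)
  } else NULL
  filtered <- lapply(filters, apply_filter, image = img,
                     subband_cache = cache)
  fnames <- vapply(filters, filter_name, character(1))
  rows <- lapply(names(rs$masks), function(rg) {
    vals <- unlist(lapply(seq_along(filtered), function(k) {
      region_feature_row(filtered[[k]], rs$masks[[rg]], fnames[k], bin_width)
    }))
    dplyr::bind_cols(tibble::tibble(region = rg),
                     tibble::as_tibble(as.list(vals)))
  })
  dplyr::bind_rows(rows)
}
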