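#' Simulate a pre/post-gadolinium T1-weighted image pair
#'
#' Generates an aligned pair of T1-weighted images with the study's
#' anatomical geometry (256x256 matrix, 20x20 mm^2 field of view, 0.8 mm
#' slice; voxel volume about 0.0049 mm^3). The pre image is a uniform
#' tissue intensity; in the post image, lesion voxels (blood-brain-barrier
#' leakage) are scaled by `1 + fraction`. Independent Gaussian noise is
#' added to both images; intensities are clipped at zero.
#'
#' Lesions can be given either as a data frame of circular blobs
#' (`row`, `col`, `radius_px`, `fraction`) or as an explicit logical
#' `lesion_mask` with a scalar `fraction`.
#'
#' @param lesions data.frame of blobs, or `NULL`.
#' @param lesion_mask logical matrix of lesion voxels (alternative to
#'   `lesions`).
#' @param fraction enhancement fraction used with `lesion_mask`.
#' @param image_size image matrix (rows, cols).
#' @param fov_mm in-plane field of view (mm).
#' @param slice_thickness_mm slice thickness (mm).
#' @param background tissue intensity of the pre image.
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @return An object of class `t1_image_pair`: list with `pre`, `post`,
#'   `lesion_mask`, `voxel_volume_mm3`, `noise_sigma`, `seed`.
#' @export
#' @examples
#' pair <- simulate_t1_pair(data.frame(row = 128, col = 128, radius_px = 6,
#'                                     fraction = 0.5), noise_sigma = 0)
#' sum(pair$post != pair$pre)
simulate_t1_pair <- function(lesions = NULL, lesion_mask = NULL,
                             fraction = 0.5,
                             image_size = c(256L, 256L), fov_mm = 20,
                             slice_thickness_mm = 0.8, background = 1,
                             noise_sigma = 0.02, seed = 1) {
  .check_scalar(noise_sigma, "noise_sigma", 0)
  .check_scalar(background, "background", 0)
  nr <- as.integer(image_size[1L]); nc <- as.integer(image_size[2L])

  frac_map <- matrix(0, nr, nc)
  if (!is.null(lesion_mask)) {
    stopifnot(is.logical(lesion_mask), all(dim(lesion_mask) == c(nr, nc)))
    .check_scalar(fraction, "fraction", 0)
    frac_map[lesion_mask] <- fraction
  } else if (!is.null(lesions) && nrow(lesions) > 0L) {
    stopifnot(all(c("row", "col", "radius_px", "fraction") %in%
                    names(lesions)))
    if (any(lesions$fraction < 0))
      stop("enhancement fractions must be >= 0", call. = FALSE)
    rr <- row(frac_map); cc <- col(frac_map)
    for (b in seq_len(nrow(lesions))) {
      inside <- (rr - lesions$row[b])^2 + (cc - lesions$col[b])^2 <=
        lesions$radius_px[b]^2
      frac_map[inside] <- pmax(frac_map[inside], lesions$fraction[b])
    }
  }

  pre0 <- matrix(background, nr, nc)
  post0 <- pre0 * (1 + frac_map)
  if (noise_sigma > 0) {
    set.seed(seed)
    pre <- pre0 + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
    post <- post0 + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
  } else {
    pre <- pre0
    post <- post0
  }
  structure(list(pre = pmax(pre, 0), post = pmax(post, 0),
                 lesion_mask = frac_map > 0,
                 voxel_volume_mm3 =
                   (fov_mm / nr) * (fov_mm / nc) * slice_thickness_mm,
                 noise_sigma = noise_sigma, seed = seed),
            class = "t1_image_pair")
}

#' Border band mask used as normal-appearing reference tissue
#'
#' @param image_size image matrix (rows, cols).
#' @param width band width in pixels.
#' @return Logical matrix, `TRUE` on the border band.
#' @export
normal_region_border <- function(image_size = c(256L, 256L), width = 32L) {
  nr <- as.integer(image_size[1L]); nc <- as.integer(image_size[2L])
  m <- matrix(FALSE, nr, nc)
  m[c(seq_len(width), nr - seq_len(width) + 1L), ] <- TRUE
  m[, c(seq_len(width), nc - seq_len(width) + 1L)] <- TRUE
  m
}

#' Enhancement volume of a T1 image pair
#'
#' Threshold-over-normal-tissue segmentation of gadolinium enhancement:
#' the relative signal change `d = (post - pre) / max(pre, eps)` is
#' computed per voxel, and voxels exceeding
#' `mean(d[normal]) + k_sd * sd(d[normal])` are classified as enhancing.
#' The endpoint is the enhancing volume in mm^3 (voxel count times voxel
#' volume).
#'
#' @param pair a [simulate_t1_pair()] object.
#' @param normal_region_mask logical matrix marking normal-appearing
#'   reference tissue (non-empty).
#' @param k_sd threshold multiplier (default 3).
#' @param analysis_mask optional logical matrix restricting where enhancing
#'   voxels are counted (e.g. a brain mask); `NULL` counts everywhere.
#' @param eps floor applied to the pre image in the denominator.
#' @return An object of class `enhancement_result`: list with `mask`,
#'   `n_voxels`, `volume_mm3`, `threshold`, `k_sd`.
#' @export
#' @examples
#' pair <- simulate_t1_pair(noise_sigma = 0)
#' enhancement_volume(pair, normal_region_border())$volume_mm3 # 0
enhancement_volume <- function(pair, normal_region_mask, k_sd = 3,
                               analysis_mask = NULL, eps = 1e-3) {
  stopifnot(inherits(pair, "t1_image_pair"))
  if (!is.logical(normal_region_mask) ||
      !all(dim(normal_region_mask) == dim(pair$pre)))
    stop("`normal_region_mask` must be a logical matrix matching the images",
         call. = FALSE)
  if (!any(normal_region_mask))
    stop("the normal-region mask is empty", call. = FALSE)
  .check_scalar(k_sd, "k_sd", 0)

  d <- (pair$post - pair$pre) / pmax(pair$pre, eps)
  dn <- d[normal_region_mask]
  threshold <- mean(dn) + k_sd * stats::sd(dn)
  if (!is.finite(threshold)) threshold <- Inf  # constant normal region
  mask <- d > threshold
  if (!is.null(analysis_mask)) {
    stopifnot(is.logical(analysis_mask),
              all(dim(analysis_mask) == dim(pair$pre)))
    mask <- mask & analysis_mask
  }
  n <- sum(mask)
  structure(list(mask = mask, n_voxels = n,
                 volume_mm3 = n * pair$voxel_volume_mm3,
                 threshold = threshold, k_sd = k_sd),
            class = "enhancement_result")
}

# Deterministic lesion layout realizing (approximately) a target enhancing
# volume: one central disc whose pixel count matches the target voxel count,
# with a small seeded position jitter.
.lesions_for_volume <- function(volume_mm3, voxel_volume_mm3,
                                image_size = c(256L, 256L), fraction = 0.5,
                                seed = 1) {
  n_vox <- round(volume_mm3 / voxel_volume_mm3)
  if (n_vox < 1) return(NULL)
  set.seed(seed)
  jitter <- stats::runif(2, -20, 20)
  data.frame(row = round(image_size[1L] / 2 + jitter[1L]),
             col = round(image_size[2L] / 2 + jitter[2L]),
             radius_px = sqrt(n_vox / pi),
             fraction = fraction)
}
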