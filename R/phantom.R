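#' Default spatial masks for the digital brain phantom
#'
#' A compact layout on the CSI grid: a central "brain" block, a two-row
#' region of interest inside it standing in for the voxels containing
#' cortex, corpus callosum, external capsule and hippocampus, and a
#' vascular-reference band of surrounding tissue containing blood vessels
#' (used to normalize the urea signal). The remaining voxels are empty.
#'
#' @param matrix_size spatial matrix size (default 8).
#' @return A list of logical `matrix_size x matrix_size` matrices:
#'   `brain`, `roi`, `vascular`.
#' @export
default_masks <- function(matrix_size = 8L) {
  n <- as.integer(matrix_size)
  if (n < 8L) stop("default masks need a matrix size of at least 8",
                   call. = FALSE)
  brain <- vascular <- roi <- matrix(FALSE, n, n)
  core <- 3:6
  brain[core, core] <- TRUE
  roi[4:5, core] <- TRUE
  vascular[c(2L, 7L), core] <- TRUE
  list(brain = brain, roi = roi, vascular = vascular)
}

#' Digital phantom: per-voxel kinetics plus masks
#'
#' Builds the ground-truth object consumed by [generate_dynamic_csi()]:
#' an `n x n` grid of [voxel_kinetics()] together with brain, ROI and
#' vascular-reference masks. Brain voxels convert pyruvate to lactate at
#' `kpl`; vascular voxels carry pyruvate and urea but no conversion;
#' all other voxels are signal-free.
#'
#' @param kpl pyruvate-to-lactate rate of the brain voxels (1/s).
#' @param urea_amp urea delivery amplitude of brain and vascular voxels.
#' @param pyr_amp pyruvate delivery amplitude of brain and vascular voxels.
#' @param masks list with logical matrices `brain`, `roi`, `vascular`
#'   (see [default_masks()]).
#' @param brain_kin,vascular_kin optional [voxel_kinetics()] overriding the
#'   per-region defaults built from `kpl`/`urea_amp`/`pyr_amp`.
#' @return An object of class `phantom_grid`: list with `kinetics` (an
#'   `n x n` list-matrix of `voxel_kinetics`), the three masks, and
#'   `matrix_size`.
#' @export
#' @examples
#' ph <- make_phantom(kpl = 0.03)
#' sum(ph$roi_mask)
make_phantom <- function(kpl = 0.02, urea_amp = 1, pyr_amp = 1,
                         masks = default_masks(),
                         brain_kin = NULL, vascular_kin = NULL) {
  brain <- masks$brain
  roi <- masks$roi
  vascular <- masks$vascular
  n <- nrow(brain)
  stopifnot(is.matrix(brain), is.matrix(roi), is.matrix(vascular),
            all(dim(brain) == c(n, n)), all(dim(roi) == c(n, n)),
            all(dim(vascular) == c(n, n)))
  if (any(roi & !brain))
    stop("the ROI mask must lie inside the brain mask", call. = FALSE)
  if (any(vascular & brain))
    stop("vascular-reference and brain masks must be disjoint", call. = FALSE)
  if (!any(vascular))
    stop("at least one vascular-reference voxel is required", call. = FALSE)

  if (is.null(brain_kin))
    brain_kin <- voxel_kinetics(kPL = kpl, pyr_delivery_amp = pyr_amp,
                                urea_delivery_amp = urea_amp)
  if (is.null(vascular_kin))
    vascular_kin <- voxel_kinetics(kPL = 0, pyr_delivery_amp = pyr_amp,
                                   urea_delivery_amp = urea_amp)
  empty <- voxel_kinetics(kPL = 0, pyr_delivery_amp = 0, urea_delivery_amp = 0)

  kin <- vector("list", n * n)
  dim(kin) <- c(n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      kin[[i, j]] <- if (brain[i, j]) brain_kin
                     else if (vascular[i, j]) vascular_kin
                     else empty
    }
  }
  structure(list(kinetics = kin, brain_mask = brain, roi_mask = roi,
                 vascular_mask = vascular, matrix_size = n),
            class = "phantom_grid")
}

#' Replace the kinetics of the brain voxels of a phantom
#'
#' Used by the cohort generator: per-animal burden rescales the brain
#' voxels' conversion rate (and optionally their urea delivery) while the
#' vascular-reference voxels keep the template kinetics.
#'
#' @param phantom a [make_phantom()] object.
#' @param kpl new brain `kPL` (1/s).
#' @param urea_amp new brain urea delivery amplitude (`NULL` keeps the
#'   template value).
#' @return The modified `phantom_grid`.
#' @export
set_brain_kinetics <- function(phantom, kpl, urea_amp = NULL) {
  stopifnot(inherits(phantom, "phantom_grid"))
  .check_scalar(kpl, "kpl", 0)
  idx <- which(phantom$brain_mask)
  for (k in idx) {
    kin <- phantom$kinetics[[k]]
    kin$kPL <- kpl
    if (!is.null(urea_amp)) {
      .check_scalar(urea_amp, "urea_amp", 0)
      kin$urea_delivery_amp <- urea_amp
    }
    phantom$kinetics[[k]] <- kin
  }
  phantom
}

# Nearest-neighbour upsampling of a voxel mask onto the zero-filled grid:
# each coarse voxel becomes a factor x factor block.
.upsample_mask <- function(mask, factor) {
  if (factor == 1L) return(mask)
  n <- nrow(mask)
  mask[rep(seq_len(n), each = factor), rep(seq_len(n), each = factor)]
}
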