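#' Synthesize one voxel's free induction decay
#'
#' Builds the complex FID of a voxel at one dynamic frame from the
#' longitudinal magnetizations of the metabolites:
#' \deqn{s(t_k) = \sum_m M_{z,m} \sin\theta \; e^{(i 2\pi f_m - \pi\,FWHM_m)\,t_k},
#'   \quad t_k = k / SW}
#' so each resonance is a Lorentzian line by construction, positioned at its
#' apparent (aliased) offset `f_m` (see [ppm_to_offset_hz()]).
#'
#' @param mz non-negative magnetizations, one per row of `resonances`.
#' @param resonances a [resonance_table()].
#' @param acq an [acq_params()] object.
#' @return Complex vector of length `acq$n_spectral_points`.
#' @export
#' @examples
#' fid <- synthesize_voxel_fid(c(0, 1, 0.2), resonance_table(), acq_params())
synthesize_voxel_fid <- function(mz, resonances, acq) {
  stopifnot(inherits(resonances, "resonance_table"),
            inherits(acq, "acq_params"))
  if (length(mz) != nrow(resonances))
    stop("`mz` must have one value per resonance", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz < 0))
    stop("magnetizations must be finite and non-negative", call. = FALSE)
  tk <- (seq_len(acq$n_spectral_points) - 1L) / acq$spectral_width
  f <- ppm_to_offset_hz(resonances$ppm, acq)
  stheta <- sin(acq$flip_angle_deg * pi / 180)
  s <- complex(length.out = length(tk))
  for (m in seq_along(mz)) {
    if (mz[m] == 0) next
    s <- s + mz[m] * stheta *
      exp((2i * pi * f[m] - pi * resonances$fwhm_hz[m]) * tk)
  }
  s
}

#' Phase-encode an image-space grid into CSI k-space
#'
#' Forward spatial model of CSI phase encoding: a 2D discrete Fourier
#' transform over the spatial dimensions, applied independently per
#' (spectral point, frame). The transform is normalized by `1/(n*n)` and
#' stored with the DC component at the matrix centre (index `n/2 + 1`), so
#' that [reconstruct_voxels()] (an unnormalized inverse DFT) is its exact
#' inverse and spatial zero-filling around the centre performs Fourier
#' interpolation without a scale factor.
#'
#' @param voxel_grid complex array whose first two dimensions are the equal,
#'   even spatial dimensions (e.g. `8 x 8 x 128 x 15`).
#' @return Complex array of the same shape: k-space, centred layout.
#' @seealso [reconstruct_voxels()], [zero_fill_kspace()]
#' @export
encode_kspace <- function(voxel_grid) {
  d <- dim(voxel_grid)
  if (is.null(d) || length(d) < 2L || d[1L] != d[2L])
    stop("expected an array with equal spatial dimensions 1 and 2",
         call. = FALSE)
  if (d[1L] %% 2L != 0L)
    stop("spatial dimensions must be even", call. = FALSE)
  .fftshift2(.fft2(voxel_grid)) / (d[1L] * d[2L])
}

#' Simulate a dynamic CSI dataset from a phantom
#'
#' The full forward model: for every voxel the two-site kinetics are
#' integrated and sampled at the frame midpoints, each frame's magnetization
#' vector is turned into a Lorentzian-line FID ([synthesize_voxel_fid()]),
#' each (spectral point, frame) slice is phase-encoded into k-space
#' ([encode_kspace()]), and i.i.d. complex Gaussian noise of standard
#' deviation `noise_sigma` per component is added to every k-space point.
#' Identical seeds give bit-identical datasets.
#'
#' @param phantom a [make_phantom()] object.
#' @param acq an [acq_params()] object.
#' @param noise_sigma k-space noise standard deviation per real/imaginary
#'   component (>= 0).
#' @param seed integer RNG seed.
#' @param resonances a [resonance_table()]; rows must be urea, pyruvate,
#'   lactate (matched by name to the simulated species).
#' @return An object of class `dynamic_csi`: list with `kspace`
#'   (`n x n x n_spectral_points x n_frames` complex array), `acq`,
#'   `phantom`, `resonances`, `noise_sigma`, `seed`, `frame_times`.
#' @export
#' @examples
#' ds <- generate_dynamic_csi(make_phantom(), acq_params(),
#'                            noise_sigma = 0, seed = 1)
#' dim(ds$kspace)
generate_dynamic_csi <- function(phantom, acq, noise_sigma = 5e-4, seed = 1,
                                 resonances = resonance_table()) {
  stopifnot(inherits(phantom, "phantom_grid"), inherits(acq, "acq_params"))
  .check_scalar(noise_sigma, "noise_sigma", 0)
  n <- phantom$matrix_size
  ns <- acq$n_spectral_points
  nf <- acq$n_frames
  frame_times <- (seq_len(nf) - 0.5) * acq$frame_interval

  species <- c("urea", "pyruvate", "lactate")
  if (!setequal(resonances$name, species))
    stop("resonances must be exactly urea, pyruvate and lactate",
         call. = FALSE)

  img <- array(complex(real = 0, imaginary = 0), dim = c(n, n, ns, nf))
  fid_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      kin <- phantom$kinetics[[i, j]]
      if (kin$pyr_delivery_amp == 0 && kin$urea_delivery_amp == 0) next
      key <- paste(unlist(kin), collapse = "|")
      fids <- fid_cache[[key]]
      if (is.null(fids)) {
        m <- .magnetization_ode(kin, acq, frame_times)  # columns P, L, U
        mz <- cbind(urea = m[, 3L], pyruvate = m[, 1L], lactate = m[, 2L])
        mz <- mz[, resonances$name, drop = FALSE]
        fids <- vapply(seq_len(nf), function(f)
          synthesize_voxel_fid(as.numeric(mz[f, ]), resonances, acq),
          complex(ns))
        fid_cache[[key]] <- fids
      }
      img[i, j, , ] <- fids
    }
  }

  kspace <- encode_kspace(img)
  if (noise_sigma > 0) {
    set.seed(seed)
    len <- length(kspace)
    kspace <- kspace + complex(real = stats::rnorm(len, 0, noise_sigma),
                               imaginary = stats::rnorm(len, 0, noise_sigma))
  }
  structure(list(kspace = kspace, acq = acq, phantom = phantom,
                 resonances = resonances, noise_sigma = noise_sigma,
                 seed = seed, frame_times = frame_times),
            class = "dynamic_csi")
}
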