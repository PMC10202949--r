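#' Zero-fill CSI k-space spatially
#'
#' Appends zeros symmetrically around the spatial k-space centre, taking an
#' `n x n` matrix to `(factor*n) x (factor*n)` (the standard factor 2 turns
#' 8x8 into 16x16). With the centred k-space convention of
#' [encode_kspace()], reconstructing the zero-filled data performs Fourier
#' (sinc) interpolation: values at the original voxel centres are preserved
#' exactly. Spectral and time dimensions are untouched.
#'
#' @param k complex k-space array, dims 1 and 2 equal and even.
#' @param factor integer zoom factor (>= 1).
#' @return Zero-filled k-space array.
#' @export
zero_fill_kspace <- function(k, factor = 2L) {
  d <- dim(k)
  if (is.null(d) || length(d) < 2L || d[1L] != d[2L])
    stop("spatial dimensions must be square", call. = FALSE)
  if (d[1L] %% 2L != 0L)
    stop("spatial dimensions must be even", call. = FALSE)
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(k)
  n <- d[1L]
  nf <- n * factor
  dout <- d
  dout[1:2] <- nf
  out <- array(complex(real = 0, imaginary = 0), dim = dout)
  pad <- (nf - n) / 2L
  idx <- (pad + 1L):(pad + n)
  switch(as.character(length(d)),
    "2" = out[idx, idx] <- k,
    "3" = out[idx, idx, ] <- k,
    "4" = out[idx, idx, , ] <- k,
    stop("arrays with more than four dimensions are not supported",
         call. = FALSE))
  out
}

#' Reconstruct voxel FIDs from CSI k-space
#'
#' Inverse of [encode_kspace()]: an unnormalized inverse 2D spatial DFT per
#' (spectral point, frame), applied after undoing the centred layout.
#'
#' @param k complex k-space array in the centred layout.
#' @return Complex array of the same shape: one FID per voxel and frame.
#' @export
reconstruct_voxels <- function(k) {
  d <- dim(k)
  if (is.null(d) || length(d) < 2L || d[1L] != d[2L])
    stop("spatial dimensions must be square", call. = FALSE)
  .fft2(.fftshift2(k), inverse = TRUE)
}

#' Time-summed spectrum of one voxel
#'
#' Per frame: optional exponential apodization, DFT along the spectral
#' dimension (returned on the ascending frequency axis of
#' [spectrum_frequencies()]), and either zero-order phasing on the dominant
#' peak (`mode = "phased"`, default), magnitude (`mode = "magnitude"`), or
#' the raw complex spectrum (`mode = "complex"`). Frames are then summed
#' pointwise.
#'
#' The zero-order phase is estimated as the argument of the complex sum of
#' the bins in a symmetric window (`phase_window_bins` to each side) around
#' the dominant peak: the dispersive component of an off-bin-centre line is
#' odd about the peak and cancels in the sum, so the estimate is not biased
#' by the peak's fractional bin offset (the phase at the argmax bin alone
#' is).
#'
#' @param fids complex matrix `n_spectral_points x n_frames` (a vector is
#'   treated as a single frame).
#' @param acq an [acq_params()] object.
#' @param apodization_hz exponential line broadening (Hz, >= 0).
#' @param mode `"phased"`, `"magnitude"` or `"complex"`.
#' @param phase_window_bins half-width (bins) of the phase-estimation
#'   window.
#' @return Numeric (or complex for `mode = "complex"`) vector of length
#'   `n_spectral_points`.
#' @export
voxel_summed_spectrum <- function(fids, acq, apodization_hz = 0,
                                  mode = c("phased", "magnitude", "complex"),
                                  phase_window_bins = 4L) {
  stopifnot(inherits(acq, "acq_params"))
  mode <- match.arg(mode)
  .check_scalar(apodization_hz, "apodization_hz", 0)
  if (is.null(dim(fids))) fids <- matrix(fids, ncol = 1L)
  ns <- acq$n_spectral_points
  if (nrow(fids) != ns)
    stop("FID length must equal n_spectral_points", call. = FALSE)
  if (ncol(fids) < 1L) stop("at least one frame is required", call. = FALSE)
  if (apodization_hz > 0) {
    tk <- (seq_len(ns) - 1L) / acq$spectral_width
    fids <- fids * exp(-pi * apodization_hz * tk)
  }
  spec <- stats::mvfft(fids)
  spec <- spec[.shift_idx(ns), , drop = FALSE]
  per_frame <- switch(mode,
    phased = {
      apply(spec, 2L, function(s) {
        i <- which.max(Mod(s))
        w <- max(1L, i - phase_window_bins):min(ns, i + phase_window_bins)
        phi <- Arg(sum(s[w]))
        Re(s * exp(-1i * phi))
      })
    },
    magnitude = Mod(spec),
    complex = spec)
  if (is.null(dim(per_frame))) per_frame <- matrix(per_frame, ncol = 1L)
  rowSums(per_frame)
}

#' Lorentzian line shape
#'
#' `A * gamma^2 / ((f - center)^2 + gamma^2)`: amplitude `A` at the peak,
#' half width at half maximum `gamma`. Its analytic integral over frequency
#' is `pi * A * gamma`, the AUC used throughout the pipeline.
#'
#' @param f frequencies (Hz).
#' @param center peak centre (Hz).
#' @param gamma half width at half maximum (Hz, > 0).
#' @param amplitude peak amplitude.
#' @return Numeric vector of line values.
#' @export
lorentzian <- function(f, center, gamma, amplitude) {
  amplitude * gamma^2 / ((f - center)^2 + gamma^2)
}

#' Fit the urea, pyruvate and lactate peaks of a summed spectrum
#'
#' Simultaneous bounded nonlinear least squares of a three-Lorentzian model
#' plus a constant baseline, with analytic Jacobian (Levenberg-Marquardt via
#' \pkg{minpack.lm}). Centres are initialized at the nominal apparent
#' offsets of the resonance table and constrained to within
#' `center_bound_ppm` of them; half-widths are bounded in `gamma_bounds`;
#' amplitudes are non-negative. Each peak's AUC is the analytic integral
#' `pi * A * gamma`, with a delta-method standard error.
#'
#' @param spectrum real spectrum of length `acq$n_spectral_points` on the
#'   [spectrum_frequencies()] axis.
#' @param resonances a [resonance_table()].
#' @param acq an [acq_params()] object.
#' @param center_bound_ppm half-width of the centre constraint (ppm).
#' @param gamma_bounds bounds on the Lorentzian half width at half maximum
#'   (Hz).
#' @return An object of class `peak_fit`: list with `peaks` (data.frame:
#'   `name`, `center_hz`, `gamma_hz`, `amplitude`, `auc`, `auc_se`,
#'   `center_se`, `gamma_se`, `amplitude_se`, `at_bound`), `baseline`,
#'   `rss`, `converged`.
#' @export
#' @examples
#' acq <- acq_params()
#' res <- resonance_table()
#' f <- spectrum_frequencies(acq)
#' truth <- ppm_to_offset_hz(res$ppm, acq)
#' spec <- lorentzian(f, truth[1], 10, 2) + lorentzian(f, truth[2], 10, 5) +
#'   lorentzian(f, truth[3], 10, 3)
#' fit_three_peaks(spec, res, acq)$peaks$auc
fit_three_peaks <- function(spectrum, resonances, acq,
                            center_bound_ppm = 1, gamma_bounds = c(2, 200)) {
  stopifnot(inherits(resonances, "resonance_table"),
            inherits(acq, "acq_params"))
  ns <- acq$n_spectral_points
  if (length(spectrum) != ns || any(!is.finite(spectrum)))
    stop("spectrum must be a finite vector of length n_spectral_points",
         call. = FALSE)
  f <- spectrum_frequencies(acq)
  centers0 <- ppm_to_offset_hz(resonances$ppm, acq)
  np <- length(centers0)
  if (min(dist(centers0)) < 3 * max(resonances$fwhm_hz))
    warning("apparent peak positions are closer than 3 linewidths; ",
            "the fit may not be identifiable", call. = FALSE)

  bw_hz <- center_bound_ppm * acq$carbon_frequency_mhz
  base0 <- stats::median(spectrum)
  amp0 <- vapply(centers0, function(c0) {
    max(spectrum[which.min(abs(f - c0))] - base0, 1e-6)
  }, numeric(1))
  g0 <- pmin(pmax(resonances$fwhm_hz / 2, gamma_bounds[1]), gamma_bounds[2])

  # parameter order: baseline, A[1..np], f0[1..np], gamma[1..np]
  par0 <- c(base0, amp0, centers0, g0)
  lower <- c(-Inf, rep(0, np), centers0 - bw_hz,
             rep(gamma_bounds[1], np))
  upper <- c(Inf, rep(Inf, np), centers0 + bw_hz,
             rep(gamma_bounds[2], np))

  model <- function(p) {
    y <- rep(p[1L], ns)
    for (m in seq_len(np))
      y <- y + lorentzian(f, p[1L + np + m], p[1L + 2L * np + m], p[1L + m])
    y
  }
  resid_fn <- function(p) model(p) - spectrum
  jac_fn <- function(p) {
    J <- matrix(0, nrow = ns, ncol = 1L + 3L * np)
    J[, 1L] <- 1
    for (m in seq_len(np)) {
      A <- p[1L + m]; f0 <- p[1L + np + m]; g <- p[1L + 2L * np + m]
      df <- f - f0
      D <- df^2 + g^2
      J[, 1L + m] <- g^2 / D
      J[, 1L + np + m] <- 2 * A * g^2 * df / D^2
      J[, 1L + 2L * np + m] <- 2 * A * g * df^2 / D^2
    }
    J
  }

  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15,
                              gtol = 0))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  converged <- fit$info %in% c(1L, 2L, 3L)

  # covariance from the analytic Jacobian at the solution
  J <- jac_fn(p)
  sigma2 <- rss / max(1L, ns - length(p))
  cv <- tryCatch(solve(crossprod(J)) * sigma2,
                 error = function(e) matrix(NA_real_, length(p), length(p)))

  A <- p[1L + seq_len(np)]
  f0 <- p[1L + np + seq_len(np)]
  g <- p[1L + 2L * np + seq_len(np)]
  iA <- 1L + seq_len(np)
  ig <- 1L + 2L * np + seq_len(np)
  auc <- pi * A * g
  auc_se <- sqrt(pmax(0,
    pi^2 * (g^2 * diag(cv)[iA] + A^2 * diag(cv)[ig] +
              2 * A * g * cv[cbind(iA, ig)])))
  # a saturated centre or width means the line shape is not determined by
  # the data (typically a noise-level peak fitted at maximal width)
  shape_at_bound <- (abs(f0 - (centers0 - bw_hz)) < 1e-9) |
    (abs(f0 - (centers0 + bw_hz)) < 1e-9) |
    (abs(g - gamma_bounds[1]) < 1e-9) | (abs(g - gamma_bounds[2]) < 1e-9)
  at_bound <- shape_at_bound | (A <= 1e-12)
  if (any(shape_at_bound))
    warning("one or more fitted peaks saturated a bound", call. = FALSE)

  peaks <- data.frame(
    name = resonances$name,
    center_hz = f0,
    gamma_hz = g,
    amplitude = A,
    auc = auc,
    auc_se = auc_se,
    center_se = sqrt(diag(cv)[1L + np + seq_len(np)]),
    gamma_se = sqrt(diag(cv)[ig]),
    amplitude_se = sqrt(diag(cv)[iA]),
    at_bound = at_bound,
    shape_at_bound = shape_at_bound,
    stringsAsFactors = FALSE)
  structure(list(peaks = peaks, baseline = p[1L], rss = rss,
                 converged = converged, info = fit$info),
            class = "peak_fit")
}

#' Lactate-to-pyruvate AUC ratio with a reliability flag
#'
#' The model-free metabolic readout: `AUC_lac / AUC_pyr` per voxel. Voxels
#' whose pyruvate AUC does not exceed `pyr_threshold` are marked unreliable
#' (their ratio is `NA`) to avoid ratio blow-up near the noise floor.
#'
#' @param auc_lac,auc_pyr lactate and pyruvate AUCs (vectors, recycled).
#' @param pyr_threshold reliability threshold on `auc_pyr`.
#' @return `data.frame` with columns `lacpyr` and `reliable`.
#' @export
#' @examples
#' compute_lacpyr(1, 2)
compute_lacpyr <- function(auc_lac, auc_pyr, pyr_threshold = 0) {
  if (any(!is.finite(auc_lac)) || any(!is.finite(auc_pyr)))
    stop("AUCs must be finite", call. = FALSE)
  n <- max(length(auc_lac), length(auc_pyr))
  auc_lac <- rep_len(auc_lac, n)
  auc_pyr <- rep_len(auc_pyr, n)
  reliable <- auc_pyr > pyr_threshold & auc_pyr > 0
  ratio <- ifelse(reliable, auc_lac / auc_pyr, NA_real_)
  data.frame(lacpyr = ratio, reliable = reliable)
}

#' Normalize a urea AUC to the vascular reference
#'
#' Divides voxel urea AUCs by the mean urea AUC of the vascular-reference
#' voxels, removing the dependence on polarization level and transfer time.
#'
#' @param auc_urea voxel urea AUC(s).
#' @param reference_aucs urea AUCs of the vascular-reference voxels
#'   (non-empty, positive mean).
#' @return Normalized urea value(s) (dimensionless).
#' @export
#' @examples
#' normalize_urea(3, c(2, 4)) # 1
normalize_urea <- function(auc_urea, reference_aucs) {
  if (length(reference_aucs) < 1L || any(!is.finite(reference_aucs)))
    stop("reference AUCs must be a non-empty finite vector", call. = FALSE)
  ref <- mean(reference_aucs)
  if (ref <= 0)
    stop("vascular-reference urea AUCs are not positive; check the mask",
         call. = FALSE)
  auc_urea / ref
}

#' Mean of a voxel map over a region of interest
#'
#' @param voxel_map numeric matrix.
#' @param roi_mask logical matrix of the same shape, non-empty.
#' @return Scalar mean over masked, non-missing voxels (`NA` with a warning
#'   if every masked voxel is missing).
#' @export
roi_mean <- function(voxel_map, roi_mask) {
  if (!is.matrix(voxel_map) || !is.logical(roi_mask) ||
      !all(dim(voxel_map) == dim(roi_mask)))
    stop("map and mask must be matrices of the same shape", call. = FALSE)
  if (!any(roi_mask)) stop("the ROI mask is empty", call. = FALSE)
  vals <- voxel_map[roi_mask]
  if (all(is.na(vals))) {
    warning("all ROI voxels are missing/unreliable", call. = FALSE)
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

#' Per-voxel z-score maps across a cohort
#'
#' For each voxel the mean and sample standard deviation (n - 1 denominator)
#' across all animals are computed, and every animal's value is standardized
#' as `z = (x - mu) / sigma`. Voxels with zero or undefined spread are
#' masked (`NA`) and counted in a warning.
#'
#' @param values numeric array with animals on the first dimension: a matrix
#'   `n_animals x n_voxels` or a 3D array `n_animals x nx x ny`. Missing
#'   values are allowed and propagate.
#' @return An object of class `zscore_map`: list with `mu`, `sigma` (voxel
#'   shape) and `z` (input shape).
#' @export
#' @examples
#' z <- compute_zscores(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3))
#' z$z
compute_zscores <- function(values) {
  d <- dim(values)
  if (is.null(d) || length(d) < 2L)
    stop("expected a matrix or array with animals on dimension 1",
         call. = FALSE)
  if (d[1L] < 3L)
    stop("at least 3 animals are required", call. = FALSE)
  m <- matrix(values, nrow = d[1L])
  mu <- colMeans(m, na.rm = TRUE)
  sigma <- apply(m, 2L, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sigma) | sigma == 0
  n_all_na <- colSums(!is.na(m)) == 0L
  if (any(bad & !n_all_na))
    warning(sprintf("%d voxel(s) with zero spread masked in z-score map",
                    sum(bad & !n_all_na)), call. = FALSE)
  sigma[bad] <- NA_real_
  z <- sweep(sweep(m, 2L, mu, "-"), 2L, sigma, "/")
  vox_dim <- if (length(d) == 2L) d[2L] else d[-1L]
  structure(list(mu = array(mu, vox_dim), sigma = array(sigma, vox_dim),
                 z = array(z, d)),
            class = "zscore_map")
}

# Bilinear interpolation of `map` at (possibly fractional) row/col indices,
# edge-clamped to the source voxel centres.
.bilinear_at <- function(map, u, v) {
  nx <- nrow(map); ny <- ncol(map)
  u <- pmin(pmax(u, 1), nx)
  v <- pmin(pmax(v, 1), ny)
  i0 <- pmin(floor(u), nx - 1L); j0 <- pmin(floor(v), ny - 1L)
  du <- u - i0; dv <- v - j0
  g <- expand.grid(a = seq_along(u), b = seq_along(v))
  i0g <- i0[g$a]; j0g <- j0[g$b]; dug <- du[g$a]; dvg <- dv[g$b]
  val <- map[cbind(i0g, j0g)] * (1 - dug) * (1 - dvg) +
    map[cbind(i0g + 1L, j0g)] * dug * (1 - dvg) +
    map[cbind(i0g, j0g + 1L)] * (1 - dug) * dvg +
    map[cbind(i0g + 1L, j0g + 1L)] * dug * dvg
  matrix(val, nrow = length(u))
}

#' Render a voxel map at anatomical resolution
#'
#' Bilinear interpolation of a coarse metabolic map (for example the 16x16
#' lactate/pyruvate grid) onto a fine display grid such as 256x256. The fine
#' grid spans the source voxel centres ("align corners"), so every source
#' voxel-centre value is preserved exactly and values never extrapolate
#' beyond the source hull (edge clamping).
#'
#' @param voxel_map numeric matrix.
#' @param target_shape integer vector of length 2, each at least the source
#'   dimension.
#' @return Interpolated numeric matrix of dimension `target_shape`.
#' @export
render_heatmap <- function(voxel_map, target_shape = c(256L, 256L)) {
  if (!is.matrix(voxel_map)) stop("`voxel_map` must be a matrix",
                                  call. = FALSE)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 2L || any(target_shape < dim(voxel_map)))
    stop("target dimensions must be at least the source dimensions",
         call. = FALSE)
  nx <- nrow(voxel_map); ny <- ncol(voxel_map)
  u <- if (target_shape[1L] == 1L) 1 else
    seq(1, nx, length.out = target_shape[1L])
  v <- if (target_shape[2L] == 1L) 1 else
    seq(1, ny, length.out = target_shape[2L])
  .bilinear_at(voxel_map, u, v)
}

#' Run the quantification chain on one dynamic CSI dataset
#'
#' The standard per-animal analysis: spatial zero-filling (factor 2 by
#' default), Fourier reconstruction, per-voxel time-summed spectra,
#' three-peak Lorentzian fitting, AUCs, the lactate/pyruvate ratio,
#' urea normalization to the vascular reference, and ROI averages.
#'
#' Voxels are fitted inside the union of the (upsampled) brain and
#' vascular masks by default (`fit_scope = "masked"`); `"all"` fits every
#' voxel. A voxel's ratio is kept only when the fit converged, its
#' pyruvate AUC exceeds `reliability_factor` times its standard error, and
#' neither the pyruvate nor the lactate line saturated a centre/width
#' bound (a saturated width turns a noise-level peak into an arbitrarily
#' large analytic AUC; such voxels are flagged and excluded downstream).
#'
#' @param dataset a [generate_dynamic_csi()] object (or any `dynamic_csi`).
#' @param masks optional list with logical `brain`, `roi`, `vascular`
#'   matrices on the acquisition grid; defaults to the dataset's phantom
#'   masks.
#' @param zero_fill spatial zero-fill factor (1 disables).
#' @param apodization_hz exponential line broadening before the spectral
#'   DFT (Hz).
#' @param mode spectral combination mode, see [voxel_summed_spectrum()]
#'   (`"complex"` is not supported here).
#' @param reliability_factor multiple of the pyruvate AUC standard error a
#'   voxel must exceed to be considered reliable.
#' @param fit_scope `"masked"` or `"all"`.
#' @return An object of class `csi_analysis`: list with `voxels` (long
#'   data.frame), `maps` (list of matrices: `auc_pyr`, `auc_lac`,
#'   `auc_urea`, `lacpyr`, `nurea`), `masks` (upsampled), `roi_lacpyr`,
#'   `roi_nurea`, `urea_reference`, and the processing options.
#' @export
analyze_csi <- function(dataset, masks = NULL, zero_fill = 2L,
                        apodization_hz = 0,
                        mode = c("phased", "magnitude"),
                        reliability_factor = 5, fit_scope = c("masked", "all")) {
  stopifnot(inherits(dataset, "dynamic_csi"))
  mode <- match.arg(mode)
  fit_scope <- match.arg(fit_scope)
  acq <- dataset$acq
  if (is.null(masks))
    masks <- list(brain = dataset$phantom$brain_mask,
                  roi = dataset$phantom$roi_mask,
                  vascular = dataset$phantom$vascular_mask)

  k <- dataset$kspace
  if (zero_fill > 1L) k <- zero_fill_kspace(k, zero_fill)
  img <- reconstruct_voxels(k)
  ng <- dim(img)[1L]
  up <- ng / dataset$phantom$matrix_size
  brain <- .upsample_mask(masks$brain, up)
  roi <- .upsample_mask(masks$roi, up)
  vascular <- .upsample_mask(masks$vascular, up)

  todo <- if (fit_scope == "masked") which(brain | vascular) else
    seq_len(ng * ng)

  maps <- list(auc_pyr = matrix(NA_real_, ng, ng),
               auc_lac = matrix(NA_real_, ng, ng),
               auc_urea = matrix(NA_real_, ng, ng),
               lacpyr = matrix(NA_real_, ng, ng),
               nurea = matrix(NA_real_, ng, ng))
  rows <- vector("list", length(todo))
  se_pyr <- matrix(NA_real_, ng, ng)
  conv <- matrix(FALSE, ng, ng)
  flagged <- matrix(FALSE, ng, ng)

  for (t in seq_along(todo)) {
    idx <- todo[t]
    ij <- arrayInd(idx, c(ng, ng))
    i <- ij[1L]; j <- ij[2L]
    spec <- voxel_summed_spectrum(img[i, j, , , drop = TRUE], acq,
                                  apodization_hz = apodization_hz,
                                  mode = mode)
    fit <- suppressWarnings(fit_three_peaks(spec, dataset$resonances, acq))
    pk <- fit$peaks
    get <- function(nm, col) pk[pk$name == nm, col]
    maps$auc_pyr[i, j] <- get("pyruvate", "auc")
    maps$auc_lac[i, j] <- get("lactate", "auc")
    maps$auc_urea[i, j] <- get("urea", "auc")
    se_pyr[i, j] <- get("pyruvate", "auc_se")
    conv[i, j] <- fit$converged
    flagged[i, j] <- get("pyruvate", "shape_at_bound") ||
      get("lactate", "shape_at_bound")
    rows[[t]] <- data.frame(
      row = i, col = j,
      auc_pyr = maps$auc_pyr[i, j], auc_lac = maps$auc_lac[i, j],
      auc_urea = maps$auc_urea[i, j],
      auc_pyr_se = se_pyr[i, j],
      auc_lac_se = get("lactate", "auc_se"),
      auc_urea_se = get("urea", "auc_se"),
      converged = fit$converged, flagged = flagged[i, j],
      in_brain = brain[i, j], in_roi = roi[i, j],
      in_vascular = vascular[i, j])
  }
  voxels <- do.call(rbind, rows)

  pyr_floor <- reliability_factor * ifelse(is.finite(se_pyr), se_pyr, Inf)
  reliable <- conv & !flagged & is.finite(maps$auc_pyr) &
    maps$auc_pyr > pyr_floor
  maps$lacpyr <- ifelse(reliable, maps$auc_lac / maps$auc_pyr, NA_real_)

  ref_vals <- maps$auc_urea[vascular & conv]
  ref_vals <- ref_vals[is.finite(ref_vals)]
  maps$nurea <- matrix(normalize_urea(as.vector(maps$auc_urea), ref_vals),
                       ng, ng)

  voxels$reliable <- reliable[cbind(voxels$row, voxels$col)]
  voxels$lacpyr <- maps$lacpyr[cbind(voxels$row, voxels$col)]
  voxels$nurea <- maps$nurea[cbind(voxels$row, voxels$col)]

  structure(list(
    voxels = voxels, maps = maps,
    masks = list(brain = brain, roi = roi, vascular = vascular),
    roi_lacpyr = roi_mean(maps$lacpyr, roi),
    roi_nurea = roi_mean(maps$nurea, roi),
    urea_reference = mean(ref_vals),
    options = list(zero_fill = zero_fill, apodization_hz = apodization_hz,
                   mode = mode, reliability_factor = reliability_factor,
                   fit_scope = fit_scope)),
    class = "csi_analysis")
}
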