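#' Acquisition parameters for dynamic 2D 13C chemical-shift imaging
#'
#' Collects the fixed acquisition constants of a dynamic two-dimensional CSI
#' experiment on a high-field small-animal system: the spatial phase-encode
#' matrix and field of view, the spectral bandwidth and resolution, the
#' repetition time and excitation flip angle, and the dynamic frame timing.
#' The defaults describe a 14.1 T protocol with an 8x8 matrix over a
#' 24x24 mm^2 field of view (5 mm slice), 2500 Hz spectral width over 128
#' complex points, TR 60 ms, 10 degree flip angle, and one frame every 4 s
#' for one minute (15 frames).
#'
#' The carbon centre frequency is derived as `gamma_13c_mhz_per_t * B0`
#' (about 150.99 MHz at 14.1 T), so 1 ppm corresponds to about 151 Hz and the
#' 21 ppm span of the urea/pyruvate/lactate resonances does not fit inside
#' the 2500 Hz window: resonances outside the window alias back in (see
#' [ppm_to_offset_hz()]).
#'
#' @param B0 static field strength (T).
#' @param gamma_13c_mhz_per_t gyromagnetic ratio of 13C (MHz/T).
#' @param spectral_width spectral bandwidth (Hz).
#' @param n_spectral_points number of complex points per free induction decay
#'   (even).
#' @param TR repetition time between successive excitations (s).
#' @param flip_angle_deg excitation flip angle (degrees, in `[0, 90)`).
#' @param matrix_size spatial phase-encode matrix size (square, even, >= 2).
#' @param fov_mm in-plane field of view (mm).
#' @param slice_thickness_mm slice thickness (mm).
#' @param frame_interval time between dynamic frames (s).
#' @param n_frames number of dynamic frames.
#' @param carrier_ppm spectral carrier position (ppm). The default 173 ppm
#'   sits between pyruvate (171 ppm) and lactate (183.5 ppm).
#'
#' @return An object of class `acq_params`: a list with the above fields plus
#'   the derived `carbon_frequency_mhz`.
#' @seealso [rf_depletion_rate()], [resonance_table()], [ppm_to_offset_hz()]
#' @export
#' @examples
#' acq <- acq_params()
#' acq$carbon_frequency_mhz
acq_params <- function(B0 = 14.1,
                       gamma_13c_mhz_per_t = 10.7084,
                       spectral_width = 2500,
                       n_spectral_points = 128L,
                       TR = 0.06,
                       flip_angle_deg = 10,
                       matrix_size = 8L,
                       fov_mm = 24,
                       slice_thickness_mm = 5,
                       frame_interval = 4,
                       n_frames = 15L,
                       carrier_ppm = 173) {
  .check_scalar(B0, "B0", 0, strict = TRUE)
  .check_scalar(gamma_13c_mhz_per_t, "gamma_13c_mhz_per_t", 0, strict = TRUE)
  .check_scalar(spectral_width, "spectral_width", 0, strict = TRUE)
  .check_scalar(TR, "TR", 0, strict = TRUE)
  .check_scalar(flip_angle_deg, "flip_angle_deg", 0)
  if (flip_angle_deg >= 90)
    stop("`flip_angle_deg` must be below 90", call. = FALSE)
  .check_scalar(frame_interval, "frame_interval", 0, strict = TRUE)
  n_spectral_points <- as.integer(n_spectral_points)
  matrix_size <- as.integer(matrix_size)
  n_frames <- as.integer(n_frames)
  if (n_spectral_points < 8L || n_spectral_points %% 2L != 0L)
    stop("`n_spectral_points` must be an even integer >= 8", call. = FALSE)
  if (matrix_size < 2L || matrix_size %% 2L != 0L)
    stop("`matrix_size` must be an even integer >= 2", call. = FALSE)
  if (n_frames < 1L) stop("`n_frames` must be >= 1", call. = FALSE)
  structure(list(
    B0 = B0,
    carbon_frequency_mhz = gamma_13c_mhz_per_t * B0,
    spectral_width = spectral_width,
    n_spectral_points = n_spectral_points,
    TR = TR,
    flip_angle_deg = flip_angle_deg,
    matrix_size = matrix_size,
    fov_mm = fov_mm,
    slice_thickness_mm = slice_thickness_mm,
    frame_interval = frame_interval,
    n_frames = n_frames,
    carrier_ppm = carrier_ppm
  ), class = "acq_params")
}

#' Continuous-equivalent RF depletion rate
#'
#' Repeated excitation at flip angle theta every TR destroys longitudinal
#' magnetization by a factor cos(theta) per shot. With 64 phase encodes per
#' 4 s frame the excitations are nearly continuous, so the loss is modeled as
#' a first-order rate `-log(cos(theta)) / TR` entering the relaxation terms
#' of the kinetic model.
#'
#' @param acq an [acq_params()] object.
#' @return RF depletion rate (1/s).
#' @export
#' @examples
#' rf_depletion_rate(acq_params()) # about 0.255 1/s
rf_depletion_rate <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  -log(cos(acq$flip_angle_deg * pi / 180)) / acq$TR
}

#' Resonance table for the three hyperpolarized species
#'
#' Chemical shifts and linewidths of the resonances observed after
#' co-injection of hyperpolarized \[1-13C\]pyruvate and \[13C\]urea:
#' urea at 162.5 ppm, pyruvate at 171 ppm and lactate at 183.5 ppm, each
#' with a default 20 Hz full width at half maximum.
#'
#' @param name metabolite names.
#' @param ppm chemical shifts (ppm); must be distinct.
#' @param fwhm_hz T2*-linewidths (full width at half maximum, Hz); recycled.
#' @return A `data.frame` of class `resonance_table` with columns `name`,
#'   `ppm`, `fwhm_hz`.
#' @export
#' @examples
#' resonance_table()
resonance_table <- function(name = c("urea", "pyruvate", "lactate"),
                            ppm = c(162.5, 171, 183.5),
                            fwhm_hz = 20) {
  if (length(name) != length(ppm))
    stop("`name` and `ppm` must have the same length", call. = FALSE)
  if (anyDuplicated(ppm))
    stop("chemical shifts must be distinct", call. = FALSE)
  if (any(!is.finite(ppm)) || any(!is.finite(fwhm_hz)) || any(fwhm_hz <= 0))
    stop("shifts must be finite and linewidths positive", call. = FALSE)
  out <- data.frame(name = as.character(name), ppm = as.numeric(ppm),
                    fwhm_hz = rep_len(as.numeric(fwhm_hz), length(ppm)),
                    stringsAsFactors = FALSE)
  class(out) <- c("resonance_table", "data.frame")
  out
}

#' Apparent spectral offset of a chemical shift, with aliasing
#'
#' Converts a chemical shift to its offset from the carrier in Hz and folds
#' it into the acquisition window `[-SW/2, SW/2)` (wrap-around aliasing).
#' At 14.1 T the three resonances span about 21 ppm (> 3100 Hz), which does
#' not fit into the 2500 Hz window, so the urea and lactate resonances appear
#' at aliased positions; downstream peak fitting uses these apparent offsets.
#'
#' @param ppm chemical shift(s) in ppm.
#' @param acq an [acq_params()] object.
#' @return Apparent offset(s) from the carrier, in Hz.
#' @export
#' @examples
#' acq <- acq_params()
#' ppm_to_offset_hz(acq$carrier_ppm, acq) # 0
#' ppm_to_offset_hz(183.5, acq)           # lactate aliases to about -915 Hz
ppm_to_offset_hz <- function(ppm, acq) {
  stopifnot(inherits(acq, "acq_params"))
  offset <- (ppm - acq$carrier_ppm) * acq$carbon_frequency_mhz
  sw <- acq$spectral_width
  ((offset + sw / 2) %% sw) - sw / 2
}

#' Frequency axis of the reconstructed spectrum
#'
#' Ascending frequency axis matching the layout returned by
#' [voxel_summed_spectrum()]: `n_spectral_points` bins from `-SW/2` to
#' `SW/2 - SW/n`, with DC at index `n/2 + 1`.
#'
#' @param acq an [acq_params()] object.
#' @return Numeric vector of bin frequencies (Hz).
#' @export
spectrum_frequencies <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  n <- acq$n_spectral_points
  (seq_len(n) - 1L - n / 2L) * acq$spectral_width / n
}
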