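#' Persist a dynamic CSI dataset as plain text
#'
#' Writes a [generate_dynamic_csi()] object to a directory of portable
#' text files: `kspace.csv` (long format: `kx, ky, point, frame, re, im`),
#' `masks.csv` (long format of the three phantom masks), and `meta.json`
#' (acquisition parameters, resonances, noise level, seed and the
#' ground-truth brain/vascular kinetics summary).
#'
#' @param dataset a `dynamic_csi` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_csi_dataset()]
#' @export
write_csi_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "dynamic_csi"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- dataset$kspace
  d <- dim(k)
  grid <- expand.grid(kx = seq_len(d[1L]), ky = seq_len(d[2L]),
                      point = seq_len(d[3L]), frame = seq_len(d[4L]))
  grid$re <- as.vector(Re(k))
  grid$im <- as.vector(Im(k))
  utils::write.csv(grid, file.path(dir, "kspace.csv"), row.names = FALSE)

  ph <- dataset$phantom
  m <- expand.grid(row = seq_len(ph$matrix_size),
                   col = seq_len(ph$matrix_size))
  m$brain <- as.vector(ph$brain_mask)
  m$roi <- as.vector(ph$roi_mask)
  m$vascular <- as.vector(ph$vascular_mask)
  utils::write.csv(m, file.path(dir, "masks.csv"), row.names = FALSE)

  kpl_map <- matrix(vapply(ph$kinetics, `[[`, numeric(1), "kPL"),
                    ph$matrix_size, ph$matrix_size)
  meta <- list(acq = unclass(dataset$acq),
               resonances = as.data.frame(dataset$resonances),
               noise_sigma = dataset$noise_sigma,
               seed = dataset$seed,
               frame_times = dataset$frame_times,
               kpl_map = kpl_map)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a dynamic CSI dataset written by [write_csi_dataset()]
#'
#' Restores the k-space hypercube, the acquisition parameters, the masks
#' and the per-voxel ground-truth kPL map. The returned object analyzes
#' identically to the original (the phantom's full kinetic objects are not
#' round-tripped; its masks and kPL map are).
#'
#' @param dir directory written by [write_csi_dataset()].
#' @return A `dynamic_csi` object (with `kpl_map` replacing the full
#'   per-voxel kinetics in the phantom slot).
#' @export
read_csi_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  acq <- do.call(acq_params, c(
    meta$acq[c("B0", "spectral_width", "n_spectral_points", "TR",
               "matrix_size", "fov_mm", "slice_thickness_mm",
               "frame_interval", "n_frames", "carrier_ppm")],
    list(flip_angle_deg = meta$acq$flip_angle_deg,
         gamma_13c_mhz_per_t =
           meta$acq$carbon_frequency_mhz / meta$acq$B0)))
  res <- resonance_table(meta$resonances$name, meta$resonances$ppm,
                         meta$resonances$fwhm_hz)
  kcsv <- utils::read.csv(file.path(dir, "kspace.csv"))
  d <- c(max(kcsv$kx), max(kcsv$ky), max(kcsv$point), max(kcsv$frame))
  ord <- order(kcsv$frame, kcsv$point, kcsv$ky, kcsv$kx)
  k <- array(complex(real = kcsv$re[ord], imaginary = kcsv$im[ord]), dim = d)

  mcsv <- utils::read.csv(file.path(dir, "masks.csv"))
  n <- max(mcsv$row)
  ordm <- order(mcsv$col, mcsv$row)
  tomat <- function(v) matrix(v[ordm], n, n)
  phantom <- structure(list(
    kinetics = NULL,
    kpl_map = matrix(unlist(meta$kpl_map), n, n),
    brain_mask = tomat(mcsv$brain),
    roi_mask = tomat(mcsv$roi),
    vascular_mask = tomat(mcsv$vascular),
    matrix_size = n), class = "phantom_grid")

  structure(list(kspace = k, acq = acq, phantom = phantom,
                 resonances = res, noise_sigma = meta$noise_sigma,
                 seed = meta$seed, frame_times = meta$frame_times),
            class = "dynamic_csi")
}

#' Serialize a study specification to YAML
#'
#' @param study a [study_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_study_spec <- function(study, path) {
  stopifnot(inherits(study, "study_spec"))
  ser <- list(master_seed = study$master_seed,
              csi_noise_sigma = study$csi_noise_sigma,
              acq = unclass(study$acq),
              groups = lapply(study$groups, unclass))
  yaml::write_yaml(ser, path, precision = 17L)  # lossless doubles
  invisible(path)
}

#' Read a study specification written by [write_study_spec()]
#'
#' @param path YAML file.
#' @return A `study_spec` (with the default phantom template).
#' @export
read_study_spec <- function(path) {
  ser <- yaml::read_yaml(path)
  acq <- do.call(acq_params, c(
    ser$acq[c("B0", "spectral_width", "n_spectral_points", "TR",
              "matrix_size", "fov_mm", "slice_thickness_mm",
              "frame_interval", "n_frames", "carrier_ppm")],
    list(flip_angle_deg = ser$acq$flip_angle_deg,
         gamma_13c_mhz_per_t = ser$acq$carbon_frequency_mhz / ser$acq$B0)))
  groups <- lapply(ser$groups, function(g) {
    g$eae$cutpoints <- as.numeric(unlist(g$eae$cutpoints))
    do.call(group_spec, g)
  })
  study_spec(groups, acq = acq, master_seed = ser$master_seed,
             csi_noise_sigma = ser$csi_noise_sigma)
}
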