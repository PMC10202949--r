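#' Specification of one experimental group
#'
#' All animals of a group share a latent Gaussian "inflammation burden"
#' distribution `b ~ N(burden_mean, burden_sd)` and a set of link
#' coefficients mapping `b` to the observable quantities:
#' log-kPL (`kPL = kpl_base * exp(kpl_log_slope * b)`), urea delivery,
#' an ordered-categorical clinical (EAE) score, a T1 lesion enhancing
#' volume, and each ex vivo marker via a linear link
#' `value = marker_mean + slope * (b - burden_mean) + N(0, sd)` truncated at
#' zero. Because every quantity is driven by the same latent variable, the
#' generated cohort carries the correlated-marker structure that the
#' association analysis expects.
#'
#' @param name group name.
#' @param n_animals number of animals (>= 1).
#' @param burden_mean,burden_sd latent burden distribution.
#' @param kpl_base conversion rate at `b = 0` (1/s).
#' @param kpl_log_slope log-linear link of `kPL` on `b`.
#' @param urea_amp_base,urea_log_slope urea delivery link (log-linear).
#' @param eae list with `latent_base`, `latent_slope`, `latent_sd`,
#'   `cutpoints` (ordinal thresholds) and `euthanasia_score`.
#' @param markers named list; each element a list with `mean`, `slope`,
#'   `sd` (>= 0) and optional `direction` (`"increase"`, `"decrease"`,
#'   `"none"`; checked against the sign of `slope`).
#' @param t1 list with `mean`, `slope`, `sd` for the enhancing volume
#'   (mm^3), plus `lesion_fraction` and `image_noise_sigma`.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, n_animals,
                       burden_mean = 0, burden_sd = 0.3,
                       kpl_base = 0.02, kpl_log_slope = 1,
                       urea_amp_base = 1, urea_log_slope = 0,
                       eae = list(latent_base = -3, latent_slope = 1,
                                  latent_sd = 0.8,
                                  cutpoints = seq(0.5, 5.5, by = 1),
                                  euthanasia_score = 4),
                       markers = list(),
                       t1 = list(mean = 0.3, slope = 0, sd = 0.06,
                                 lesion_fraction = 0.5,
                                 image_noise_sigma = 0.02)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_animals <- as.integer(n_animals)
  if (n_animals < 1L) stop("`n_animals` must be >= 1", call. = FALSE)
  .check_scalar(burden_sd, "burden_sd", 0)
  .check_scalar(kpl_base, "kpl_base", 0)
  .check_scalar(urea_amp_base, "urea_amp_base", 0)
  .check_scalar(eae$latent_sd, "eae$latent_sd", 0)
  .check_scalar(t1$mean, "t1$mean", 0)
  .check_scalar(t1$sd, "t1$sd", 0)
  for (nm in names(markers)) {
    mk <- markers[[nm]]
    .check_scalar(mk$mean, paste0("markers$", nm, "$mean"), 0)
    .check_scalar(mk$sd, paste0("markers$", nm, "$sd"), 0)
    dir <- mk$direction
    if (!is.null(dir) && dir == "increase" && mk$slope < 0)
      stop(sprintf("marker '%s' declared increasing but slope < 0", nm),
           call. = FALSE)
    if (!is.null(dir) && dir == "decrease" && mk$slope > 0)
      stop(sprintf("marker '%s' declared decreasing but slope > 0", nm),
           call. = FALSE)
  }
  structure(list(name = name, n_animals = n_animals,
                 burden_mean = burden_mean, burden_sd = burden_sd,
                 kpl_base = kpl_base, kpl_log_slope = kpl_log_slope,
                 urea_amp_base = urea_amp_base,
                 urea_log_slope = urea_log_slope,
                 eae = eae, markers = markers, t1 = t1),
            class = "group_spec")
}

#' Specification of a whole synthetic study
#'
#' @param groups list of [group_spec()] objects with unique names.
#' @param acq an [acq_params()] object shared by all animals.
#' @param phantom_template a [make_phantom()] used as the per-animal
#'   template (brain kinetics are overridden per animal).
#' @param master_seed integer seed from which all per-animal seeds derive.
#' @param csi_noise_sigma k-space noise handed to the CSI simulator.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(groups, acq = acq_params(),
                       phantom_template = make_phantom(),
                       master_seed = 1L, csi_noise_sigma = 5e-4) {
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "group_spec")))
  nms <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("group names must be unique", call. = FALSE)
  .check_scalar(csi_noise_sigma, "csi_noise_sigma", 0)
  structure(list(groups = groups, acq = acq,
                 phantom_template = phantom_template,
                 master_seed = as.integer(master_seed),
                 csi_noise_sigma = csi_noise_sigma),
            class = "study_spec")
}

#' Draw one synthetic animal from a group specification
#'
#' Draws the latent burden, derives the voxelwise kinetics (brain voxels get
#' the burden-scaled `kPL` and urea delivery, vascular-reference voxels keep
#' the template kinetics), the ordinal clinical score (with the
#' euthanasia-at-4 censoring rule), the T1 enhancing-volume target and the
#' ex vivo markers. Fully reproducible from `seed`.
#'
#' @param spec a [group_spec()].
#' @param acq an [acq_params()] object.
#' @param phantom_template a [make_phantom()] template.
#' @param seed integer RNG seed.
#' @return An object of class `animal_record`: list with `group`, `burden`,
#'   `kpl`, `urea_amp`, `eae_score`, `censored`, `t1_volume_mm3` (designed
#'   target), `markers` (named numeric), `phantom`, and the seeds used
#'   downstream (`seed`, `csi_seed`, `t1_seed`).
#' @export
sample_animal <- function(spec, acq = acq_params(),
                          phantom_template = make_phantom(), seed = 1L) {
  stopifnot(inherits(spec, "group_spec"),
            inherits(phantom_template, "phantom_grid"))
  set.seed(seed)
  b <- stats::rnorm(1, spec$burden_mean, spec$burden_sd)

  kpl <- spec$kpl_base * exp(spec$kpl_log_slope * b)
  urea_amp <- spec$urea_amp_base * exp(spec$urea_log_slope * b)
  phantom <- set_brain_kinetics(phantom_template, kpl = kpl,
                                urea_amp = urea_amp)

  eae <- spec$eae
  latent <- eae$latent_base + eae$latent_slope * b +
    stats::rnorm(1, 0, eae$latent_sd)
  cut <- eae$cutpoints
  score <- findInterval(latent, cut)
  score <- max(0L, min(score, length(cut)))
  censored <- FALSE
  if (!is.null(eae$euthanasia_score) && score >= eae$euthanasia_score) {
    censored <- score >= eae$euthanasia_score
    score <- eae$euthanasia_score
  }

  t1_vol <- max(0, spec$t1$mean + spec$t1$slope * (b - spec$burden_mean) +
                  stats::rnorm(1, 0, spec$t1$sd))

  markers <- vapply(spec$markers, function(mk) {
    max(0, mk$mean + mk$slope * (b - spec$burden_mean) +
          stats::rnorm(1, 0, mk$sd))
  }, numeric(1))

  structure(list(group = spec$name, burden = b, kpl = kpl,
                 urea_amp = urea_amp,
                 eae_score = as.integer(score), censored = censored,
                 t1_volume_mm3 = t1_vol, markers = markers,
                 phantom = phantom, seed = seed,
                 csi_seed = .derive_seed(seed, 1L),
                 t1_seed = .derive_seed(seed, 2L)),
            class = "animal_record")
}

#' Generate a full synthetic study
#'
#' Samples every animal of every group with deterministic per-animal seeds
#' derived from the master seed, and assembles the ground-truth table.
#' Imaging data are not materialized here (they can be large); the records
#' carry the phantoms and seeds from which [run_study()] (or
#' [generate_dynamic_csi()] directly) reproduces them bit-identically.
#'
#' @param study a [study_spec()].
#' @return An object of class `synthetic_study`: list with `spec`,
#'   `records` (list of [sample_animal()] results with `animal_id` set) and
#'   `truth` (one row per animal: group, burden, kPL, EAE score, censoring,
#'   designed T1 volume, markers).
#' @export
#' @examples
#' st <- generate_study(study_spec(list(
#'   group_spec("a", 2), group_spec("b", 2)), master_seed = 7))
#' st$truth$kpl
generate_study <- function(study) {
  stopifnot(inherits(study, "study_spec"))
  records <- list()
  idx <- 0L
  for (g in study$groups) {
    for (i in seq_len(g$n_animals)) {
      idx <- idx + 1L
      seed_i <- .derive_seed(study$master_seed, idx * 13L)
      rec <- sample_animal(g, study$acq, study$phantom_template, seed_i)
      rec$animal_id <- sprintf("%s_%02d", g$name, i)
      records[[idx]] <- rec
    }
  }
  truth <- do.call(rbind, lapply(records, function(r) {
    data.frame(animal_id = r$animal_id, group = r$group, burden = r$burden,
               kpl = r$kpl, urea_amp = r$urea_amp,
               eae_score = r$eae_score, censored = r$censored,
               t1_volume_design_mm3 = r$t1_volume_mm3,
               t(r$markers), stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  structure(list(spec = study, records = records, truth = truth),
            class = "synthetic_study")
}

#' Calibrated four-group treatment-response study preset
#'
#' Builds a [study_spec()] whose designed group contrasts reproduce the
#' fold changes of a treatment-response study in an inflammatory
#' demyelination mouse model: lactate/pyruvate 2.1-fold higher in untreated
#' disease than control with 1.31- and 1.35-fold decreases under the two
#' therapies; matching designed means for the clinical score, the T1
#' enhancing volume, and nine ex vivo markers; and a urea (perfusion)
#' readout designed to be null. All tuned constants live in the packaged
#' YAML configuration (`system.file("extdata", "cpz_eae_preset.yaml")`).
#'
#' Group burden means are derived from the designed lactate/pyruvate folds
#' through the log-linear kPL link, so the expected control lactate/pyruvate
#' ratio equals [auc_ratio_theory()] at the control median kPL. Marker and
#' T1-volume links are linear in the burden with per-group intercepts that
#' hit the designed means exactly and slopes proportional to the group mean
#' (sign from the marker's declared direction), which keeps the
#' within-group coefficient of variation uniform and the zero-truncation
#' negligible even for near-zero control means.
#'
#' @param n_animals optional integer vector of group sizes overriding the
#'   configured ones (order: control, disease, disease+DMF,
#'   disease+FTY720).
#' @param master_seed master seed of the study.
#' @param config path to the preset YAML (defaults to the packaged file).
#' @return A `study_spec` with attribute `design`: list with the group
#'   names, designed per-endpoint group means, and designed
#'   lactate/pyruvate folds.
#' @export
#' @examples
#' preset <- cpz_eae_preset()
#' attr(preset, "design")$lacpyr_fold["cpz_eae_vs_control"]
cpz_eae_preset <- function(n_animals = NULL, master_seed = 20260101L,
                           config = system.file("extdata",
                                                "cpz_eae_preset.yaml",
                                                package = "hpcsi")) {
  cfg <- yaml::read_yaml(config)
  gnames <- cfg$groups
  if (is.null(n_animals)) n_animals <- as.integer(cfg$n_animals)
  stopifnot(length(n_animals) == length(gnames))

  kin <- cfg$kinetics
  fold_d <- kin$lacpyr_fold_disease_vs_control
  mu <- c(0,
          log(fold_d),
          log(fold_d / kin$lacpyr_fold_decrease_dmf),
          log(fold_d / kin$lacpyr_fold_decrease_fty720)) / kin$slope_log_kpl
  names(mu) <- gnames
  sigma <- cfg$latent$sigma
  # per-unit-burden slope giving a within-group burden-driven CV of
  # burden_cv around the group mean
  slope_unit <- cfg$latent$burden_cv / sigma
  dir_sign <- function(direction)
    switch(direction, increase = 1, decrease = -1, none = 0)

  acq <- acq_params()
  lam <- rf_depletion_rate(acq)
  r1_lac <- voxel_kinetics()$R1_lac
  design <- list(
    groups = gnames,
    burden_mean = mu,
    lacpyr = kin$kpl_base * exp(kin$slope_log_kpl * mu +
                                  (kin$slope_log_kpl * sigma)^2 / 2) /
      (r1_lac + lam),
    lacpyr_fold = c(
      cpz_eae_vs_control = fold_d,
      cpz_eae_vs_dmf = kin$lacpyr_fold_decrease_dmf,
      cpz_eae_vs_fty720 = kin$lacpyr_fold_decrease_fty720),
    control_median_kpl = kin$kpl_base,
    markers = lapply(cfg$markers, function(mk)
      stats::setNames(as.numeric(mk$means), gnames)),
    t1_volume = stats::setNames(as.numeric(cfg$t1_enhancement$means),
                                gnames),
    eae_score = stats::setNames(as.numeric(cfg$eae$target_score), gnames))

  groups <- vector("list", length(gnames))
  for (gi in seq_along(gnames)) {
    markers <- lapply(names(cfg$markers), function(nm) {
      mk <- cfg$markers[[nm]]
      mean_g <- mk$means[[gi]]
      list(mean = mean_g,
           slope = dir_sign(mk$direction) * slope_unit * mean_g,
           sd = mk$cv * mean_g,
           direction = mk$direction)
    })
    names(markers) <- names(cfg$markers)

    target_score <- cfg$eae$target_score[[gi]]
    latent_base <- if (target_score < 0.25) cfg$eae$floor_latent else
      target_score - cfg$eae$latent_slope * mu[gi]
    t1cfg <- cfg$t1_enhancement
    mean_t1 <- t1cfg$means[[gi]]

    groups[[gi]] <- group_spec(
      name = gnames[gi], n_animals = n_animals[gi],
      burden_mean = unname(mu[gi]), burden_sd = sigma,
      kpl_base = kin$kpl_base, kpl_log_slope = kin$slope_log_kpl,
      urea_amp_base = kin$urea_amp_base,
      urea_log_slope = kin$urea_log_slope,
      eae = list(latent_base = latent_base,
                 latent_slope = cfg$eae$latent_slope,
                 latent_sd = cfg$eae$latent_sd,
                 cutpoints = seq(0.5, 5.5, by = 1),
                 euthanasia_score = cfg$eae$euthanasia_score),
      markers = markers,
      t1 = list(mean = mean_t1,
                slope = slope_unit * mean_t1,
                sd = t1cfg$cv * mean_t1,
                lesion_fraction = t1cfg$lesion_fraction,
                image_noise_sigma = t1cfg$image_noise_sigma))
  }

  out <- study_spec(groups, acq = acq, master_seed = master_seed,
                    csi_noise_sigma = cfg$csi$noise_sigma)
  attr(out, "design") <- design
  out
}
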