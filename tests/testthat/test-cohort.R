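acq <- acq_params()

degenerate_spec <- function() {
  group_spec("flat", 3, burden_mean = 0.2, burden_sd = 0,
             eae = list(latent_base = 1.1, latent_slope = 0, latent_sd = 0,
                        cutpoints = seq(0.5, 5.5, 1), euthanasia_score = 4),
             markers = list(m1 = list(mean = 5, slope = 0, sd = 0)),
             t1 = list(mean = 0.4, slope = 0, sd = 0, lesion_fraction = 0.5,
                       image_noise_sigma = 0))
}

test_that("a degenerate specification produces identical animals", {
  a1 <- sample_animal(degenerate_spec(), acq, seed = 1)
  a2 <- sample_animal(degenerate_spec(), acq, seed = 99)
  expect_equal(a1$kpl, a2$kpl)
  expect_equal(a1$markers, a2$markers)
  expect_identical(a1$eae_score, a2$eae_score)
  expect_equal(a1$t1_volume_mm3, a2$t1_volume_mm3)
})

test_that("a floored clinical latent keeps every score at zero", {
  spec <- group_spec("prevented", 1,
                     eae = list(latent_base = -3, latent_slope = 1,
                                latent_sd = 0.8,
                                cutpoints = seq(0.5, 5.5, 1),
                                euthanasia_score = 4))
  scores <- vapply(1:200, function(s)
    sample_animal(spec, acq, seed = s)$eae_score, integer(1))
  expect_true(all(scores == 0L))
})

test_that("euthanasia censoring caps scores at 4", {
  spec <- group_spec("severe", 1,
                     eae = list(latent_base = 5, latent_slope = 1,
                                latent_sd = 1.5,
                                cutpoints = seq(0.5, 5.5, 1),
                                euthanasia_score = 4))
  recs <- lapply(1:150, function(s) sample_animal(spec, acq, seed = s))
  scores <- vapply(recs, `[[`, integer(1), "eae_score")
  cens <- vapply(recs, `[[`, logical(1), "censored")
  expect_true(all(scores <= 4L))
  expect_true(all(scores[cens] == 4L))
  expect_true(any(cens))
})

test_that("latent-burden links reproduce the closed-form correlation", {
  lam <- 1; s <- 0.3; d <- 30; e <- 3
  spec <- group_spec("g", 1, burden_mean = 0.5, burden_sd = s,
                     kpl_log_slope = lam,
                     markers = list(iba1 = list(mean = 40, slope = d,
                                                sd = e)))
  draws <- vapply(1:2000, function(i) {
    a <- sample_animal(spec, acq, seed = 10000 + i)
    c(a$kpl, a$markers[["iba1"]])
  }, numeric(2))
  r_emp <- cor(draws[1, ], draws[2, ])
  r_theory <- corr_lognormal_linear(lam, s, d, e)
  expect_gt(r_emp, 0)
  expect_lt(abs(r_emp - r_theory), 0.05)
})

test_that("study generation respects sizes, seeds and the group means", {
  preset <- cpz_eae_preset()
  st <- generate_study(preset)
  expect_equal(as.integer(table(st$truth$group)[
    c("control", "cpz_eae", "cpz_eae_dmf", "cpz_eae_fty720")]),
    c(14L, 12L, 11L, 14L))
  expect_equal(nrow(st$truth), 51L)
  st2 <- generate_study(preset)
  expect_identical(st$truth, st2$truth)
  expect_error(study_spec(list(group_spec("a", 2), group_spec("a", 2))),
               "unique")
})

test_that("empirical group-mean kPL converges to its design value", {
  design <- attr(cpz_eae_preset(), "design")
  spec <- cpz_eae_preset(n_animals = c(1, 200, 1, 1))$groups[[2]]
  kpls <- vapply(1:200, function(i)
    sample_animal(spec, acq, seed = 3000 + i)$kpl, numeric(1))
  mean_design <- spec$kpl_base *
    exp(spec$kpl_log_slope * spec$burden_mean +
          (spec$kpl_log_slope * spec$burden_sd)^2 / 2)
  se <- sd(kpls) / sqrt(length(kpls))
  expect_lt(abs(mean(kpls) - mean_design), 3 * se)
  expect_equal(design$burden_mean[["cpz_eae"]], log(2.1))
})

test_that("the calibrated preset encodes the designed contrasts", {
  preset <- cpz_eae_preset()
  design <- attr(preset, "design")
  # expected control ratio equals the kinetic identity at the control
  # median conversion rate
  expect_equal(
    auc_ratio_theory(voxel_kinetics(kPL = design$control_median_kpl), acq) *
      exp(design$burden_mean[["control"]]) *
      exp((preset$groups[[1]]$kpl_log_slope *
             preset$groups[[1]]$burden_sd)^2 / 2),
    design$lacpyr[["control"]])
  expect_equal(unname(design$lacpyr[["cpz_eae"]] /
                        design$lacpyr[["control"]]), 2.1)
  # marker sign structure: oxidative enzyme and myelin fall with burden,
  # immune and glial markers rise
  slope_of <- function(nm) preset$groups[[1]]$markers[[nm]]$slope
  expect_lt(slope_of("pdh_activity"), 0)
  expect_lt(slope_of("myelin_area"), 0)
  for (nm in c("iba1_area", "cd68_area", "cd3_count", "pdk1_area",
               "gfap_area", "fibrinogen_area"))
    expect_gt(slope_of(nm), 0)
  expect_equal(slope_of("ldh_activity"), 0)
  # designed group means are monotone the right way
  expect_gt(design$markers$pdh_activity[["control"]],
            design$markers$pdh_activity[["cpz_eae"]])
  expect_gt(design$markers$iba1_area[["cpz_eae"]],
            design$markers$iba1_area[["control"]])
})

test_that("a 2000-animal draw reproduces the designed folds within 2%", {
  preset <- cpz_eae_preset(n_animals = c(500, 500, 500, 500),
                           master_seed = 424242)
  st <- generate_study(preset)
  design <- attr(preset, "design")
  mk <- tapply(st$truth$kpl, st$truth$group, mean)
  fold_dc <- mk[["cpz_eae"]] / mk[["control"]]
  fold_dmf <- mk[["cpz_eae"]] / mk[["cpz_eae_dmf"]]
  fold_fty <- mk[["cpz_eae"]] / mk[["cpz_eae_fty720"]]
  expect_lt(abs(fold_dc / design$lacpyr_fold[["cpz_eae_vs_control"]] - 1),
            0.02)
  expect_lt(abs(fold_dmf / design$lacpyr_fold[["cpz_eae_vs_dmf"]] - 1), 0.02)
  expect_lt(abs(fold_fty / design$lacpyr_fold[["cpz_eae_vs_fty720"]] - 1),
            0.02)
  # designed mean clinical score of the untreated arm
  expect_lt(abs(mean(st$truth$eae_score[st$truth$group == "cpz_eae"]) - 2.6),
            0.15)
})

test_that("declared marker directions are enforced", {
  expect_error(group_spec("bad", 2, markers = list(
    x = list(mean = 1, slope = -2, sd = 0.1, direction = "increase"))),
    "increasing")
  expect_error(group_spec("bad", 2, markers = list(
    x = list(mean = 1, slope = 2, sd = 0.1, direction = "decrease"))),
    "decreasing")
})
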