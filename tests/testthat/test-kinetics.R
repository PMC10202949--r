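acq <- acq_params()

test_that("no conversion pathway means no lactate", {
  curves <- simulate_magnetization(voxel_kinetics(kPL = 0), acq,
                                   t_end = 60, dt = 0.5)
  expect_true(all(curves$Mz_lac == 0))
  expect_gt(max(curves$Mz_pyr), 0)
})

test_that("pyruvate plus lactate is conserved without losses", {
  # zero flip angle, zero relaxation: after the bolus the total pool is flat
  acq0 <- acq_params(flip_angle_deg = 0)
  kin <- voxel_kinetics(kPL = 0.05, R1_pyr = 0, R1_lac = 0, R1_urea = 0)
  curves <- simulate_magnetization(kin, acq0, t_end = 60, dt = 0.25)
  tot <- curves$Mz_pyr + curves$Mz_lac
  after <- tot[curves$time > 12.5]
  expect_lt(max(abs(after - after[1])) / after[1], 1e-6)
})

test_that("adaptive solver matches an independent fixed-step RK4 oracle", {
  kin <- voxel_kinetics(kPL = 0.05, R1_pyr = 1 / 30, R1_lac = 1 / 30)
  curves <- simulate_magnetization(kin, acq, t_end = 60, dt = 0.5)
  oracle <- rk4_two_site(kPL = 0.05, R1_pyr = 1 / 30, R1_lac = 1 / 30,
                         R1_urea = 1 / 20, amp_p = 1, amp_u = 1,
                         t_on = 0, t_off = 12,
                         lambda_rf = rf_depletion_rate(acq),
                         t_end = 60, dt = 0.001)
  idx <- match(curves$time, seq(0, 60, by = 0.001))
  scale <- max(oracle[, "P"])
  expect_lt(max(abs(curves$Mz_pyr - oracle[idx, "P"])) / scale, 1e-4)
  expect_lt(max(abs(curves$Mz_lac - oracle[idx, "L"])) / scale, 1e-4)
  expect_lt(max(abs(curves$Mz_urea - oracle[idx, "U"])) / scale, 1e-4)
})

test_that("closed-form solution agrees with the ODE solver", {
  for (k in c(0, 0.01, 0.08)) {
    kin <- voxel_kinetics(kPL = k)
    tt <- seq(0, 80, by = 0.8)
    ode <- hpcsi:::.magnetization_ode(kin, acq, tt)
    cf <- hpcsi:::.magnetization_closed_form(kin, acq, tt)
    expect_lt(max(abs(ode - cf)) / max(cf), 1e-6)
  }
})

test_that("impulse-like bolus decays as a pure exponential after delivery", {
  acq0 <- acq_params(flip_angle_deg = 0)  # lambda_RF -> 0
  kin <- voxel_kinetics(kPL = 0.04, R1_pyr = 1 / 25, R1_lac = 1 / 30,
                        bolus_duration = 0.01, pyr_delivery_amp = 100)
  curves <- simulate_magnetization(kin, acq0, t_end = 40, dt = 0.1)
  sel <- curves$time >= 1
  expected <- curves$Mz_pyr[curves$time == 1] *
    exp(-(1 / 25 + 0.04) * (curves$time[sel] - 1))
  expect_lt(max(abs(curves$Mz_pyr[sel] - expected)) / max(expected), 1e-5)
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(voxel_kinetics(kPL = -0.1), "kPL")
  expect_error(voxel_kinetics(R1_lac = NaN), "R1_lac")
  expect_error(voxel_kinetics(bolus_duration = 0), "bolus_duration")
  expect_error(voxel_kinetics(pyr_delivery_amp = -1), "pyr_delivery_amp")
})

test_that("AUC-ratio identity: closed form and limiting cases", {
  expect_identical(auc_ratio_theory(voxel_kinetics(kPL = 0), acq), 0)
  # with lambda_RF = 0 and R1_lac = 0.04 the ratio is kPL / 0.04 exactly
  acq0 <- acq_params(flip_angle_deg = 0)
  kin <- voxel_kinetics(kPL = 0.02, R1_lac = 0.04)
  expect_equal(auc_ratio_theory(kin, acq0), 0.5)
  expect_error(
    auc_ratio_theory(voxel_kinetics(kPL = 0.02, kLP = 0.01), acq), "kLP")
})

test_that("AUC-ratio identity matches numerical integrals within 1%", {
  tt <- seq(0, 300, by = 0.01)
  for (k in c(0.005, 0.02, 0.08)) {
    kin <- voxel_kinetics(kPL = k)
    m <- hpcsi:::.magnetization_closed_form(kin, acq, tt)
    num <- sum(m[, "L"]) / sum(m[, "P"])
    expect_lt(abs(num / auc_ratio_theory(kin, acq) - 1), 0.01)
  }
})

test_that("theoretical AUC ratio is strictly increasing in kPL", {
  grid <- seq(0.001, 0.1, length.out = 25)
  vals <- vapply(grid, function(k)
    auc_ratio_theory(voxel_kinetics(kPL = k), acq), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("kPL is recovered without bias from noiseless curves", {
  ft <- frame_midpoints(acq)
  for (k in c(0.005, 0.01, 0.03, 0.05, 0.08)) {
    kin <- voxel_kinetics(kPL = k)
    m <- hpcsi:::.magnetization_closed_form(kin, acq, ft)
    fit <- fit_kpl(m[, "P"], m[, "L"], ft, acq, kin)
    expect_lt(abs(fit$kPL_hat - k), 1e-4)
    expect_true(fit$converged)
  }
})

test_that("all-zero lactate yields a zero rate estimate", {
  ft <- frame_midpoints(acq)
  kin <- voxel_kinetics(kPL = 0)
  m <- hpcsi:::.magnetization_closed_form(kin, acq, ft)
  fit <- fit_kpl(m[, "P"], rep(0, length(ft)), ft, acq, kin)
  expect_identical(fit$kPL_hat, 0)
})

test_that("kPL estimation tolerates frame noise (reduced Monte Carlo)", {
  ft <- frame_midpoints(acq)
  kin <- voxel_kinetics(kPL = 0.03)
  m <- hpcsi:::.magnetization_closed_form(kin, acq, ft)
  # frame SNR 20 on each series (peak / noise SD)
  sig <- c(max(m[, "P"]), max(m[, "L"])) / 20
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    fit <- fit_kpl(m[, "P"] + rnorm(length(ft), 0, sig[1]),
                   m[, "L"] + rnorm(length(ft), 0, sig[2]),
                   ft, acq, kin, noise_sd = sig)
    abs(fit$kPL_hat - 0.03) / 0.03
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("fit_kpl validates its inputs", {
  ft <- frame_midpoints(acq)
  kin <- voxel_kinetics(kPL = 0.03)
  m <- hpcsi:::.magnetization_closed_form(kin, acq, ft)
  expect_error(fit_kpl(m[1:4, "P"], m[1:4, "L"], ft[1:4], acq, kin),
               "5 frames")
  expect_error(fit_kpl(m[, "P"], m[, "L"] * NA, ft, acq, kin), "finite")
  expect_error(fit_kpl(m[, "P"], m[, "L"], ft, acq,
                       voxel_kinetics(kPL = 0.03, kLP = 0.01)),
               "unidirectional")
})
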