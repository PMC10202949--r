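acq <- acq_params()
res <- resonance_table()

test_that("chemical shifts map to apparent offsets with wrap-around", {
  expect_equal(ppm_to_offset_hz(acq$carrier_ppm, acq), 0)
  # lactate sits 10.5 ppm above the carrier: beyond +SW/2, so it aliases
  raw <- 10.5 * acq$carbon_frequency_mhz
  expect_gt(raw, acq$spectral_width / 2)
  expect_equal(ppm_to_offset_hz(183.5, acq), raw - acq$spectral_width)
  # shifts one full bandwidth apart are indistinguishable
  sw_ppm <- acq$spectral_width / acq$carbon_frequency_mhz
  expect_equal(ppm_to_offset_hz(175, acq),
               ppm_to_offset_hz(175 + sw_ppm, acq))
})

test_that("apparent offsets of the three resonances are well separated", {
  offs <- ppm_to_offset_hz(res$ppm, acq)
  expect_gt(min(dist(offs)), 5 * max(res$fwhm_hz))
})

test_that("voxel FIDs behave as Lorentzian lines", {
  expect_equal(synthesize_voxel_fid(c(0, 0, 0), res, acq),
               complex(real = rep(0, 128)))
  # single species at the carrier: pure decay, no oscillation
  res1 <- resonance_table("x", acq$carrier_ppm, 20)
  fid <- synthesize_voxel_fid(1, res1, acq)
  expect_true(all(abs(Im(fid)) < 1e-12))
  expect_true(all(diff(Mod(fid)) < 0))
  # each resonance peaks at the bin nearest its apparent offset
  f <- spectrum_frequencies(acq)
  for (i in 1:3) {
    mz <- c(0, 0, 0); mz[i] <- 1
    spec <- Mod(hpcsi:::.fftshift1(stats::fft(
      synthesize_voxel_fid(mz, res, acq))))
    expect_equal(which.max(spec),
                 which.min(abs(f - ppm_to_offset_hz(res$ppm[i], acq))))
  }
})

test_that("phase encoding and reconstruction are exact inverses", {
  set.seed(42)
  img <- array(complex(real = rnorm(8 * 8 * 6 * 2),
                       imaginary = rnorm(8 * 8 * 6 * 2)), c(8, 8, 6, 2))
  k <- encode_kspace(img)
  expect_lt(max(Mod(reconstruct_voxels(k) - img)) / max(Mod(img)), 1e-10)
  # energy relation under the 1/(n*n)-normalized forward transform
  expect_equal(sum(Mod(img)^2), 64 * sum(Mod(k)^2))
  expect_error(encode_kspace(array(0i, c(8, 4, 2))), "equal")
})

test_that("a single-voxel impulse spreads to constant k-space magnitude", {
  img <- array(complex(real = 0), c(8, 8, 1, 1))
  img[3, 5, 1, 1] <- 2 + 1i
  k <- encode_kspace(img)
  expect_equal(max(Mod(k)), min(Mod(k)))
})

test_that("identical seeds reproduce datasets bit for bit", {
  ph <- make_phantom(kpl = 0.03)
  d1 <- generate_dynamic_csi(ph, acq, noise_sigma = 1e-3, seed = 7)
  d2 <- generate_dynamic_csi(ph, acq, noise_sigma = 1e-3, seed = 7)
  expect_identical(d1$kspace, d2$kspace)
  d3 <- generate_dynamic_csi(ph, acq, noise_sigma = 1e-3, seed = 8)
  expect_false(identical(d3$kspace, d1$kspace))
  expect_error(generate_dynamic_csi(ph, acq, noise_sigma = -1), "noise_sigma")
})

test_that("noiseless signal is linear in the delivery amplitudes", {
  ph1 <- make_phantom(kpl = 0.02, pyr_amp = 1, urea_amp = 1)
  ph2 <- make_phantom(kpl = 0.02, pyr_amp = 2, urea_amp = 2)
  d1 <- generate_dynamic_csi(ph1, acq, noise_sigma = 0, seed = 1)
  d2 <- generate_dynamic_csi(ph2, acq, noise_sigma = 0, seed = 1)
  # tolerance reflects the adaptive ODE solver's relative accuracy
  expect_equal(Mod(d2$kspace), 2 * Mod(d1$kspace), tolerance = 1e-6)
})

test_that("signal-free voxels look like pure noise after reconstruction", {
  ph <- make_phantom(kpl = 0.02)
  sig <- 5e-4
  ds <- generate_dynamic_csi(ph, acq, noise_sigma = sig, seed = 5)
  img <- reconstruct_voxels(ds$kspace)
  empty <- !(ph$brain_mask | ph$vascular_mask)
  vals <- Mod(img)[rep(as.vector(empty), times = 128 * 15)]
  # an all-noise dataset built the same way gives the reference level
  ph0 <- make_phantom(pyr_amp = 0, urea_amp = 0)
  ds0 <- generate_dynamic_csi(ph0, acq, noise_sigma = sig, seed = 6)
  img0 <- reconstruct_voxels(ds0$kspace)
  ref <- Mod(img0)
  se <- sd(ref) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - mean(ref)), 3 * se * sqrt(2))
})

test_that("zero-conversion phantoms give noise-floor lactate fits", {
  # pooled over datasets: lactate AUC within 3 fit standard errors of zero
  # in at least 95% of brain voxels
  ph <- make_phantom(kpl = 0)
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    ds <- generate_dynamic_csi(ph, acq, noise_sigma = 5e-4, seed = 100 + s)
    # without conversion the whole ratio map is expected to be unreliable
    an <- suppressWarnings(analyze_csi(ds, zero_fill = 1))
    v <- an$voxels[an$voxels$in_brain, ]
    total <- total + nrow(v)
    hits <- hits + sum((v$auc_lac < 1e-8) |
                         (is.finite(v$auc_lac_se) &
                            v$auc_lac <= 3 * v$auc_lac_se))
  }
  expect_gte(hits / total, 0.95)
})
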