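test_that("tracer-kinetic conversion inverts the signal model", {
  t <- default_t()
  bw <- 1:10
  s_pre <- 500
  expect_equal(signal_to_conc(rep(s_pre, 60), bw, 0.029), rep(0, 60))

  sig <- rep(s_pre, 60); sig[20] <- s_pre * exp(-1)
  cc <- signal_to_conc(sig, bw, 0.029)
  expect_equal(cc[20], 1 / 0.029)

  # round-trip from a known gamma-variate curve
  c_true <- gamma_variate_aif(t, amp = 10)
  sig <- s_pre * exp(-0.029 * c_true)
  expect_equal(signal_to_conc(sig, bw, 0.029), c_true, tolerance = 1e-10)

  # degenerate baseline
  expect_true(all(is.na(signal_to_conc(rep(0, 60), bw, 0.029))))
})

test_that("bolus arrival detection brackets the pre-bolus frames", {
  t <- default_t()
  sig <- 500 * exp(-0.029 * gamma_variate_aif(t, t0 = 15, amp = 10))
  bw <- detect_baseline(sig)
  expect_true(max(bw) >= 10 && max(bw) <= 14)
})

test_that("AIF selection honours degenerate homogeneity and candidate masks", {
  t <- default_t()
  curve <- gamma_variate_aif(t)
  conc <- matrix(curve, length(t), 60)
  aif <- select_aif(conc, t)
  expect_equal(aif$c, curve)
  expect_equal(aif$n_voxels, 10)

  # restricting candidates changes the selection pool
  conc2 <- cbind(conc, matrix(0.1 * curve, length(t), 20))
  aif2 <- select_aif(conc2[, 61:80, drop = FALSE], t)
  expect_equal(aif2$c, 0.1 * curve)

  expect_error(select_aif(matrix(0, length(t), 60), t), "seed region")
})

test_that("leakage fit is exact on model-consistent curves", {
  t <- default_t()
  ref <- gamma_variate_aif(t, amp = 6)
  fit0 <- leakage_correct(t, ref, ref)
  expect_equal(fit0$k1, 1, tolerance = 1e-10)
  expect_equal(fit0$k2, 0, tolerance = 1e-10)
  expect_equal(fit0$corrected, ref, tolerance = 1e-10)

  cum <- aptperf:::cumtrapz_vec(t, ref)
  voxel <- ref - 0.1 * cum
  fit <- leakage_correct(t, voxel, ref)
  expect_equal(fit$k1, 1, tolerance = 1e-8)
  expect_equal(fit$k2, 0.1 * 60, tolerance = 1e-8)   # 1/s -> 1/min
  expect_equal(fit$corrected, ref, tolerance = 1e-8)

  # residual orthogonal to both regressors (normal equations)
  resid <- voxel - (fit$k1 * ref - (fit$k2 / 60) * cum)
  expect_lt(abs(sum(resid * ref)), 1e-8)
  expect_lt(abs(sum(resid * cum)), 1e-8)

  expect_error(leakage_correct(t, ref, rep(0, 60)), "degenerate")
})

test_that("leakage rate is recovered within 10% at bolus SNR 50", {
  t <- default_t()
  ref <- gamma_variate_aif(t, amp = 6)
  cum <- aptperf:::cumtrapz_vec(t, ref)
  k2_s <- 0.05 / 60
  set.seed(99)
  k2_hat <- replicate(200, {
    voxel <- 1.2 * ref - k2_s * cum + rnorm(60, 0, max(ref) / 50)
    leakage_correct(t, voxel, ref)$k2
  })
  expect_lt(abs(mean(k2_hat) - 0.05) / 0.05, 0.10)
})

test_that("blood volume is a ratio of integrals", {
  t <- default_t()
  a <- gamma_variate_aif(t)
  expect_equal(cbv(t, 0.5 * a, a), 0.5, tolerance = 1e-12)
  expect_equal(cbv(t, rep(0, 60), a), 0)
  expect_error(cbv(t, a, rep(0, 60)), "positive")
})

test_that("circulant-SVD deconvolution recovers flow and tolerates delay", {
  t <- default_t()
  tr <- 1.243
  a <- gamma_variate_aif(t)
  cbf_true <- 0.01; mtt <- 4
  r <- exp(-t / mtt)
  conv <- convolve(a, rev(r), type = "open")[seq_along(t)]
  curve <- cbf_true * tr * conv

  est <- deconvolve_cbf(t, curve, a, tr, threshold = 0.10)
  expect_equal(est$cbf, cbf_true, tolerance = 0.10)
  expect_equal(est$mtt, cbv(t, curve, a) / est$cbf, tolerance = 1e-10)

  # empty voxel
  expect_equal(deconvolve_cbf(t, rep(0, 60), a, tr)$cbf, 0)

  # linearity in the tissue curve
  est3 <- deconvolve_cbf(t, 3 * curve, a, tr, threshold = 0.10)
  expect_equal(est3$cbf, 3 * est$cbf, tolerance = 1e-10)

  # two-frame delay changes the estimate by < 5%
  delayed <- c(rep(0, 2), curve[1:58])
  est_d <- deconvolve_cbf(t, delayed, a, tr, threshold = 0.10)
  expect_lt(abs(est_d$cbf - est$cbf) / est$cbf, 0.05)

  expect_error(deconvolve_cbf(t, curve, rep(0, 60), tr), "zero")
})

test_that("circulant deconvolution matches standard SVD at zero delay", {
  t <- default_t()
  tr <- 1.243
  a <- gamma_variate_aif(t)
  for (mtt in c(3, 5, 8)) {
    r <- exp(-t / mtt)
    curve <- 0.01 * tr * convolve(a, rev(r), type = "open")[seq_along(t)]
    csvd <- deconvolve_cbf(t, curve, a, tr, threshold = 0.10)$cbf
    ssvd <- standard_svd_cbf(curve, a, tr, threshold = 0.10)
    expect_equal(csvd, ssvd, tolerance = 0.02)
  }
})

test_that("voxelwise perfusion maps honour the no-leakage limit and masks", {
  truth <- matched_kinetics_truth(seed = 5, k2 = 0)
  labels <- build_phantom(c(16, 16, 16))
  dsc <- generate_dsc(truth, labels, noise_sd = 0, seed = 1)
  series <- dsc_series(dsc$dsc_4d, baseline_window = dsc$baseline_window)
  enh <- labels %in% phantom_labels[c("et", "et_hot", "artery")]
  dim(enh) <- dim(labels)
  art <- labels == phantom_labels[["artery"]]
  pm <- compute_perfusion_maps(series, labels > 0, enhancing_mask = enh,
                               aif_mask = art)
  # arterial voxels carry the bolus itself, not tissue kinetics
  tissue <- labels > 0 & !art
  expect_lt(max(abs(pm$k2[tissue]), na.rm = TRUE), 1e-6)
  expect_equal(pm$ccbv[tissue], pm$cbv[tissue], tolerance = 1e-6)
  brain <- labels > 0

  # the selected AIF tracks the generating bolus
  expect_gt(cor(pm$aif$c, dsc$aif_true), 0.99)

  # excluded voxels are missing
  mask2 <- brain
  off <- which(brain)[1:3]
  mask2[off] <- FALSE
  pm2 <- compute_perfusion_maps(series, mask2, enhancing_mask = enh,
                                aif_mask = art)
  expect_true(all(is.na(pm2$cbv[off])))
})

test_that("corrected volume exceeds uncorrected exactly when K2 is positive", {
  t <- default_t()
  ref <- gamma_variate_aif(t, amp = 6)
  cum <- aptperf:::cumtrapz_vec(t, ref)
  voxel <- 2 * ref - (0.08 / 60) * cum
  fit <- leakage_correct(t, voxel, ref)
  expect_gt(fit$k2, 0)
  expect_gt(cbv(t, fit$corrected, ref), cbv(t, voxel, ref))
})
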