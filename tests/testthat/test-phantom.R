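test_that("phantom geometry is deterministic with analytic region volumes", {
  l1 <- build_phantom(c(64, 64, 24))
  l2 <- build_phantom(c(64, 64, 24))
  expect_identical(l1, l2)

  # voxel counts vs analytic ellipsoid volumes
  vol <- function(r) 4 / 3 * pi * prod(r)
  re <- c(0.19 * 64, 0.19 * 64, 0.25 * 24)
  rt <- c(0.125 * 64, 0.125 * 64, 0.167 * 24)
  rn <- c(0.078 * 64, 0.078 * 64, 0.104 * 24)
  n_tumor <- sum(l1 %in% phantom_labels[c("et", "et_hot", "necrosis")])
  expect_equal(n_tumor, vol(rt), tolerance = 0.10)
  n_core <- sum(l1 == phantom_labels[["necrosis"]])
  expect_equal(n_core, vol(rn), tolerance = 0.10)
  n_edema <- sum(l1 == phantom_labels[["edema"]])
  expect_equal(n_edema, vol(re) - vol(rt), tolerance = 0.10)

  # degenerate geometry: no tumor labels
  l0 <- build_phantom(c(32, 32, 16), tumor_scale = 0)
  expect_true(all(l0 %in% phantom_labels[c("background", "nawm", "artery")]))

  expect_error(build_phantom(c(32, 32, 16), tumor_scale = 3), "exceeds")
})

test_that("subject truth draws are reproducible and group-ordered", {
  t1 <- sample_subject_truth("gbm", seed = 10)
  t2 <- sample_subject_truth("gbm", seed = 10)
  expect_identical(t1$tissues, t2$tissues)
  expect_false(identical(
    t1$tissues, sample_subject_truth("gbm", seed = 11)$tissues))

  # zero between-group effect makes the groups indistinguishable
  cfg0 <- effect_config(null_effect = TRUE)
  tg <- sample_subject_truth("gbm", cfg0, seed = 10)
  tm <- sample_subject_truth("met", cfg0, seed = 10)
  expect_identical(tg$tissues, tm$tissues)

  # law of large numbers on the default configuration
  draws <- function(group) {
    vapply(1:100, function(s) {
      tt <- sample_subject_truth(group, seed = 2000 + s)$tissues
      tt$cbv_rel[tt$name == "et"]
    }, numeric(1))
  }
  expect_gt(mean(draws("gbm")), mean(draws("met")))

  expect_error(sample_subject_truth("gbm", local({
    cfg <- effect_config(); cfg$gbm$cbv_et["sd"] <- -1; cfg
  }), seed = 1))
})

test_that("noiseless CEST generation round-trips through the map pipeline", {
  truth <- sample_subject_truth("met", seed = 8)
  labels <- build_phantom(c(16, 16, 16))
  cest <- generate_cest(truth, labels, noise_sd = 0, b0_amp = 0, seed = 2)
  am <- compute_aptw_maps(cest$cest_4d, cest$s0, labels > 0,
                          offsets = cest$offsets)
  for (i in seq_len(nrow(truth$tissues))) {
    row <- truth$tissues[i, ]
    vox <- which(labels == row$label)
    if (length(vox) == 0) next
    spec <- b0_correct(simulate_zspectrum(
      aptperf:::tissue_pools(row, row$amide_fraction),
      saturation_module(), offset_plan(), 256, steady_state = TRUE))
    expect_equal(unname(am$aptw[vox[1]]), aptw(spec), tolerance = 1e-6)
  }
})

test_that("voxel noise propagates to APTw at the first-order prediction", {
  truth <- sample_subject_truth("gbm", seed = 4)
  labels <- build_phantom(c(24, 24, 12), tumor_scale = 0)
  noise_sd <- 0.02
  cest <- generate_cest(truth, labels, noise_sd = noise_sd, b0_amp = 0,
                        seed = 3)
  am <- compute_aptw_maps(cest$cest_4d, cest$s0, labels == 1,
                          offsets = cest$offsets)
  measured_sd <- sd(am$aptw[labels == 1], na.rm = TRUE)

  # delta method: numeric gradient of the scalar chain at the clean spectrum
  row <- truth$tissues[truth$tissues$name == "nawm", ]
  spec <- simulate_zspectrum(aptperf:::tissue_pools(row, row$amide_fraction),
                             saturation_module(), offset_plan(), 256,
                             steady_state = TRUE)
  f <- function(z) aptw(b0_correct(new_zspectrum(spec$offsets, z)))
  g <- vapply(seq_along(spec$z), function(k) {
    zp <- spec$z; zp[k] <- zp[k] + 1e-5
    (f(zp) - f(spec$z)) / 1e-5
  }, numeric(1))
  # z = s/s0 noise: sd_z ~ noise_sd * sqrt(1 + z^2) at S0-relative noise
  sd_z <- noise_sd * sqrt(1 + spec$z^2)
  predicted_sd <- sqrt(sum((g * sd_z)^2))
  expect_gt(measured_sd / predicted_sd, 0.5)
  expect_lt(measured_sd / predicted_sd, 2)
})

test_that("leaking enhancing tissue is recovered by the perfusion pipeline", {
  truth <- matched_kinetics_truth(seed = 6, k2 = 0.05)
  labels <- build_phantom(c(24, 24, 12))
  dsc <- generate_dsc(truth, labels, noise_sd = 0, seed = 1)
  series <- dsc_series(dsc$dsc_4d, baseline_window = dsc$baseline_window)
  enh <- labels %in% phantom_labels[c("et", "et_hot", "artery")]
  dim(enh) <- dim(labels)
  pm <- compute_perfusion_maps(series, labels > 0, enhancing_mask = enh,
                               aif_mask = labels == phantom_labels[["artery"]])
  et <- labels == phantom_labels[["et"]]
  nawm <- labels == phantom_labels[["nawm"]]
  expect_equal(mean(pm$k2[et]), 0.05, tolerance = 0.10)
  # K2 elevated only in leaking tissue
  expect_lt(max(abs(pm$k2[nawm])), 1e-6)

  # doubling the vascular amplitude (CBV and CBF at fixed MTT, no leakage)
  # doubles the recovered volume and flow exactly (fixed AIF linearity)
  truth_a <- matched_kinetics_truth(seed = 6, k2 = 0)
  truth_b <- truth_a
  sel <- truth_b$tissues$name == "et"
  truth_b$tissues$cbv_rel[sel] <- 2 * truth_a$tissues$cbv_rel[sel]
  truth_b$tissues$cbf_rel[sel] <- 2 * truth_a$tissues$cbf_rel[sel]
  run1 <- function(tr_) {
    d <- generate_dsc(tr_, labels, noise_sd = 0, seed = 1)
    compute_perfusion_maps(
      dsc_series(d$dsc_4d, baseline_window = d$baseline_window),
      labels > 0, enhancing_mask = enh,
      aif_mask = labels == phantom_labels[["artery"]])
  }
  pa <- run1(truth_a); pb <- run1(truth_b)
  expect_equal(mean(pb$cbv[et]) / mean(pa$cbv[et]), 2, tolerance = 1e-6)
  expect_equal(mean(pb$cbf[et]) / mean(pa$cbf[et]), 2, tolerance = 1e-6)
})

test_that("cohort generation is seed-deterministic with distinct subjects", {
  c1 <- generate_cohort(2, 1, seed = 5, shape = c(16, 16, 16),
                        modalities = "dsc")
  c2 <- generate_cohort(2, 1, seed = 5, shape = c(16, 16, 16),
                        modalities = "dsc")
  expect_equal(length(c1), 3)
  expect_identical(c1[[1]]$dsc$dsc_4d, c2[[1]]$dsc$dsc_4d)
  expect_identical(c1[[3]]$truth$tissues, c2[[3]]$truth$tissues)
  expect_false(identical(c1[[1]]$truth$tissues, c1[[2]]$truth$tissues))
  expect_equal(vapply(c1, function(s) s$group, character(1)),
               c("gbm", "gbm", "met"))
})
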