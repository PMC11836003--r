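#' Tissue classes of the digital tumor phantom
#'
#' Integer label codes used throughout the phantom and ROI modules. The
#' `et_hot` code marks the hypercellular/hypervascular hotspot generated
#' inside the enhancing tumor; for ROI statistics it is part of ET (see
#' [roi_labels()]).
#'
#' @export
phantom_labels <- c(background = 0L, nawm = 1L, et = 2L, necrosis = 3L,
                    edema = 4L, artery = 5L, et_hot = 6L)

#' Collapse generator labels to ROI labels
#'
#' Maps the internal hotspot code back into ET so that region statistics see
#' the enhancing tumor as one region.
#'
#' @param labels Integer label volume from [build_phantom()].
#' @return Integer volume with codes background/nawm/et/necrosis/edema/artery.
#' @export
roi_labels <- function(labels) {
  labels[labels == phantom_labels[["et_hot"]]] <- phantom_labels[["et"]]
  labels
}

# Per-tissue CEST response calibration: the APTw asymmetry (percent) of the
# simulated steady-state Z-spectrum is a gently saturating function of the
# amide proton fraction, captured to <0.003% by a quadratic
# APTw = c0 + c1*f + c2*f^2 over each tissue's generation range, with
# coefficients depending on the tissue's water relaxation and semisolid
# content. Calibrated once against the package's own simulator (default
# saturation module, 256 segments, steady state).
tissue_base <- function() {
  tibble::tribble(
    ~name,       ~wt1,  ~wt2,  ~mtf,  ~apt_c0,  ~apt_c1,   ~apt_c2,
    "nawm",      1.084, 0.069, 0.139, 0.000081, 274.8101,  -1715.606,
    "et",        1.400, 0.090, 0.080, 0.002061, 429.7820,  -3538.612,
    "edema",     1.600, 0.120, 0.060, 0.000537, 574.7595,  -6394.977,
    "necrosis",  2.500, 0.250, 0.010, 0.000038, 1711.8778, -47246.877,
    "artery",    1.650, 0.150, 0.020, 0.000317, 1010.8840, -16599.082
  )
}

# invert the quadratic calibration: amide fraction for a target APTw (%)
amide_fraction_for <- function(c0, c1, c2, target) {
  disc <- pmax(c1^2 + 4 * c2 * (target - c0), 0)
  pmax((-c1 + sqrt(disc)) / (2 * c2), 1e-6)
}

tissue_pools <- function(tissue_row, af) {
  dplyr::bind_rows(
    pool("water", t1 = tissue_row$wt1, t2 = tissue_row$wt2),
    pool("mt", t1 = 1.0, t2 = 9.6e-6, fraction = tissue_row$mtf,
         exchange_rate = 23, lineshape = "superlorentzian"),
    pool("amide", t1 = 1.0, t2 = 0.01, fraction = af,
         exchange_rate = 30, chemical_shift = 3.5)
  )
}

#' Default two-group effect configuration of the cohort generator
#'
#' Group-level distributions for the subject-varying enhancing-tumor
#' parameters, plus fixed parameters of the remaining tissues. APTw entries
#' are targets in percent (normal-appearing white matter is generated at
#' 1.0%, so targets double as NAWM-normalized values); perfusion entries are
#' relative to NAWM = 1; K2 is in 1/min. The GBM-like distributions
#' stochastically dominate the MET-like ones for ET amide content, CBF and
#' CBV, emulating the reported contrast between the groups; the `*_hot`
#' entries parameterize the intratumoral hotspot that drives the max
#' statistics. Region-presence probabilities emulate cohorts in which some
#' subjects lack visible necrosis or edema. Setting `null_effect = TRUE`
#' collapses every group difference (both groups draw from the GBM-like
#' distributions), for calibration of false-positive rates.
#'
#' @param null_effect If `TRUE`, make the two groups identical.
#' @return A nested list of group parameter distributions.
#' @export
effect_config <- function(null_effect = FALSE) {
  gbm <- list(
    aptw_et = c(mean = 2.0, sd = 0.60), aptw_hot = c(mean = 4.9, sd = 0.25),
    cbv_et = c(mean = 4.3, sd = 1.8),   cbv_hot = c(mean = 23, sd = 5.5),
    cbf_et = c(mean = 3.7, sd = 1.7),   cbf_hot = c(mean = 18, sd = 5.0),
    k2_et = c(mean = 0.03, sd = 0.02),
    p_necrosis = 0.5, p_edema = 1.0
  )
  met <- list(
    aptw_et = c(mean = 1.7, sd = 0.74), aptw_hot = c(mean = 4.4, sd = 0.25),
    cbv_et = c(mean = 2.4, sd = 0.86),  cbv_hot = c(mean = 12, sd = 4.0),
    cbf_et = c(mean = 2.3, sd = 1.0),   cbf_hot = c(mean = 13, sd = 4.0),
    k2_et = c(mean = 0.04, sd = 0.02),
    p_necrosis = 0.25, p_edema = 0.75
  )
  if (null_effect) met <- gbm
  list(
    gbm = gbm, met = met,
    fixed = tibble::tribble(
      ~name,      ~aptw_target, ~cbf_rel, ~cbv_rel, ~k2, ~delay,
      "nawm",     1.00,         1.00,     1.00,     0,   0.8,
      "edema",    0.88,         0.95,     1.00,     0,   1.0,
      "necrosis", 0.50,         0.25,     0.23,     0,   1.5,
      "artery",   1.00,         NA,       NA,       0,   0.0
    ),
    noise_sd_cest = 0.005, noise_sd_dsc = 0.02, b0_amp = 0.3
  )
}

#' Build the phantom label volume
#'
#' Concentric ellipsoids -- a necrotic core inside an enhancing-tumor (ET)
#' rim inside an edema shell -- embedded in a NAWM brain ellipsoid, plus a
#' small artery tube and an ET hotspot sub-region. All radii scale with the
#' volume shape.
#'
#' @param shape Integer vector (nx, ny, nz), each >= 12 (default 64x64x24).
#' @param tumor_scale Multiplies all tumor radii; 0 removes the tumor.
#' @param with_necrosis,with_edema Include the necrotic core / edema shell.
#' @param with_hotspot Carve the hotspot sub-region out of ET.
#' @return Integer 3D array of [phantom_labels] codes.
#' @export
build_phantom <- function(shape = c(64, 64, 24), tumor_scale = 1,
                          with_necrosis = TRUE, with_edema = TRUE,
                          with_hotspot = TRUE) {
  stopifnot(length(shape) == 3, all(shape >= 12), tumor_scale >= 0)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  x <- seq_len(nx); y <- seq_len(ny); z <- seq_len(nz)
  X <- array(rep(x, times = ny * nz), shape)
  Y <- array(rep(rep(y, each = nx), times = nz), shape)
  Z <- array(rep(z, each = nx * ny), shape)

  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  inside <- function(xc, yc, zc, rx, ry, rz) {
    ((X - xc) / rx)^2 + ((Y - yc) / ry)^2 + ((Z - zc) / rz)^2 <= 1
  }

  labels <- array(phantom_labels[["background"]], shape)
  labels[inside(cx, cy, cz, 0.45 * nx, 0.45 * ny, 0.45 * nz)] <-
    phantom_labels[["nawm"]]

  # tumor centered off-axis inside the brain
  tx <- cx + 0.14 * nx; ty <- cy; tz <- cz
  re <- tumor_scale * c(0.19 * nx, 0.19 * ny, 0.25 * nz)   # edema shell
  rt <- tumor_scale * c(0.125 * nx, 0.125 * ny, 0.167 * nz) # ET rim
  rn <- tumor_scale * c(0.078 * nx, 0.078 * ny, 0.104 * nz) # necrotic core
  if (any(re > c(0.45 * nx, 0.45 * ny, 0.45 * nz))) {
    abort("tumor geometry exceeds the brain volume")
  }
  if (tumor_scale > 0) {
    if (with_edema) labels[inside(tx, ty, tz, re[1], re[2], re[3])] <-
      phantom_labels[["edema"]]
    labels[inside(tx, ty, tz, rt[1], rt[2], rt[3])] <- phantom_labels[["et"]]
    if (with_necrosis) labels[inside(tx, ty, tz, rn[1], rn[2], rn[3])] <-
      phantom_labels[["necrosis"]]
    if (with_hotspot) {
      hx <- tx + (rn[1] + rt[1]) / 2
      hr <- pmax(0.45 * (rt - rn), 1)
      hot <- inside(hx, ty, tz, hr[1], hr[2], hr[3]) &
        labels == phantom_labels[["et"]]
      labels[hot] <- phantom_labels[["et_hot"]]
    }
  }

  # artery: small tube along z near the anterior brain edge
  art <- (X - cx)^2 + (Y - (cy - 0.32 * ny))^2 <= max(0.03 * nx, 1.1)^2
  labels[art & labels == phantom_labels[["nawm"]]] <- phantom_labels[["artery"]]
  labels
}

rtruncnorm1 <- function(n, mean, sd, lower) {
  pmax(rnorm(n, mean, sd), lower)
}

#' Draw one subject's ground-truth tissue parameters
#'
#' Samples the subject-level enhancing-tumor parameters (APTw contrast
#' targets, relative CBF/CBV of the ET rim and its hotspot, leakage K2) from
#' the group distributions of an [effect_config()], together with the
#' presence of necrosis and edema. All other tissues use the fixed defaults.
#'
#' @param group `"gbm"` or `"met"`.
#' @param config An [effect_config()].
#' @param seed Integer seed; the draw is reproducible.
#' @return A `subject_truth` object: list with `group`, `seed`, `has_necrosis`,
#'   `has_edema`, and a `tissues` tibble (one row per label present).
#' @export
sample_subject_truth <- function(group = c("gbm", "met"),
                                 config = effect_config(), seed = 1) {
  group <- match.arg(group)
  g <- config[[group]]
  stopifnot(all(vapply(g[1:7], function(p) p[["sd"]] >= 0, logical(1))))
  set.seed(seed)
  et <- tibble::tibble(
    name = c("et", "et_hot"),
    aptw_target = c(rtruncnorm1(1, g$aptw_et["mean"], g$aptw_et["sd"], 0.3),
                    rtruncnorm1(1, g$aptw_hot["mean"], g$aptw_hot["sd"], 1.0)),
    cbf_rel = c(rtruncnorm1(1, g$cbf_et["mean"], g$cbf_et["sd"], 0.3),
                rtruncnorm1(1, g$cbf_hot["mean"], g$cbf_hot["sd"], 2.0)),
    cbv_rel = c(rtruncnorm1(1, g$cbv_et["mean"], g$cbv_et["sd"], 0.3),
                rtruncnorm1(1, g$cbv_hot["mean"], g$cbv_hot["sd"], 2.0)),
    k2 = rep(rnorm(1, g$k2_et["mean"], g$k2_et["sd"]), 2),
    delay = 0.5
  )
  has_necrosis <- runif(1) < g$p_necrosis
  has_edema <- runif(1) < g$p_edema
  fixed <- config$fixed
  if (!has_necrosis) fixed <- fixed[fixed$name != "necrosis", ]
  if (!has_edema) fixed <- fixed[fixed$name != "edema", ]
  tissues <- dplyr::bind_rows(
    dplyr::mutate(fixed, delay = .data$delay),
    et
  )
  tissues$label <- phantom_labels[tissues$name]
  base <- tissue_base()
  base$base_name <- base$name
  tissues <- dplyr::left_join(
    tissues,
    dplyr::select(base, -"name"),
    by = c("name" = "base_name")
  )
  # hotspot shares the ET tissue matrix
  hot <- tissues$name == "et_hot"
  for (cn in c("wt1", "wt2", "mtf", "apt_c0", "apt_c1", "apt_c2")) {
    tissues[[cn]][hot] <- tissues[[cn]][tissues$name == "et"]
  }
  tissues$amide_fraction <- amide_fraction_for(
    tissues$apt_c0, tissues$apt_c1, tissues$apt_c2, tissues$aptw_target)
  structure(list(group = group, seed = seed, has_necrosis = has_necrosis,
                 has_edema = has_edema, tissues = tissues),
            class = "subject_truth")
}

# Smooth B0 offset field (ppm): in-plane linear gradient plus a broad
# Gaussian bump, scaled so max |b0| ~= amp.
b0_field <- function(shape, amp = 0.3) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  X <- array(rep(seq_len(nx), times = ny * nz), shape)
  Y <- array(rep(rep(seq_len(ny), each = nx), times = nz), shape)
  grad <- (2 * (X - 1) / (nx - 1) - 1) * 0.5
  bump <- exp(-(((X - 0.35 * nx)^2 + (Y - 0.6 * ny)^2) / (2 * (0.25 * nx)^2))) * 0.5
  f <- grad + bump
  amp * f / max(abs(f))
}

# Simulate (or interpolate from a cached bank) the fine-grid Z-spectrum and
# S0 magnetization for one tissue row. The bank linearly interpolates over
# amide fraction, which is accurate to ~1e-5 in Z because the dilute-pool
# response is nearly linear; used by the replicate-calibration fast path.
tissue_spectrum <- function(row, sat, fine_offsets, s0_offset, n_segments,
                            bank = NULL) {
  if (!is.null(bank)) {
    key <- row$name
    if (is.null(bank[[key]])) {
      af_grid <- attr(bank, "af_grid")[[key]]
      if (is.null(af_grid)) af_grid <- pmax(row$amide_fraction * c(0.25, 1, 2.5), 1e-6)
      zm <- vapply(af_grid, function(af) {
        bm_run(tissue_pools(row, af), sat, c(fine_offsets, s0_offset),
               n_segments, steady_state = TRUE)
      }, numeric(length(fine_offsets) + 1))
      bank[[key]] <- list(af = af_grid, zm = zm)
    }
    bk <- bank[[key]]
    af <- min(max(row$amide_fraction, bk$af[1]), bk$af[length(bk$af)])
    j <- pmin(findInterval(af, bk$af), length(bk$af) - 1)
    w <- (af - bk$af[j]) / (bk$af[j + 1] - bk$af[j])
    mz <- (1 - w) * bk$zm[, j] + w * bk$zm[, j + 1]
  } else {
    mz <- bm_run(tissue_pools(row, row$amide_fraction), sat,
                 c(fine_offsets, s0_offset), n_segments, steady_state = TRUE)
  }
  n <- length(fine_offsets)
  list(z = abs(mz[seq_len(n)]) / abs(mz[n + 1]), s0 = abs(mz[n + 1]))
}

#' Generate a subject's 4D CEST stack
#'
#' Simulates each tissue's steady-state Z-spectrum on a fine offset grid
#' (Bloch-McConnell, per-label broadcast), applies a smooth B0 offset field
#' by sampling each voxel's spectrum at the acquisition offsets shifted by
#' the local field offset, scales to signal units, and adds Gaussian noise.
#'
#' @param truth A [sample_subject_truth()].
#' @param labels Label volume from [build_phantom()].
#' @param sat,plan Saturation module and offset plan.
#' @param noise_sd Gaussian noise SD as a fraction of S0.
#' @param b0_amp Amplitude of the smooth B0 field, ppm.
#' @param seed Noise seed.
#' @param n_segments Pulse discretization for the simulator.
#' @param bank Optional spectrum bank environment for the fast
#'   amide-interpolation path (see the methods vignette); `NULL` simulates
#'   each tissue exactly.
#' @return List with `cest_4d` (x,y,z,offset), `s0` (3D), `b0_true` (3D, ppm)
#'   and `offsets`.
#' @export
generate_cest <- function(truth, labels, sat = saturation_module(),
                          plan = offset_plan(), noise_sd = 0.005,
                          b0_amp = 0.3, seed = 1, n_segments = 256,
                          bank = NULL) {
  shape <- dim(labels)
  offs <- plan$offsets
  pad <- b0_amp + 2 * max(diff(offs))
  # grid aligned to quarter-ppm so acquisition offsets are exact grid points
  fine <- seq(floor((min(offs) - pad) * 4) / 4,
              ceiling((max(offs) + pad) * 4) / 4, by = 0.25)

  b0 <- if (b0_amp > 0) b0_field(shape, b0_amp) else array(0, shape)
  s0_scale <- 1000

  cest <- array(0, c(shape, length(offs)))
  s0_vol <- array(0, shape)
  nvox <- prod(shape)

  for (i in seq_len(nrow(truth$tissues))) {
    row <- truth$tissues[i, ]
    vox <- which(labels == row$label)
    if (length(vox) == 0) next
    sp <- tissue_spectrum(row, sat, fine, plan$s0_offset, n_segments, bank)
    # voxel spectrum: Z_vox(w) = Z_tissue(w - b0); query at acquisition offsets
    b0v <- b0[vox]
    for (k in seq_along(offs)) {
      zq <- approx(fine, sp$z, xout = offs[k] - b0v, method = "linear")$y
      cest[vox + (k - 1) * nvox] <- zq * s0_scale
    }
    s0_vol[vox] <- s0_scale
  }

  set.seed(seed)
  brain <- labels > 0
  nb <- sum(brain)
  if (noise_sd > 0) {
    for (k in seq_along(offs)) {
      idx <- which(brain) + (k - 1) * nvox
      cest[idx] <- cest[idx] + rnorm(nb, 0, noise_sd * s0_scale)
    }
    s0_vol[brain] <- s0_vol[brain] + rnorm(nb, 0, noise_sd * s0_scale)
  }
  list(cest_4d = cest, s0 = s0_vol, b0_true = b0, offsets = offs)
}

#' Gamma-variate arterial bolus
#'
#' `c_a(t) = amp * ((t-t0)/(alpha*beta))^alpha * exp(alpha - (t-t0)/beta)`
#' for `t > t0`, 0 before: peak value `amp` at `t = t0 + alpha*beta`.
#'
#' @param t Time axis, s.
#' @param t0 Bolus arrival, s (default 15).
#' @param alpha,beta Shape and scale of the gamma variate.
#' @param amp Peak concentration, 1/s.
#' @return Concentration values on `t`.
#' @export
gamma_variate_aif <- function(t, t0 = 15, alpha = 3, beta = 1.5, amp = 30) {
  stopifnot(alpha > 0, beta > 0, amp > 0)
  tt <- pmax(t - t0, 0)
  out <- amp * (tt / (alpha * beta))^alpha * exp(alpha - tt / beta)
  out[t <= t0] <- 0
  out
}

#' Generate a subject's 4D DSC series
#'
#' Forward perfusion model: each tissue's concentration curve is the
#' delayed gamma-variate AIF convolved with an exponential residue function
#' and scaled by relative CBF (`c = cbf * tr * (AIF (*) exp(-t/MTT))`, MTT
#' chosen so that CBV = CBF x MTT matches the tissue's relative CBV), minus
#' the leakage term `k2 * integral` of the NAWM reference curve in leaking
#' tissue. Curves are converted to signal `S = S_pre * exp(-TE * c)` with
#' additive Gaussian noise; artery voxels carry the AIF itself.
#'
#' @param truth A [sample_subject_truth()].
#' @param labels Label volume.
#' @param tr,te Repetition/echo time, s.
#' @param n_frames Number of dynamic frames (default 60).
#' @param bolus Parameters passed to [gamma_variate_aif()].
#' @param mtt_nawm NAWM mean transit time, s.
#' @param cbv_abs_nawm NAWM time-integral ratio against the AIF. This is an
#'   apparent (relaxivity-amplified) volume: susceptibility contrast makes
#'   tissue Delta-R2* far larger than the plain blood-volume fraction, so
#'   the default 0.2 yields realistic peak signal drops (~10% in NAWM at
#'   TE = 29 ms) rather than the ~2% a literal volume fraction would give.
#' @param noise_sd Gaussian noise SD as a fraction of baseline signal.
#' @param seed Noise seed.
#' @return List with `dsc_4d`, `t`, `aif_true` and `conc_true` (per-label
#'   tibble of generating curves).
#' @export
generate_dsc <- function(truth, labels, tr = 1.243, te = 0.029, n_frames = 60,
                         bolus = list(t0 = 15, alpha = 3, beta = 1.5, amp = 30),
                         mtt_nawm = 4, cbv_abs_nawm = 0.2, noise_sd = 0.02,
                         seed = 1) {
  shape <- dim(labels)
  t <- (seq_len(n_frames) - 1) * tr
  cbf_abs_nawm <- cbv_abs_nawm / mtt_nawm

  aif_at <- function(tax) do.call(gamma_variate_aif, c(list(t = tax), bolus))
  aif <- aif_at(t)

  tissue_curve <- function(cbf_rel, cbv_rel, delay) {
    mtt <- mtt_nawm * cbv_rel / cbf_rel
    r <- exp(-t / mtt)
    a_del <- aif_at(t - delay)
    # discrete convolution on the acquisition grid, rectangle rule
    full <- convolve(a_del, rev(r), type = "open")[seq_len(n_frames)]
    cbf_abs_nawm * cbf_rel * tr * full
  }

  nawm_row <- truth$tissues[truth$tissues$name == "nawm", ]
  ref <- tissue_curve(nawm_row$cbf_rel, nawm_row$cbv_rel, nawm_row$delay)
  cum_ref <- cumtrapz_vec(t, ref)

  s_pre <- 500
  dsc <- array(0, c(shape, n_frames))
  nvox <- prod(shape)
  for (i in seq_len(nrow(truth$tissues))) {
    row <- truth$tissues[i, ]
    vox <- which(labels == row$label)
    if (length(vox) == 0) next
    cc <- if (row$name == "artery") aif else {
      tissue_curve(row$cbf_rel, row$cbv_rel, row$delay) -
        (row$k2 / 60) * cum_ref
    }
    sig <- s_pre * exp(-te * cc)
    for (k in seq_len(n_frames)) dsc[vox + (k - 1) * nvox] <- sig[k]
  }

  set.seed(seed)
  brain <- labels > 0
  nb <- sum(brain)
  if (noise_sd > 0) {
    for (k in seq_len(n_frames)) {
      idx <- which(brain) + (k - 1) * nvox
      dsc[idx] <- dsc[idx] + rnorm(nb, 0, noise_sd * s_pre)
    }
  }
  list(dsc_4d = dsc, t = t, aif_true = aif,
       baseline_window = seq_len(max(which(t < bolus$t0))))
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject ground truth and synthesizes CEST and DSC volumes for
#' `n_gbm` GBM-like and `n_met` MET-like subjects. Per-subject seeds are
#' derived deterministically from the master seed, so the whole cohort is
#' reproducible.
#'
#' @param n_gbm,n_met Subjects per group (defaults 10 and 8).
#' @param config An [effect_config()].
#' @param seed Master seed.
#' @param shape Phantom shape.
#' @param modalities Character subset of `c("cest", "dsc")` to synthesize.
#' @param bank Optional spectrum bank (see [generate_cest()]).
#' @param ... Passed on to [generate_cest()] / [generate_dsc()].
#' @return List of `synthetic_subject` lists: `id`, `group`, `truth`,
#'   `labels`, and the requested modality data.
#' @export
generate_cohort <- function(n_gbm = 10, n_met = 8, config = effect_config(),
                            seed = 1, shape = c(64, 64, 24),
                            modalities = c("cest", "dsc"), bank = NULL, ...) {
  stopifnot(n_gbm >= 1, n_met >= 1)
  groups <- c(rep("gbm", n_gbm), rep("met", n_met))
  base_seed <- (as.integer(seed) %% 1000000L) * 1000L
  lapply(seq_along(groups), function(i) {
    truth <- sample_subject_truth(groups[i], config, seed = base_seed + i)
    labels <- build_phantom(shape, with_necrosis = truth$has_necrosis,
                            with_edema = truth$has_edema)
    subj <- list(id = sprintf("S%02d", i), group = groups[i], truth = truth,
                 labels = labels)
    if ("cest" %in% modalities) {
      subj$cest <- generate_cest(truth, labels,
                                 noise_sd = config$noise_sd_cest,
                                 b0_amp = config$b0_amp,
                                 seed = base_seed + i + 500L, bank = bank, ...)
    }
    if ("dsc" %in% modalities) {
      subj$dsc <- generate_dsc(truth, labels, noise_sd = config$noise_sd_dsc,
                               seed = base_seed + i + 700L)
    }
    subj
  })
}
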