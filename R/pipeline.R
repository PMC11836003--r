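#' Analyze one synthetic subject end to end
#'
#' Runs the APTw chain on the subject's CEST stack and the perfusion chain
#' on its DSC series, extracts region statistics and normalizes them to
#' NAWM. The arterial tube is used as the AIF seed region and, together with
#' the enhancing tumor, excluded from the leakage reference curve.
#'
#' @param subj One element of a [generate_cohort()] result.
#' @param cfg An [aptw_config()].
#' @param svd_threshold Deconvolution truncation threshold.
#' @return Tibble of normalized statistics with `subject` and `group`.
#' @export
analyze_subject <- function(subj, cfg = aptw_config(), svd_threshold = 0.15) {
  labels <- subj$labels
  maps <- list()
  if (!is.null(subj$cest)) {
    am <- compute_aptw_maps(subj$cest$cest_4d, subj$cest$s0, labels > 0,
                            offsets = subj$cest$offsets, cfg = cfg)
    maps$APTw <- am$aptw
    maps$APTw_FS <- am$aptw_fs
  }
  if (!is.null(subj$dsc)) {
    series <- dsc_series(subj$dsc$dsc_4d,
                         baseline_window = subj$dsc$baseline_window)
    enh <- labels %in% phantom_labels[c("et", "et_hot", "artery")]
    dim(enh) <- dim(labels)
    art <- labels == phantom_labels[["artery"]]
    pm <- compute_perfusion_maps(series, labels > 0, enhancing_mask = enh,
                                 aif_mask = art,
                                 svd_threshold = svd_threshold)
    maps$CBF <- pm$cbf
    maps$CBV <- pm$cbv
    maps$cCBV <- pm$ccbv
    maps$K2 <- pm$k2
    maps$MTT <- pm$mtt
  }
  st <- subject_stats(maps, labels)
  dplyr::mutate(st, subject = subj$id, group = subj$group, .before = 1)
}

#' Run a full synthetic two-group study
#'
#' Generates a seeded cohort, analyzes every subject, and assembles the
#' cohort report tables.
#'
#' @inheritParams generate_cohort
#' @param svd_threshold Deconvolution truncation threshold.
#' @return List with `stats` (per-subject normalized statistics) and
#'   `report` (see [cohort_report()]).
#' @export
run_synthetic_study <- function(n_gbm = 10, n_met = 8,
                                config = effect_config(), seed = 1,
                                shape = c(64, 64, 24),
                                svd_threshold = 0.15) {
  groups <- c(rep("gbm", n_gbm), rep("met", n_met))
  base_seed <- (as.integer(seed) %% 1000000L) * 1000L
  # generate and analyze subject-by-subject to bound memory
  stats <- purrr::map_dfr(seq_along(groups), function(i) {
    truth <- sample_subject_truth(groups[i], config, seed = base_seed + i)
    labels <- build_phantom(shape, with_necrosis = truth$has_necrosis,
                            with_edema = truth$has_edema)
    subj <- list(id = sprintf("S%02d", i), group = groups[i], truth = truth,
                 labels = labels)
    subj$cest <- generate_cest(truth, labels, noise_sd = config$noise_sd_cest,
                               b0_amp = config$b0_amp,
                               seed = base_seed + i + 500L)
    subj$dsc <- generate_dsc(truth, labels, noise_sd = config$noise_sd_dsc,
                             seed = base_seed + i + 700L)
    analyze_subject(subj, svd_threshold = svd_threshold)
  })
  list(stats = stats, report = cohort_report(stats))
}

#' False-positive calibration of the cohort pipeline
#'
#' Repeatedly generates reduced null cohorts (zero between-group effect,
#' noise on), runs the CEST arm of the pipeline, and tests ET nAPTw max
#' between the groups with [mann_whitney()]. Under the null the rejection
#' rate at level `alpha` should match `alpha` up to the discreteness of the
#' exact test. Uses the spectrum-bank fast path: tissue Z-spectra are
#' linearly interpolated over amide fraction from a per-tissue simulated
#' grid (see the methods vignette for the approximation error bound).
#'
#' @param n_cohorts Number of replicate cohorts (>= 500 recommended).
#' @param n_gbm,n_met Subjects per group in each reduced cohort.
#' @param shape Reduced phantom shape.
#' @param alpha Test level.
#' @param seed Master seed.
#' @return List with `rejection_rate`, `p_values`, `n_cohorts`.
#' @export
calibrate_null_rejection <- function(n_cohorts = 500, n_gbm = 10, n_met = 8,
                                     shape = c(32, 32, 16), alpha = 0.05,
                                     seed = 1) {
  config <- effect_config(null_effect = TRUE)
  bank <- new.env()
  g <- config$gbm
  base <- tissue_base()
  af_range <- function(tiss, lo, hi) {
    row <- base[base$name == tiss, ]
    rng <- amide_fraction_for(row$apt_c0, row$apt_c1, row$apt_c2, c(lo, hi))
    seq(rng[1], rng[2], length.out = 4)
  }
  attr(bank, "af_grid") <- list(
    et = af_range("et", 0.3, g$aptw_et["mean"] + 5 * g$aptw_et["sd"]),
    et_hot = af_range("et", 1.0, g$aptw_hot["mean"] + 5 * g$aptw_hot["sd"])
  )
  pvals <- vapply(seq_len(n_cohorts), function(r) {
    groups <- c(rep("gbm", n_gbm), rep("met", n_met))
    vals <- vapply(seq_along(groups), function(i) {
      # distinct sub-2^31 seed per (master, cohort, subject)
      s <- as.integer((as.integer(seed) %% 1000L) * 2e6 + r * 2000 + i * 20)
      truth <- sample_subject_truth(groups[i], config, seed = s)
      labels <- build_phantom(shape, with_necrosis = truth$has_necrosis,
                              with_edema = truth$has_edema)
      cest <- generate_cest(truth, labels, noise_sd = config$noise_sd_cest,
                            b0_amp = config$b0_amp, seed = s + 7L,
                            bank = bank)
      roi <- labels
      keep <- roi %in% phantom_labels[c("nawm", "et", "et_hot")]
      dim(keep) <- dim(roi)
      am <- compute_aptw_maps(cest$cest_4d, cest$s0, keep,
                              offsets = cest$offsets)
      st <- extract_region_stats(am$aptw, labels, "APTw")
      st$max[st$region == "ET"] / st$mean[st$region == "NAWM"]
    }, numeric(1))
    mann_whitney(vals[groups == "gbm"], vals[groups == "met"])$p
  }, numeric(1))
  list(rejection_rate = mean(pvals < alpha), p_values = pvals,
       n_cohorts = n_cohorts)
}
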