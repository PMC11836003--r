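#' DSC-MRI time series
#'
#' Container for a dynamic susceptibility contrast acquisition: the 4D signal,
#' the repetition and echo times, and the pre-bolus baseline window.
#'
#' @param signal 4D array (x, y, z, t), non-negative.
#' @param tr Repetition time, s (default 1.243).
#' @param te Echo time, s (default 0.029).
#' @param baseline_window Integer indices of pre-bolus frames; `NULL` to
#'   detect the bolus arrival from the whole-volume mean signal
#'   (see [detect_baseline()]).
#' @return A `dsc_series` object.
#' @export
dsc_series <- function(signal, tr = 1.243, te = 0.029, baseline_window = NULL) {
  stopifnot(length(dim(signal)) == 4, te > 0, tr > 0)
  structure(list(signal = signal, tr = tr, te = te,
                 baseline_window = baseline_window),
            class = "dsc_series")
}

#' Detect the pre-bolus baseline window
#'
#' Tracks the running mean and standard deviation of a mean-signal curve and
#' returns the frames before the first frame that drops more than
#' `n_sd` running standard deviations below the running baseline mean
#' (the bolus arrival).
#'
#' @param mean_signal Whole-volume (or ROI) mean signal per frame.
#' @param n_sd Drop threshold in baseline standard deviations (default 3).
#' @param min_frames Minimum number of baseline frames assumed bolus-free.
#' @return Integer vector of baseline frame indices.
#' @export
detect_baseline <- function(mean_signal, n_sd = 3, min_frames = 5) {
  n <- length(mean_signal)
  for (j in (min_frames + 1):n) {
    mu <- mean(mean_signal[1:(j - 1)])
    s <- max(sd(mean_signal[1:(j - 1)]), 1e-6 * mu)
    if (mean_signal[j] < mu - n_sd * s) return(seq_len(j - 1))
  }
  warn("no bolus arrival detected; using first half of the series as baseline")
  seq_len(floor(n / 2))
}

#' Convert a signal time course to relative concentration
#'
#' Standard tracer-kinetic conversion for T2*-weighted dynamic imaging:
#' `c(t) = -ln(S(t)/S_pre) / TE`, with `S_pre` the mean over the baseline
#' window. The result (Delta R2*, 1/s) is proportional to contrast-agent
#' concentration.
#'
#' @param signal Numeric vector, one voxel's time course (or a T x V matrix,
#'   one column per voxel).
#' @param baseline_window Indices of pre-bolus frames.
#' @param te Echo time, s.
#' @return Concentration values, same shape as `signal`; `NA` where
#'   `S(t) <= 0`, all-`NA` for a voxel with non-positive baseline.
#' @export
signal_to_conc <- function(signal, baseline_window, te) {
  if (is.matrix(signal)) {
    s_pre <- colMeans(signal[baseline_window, , drop = FALSE])
    rat <- sweep(signal, 2, s_pre, "/")
    rat[signal <= 0] <- NA_real_         # signal voids
    c_mat <- -log(rat) / te
    c_mat[, !is.finite(s_pre) | s_pre <= 0] <- NA_real_
    return(c_mat)
  }
  s_pre <- mean(signal[baseline_window])
  if (!is.finite(s_pre) || s_pre <= 0) return(rep(NA_real_, length(signal)))
  rat <- signal / s_pre
  rat[signal <= 0] <- NA_real_
  -log(rat) / te
}

cumtrapz_vec <- function(t, y) {
  c(0, cumsum(diff(t) * (head(y, -1) + y[-1]) / 2))
}

trapz_vec <- function(t, y) sum(diff(t) * (head(y, -1) + y[-1]) / 2)

#' Semi-automatic arterial input function selection
#'
#' Ranks candidate voxels by a composite score favouring high peak
#' concentration, early bolus arrival and low first moment, then averages the
#' top `n_top` concentration-time curves into the AIF.
#'
#' @param conc T x V matrix of concentration-time curves (columns = voxels).
#' @param t Time axis, s.
#' @param n_top Number of top-ranked curves to average (default 10).
#' @param weights Score weights for (peak, arrival, first moment).
#' @return An `aif` object: list with `t`, `c` and `n_voxels`.
#' @export
select_aif <- function(conc, t, n_top = 10,
                       weights = c(peak = 0.5, arrival = 0.25, moment = 0.25)) {
  ok <- colSums(!is.finite(conc)) == 0
  if (sum(ok) < 1) abort("no finite candidate curves; supply a manual seed region")
  conc <- conc[, ok, drop = FALSE]
  peak <- apply(conc, 2, max)
  # sanity screen: a real bolus peak stands clear of baseline fluctuation
  noise <- apply(conc[seq_len(max(3, floor(nrow(conc) / 10))), , drop = FALSE], 2, sd)
  pass <- peak > pmax(5 * noise, 1e-12) & peak > 0
  if (!any(pass)) abort("no candidate passes the AIF sanity screens; supply a manual seed region")
  conc <- conc[, pass, drop = FALSE]; peak <- peak[pass]
  arrival <- apply(conc, 2, function(cc) which(cc >= 0.1 * max(cc))[1])
  cpos <- pmax(conc, 0)
  moment <- colSums(cpos * t) / pmax(colSums(cpos), 1e-12)
  score <- weights[1] * rank(peak) + weights[2] * rank(-arrival) +
    weights[3] * rank(-moment)
  top <- order(score, decreasing = TRUE)[seq_len(min(n_top, ncol(conc)))]
  structure(list(t = t, c = rowMeans(conc[, top, drop = FALSE]),
                 n_voxels = length(top)),
            class = "aif")
}

#' @export
print.aif <- function(x, ...) {
  cat(sprintf("<aif: %d frames, peak %.3g at t = %.1f s, from %d voxels>\n",
              length(x$t), max(x$c), x$t[which.max(x$c)], x$n_voxels))
  invisible(x)
}

#' Model-based leakage correction of a concentration-time curve
#'
#' Fits the two-parameter linear leakage model
#' `c(t) ~ K1 * ref(t) - K2 * integral_0^t ref(tau) dtau`
#' by least squares against a non-enhancing reference curve, and returns the
#' corrected curve `c(t) + K2 * integral ref`. A positive K2 corresponds to
#' extravasation depressing the measured curve; K2 is reported in 1/min.
#'
#' @param t Time axis, s.
#' @param curve Voxel concentration-time curve (1/s).
#' @param ref Reference curve: average over non-enhancing brain (1/s).
#' @return List with `k1` (dimensionless), `k2` (1/min), `corrected` (curve).
#' @export
leakage_correct <- function(t, curve, ref) {
  cum_ref <- cumtrapz_vec(t, ref)
  if (sum(ref^2) <= 0) abort("degenerate reference curve (zero energy)")
  X <- cbind(ref, -cum_ref)
  fit <- lm.fit(X, curve)
  k1 <- unname(coef(fit)[1])
  k2_s <- unname(coef(fit)[2])      # 1/s
  list(k1 = k1, k2 = k2_s * 60, corrected = curve + k2_s * cum_ref)
}

#' Relative cerebral blood volume of a voxel curve
#'
#' Ratio of the time integrals of the voxel concentration curve and the AIF.
#' Applied to a leakage-corrected curve this yields cCBV.
#'
#' @param t Time axis, s.
#' @param curve Voxel concentration-time curve.
#' @param aif An [select_aif()] result or a numeric AIF curve on `t`.
#' @return Relative blood volume (dimensionless).
#' @export
cbv <- function(t, curve, aif) {
  ac <- if (inherits(aif, "aif")) aif$c else aif
  ia <- trapz_vec(t, ac)
  if (ia <= 0) abort("AIF integral must be positive")
  trapz_vec(t, curve) / ia
}

# Truncated pseudo-inverse of the block-circulant AIF convolution matrix,
# zero-padded to 2N (delay-insensitive cSVD). Shared by all voxels.
circulant_svd_inverse <- function(aif_c, tr, threshold) {
  n <- length(aif_c)
  L <- 2 * n
  pad <- c(aif_c, rep(0, n))
  idx <- outer(seq_len(L), seq_len(L), function(i, j) ((i - j) %% L) + 1L)
  D <- matrix(pad[idx], L, L) * tr
  sv <- svd(D)
  keep <- sv$d >= threshold * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

#' Deconvolve a tissue curve against the AIF for CBF
#'
#' Builds the block-circulant convolution matrix of the AIF (zero-padded to
#' twice the series length, making the estimate insensitive to bolus arrival
#' delay), applies truncated singular value decomposition with singular
#' values below `threshold` times the maximum zeroed, and recovers the
#' flow-scaled residue function. CBF is its maximum; MTT = CBV/CBF.
#'
#' @param t Time axis, s (uniform spacing `tr`).
#' @param curve Voxel concentration-time curve.
#' @param aif An [select_aif()] result or numeric AIF curve.
#' @param tr Frame spacing, s.
#' @param threshold Relative singular-value cutoff (default 0.15).
#' @return List with `cbf` (relative flow, 1/s), `mtt` (s) and `residue`
#'   (the flow-scaled residue function, length 2N).
#' @export
deconvolve_cbf <- function(t, curve, aif, tr, threshold = 0.15) {
  ac <- if (inherits(aif, "aif")) aif$c else aif
  if (all(ac == 0)) abort("AIF is identically zero")
  Dinv <- circulant_svd_inverse(ac, tr, threshold)
  r <- as.vector(Dinv %*% c(curve, rep(0, length(curve))))
  cbf_v <- max(r)
  v <- cbv(t, curve, ac)
  list(cbf = cbf_v, mtt = if (cbf_v > 0) v / cbf_v else NA_real_, residue = r)
}

#' Voxelwise perfusion quantification of a DSC series
#'
#' Full chain: tracer-kinetic conversion, AIF selection, per-voxel linear
#' leakage correction against the non-enhancing brain reference, CBV/cCBV/K2,
#' and delay-insensitive circulant-SVD deconvolution for CBF and MTT. The
#' per-voxel stages are algebraically identical to [leakage_correct()],
#' [cbv()] and [deconvolve_cbf()] but batched: the leakage design matrix and
#' the truncated SVD inverse are shared by all voxels.
#'
#' @param series A [dsc_series()].
#' @param brain_mask 3D logical/0-1 array of brain voxels.
#' @param enhancing_mask Optional 3D mask of contrast-enhancing voxels,
#'   excluded from the leakage reference curve.
#' @param aif_mask Optional 3D mask restricting AIF candidate voxels (e.g. an
#'   arterial seed region); default: all brain voxels.
#' @param svd_threshold Relative singular-value cutoff for deconvolution.
#' @return A `perfusion_maps` object: 3D arrays `cbf`, `cbv`, `ccbv`, `k2`
#'   (1/min), `mtt` (s), plus the `aif`, the reference curve `ref`, the time
#'   axis `t` and the baseline window.
#' @export
compute_perfusion_maps <- function(series, brain_mask, enhancing_mask = NULL,
                                   aif_mask = NULL, svd_threshold = 0.15) {
  stopifnot(inherits(series, "dsc_series"))
  dm <- dim(series$signal)
  if (!all(dm[1:3] == dim(brain_mask))) abort("mask shape mismatch")
  nt <- dm[4]
  t <- (seq_len(nt) - 1) * series$tr

  vox <- which(as.logical(brain_mask))
  sig <- t(matrix(series$signal, ncol = nt)[vox, , drop = FALSE])  # T x V

  bw <- series$baseline_window
  if (is.null(bw)) bw <- detect_baseline(rowMeans(sig))
  conc <- signal_to_conc(sig, bw, series$te)

  ok <- colSums(!is.finite(conc)) == 0
  # AIF from candidate voxels
  cand <- if (is.null(aif_mask)) ok else ok & as.logical(aif_mask)[vox]
  aif <- select_aif(conc[, cand, drop = FALSE], t)

  # reference: mean over non-enhancing brain
  ref_sel <- ok
  if (!is.null(enhancing_mask)) ref_sel <- ref_sel & !as.logical(enhancing_mask)[vox]
  if (!any(ref_sel)) abort("no voxels available for the leakage reference curve")
  ref <- rowMeans(conc[, ref_sel, drop = FALSE])

  # batched leakage fit: same design matrix for every voxel
  cum_ref <- cumtrapz_vec(t, ref)
  X <- cbind(ref, -cum_ref)
  XtXinv <- solve(crossprod(X))
  conc_ok <- conc[, ok, drop = FALSE]
  B <- XtXinv %*% crossprod(X, conc_ok)           # 2 x V
  k2_s <- B[2, ]
  corrected <- conc_ok + outer(cum_ref, k2_s)

  # integral ratios
  w <- trapz_weights(t)
  ia <- sum(w * aif$c)
  cbv_v <- colSums(w * conc_ok) / ia
  ccbv_v <- colSums(w * corrected) / ia

  # batched circulant-SVD deconvolution
  Dinv <- circulant_svd_inverse(aif$c, series$tr, svd_threshold)
  R <- Dinv %*% rbind(conc_ok, matrix(0, nt, ncol(conc_ok)))
  tR <- t(R)
  cbf_v <- tR[cbind(seq_len(nrow(tR)), max.col(tR, ties.method = "first"))]
  mtt_v <- ifelse(cbf_v > 0, cbv_v / cbf_v, NA_real_)

  mk_map <- function(values) {
    m <- array(NA_real_, dm[1:3]); m[vox[ok]] <- values; m
  }
  structure(list(cbf = mk_map(cbf_v), cbv = mk_map(cbv_v),
                 ccbv = mk_map(ccbv_v), k2 = mk_map(k2_s * 60),
                 mtt = mk_map(mtt_v), aif = aif, ref = ref, t = t,
                 baseline_window = bw),
            class = "perfusion_maps")
}

trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2; w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  w
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("<perfusion_maps: %s, %d voxels, AIF peak %.3g>\n",
              paste(dim(x$cbf), collapse = "x"), sum(is.finite(x$cbv)),
              max(x$aif$c)))
  invisible(x)
}

#' @export
autoplot.aif <- function(object, ...) {
  df <- tibble::tibble(t = object$t, c = object$c)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$c)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * R2 * "* (1/s)"),
                  title = "Arterial input function") +
    ggplot2::theme_minimal()
}
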