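#' Z-spectrum object
#'
#' A per-voxel normalized saturation profile: dimensionless intensities
#' `z = S_sat/S0` on a strictly increasing axis of saturation offsets (ppm).
#'
#' @param offsets Saturation offsets, ppm, strictly increasing.
#' @param z Normalized intensities, same length as `offsets`.
#' @param b0_shift Field-offset shift already applied, ppm (0 before
#'   correction).
#' @param valid Logical; `FALSE` marks a voxel excluded from maps (e.g.
#'   non-positive S0).
#' @param uncorrectable Logical; set by [b0_correct()] when no interior
#'   spectral minimum exists.
#' @return An object of class `zspectrum`.
#' @export
new_zspectrum <- function(offsets, z, b0_shift = 0, valid = TRUE,
                          uncorrectable = FALSE) {
  if (valid) {
    stopifnot(length(offsets) == length(z),
              !is.unsorted(offsets, strictly = TRUE),
              all(is.finite(z)), all(z >= 0))
  }
  structure(list(offsets = as.numeric(offsets), z = as.numeric(z),
                 b0_shift = b0_shift, valid = valid,
                 uncorrectable = uncorrectable),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum: %d offsets [%g, %g] ppm, b0_shift = %.3g ppm%s>\n",
              length(x$offsets), min(x$offsets), max(x$offsets), x$b0_shift,
              if (!x$valid) ", INVALID" else ""))
  invisible(x)
}

#' Normalize saturated intensities into a Z-spectrum
#'
#' Divides the water signal at each saturation offset by the unsaturated
#' reference intensity S0.
#'
#' @param offsets Saturation offsets, ppm.
#' @param s_sat Saturated intensities, one per offset; finite, non-negative.
#' @param s0 Unsaturated reference intensity (scalar).
#' @return A [new_zspectrum()] with `b0_shift = 0`. A non-positive or
#'   non-finite `s0` yields an invalid spectrum rather than an error, so map
#'   level code can skip the voxel.
#' @export
normalize_zspectrum <- function(offsets, s_sat, s0) {
  if (!is.finite(s0) || s0 <= 0 || any(!is.finite(s_sat)) || any(s_sat < 0)) {
    return(new_zspectrum(offsets, rep(NA_real_, length(offsets)),
                         valid = FALSE))
  }
  new_zspectrum(offsets, s_sat / s0)
}

# Sub-sample location of the spectral minimum: parabola through the discrete
# minimum and its two neighbours. Returns NA when the minimum sits on the
# axis boundary or the spectrum is flat within `flat_tol`.
locate_minimum <- function(offsets, z, flat_tol = 1e-9) {
  if (diff(range(z)) < flat_tol) return(NA_real_)
  m <- which.min(z)
  if (m == 1L || m == length(z)) return(NA_real_)
  d2 <- z[m - 1] - 2 * z[m] + z[m + 1]
  if (d2 <= flat_tol) return(offsets[m])
  # vertex of the parabola through the three points (uniform or not)
  x <- offsets[(m - 1):(m + 1)]
  y <- z[(m - 1):(m + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  -b / (2 * a)
}

#' B0-correct a Z-spectrum
#'
#' Shifts the spectrum so its minimum (the direct water saturation dip) lies
#' at 0 ppm. The sub-sample minimum location `delta` is found by fitting a
#' parabola to the discrete minimum and its two neighbours; the offset axis
#' is shifted by `-delta` and `delta` is recorded in `b0_shift`. Shifts are
#' clamped to +/-1 ppm; a flat spectrum or a minimum at the axis boundary
#' leaves the spectrum unshifted and flags it `uncorrectable`.
#'
#' @param spec A [new_zspectrum()] with at least 5 offsets.
#' @return The corrected `zspectrum` (z values unchanged).
#' @export
b0_correct <- function(spec) {
  stopifnot(inherits(spec, "zspectrum"))
  if (!spec$valid) return(spec)
  if (length(spec$offsets) < 5) abort("need >= 5 offsets for B0 correction")
  delta <- locate_minimum(spec$offsets, spec$z)
  if (is.na(delta)) {
    return(new_zspectrum(spec$offsets, spec$z, b0_shift = 0,
                         uncorrectable = TRUE))
  }
  delta <- max(min(delta, 1), -1)
  new_zspectrum(spec$offsets - delta, spec$z, b0_shift = delta)
}

#' Interpolate a Z-spectrum at an arbitrary offset
#'
#' Piecewise-linear interpolation between the two bracketing knots; exact at
#' knots; no extrapolation.
#'
#' @param spec A [new_zspectrum()].
#' @param omega Query offset, ppm, inside the offset range.
#' @return Interpolated dimensionless intensity.
#' @export
interp_z <- function(spec, omega) {
  stopifnot(inherits(spec, "zspectrum"))
  if (any(omega < min(spec$offsets)) || any(omega > max(spec$offsets))) {
    abort("interpolation offset outside the sampled range")
  }
  approx(spec$offsets, spec$z, xout = omega, method = "linear")$y
}

# Exact integral of the piecewise-linear interpolant of (x, y) over [a, b],
# including partial end segments (analytic trapezoid on each piece).
integrate_linear <- function(x, y, a, b) {
  stopifnot(a <= b, a >= x[1], b >= x[1], a <= x[length(x)], b <= x[length(x)])
  ct <- c(0, cumsum(diff(x) * (head(y, -1) + y[-1]) / 2))
  val_at <- function(q) {
    jj <- pmin(findInterval(q, x), length(x) - 1)
    yq <- y[jj] + (y[jj + 1] - y[jj]) * (q - x[jj]) / (x[jj + 1] - x[jj])
    ct[jj] + (q - x[jj]) * (y[jj] + yq) / 2
  }
  val_at(b) - val_at(a)
}

#' APTw configuration
#'
#' Integration bounds of the asymmetry metric, the fluid-suppression
#' reference offset and the white-matter correction factor.
#'
#' @param delta_omega_1,delta_omega_2 Lower/upper integration bounds, ppm
#'   (defaults 3.1 and 3.9, bracketing the amide resonance at +3.5 ppm).
#' @param ref_offset Offset of the fluid-suppression reference intensity
#'   `Z_ref`, ppm (default -3.5).
#' @param sigma_wm White-matter fluid-suppression factor, dimensionless in
#'   (0, 1] (default 0.4; see [derive_sigma_wm()]).
#' @return An object of class `aptw_config`.
#' @export
aptw_config <- function(delta_omega_1 = 3.1, delta_omega_2 = 3.9,
                        ref_offset = -3.5, sigma_wm = 0.4) {
  stopifnot(0 < delta_omega_1, delta_omega_1 < delta_omega_2,
            sigma_wm > 0, sigma_wm <= 1)
  structure(list(delta_omega_1 = delta_omega_1, delta_omega_2 = delta_omega_2,
                 ref_offset = ref_offset, sigma_wm = sigma_wm),
            class = "aptw_config")
}

#' APTw asymmetry metric (percent)
#'
#' The integral asymmetry of the linear-interpolated Z-spectrum between the
#' offset boundaries `[delta_omega_1, delta_omega_2]`:
#' `100 * (int_{-dw2}^{-dw1} Z - int_{dw1}^{dw2} Z) / (dw2 - dw1)`.
#' Integrals are computed exactly over the piecewise-linear interpolant,
#' including partial end segments when the bounds fall between knots.
#'
#' @param spec A B0-corrected [new_zspectrum()].
#' @param cfg An [aptw_config()].
#' @return APTw in percent (`NA` for an invalid spectrum).
#' @export
aptw <- function(spec, cfg = aptw_config()) {
  stopifnot(inherits(spec, "zspectrum"))
  if (!spec$valid) return(NA_real_)
  lo <- min(spec$offsets); hi <- max(spec$offsets)
  if (-cfg$delta_omega_2 < lo || cfg$delta_omega_2 > hi) {
    abort("integration bounds outside the sampled offset range")
  }
  neg <- integrate_linear(spec$offsets, spec$z,
                          -cfg$delta_omega_2, -cfg$delta_omega_1)
  pos <- integrate_linear(spec$offsets, spec$z,
                          cfg$delta_omega_1, cfg$delta_omega_2)
  100 * (neg - pos) / (cfg$delta_omega_2 - cfg$delta_omega_1)
}

#' Fluid-suppress an APTw value (percent)
#'
#' Down-weights long-T2 fluid compartments (CSF, liquefactive necrosis) by
#' `APTw_FS = APTw * sigma_wm^2 / Z_ref^2`, where `Z_ref` is the spectral
#' intensity at the reference offset (-3.5 ppm). Fluids have a narrow direct
#' saturation dip, hence a `Z_ref` above the white-matter factor and an
#' attenuated APTw_FS.
#'
#' @param aptw_value APTw in percent.
#' @param z_ref Spectral intensity at the reference offset; must be > 0.
#' @param cfg An [aptw_config()].
#' @return APTw_FS in percent (`NA` when `z_ref <= 0`).
#' @export
fluid_suppress <- function(aptw_value, z_ref, cfg = aptw_config()) {
  out <- aptw_value * cfg$sigma_wm^2 / z_ref^2
  out[rep_len(!(is.finite(z_ref) & z_ref > 0), length(out))] <- NA_real_
  out
}

#' @describeIn fluid_suppress Convenience: read `Z_ref` off a B0-corrected
#'   spectrum at `cfg$ref_offset` and apply the suppression to its APTw.
#' @param spec A B0-corrected [new_zspectrum()].
#' @export
aptw_fs <- function(spec, cfg = aptw_config()) {
  fluid_suppress(aptw(spec, cfg), interp_z(spec, cfg$ref_offset), cfg)
}

#' @export
autoplot.zspectrum <- function(object, ...) {
  df <- tibble::tibble(offset = object$offsets, z = object$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$z)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "saturation offset (ppm)", y = "Z = S_sat / S0") +
    ggplot2::theme_minimal()
}
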