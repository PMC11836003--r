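#' Voxelwise APTw map computation
#'
#' Applies the per-voxel processing chain (normalization, B0 correction,
#' asymmetry integration, fluid suppression) to a 4D CEST stack. The chain is
#' identical to composing [normalize_zspectrum()], [b0_correct()], [aptw()]
#' and [fluid_suppress()] voxel by voxel, but vectorized across voxels:
#' after B0 correction by `-delta`, integrating the shifted interpolant over
#' `[dw1, dw2]` equals integrating the original interpolant over
#' `[dw1 + delta, dw2 + delta]`, so all voxels share one knot grid.
#'
#' @param cest_4d 4D array (x, y, z, offset), one volume per saturation
#'   offset, in acquisition intensity units.
#' @param s0_vol 3D array, the unsaturated reference volume.
#' @param mask 3D logical/0-1 array selecting brain voxels.
#' @param offsets Saturation offsets (ppm) for the 4th dimension, ascending.
#' @param cfg An [aptw_config()].
#' @return An `aptw_maps` object: list with 3D arrays `aptw` (percent),
#'   `aptw_fs` (percent), `b0` (ppm) and `valid` (logical). Voxels outside
#'   the mask, with non-positive S0, or with no interior spectral minimum
#'   carry `NA`.
#' @export
compute_aptw_maps <- function(cest_4d, s0_vol, mask, offsets = seq(-5, 5, 0.5),
                              cfg = aptw_config()) {
  dm <- dim(cest_4d)
  if (length(dm) != 4 || dm[4] != length(offsets)) {
    abort("cest_4d must be 4D with one volume per offset")
  }
  if (!all(dm[1:3] == dim(s0_vol)) || !all(dm[1:3] == dim(mask))) {
    abort("cest_4d, s0_vol and mask shapes disagree")
  }
  n_off <- length(offsets)
  nv <- prod(dm[1:3])

  out <- list(
    aptw = array(NA_real_, dm[1:3]), aptw_fs = array(NA_real_, dm[1:3]),
    b0 = array(NA_real_, dm[1:3]), valid = array(FALSE, dm[1:3])
  )

  vox <- which(as.logical(mask) & is.finite(s0_vol) & s0_vol > 0)
  if (length(vox) == 0) return(structure(out, class = "aptw_maps"))

  cest <- matrix(cest_4d, nrow = nv, ncol = n_off)[vox, , drop = FALSE]
  z <- cest / s0_vol[vox]
  ok <- rowSums(!is.finite(z) | z < 0) == 0
  vox <- vox[ok]; z <- z[ok, , drop = FALSE]
  if (length(vox) == 0) return(structure(out, class = "aptw_maps"))

  # --- B0: parabolic sub-sample minimum per voxel -------------------------
  m <- max.col(-z, ties.method = "first")
  mx <- max.col(z, ties.method = "first")
  i0 <- seq_len(nrow(z))
  interior <- m > 1L & m < n_off &
    (z[cbind(i0, mx)] - z[cbind(i0, m)]) > 1e-9
  i <- seq_along(vox)
  zl <- z[cbind(i, pmax(m - 1L, 1L))]
  zm <- z[cbind(i, m)]
  zr <- z[cbind(i, pmin(m + 1L, n_off))]
  d2 <- zl - 2 * zm + zr
  usable <- interior & d2 > 1e-9
  xl <- offsets[pmax(m - 1L, 1L)]; xm <- offsets[m]; xr <- offsets[pmin(m + 1L, n_off)]
  denom <- (xl - xm) * (xl - xr) * (xm - xr)
  a2 <- (xr * (zm - zl) + xm * (zl - zr) + xl * (zr - zm)) / denom
  b1 <- (xr^2 * (zl - zm) + xm^2 * (zr - zl) + xl^2 * (zm - zr)) / denom
  delta <- ifelse(usable, -b1 / (2 * a2), NA_real_)
  delta <- pmax(pmin(delta, 1), -1)

  keep <- !is.na(delta)
  vox <- vox[keep]; z <- z[keep, , drop = FALSE]; delta <- delta[keep]
  if (length(vox) == 0) return(structure(out, class = "aptw_maps"))

  # --- asymmetry integral with per-voxel shifted bounds -------------------
  neg <- integrate_linear_rows(offsets, z, -cfg$delta_omega_2 + delta,
                               -cfg$delta_omega_1 + delta)
  pos <- integrate_linear_rows(offsets, z, cfg$delta_omega_1 + delta,
                               cfg$delta_omega_2 + delta)
  aptw_v <- 100 * (neg - pos) / (cfg$delta_omega_2 - cfg$delta_omega_1)

  # --- fluid suppression ---------------------------------------------------
  zref <- interp_rows(offsets, z, cfg$ref_offset + delta)
  fs_v <- ifelse(zref > 0, aptw_v * cfg$sigma_wm^2 / zref^2, NA_real_)

  out$aptw[vox] <- aptw_v
  out$aptw_fs[vox] <- fs_v
  out$b0[vox] <- delta
  out$valid[vox] <- TRUE
  structure(out, class = "aptw_maps")
}

#' @export
print.aptw_maps <- function(x, ...) {
  cat(sprintf("<aptw_maps: %s, %d valid voxels>\n",
              paste(dim(x$aptw), collapse = "x"), sum(x$valid)))
  invisible(x)
}

# Row-wise exact integral of the piecewise-linear interpolant of (x, Z[v, ])
# over per-voxel bounds [a[v], b[v]]. All rows share the knot grid x.
integrate_linear_rows <- function(x, z, a, b) {
  n <- length(x)
  stopifnot(all(a >= x[1]), all(b <= x[n]), all(a <= b))
  # cumulative trapezoid per row, computed column-wise (few columns)
  seg <- (z[, -n, drop = FALSE] + z[, -1, drop = FALSE]) / 2 *
    rep(diff(x), each = nrow(z))
  ct <- matrix(0, nrow(z), n)
  for (k in 2:n) ct[, k] <- ct[, k - 1] + seg[, k - 1]
  val_at <- function(q) {
    j <- pmin(findInterval(q, x), n - 1L)
    i <- seq_len(nrow(z))
    zj <- z[cbind(i, j)]; zj1 <- z[cbind(i, j + 1L)]
    yq <- zj + (zj1 - zj) * (q - x[j]) / (x[j + 1] - x[j])
    ct[cbind(i, j)] + (q - x[j]) * (zj + yq) / 2
  }
  val_at(b) - val_at(a)
}

# Row-wise linear interpolation of (x, Z[v, ]) at per-voxel points q[v].
interp_rows <- function(x, z, q) {
  n <- length(x)
  j <- pmin(findInterval(q, x), n - 1L)
  i <- seq_len(nrow(z))
  zj <- z[cbind(i, j)]; zj1 <- z[cbind(i, j + 1L)]
  zj + (zj1 - zj) * (q - x[j]) / (x[j + 1] - x[j])
}
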