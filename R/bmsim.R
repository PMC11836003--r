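#' Define an exchanging proton pool
#'
#' A pool is described by its relaxation times, its proton fraction relative
#' to water, its exchange rate with water, and its chemical shift. The water
#' pool has `fraction = 1`, `exchange_rate = 0`, `chemical_shift = 0`.
#'
#' @param name Label, e.g. `"water"`, `"mt"`, `"amide"`.
#' @param t1,t2 Longitudinal / transverse relaxation times in seconds.
#' @param fraction Proton fraction relative to water (water = 1).
#' @param exchange_rate Exchange rate towards water, 1/s.
#' @param chemical_shift Resonance offset from water, ppm.
#' @param lineshape Transverse lineshape used during saturation:
#'   `"lorentzian"` (full Bloch treatment, the default) or
#'   `"superlorentzian"` (absorption-rate treatment for a semisolid pool).
#' @return A one-row tibble; bind rows to build a pool system (water first).
#' @export
#' @examples
#' pools <- dplyr::bind_rows(
#'   pool("water", t1 = 1.084, t2 = 0.069),
#'   pool("amide", t1 = 1.0, t2 = 0.01, fraction = 6.5e-4,
#'        exchange_rate = 30, chemical_shift = 3.5)
#' )
pool <- function(name, t1, t2, fraction = 1, exchange_rate = 0,
                 chemical_shift = 0, lineshape = "lorentzian") {
  stopifnot(t1 > 0, t2 > 0, fraction >= 0, fraction <= 1, exchange_rate >= 0)
  lineshape <- match.arg(lineshape, c("lorentzian", "superlorentzian"))
  tibble::tibble(
    name = name, t1 = t1, t2 = t2, fraction = fraction,
    exchange_rate = exchange_rate, chemical_shift = chemical_shift,
    lineshape = lineshape
  )
}

#' Pulsed saturation module
#'
#' Describes a train of identical off-resonance saturation pulses. The default
#' is the protocol this package models: 5 hyperbolic-secant pulses of 100 ms
#' with 61 ms interpulse delays at a peak B1 of 2 uT on a 3 T system.
#'
#' @param n_pulses Number of pulses in the train.
#' @param pulse_duration Duration of one pulse, s.
#' @param interpulse_delay Free relaxation gap between pulses, s.
#' @param b1 Saturation amplitude, uT; interpreted per `b1_reference`.
#' @param b1_reference How `b1` specifies the pulse amplitude: `"rms_train"`
#'   (default) means `b1` is the root-mean-square amplitude over the whole
#'   train including interpulse gaps -- the standard way APTw saturation
#'   power is reported -- and the envelope peak is scaled up accordingly;
#'   `"peak"` means `b1` is the envelope maximum itself.
#' @param pulse_shape `"hs"` (hyperbolic secant envelope) or `"block"`.
#' @param field_strength Static field, T.
#' @return An object of class `saturation_module`.
#' @export
saturation_module <- function(n_pulses = 5, pulse_duration = 0.100,
                              interpulse_delay = 0.061, b1 = 2,
                              b1_reference = c("rms_train", "peak"),
                              pulse_shape = c("hs", "block"),
                              field_strength = 3) {
  stopifnot(n_pulses >= 1, pulse_duration > 0, interpulse_delay >= 0,
            b1 >= 0, field_strength > 0)
  structure(
    list(n_pulses = as.integer(n_pulses), pulse_duration = pulse_duration,
         interpulse_delay = interpulse_delay, b1 = b1,
         b1_reference = match.arg(b1_reference),
         pulse_shape = match.arg(pulse_shape),
         field_strength = field_strength),
    class = "saturation_module"
  )
}

#' Effective peak B1 amplitude of the pulse envelope (uT)
#'
#' For `b1_reference = "peak"` this is `b1` itself; for `"rms_train"` the
#' envelope maximum is `b1 / sqrt(mean(env^2) * duty)` with the duty cycle of
#' the train, so that the rms amplitude over the full train equals `b1`.
#'
#' @param sat A [saturation_module()].
#' @return Peak amplitude in uT.
#' @export
b1_peak <- function(sat) {
  if (sat$b1_reference == "peak") return(sat$b1)
  env2 <- switch(sat$pulse_shape,
    hs = {
      beta <- acosh(1 / 0.01)
      # mean of sech^2(beta*(2t/tp - 1)) over the pulse = tanh(beta)/beta
      tanh(beta) / beta
    },
    block = 1
  )
  t_on <- sat$n_pulses * sat$pulse_duration
  duty <- t_on / (t_on + (sat$n_pulses - 1) * sat$interpulse_delay)
  sat$b1 / sqrt(env2 * duty)
}

#' Saturation offset sampling plan
#'
#' @param offsets Saturation frequency offsets in ppm. Default: +/-5 ppm in
#'   0.5 ppm steps (21 offsets).
#' @param s0_offset Offset of the unsaturated reference acquisition, ppm;
#'   must be far off-resonance (default -150).
#' @return An object of class `offset_plan`.
#' @export
offset_plan <- function(offsets = seq(-5, 5, by = 0.5), s0_offset = -150) {
  stopifnot(abs(s0_offset) >= 20, !is.unsorted(offsets, strictly = TRUE))
  structure(list(offsets = offsets, s0_offset = s0_offset),
            class = "offset_plan")
}

#' Discretize a saturation pulse into constant-B1 segments
#'
#' The hyperbolic-secant envelope is `sech(beta * (2 t / tp - 1))` with the
#' truncation `beta` chosen so the envelope edge is 1% of peak; the envelope
#' maximum equals `b1_peak`. Frequency is held constant (no sweep): the pulse
#' is used for saturation, not adiabatic inversion.
#'
#' @param sat A [saturation_module()].
#' @param n_segments Number of piecewise-constant segments (>= 1; >= 16 for
#'   simulation use; a single segment degenerates to a block pulse).
#' @return Tibble with `t_mid` (segment midpoints, s), `b1_ut` (uT) and
#'   `w1` (rad/s).
#' @export
discretize_pulse <- function(sat, n_segments = 64) {
  stopifnot(inherits(sat, "saturation_module"), n_segments >= 1)
  dt <- sat$pulse_duration / n_segments
  t_mid <- (seq_len(n_segments) - 0.5) * dt
  env <- switch(sat$pulse_shape,
    hs = {
      beta <- acosh(1 / 0.01)  # edge at 1% of peak
      1 / cosh(beta * (2 * t_mid / sat$pulse_duration - 1))
    },
    block = rep(1, n_segments)
  )
  b1 <- b1_peak(sat) * env / max(env)
  # w1 [rad/s] = 2*pi*gamma[Hz/T] * B1[T]
  tibble::tibble(t_mid = t_mid, b1_ut = b1, w1 = 2 * pi * GAMMA_HZ * 1e-6 * b1)
}

# super-Lorentzian absorption lineshape g(delta) [s]; delta in rad/s relative
# to the pool center, t2 in s. Divergent on resonance: |delta| is floored at
# the value of 1 ppm at 3 T before evaluation (standard cutoff practice).
superlorentzian_g <- function(delta, t2, floor_rad = 2 * pi * GAMMA_HZ * 1e-6 * 3) {
  vapply(pmax(abs(delta), floor_rad), function(d) {
    f <- function(th) {
      u <- abs(3 * cos(th)^2 - 1)
      u <- pmax(u, 1e-8)
      sin(th) * sqrt(2 / pi) * (t2 / u) * exp(-2 * (d * t2 / u)^2)
    }
    stats::integrate(f, 0, pi / 2, rel.tol = 1e-8)$value
  }, numeric(1))
}

# Internal: run the C++ propagator for a set of offsets. Returns water Mz/M0.
# steady_state = TRUE repeats the saturation train (ideal spoiling between
# repetitions) until the end-of-train water Mz converges, emulating the
# pseudo steady state reached when the module is replayed for every
# measurement of a 3D acquisition.
bm_run <- function(pools, sat, offsets_ppm, n_segments = 64,
                   steady_state = FALSE) {
  stopifnot(is.data.frame(pools), nrow(pools) >= 1)
  if (pools$name[1] != "water" || pools$fraction[1] != 1) {
    abort("first pool must be water with fraction 1")
  }
  seg <- discretize_pulse(sat, n_segments)
  ppm2rad <- 2 * pi * GAMMA_HZ * sat$field_strength * 1e-6
  pm <- as.matrix(pools[, c("t1", "t2", "fraction", "exchange_rate",
                            "chemical_shift")])
  sl <- which(pools$lineshape == "superlorentzian")
  if (length(sl) > 1) abort("at most one super-Lorentzian pool is supported")
  if (length(sl) == 1) {
    mt_idx <- sl - 1L
    delta <- (offsets_ppm - pools$chemical_shift[sl]) * ppm2rad
    g <- superlorentzian_g(delta, pools$t2[sl])
  } else {
    mt_idx <- -1L
    g <- numeric(length(offsets_ppm))
  }
  .bm_simulate_offsets(pm, seg$w1, sat$pulse_duration / n_segments,
                       sat$interpulse_delay, sat$n_pulses,
                       as.numeric(offsets_ppm), ppm2rad, mt_idx, g,
                       if (steady_state) 200L else 1L, 0, 1e-6)
}

#' Simulate water magnetization after the saturation train at one offset
#'
#' Integrates the coupled Bloch-McConnell equations through the full pulse
#' train (piecewise matrix-exponential propagation over constant-B1 pulse
#' segments, free relaxation/exchange during interpulse delays with ideal
#' spoiling of transverse coherence), starting from thermal equilibrium.
#'
#' @param pools Pool tibble (water first), see [pool()].
#' @param sat A [saturation_module()].
#' @param offset Saturation offset, ppm.
#' @param n_segments Segments per pulse for the piecewise-constant envelope.
#' @param steady_state If `TRUE`, repeat the train until the end-of-train
#'   water Mz converges (the saturation module is replayed for every
#'   measurement of a 3D readout, so acquisition happens in this pseudo
#'   steady state); if `FALSE` (default), a single train from thermal
#'   equilibrium.
#' @return Water Mz/M0 at the end of the train (dimensionless).
#' @export
simulate_offset <- function(pools, sat, offset, n_segments = 64,
                            steady_state = FALSE) {
  bm_run(pools, sat, offset, n_segments, steady_state)[1]
}

#' Simulate a Z-spectrum
#'
#' Runs [simulate_offset()] at every offset of the plan plus the far
#' off-resonance S0 offset, and returns the ratio as a [new_zspectrum()] object.
#'
#' @inheritParams simulate_offset
#' @param plan An [offset_plan()].
#' @return A `zspectrum` object.
#' @export
simulate_zspectrum <- function(pools, sat, plan = offset_plan(),
                               n_segments = 64, steady_state = FALSE) {
  mz <- bm_run(pools, sat, c(plan$offsets, plan$s0_offset), n_segments,
               steady_state)
  n <- length(plan$offsets)
  # magnitude readout: strong on-resonance saturation can nutate Mz through 0
  new_zspectrum(plan$offsets, abs(mz[seq_len(n)]) / abs(mz[n + 1]))
}

#' Derive the white-matter fluid-suppression factor
#'
#' The fluid-suppression correction factor is defined as the Z-spectrum
#' intensity at -3.5 ppm in white matter under the given saturation scheme.
#' Simulates the WM pool system through the pulse train and reads off
#' Z(-3.5 ppm).
#'
#' @param pools WM pool system (default: the bundled 3 T white-matter set,
#'   [wm_3t_pools()]).
#' @param sat A [saturation_module()].
#' @param plan An [offset_plan()] whose range covers -3.5 ppm.
#' @param n_segments Segments per pulse.
#' @return The dimensionless factor (around 0.4 for the default protocol).
#' @export
derive_sigma_wm <- function(pools = wm_3t_pools(), sat = saturation_module(),
                            plan = offset_plan(), n_segments = 64) {
  spec <- simulate_zspectrum(pools, sat, plan, n_segments, steady_state = TRUE)
  interp_z(spec, -3.5)
}

#' Read a pool system from YAML
#'
#' The schema follows the common Bloch-McConnell simulation layout:
#' `water_pool: {f, t1, t2}`, optional `mt_pool: {f, t1, t2, k, dw, lineshape}`
#' and a named map `cest_pool` of exchanging pools `{f, t1, t2, k, dw}`.
#'
#' @param path YAML file path.
#' @return Pool tibble (water first).
#' @export
read_pools <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$water_pool)) abort("pool file must define `water_pool`")
  wp <- y$water_pool
  out <- pool("water", t1 = wp$t1, t2 = wp$t2)
  if (!is.null(y$mt_pool)) {
    mp <- y$mt_pool
    ls <- tolower(mp$lineshape %||% "lorentzian")
    ls <- if (grepl("super", ls)) "superlorentzian" else "lorentzian"
    out <- dplyr::bind_rows(out, pool("mt", t1 = mp$t1, t2 = mp$t2,
                                      fraction = mp$f, exchange_rate = mp$k,
                                      chemical_shift = mp$dw %||% 0,
                                      lineshape = ls))
  }
  for (nm in names(y$cest_pool)) {
    cp <- y$cest_pool[[nm]]
    out <- dplyr::bind_rows(out, pool(nm, t1 = cp$t1, t2 = cp$t2,
                                      fraction = cp$f, exchange_rate = cp$k,
                                      chemical_shift = cp$dw))
  }
  out
}

#' Bundled 3 T white-matter pool system
#'
#' Water, semisolid MT and amide pools for healthy white matter at 3 T,
#' shipped as a plain-text parameter file mirroring published white-matter
#' Bloch-McConnell values (see the file header for provenance).
#'
#' @return Pool tibble (water first).
#' @export
wm_3t_pools <- function() {
  read_pools(system.file("extdata", "wm_3t_pools.yaml", package = "aptperf",
                         mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
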