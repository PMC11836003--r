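# Independent oracles used across tests. These deliberately avoid the
# package's own numerical paths.

# Midpoint Riemann sum of the linear interpolant of (x, y) over [a, b].
riemann_integral <- function(x, y, a, b, n = 1e5) {
  q <- seq(a, b, length.out = n + 1)
  mid <- (q[-1] + q[-(n + 1)]) / 2
  sum(approx(x, y, xout = mid)$y) * (b - a) / n
}

# Brute-force asymmetry metric via Riemann integration.
riemann_aptw <- function(offsets, z, cfg = aptw_config(), n = 1e5) {
  neg <- riemann_integral(offsets, z, -cfg$delta_omega_2, -cfg$delta_omega_1, n)
  pos <- riemann_integral(offsets, z, cfg$delta_omega_1, cfg$delta_omega_2, n)
  100 * (neg - pos) / (cfg$delta_omega_2 - cfg$delta_omega_1)
}

# Brute-force Mann-Whitney U by pair counting (min of the two orientations).
pair_count_u <- function(a, b) {
  u_a <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  min(u_a, length(a) * length(b) - u_a)
}

# Pair-count AUC with positives = pos.
pair_count_auc <- function(pos, neg) {
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Lorentzian direct-saturation dip centered at `center` ppm.
lorentzian_z <- function(offsets, center = 0, depth = 0.85, width = 1.0) {
  1 - depth / (1 + ((offsets - center) / width)^2)
}

# Standard (non-circulant) truncated-SVD deconvolution: lower-triangular
# Toeplitz AIF matrix, same truncation rule.
standard_svd_cbf <- function(curve, aif_c, tr, threshold) {
  n <- length(curve)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) D[i, 1:i] <- rev(aif_c[1:i])
  D <- D * tr
  sv <- svd(D)
  dinv <- ifelse(sv$d >= threshold * max(sv$d), 1 / sv$d, 0)
  r <- sv$v %*% (dinv * t(sv$u)) %*% curve
  max(r)
}

# Random positive smooth-ish spectrum on the standard 21-offset grid.
random_spectrum <- function() {
  offs <- seq(-5, 5, 0.5)
  z <- lorentzian_z(offs, 0, runif(1, 0.5, 0.9), runif(1, 0.8, 1.5)) +
    runif(21, -0.05, 0.05)
  pmax(z, 0.01)
}

default_t <- function(n = 60, tr = 1.243) (seq_len(n) - 1) * tr

# Matched-kinetics ground truth: every tissue shares MTT and delay so the
# Boxerman linear model is exactly specified; ET and hotspot leak at k2.
matched_kinetics_truth <- function(seed = 11, k2 = 0.05) {
  truth <- sample_subject_truth("gbm", seed = seed)
  tt <- truth$tissues
  tt$cbf_rel[tt$name == "et"] <- 4;    tt$cbv_rel[tt$name == "et"] <- 4
  tt$cbf_rel[tt$name == "et_hot"] <- 8; tt$cbv_rel[tt$name == "et_hot"] <- 8
  tt$cbf_rel[tt$name == "edema"] <- 1;  tt$cbv_rel[tt$name == "edema"] <- 1
  tt$cbf_rel[tt$name == "necrosis"] <- 0.25
  tt$cbv_rel[tt$name == "necrosis"] <- 0.25
  tt$delay[tt$name != "artery"] <- 0.8
  tt$k2 <- ifelse(tt$name %in% c("et", "et_hot"), k2, 0)
  truth$tissues <- tt
  truth
}
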