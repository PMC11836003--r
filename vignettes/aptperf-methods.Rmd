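---
title: "Methods: APTw CEST and DSC perfusion processing in aptperf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APTw CEST and DSC perfusion processing in aptperf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aptperf implements a quantitative-MRI analysis chain for differentiating
glioblastoma (GBM) from solitary brain metastasis (MET): amide proton
transfer weighted (APTw) CEST processing, dynamic susceptibility contrast
(DSC) perfusion quantification, region-of-interest statistics normalized to
normal-appearing white matter (NAWM), and two-group Mann-Whitney / ROC /
logistic-combination statistics. Because no patient data ship with the
package, a digital tumor phantom with known ground truth exercises the full
chain. This vignette records the models, the tunable parameters, and the
design and numerical choices behind each module.

## APTw Z-spectrum processing

A CEST acquisition saturates at offsets $\Delta\omega$ of $\pm 5$ ppm in
0.5 ppm steps (21 offsets) plus an unsaturated reference S0 at $-150$ ppm.
Per voxel:

1. **Normalization.** $Z(\Delta\omega) = S_{sat}(\Delta\omega)/S_0$.
   Voxels with non-positive or non-finite $S_0$ are flagged invalid and
   excluded from maps rather than raising an error.
2. **B0 correction.** The direct water saturation dip marks the local water
   frequency. The sub-sample dip position $\delta$ is the vertex of a
   parabola through the discrete minimum and its two neighbours — the
   minimal sub-sample refinement consistent with 0.5 ppm sampling — and the
   offset axis is shifted by $-\delta$. Shifts are clamped to $\pm 1$ ppm;
   flat spectra or boundary minima are flagged uncorrectable and excluded.
   On Lorentzian test dips the parabola recovers injected shifts of up to
   $\pm 0.4$ ppm within 0.05 ppm.
3. **Asymmetry metric.**
   $\mathrm{APTw}(\%) = 100 \cdot \frac{\int_{-\Delta\omega_2}^{-\Delta\omega_1} \tilde Z\,d\omega - \int_{\Delta\omega_1}^{\Delta\omega_2} \tilde Z\,d\omega}{\Delta\omega_2 - \Delta\omega_1}$
   with bounds 3.1 and 3.9 ppm bracketing the amide resonance at $+3.5$ ppm,
   $\tilde Z$ the linearly interpolated spectrum. Because the bounds fall
   between knots of the 0.5 ppm grid, the integral of the piecewise-linear
   interpolant is evaluated analytically including the partial end
   segments — this is exact, and matches a $10^5$-subdivision Riemann sum
   to $10^{-6}$.
4. **Fluid suppression.**
   $\mathrm{APTw_{FS}} = \mathrm{APTw} \cdot \sigma'^2_{WM} / Z_{ref}^2$
   with $Z_{ref}$ the interpolated intensity at $-3.5$ ppm. Long-T2 fluids
   (CSF, liquefactive necrosis) have a narrow direct-saturation dip, hence
   $Z_{ref} > \sigma'_{WM}$ and an attenuated APTw$_{FS}$. $Z_{ref}$ is
   read from the *B0-corrected* spectrum, since suppression follows the
   correction step in the chain; the alternative (uncorrected $Z_{ref}$)
   differs only at second order in $\delta$.

The map-level function vectorizes this chain over voxels by a change of
variables: shifting the axis by $-\delta$ and integrating over fixed bounds
equals integrating the original interpolant over bounds shifted by
$+\delta$, so all voxels share one knot grid. Unit tests verify the
vectorized path equals the scalar chain to $10^{-6}$.

## Bloch-McConnell simulator and the $\sigma'_{WM}$ factor

The white-matter factor $\sigma'_{WM}$ is defined as the WM Z-spectrum
intensity at $-3.5$ ppm under the protocol's saturation scheme: 5
hyperbolic-secant pulses of 100 ms with 61 ms gaps at 3 T. The simulator
integrates the coupled Bloch-McConnell equations for a star topology
(every pool exchanges with water) by piecewise matrix-exponential
propagation: within each constant-B1 segment the system is linear with a
constant drive, so the augmented $(3n{+}1)$-dimensional propagator is exact.
Choices that matter:

- **B1 convention.** The protocol's "2 uT" is interpreted as the rms
  amplitude over the full train including interpulse gaps — the standard
  way APTw saturation power is reported — giving an envelope peak of
  about 5.6 uT. Interpreting 2 uT as the envelope peak would leave WM
  barely saturated ($Z(-3.5) \approx 0.78$), inconsistent with the target
  factor of 0.4.
- **Steady state.** A single 0.744 s train from thermal equilibrium cannot
  saturate WM to $Z = 0.4$. In the 3D GRE acquisition the saturation module
  is replayed for every measurement, so the magnetization seen by the
  readout is the pseudo steady state of the repeated train.
  `derive_sigma_wm()` therefore repeats the train (ideal spoiling between
  repetitions, no recovery gap modelled) until the end-of-train water Mz
  converges to $10^{-6}$. `simulate_offset()` keeps the single-train
  behaviour as its default.
- **Discretization.** 256 segments per pulse. At 64 segments the
  per-segment precession phase at $\pm 5$ ppm reaches $2\pi$ and the
  piecewise-constant envelope aliases stroboscopically with precession,
  corrupting Z by ~0.15 at the spectrum edges; at 256 segments halving the
  step changes any Z by less than $10^{-4}$.
- **Lineshapes.** Exchanging pools are full Bloch pools (Lorentzian). The
  semisolid MT pool optionally uses a super-Lorentzian absorption rate
  acting on its longitudinal component only, with the on-resonance
  divergence floored at the 1 ppm value; the bundled WM parameter set uses
  this option.
- **Magnitude readout.** Simulated spectra use $|M_z|$; strong on-resonance
  saturation nutates $M_z$ through zero and a gradient-echo magnitude
  acquisition cannot distinguish the sign.

The bundled WM pool file (`inst/extdata/wm_3t_pools.yaml`) is a synthetic
stand-in mirroring published 3 T white-matter values (water T1 1.084 s /
T2 69 ms; semisolid fraction 0.139, T2 9.6 us, exchange 23 /s; amide pool
at +3.5 ppm), in a YAML schema compatible with common Bloch-McConnell
simulation layouts. With the default saturation module it yields
$\sigma'_{WM} \approx 0.43$, within the published 0.40 +/- 0.05 band, and
the package default `sigma_wm = 0.4` follows the published value.

## DSC perfusion quantification

1. **Conversion.** $\Delta R_2^*(t) = -\ln(S(t)/S_{pre})/TE$ with
   $S_{pre}$ the mean over the pre-bolus baseline; the bolus arrival is
   detected as the first frame dropping 3 running-SDs below the running
   baseline mean (overridable).
2. **AIF.** Candidate voxels (optionally restricted to an arterial seed
   region) are ranked by a composite score — 0.5 peak height, 0.25 early
   arrival, 0.25 low first moment, on ranks — after a peak-to-baseline-noise
   sanity screen; the top 10 curves are averaged. The weights are
   documented heuristics.
3. **Leakage correction.** Per voxel, least squares of
   $c(t) \approx K_1\,\bar c(t) - K_2 \int_0^t \bar c\,d\tau$ against the
   mean curve $\bar c$ of non-enhancing brain (enhancing tumor and vessels
   excluded); the corrected curve is $c + K_2 \int \bar c$, cCBV its
   integral ratio against the AIF. $K_2$ is reported in 1/min, signed:
   positive when extravasation depresses the measured curve. No fit-window
   restriction is applied (the whole post-arrival series is used).
4. **CBV.** Integral ratio $\int c \, dt / \int c_{AIF}\, dt$ (trapezoid).
   All outputs are relative; downstream analysis normalizes to NAWM, so no
   hematocrit/density scaling is applied.
5. **CBF.** Delay-insensitive circulant SVD: the AIF convolution matrix is
   zero-padded to twice the series length, singular values below a
   threshold (default 0.15 of the maximum; exposed as configuration) are
   zeroed, and CBF is the maximum of the recovered flow-scaled residue
   function; MTT = CBV/CBF. On noiseless forward-convolved curves the
   estimate is within 10% of truth at threshold 0.10 and moves by less
   than 5% under a two-frame delay.

The batched map-level implementation shares the leakage design matrix and
the truncated SVD inverse across voxels; both are algebraically identical
to the per-curve functions.

**A caveat the phantom makes explicit.** The linear leakage model assumes
the voxel's intravascular kinetics are a scaled copy of the reference
curve. When tissue MTT or delay differ from the reference, the first-pass
shape mismatch projects onto the leakage regressor and biases $K_2$ by
amounts that can exceed the physiologic signal (about $-0.3$/min for a
0.7 s MTT difference at high CBV). The forward/inverse consistency checks
therefore run on a matched-kinetics phantom (all tissues share MTT and
delay), the regime the estimator is defined for, while the default cohort
keeps heterogeneous kinetics — making its $K_2$ maps noisy and
non-discriminative, which is exactly the behaviour reported for this
parameter in patient studies.

## The digital phantom and cohort generator

Geometry: concentric ellipsoids — necrotic core (absent in some subjects),
enhancing rim (ET), edema shell (absent in some subjects) — inside a NAWM
brain ellipsoid with a small artery tube, plus an ET "hotspot"
sub-ellipsoid that models the intratumoral focus driving max statistics.
Default 64x64x24 voxels; all radii scale with the shape.

CEST: each tissue's Z-spectrum is simulated once (per-label broadcast) on a
quarter-ppm grid aligned with the acquisition offsets, and each voxel
samples its tissue spectrum at offsets shifted by a smooth B0 field
(in-plane gradient plus Gaussian bump, max amplitude 0.3 ppm). Tissue CEST
contrast is parameterized directly in APTw percent: a per-tissue quadratic
calibration APTw$(f_{amide})$, frozen against the package's own simulator,
is inverted to set the amide fraction for a sampled APTw target (affine
inversion is ~6% off at hotspot fractions). The amide pool lumps all
asymmetric exchangeable/aliphatic contributions, so fractions are effective
values chosen to land absolute APTw at clinically reported magnitudes
(NAWM 1%).

DSC: per tissue, $c(t) = \mathrm{CBF}_{rel}\, c_{abs}\, tr\,(AIF \ast
e^{-t/MTT})$ with the AIF a gamma-variate bolus arriving at 15 s (peak
30/s), MTT set so CBV = CBF x MTT matches the tissue's relative CBV, a
per-tissue arrival delay, minus $k_2 \int \bar c_{NAWM}$ in leaking tissue;
signal $S = S_{pre} e^{-TE\,c}$ plus Gaussian noise. The NAWM integral
ratio against the AIF is 0.2 — an apparent, relaxivity-amplified volume
chosen so signal drops are realistic (~10% in NAWM, ~50% in the artery at
TE 29 ms), not a literal 2% blood volume.

Group effect sizes are *emulation targets, not reproduction claims*: ET
means (normalized APTw 2.0 vs 1.7 with SD 0.60/0.74; relative CBV 4.3/1.8
vs 2.4/0.86; relative CBF 3.7/1.7 vs 2.3/1.0; K2 0.03 vs 0.04 /min) follow
the reported group tables, hotspot levels (APTw 4.9 vs 4.4; CBV 23 vs 12;
CBF 18 vs 13) follow the reported max rows with subject SDs chosen once so
the max-statistic discrimination lands near the reported single-parameter
AUCs. Necrosis/edema presence probabilities (0.5/1.0 GBM-like, 0.25/0.75
MET-like) emulate cohorts where some subjects lack those regions. Noise is
additive Gaussian on magnitude signal (CEST SD 0.5% of S0 — an effective,
post-smoothing level, since the phantom has no spatial texture to smooth —
DSC 2% of baseline); Rician effects are ignored at these SNRs and recorded
as a limitation.

What passing tests on this phantom do **not** show about real data: no
anatomical texture or partial-volume mixing, no motion or ghosting, no B1
inhomogeneity, piecewise-constant tissue parameters, a shared geometry
across subjects, and a single global B0 field model.

## ROI statistics and the cohort report

Mean, max, SD and voxel count per region (ET, necrosis, edema,
WT = ET + necrosis + edema, NAWM), missing voxels excluded, absent regions
dropped. All parameters except K2 are divided by the subject's NAWM mean
(normalizing K2 by a near-zero NAWM leakage would be meaningless);
re-normalization is flag-guarded and refused. The max statistic is the raw
voxel maximum, as in the emulated analysis; noise inflates it by roughly
the expected extreme of the voxel noise over the region, which the
generator's hotspot targets absorb.

Two-group statistics:

- **Mann-Whitney U**, reported as the smaller orientation
  ($U \le n_1 n_2 / 2$), with the exact two-sided p-value when there are no
  ties and $n_1 n_2 \le 400$ (more defensible than the asymptotic test at
  n = 10 vs 8), the tie-corrected normal approximation otherwise
  (`spss_compat` forces the asymptotic variant).
- **ROC/AUC**: trapezoidal (pair-counting) AUC with a fixed orientation —
  larger values indicate the positive (GBM) class, never flipped, so
  anti-predictive parameters report AUC < 0.5. SE by Hanley-McNeil; 95% CI
  $\pm 1.96\,SE$, deliberately unclipped. On tie-free data
  AUC $= 1 - U/(n_1 n_2)$ (or its complement) exactly.
- **Logistic combination**: unregularized maximum-likelihood fit; fitted
  in-sample probabilities scored by the same AUC; complete separation
  detected and flagged (AUC 1.0) instead of reporting divergent
  coefficients; constant predictors dropped with a warning. In-sample
  ML-logistic AUC is not mathematically guaranteed to reach the best single
  predictor; at n = 18 it occasionally lands a few hundredths below, which
  the combined-model checks should be read against.
- No multiple-comparison correction is applied, matching the emulated
  analysis; alpha = 0.05 two-sided throughout.

Group summary columns are the across-subject mean of subject means, the
across-subject maximum of subject maxima, and the SD of subject means.

## Problem sizes and fast paths

The packaged validation runs use: single subjects at 16-24 voxel cubes for
unit checks, the full study at 64x64x24 with 10 + 8 subjects, and 500
replicate zero-effect cohorts at 32x32x16 for false-positive calibration.
The calibration path interpolates tissue spectra linearly over amide
fraction from a small simulated grid per tissue ("spectrum bank"); the
dilute-pool response is nearly linear, so the interpolation error in Z is
orders of magnitude below the voxel noise. The exact per-tissue simulation
remains the default everywhere else.

## Known limitations

- The WM pool file mirrors literature values rather than any
  vendor-internal parameter set; $\sigma'_{WM}$ inherits a corresponding
  uncertainty, reflected in the 0.40 +/- 0.05 acceptance band.
- No B1 correction, Lorentzian-difference or multi-pool fitting of spectra,
  and no relaxation-compensated CEST metrics: the analysis is asymmetry
  integration only, by design.
- Perfusion outputs are relative only; no preload/dual-echo protocols or
  Bayesian/Tikhonov deconvolution variants.
- The phantom's K2 is identifiable only under matched kinetics (above);
  with heterogeneous kinetics the fitted K2 is mismatch-dominated, a
  faithful property of the linear leakage model rather than a defect of
  the phantom.
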