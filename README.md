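# aptperf

Quantitative MRI analysis for differentiating glioblastoma (GBM) from
solitary brain metastasis (MET), combining amide proton transfer weighted
(APTw) CEST imaging with dynamic susceptibility contrast (DSC) perfusion.
The package is aimed at quantitative-imaging researchers who want a tested,
scriptable version of this analysis chain — from raw saturation volumes and
dynamic series to the per-region statistics and ROC tables of a two-group
study — plus a digital tumor phantom with known ground truth to validate
every stage.

## What it computes

**APTw CEST.** Per voxel, the Z-spectrum `Z(Δω) = S_sat/S0` is normalized,
B0-corrected by shifting the spectral minimum to 0 ppm (parabolic
sub-sample refinement), and reduced to the asymmetry metric

    APTw(%) = 100 · [ ∫_{-3.9}^{-3.1} Z̃ dω − ∫_{3.1}^{3.9} Z̃ dω ] / 0.8

with `Z̃` the linear-interpolated spectrum (integrals evaluated exactly,
including partial end segments). Fluid suppression down-weights long-T2
compartments:

    APTw_FS = APTw · σ'²_WM / Z²_ref ,   Z_ref = Z̃(−3.5 ppm)

where `σ'_WM`, the white-matter Z-intensity at −3.5 ppm, is derived from a
multi-pool Bloch-McConnell simulation of the pulsed saturation scheme
(5 hyperbolic-secant pulses × 100 ms, 61 ms gaps, B1rms = 2 µT, 3 T),
giving `σ'_WM ≈ 0.4`.

**DSC perfusion.** Signal is converted to ΔR2\*, the arterial input
function is selected semi-automatically, the Boxerman linear leakage model
`c(t) ≈ K1·c̄(t) − K2·∫c̄ dτ` yields K2 and leakage-corrected CBV, and
delay-insensitive block-circulant SVD deconvolution yields CBF (MTT =
CBV/CBF).

**Cohort statistics.** Region statistics (mean/max over ET, necrosis,
edema, whole tumor, NAWM) are normalized to NAWM (K2 excepted), compared
between groups with Mann-Whitney U (exact at these sample sizes), scored by
nonparametric AUC with Hanley-McNeil standard errors (orientation fixed,
confidence intervals unclipped), and combined with binary logistic
regression.

**Synthetic cohorts.** `generate_cohort()` builds a labeled digital brain
phantom (necrotic core / enhancing rim with hotspot / edema shell / NAWM /
artery), simulates CEST stacks through the Bloch-McConnell engine with a
smooth B0 field, and synthesizes DSC series by forward convolution with a
gamma-variate bolus and injected leakage — all with per-subject ground
truth and deterministic seeding.

## Worked example

```r
library(aptperf)

# White-matter fluid-suppression factor from the saturation physics
derive_sigma_wm()
#> [1] 0.4251321

# The simulated white-matter Z-spectrum behind it
spec <- simulate_zspectrum(wm_3t_pools(), saturation_module(),
                           offset_plan(), steady_state = TRUE)
spec
#> <zspectrum: 21 offsets [-5, 5] ppm, b0_shift = 0 ppm>
aptw(b0_correct(spec))      # healthy WM has a small asymmetry, in percent
#> [1] 0.1771821

# A small synthetic two-group study (4 vs 4 subjects, 32x32x16 phantom)
study <- run_synthetic_study(n_gbm = 4, n_met = 4, seed = 7,
                             shape = c(32, 32, 16))
dplyr::filter(study$report$roc, region == "ET", statistic == "max")
#>   parameter region statistic  auc    se ci_low ci_high     p n_pos n_neg
#> 1      APTw     ET       max 0.88 0.137   0.61    1.14 0.083     4     4
#> 2   APTw_FS     ET       max 0.94 0.098   0.75    1.13 0.043     4     4
#> 3       CBF     ET       max 1.00 0.000   1.00    1.00 0.021     4     4
#> 4       CBV     ET       max 1.00 0.000   1.00    1.00 0.021     4     4
#> 5        K2     ET       max 0.25 0.184  -0.11    0.61 0.248     4     4
#> 6       MTT     ET       max 0.75 0.184   0.39    1.11 0.248     4     4
#> 7      cCBV     ET       max 1.00 0.000   1.00    1.00 0.021     4     4
```

Reading this: each row scores one NAWM-normalized parameter's ability to
separate the GBM-like from the MET-like subjects using its ET-region voxel
maximum. At this toy size the vascular parameters separate the groups
perfectly (AUC 1.0), APTw nearly so, while K2 is uninformative (AUC below
0.5 is reported as is — the orientation is never flipped). The unclipped
95% confidence intervals can exceed 1, matching the reporting convention
of clinical ROC tables. `study$report$comparison` holds the matching group
summaries with Mann-Whitney U and p, and `study$report$combined` the
logistic parameter combinations.

Plotting helpers: `autoplot()` on a `zspectrum`, an `aif`, or a
`roc_result`; `tidy()`/`glance()` on ROC and logistic-combination objects.

A thin command-line wrapper over the same functions ships in
`inst/cli/aptperf.R` (subcommands `aptw`, `derive-sigma`, `bmsim`,
`simulate-cohort`, `report`).

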