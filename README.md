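# serdti

Simulation, reconstruction and analysis pipeline for **low-field
diffusion tensor MRI (DTI)**, built as an R package.

High-resolution diffusion imaging on 0.55T-class scanners is
SNR-starved: at 2 mm isotropic resolution the diffusion-weighted images
come out of a conventional reconstruction visibly dominated by noise.
One remedy is an *SNR-enhancing joint reconstruction* (SER) that
reconstructs the entire set of diffusion-weighted images directly from
multichannel k-space in a single step, coupling them through an
edge-preserving penalty whose edge structure is shared by all images.
`serdti` implements that computational chain end to end on synthetic
data with known ground truth, so every claim about the method — its
resolution/SNR trade-off, its effect on tensor-parameter fidelity and
test-retest repeatability — can be exercised and measured exactly.

The package provides:

* **Synthetic acquisition** (`make_phantom`, `make_coils`,
  `simulate_dwi`, `acquire`): a labeled 2-D tensor phantom (CSF, GM,
  two crossing WM tract systems) with the monoexponential signal model
  `S_q = S0 · exp(−b_q gᵀ D g)`, smooth complex coil sensitivities,
  single-shell encoding (64 directions at b = 1000 s/mm² + b = 0),
  6/8 partial Fourier, EPI even/odd ghost phase, three-line navigators,
  and complex Gaussian noise at a controllable SNR.
* **Nyquist ghost correction** (`estimate_ghost`,
  `apply_ghost_correction`): variable-projection minimization of a
  navigator least-squares mismatch plus a structured low-rank
  (Toeplitz) penalty over the constant/linear phase pair.
* **Two reconstructions** (`recon_conventional`, `recon_ser`):
  zero-fill + Hamming + SENSE combination, and the joint reconstruction

      sum_q ||M F S x_q − d_q||²
        + λ_mrf Σ_pairs min(Σ_q β_q |x_{q,m} − x_{q,n}|², τ)
        + λ_imag Σ_q ||Im(e^{−iφ_q} x_q)||²

  minimized by half-quadratic alternation (shared line sites, CG inner
  solves, guaranteed non-increasing objective), with phase-constrained
  partial-Fourier recovery via the imaginary-part penalty.
* **Resolution and SNR quantification** (`compute_srf`,
  `measure_snr_gain`, `tune_to_operating_point`): effective in-plane
  resolution as the square root of the full area at half maximum of the
  2-D spatial response function, and Monte-Carlo SNR gain in smooth
  regions, with bisection of `λ_mrf` to a target gain.
* **Tensor fitting** (`fit_tensor`, `tensor_metrics`, `export_maps`):
  log-linear OLS/WLS estimation, FA/MD/primary eigenvector, NIfTI and
  FSL bval/bvec I/O.
* **Comparison statistics** (`select_voxels`, `regress`,
  `angular_discrepancy`, `bland_altman`, `cov_intrasubject`,
  `compare_report`): the analysis suite — regression R², angular
  discrepancy `acos|e1·e1'|`, Bland-Altman limits of agreement,
  intra-subject coefficients of variation — with FA > 0.3 white-matter
  masking.

See `vignettes/serdti-methods.Rmd` for the models, parameter meanings,
numerical choices and limitations.

## Worked example

Simulate a complete two-repeat low-field study (64×64 grid, 2 mm
voxels, 24 directions + b = 0, 8 channels, b = 0 SNR 15, ghost
(0.3, 0.001) estimated and corrected per repeat), reconstruct each
repeat both ways, fit tensors, and compare:

```r
library(serdti)

st <- simulate_study(grid = c(64, 64), n_directions = 24, n_channels = 8,
                     snr = 15, n_repeats = 2, seed = 42)
sel <- select_voxels(st$phantom$labels, include_labels = c(3, 4),
                     fa_reference = st$truth$fa, fa_threshold = 0.3,
                     fov_masks = lapply(st$fits, function(f) f$fit_mask))
report <- compare_report(c(st$fits, list(truth = st$truth)),
                         standard_pairings(), sel)
report
```

```
<dti_comparison>
# A tibble: 8 × 7
  pairing       metric r_squared        bias loa_width cov_pct     n
  <chr>         <chr>      <dbl>       <dbl>     <dbl>   <dbl> <int>
1 ser_vs_truth  FA         0.516 -0.0326      0.224       3.83  1415
2 ser_vs_truth  MD         0.487 -0.00000575  0.000100    1.81  1415
3 conv_vs_truth FA         0.458 -0.0369      0.270       4.79  1415
4 conv_vs_truth MD         0.264 -0.00000214  0.000234    2.92  1415
5 ser_repeat    FA         0.867 -0.00230     0.119       2.33  1415
6 ser_repeat    MD         0.289  0.00000541  0.000141    2.58  1415
7 conv_repeat   FA         0.874 -0.00289     0.133       2.74  1415
8 conv_repeat   MD         0.616  0.00000583  0.000180    3.29  1415
  median angular discrepancy [ser_vs_truth]: 1.22 deg (n = 1415)
  median angular discrepancy [conv_vs_truth]: 1.47 deg (n = 1415)
  median angular discrepancy [ser_repeat]: 1.65 deg (n = 1415)
  median angular discrepancy [conv_repeat]: 2.06 deg (n = 1415)
```

Reading this: over the 1415 white-matter voxels selected by the
FA > 0.3 rule, the joint reconstruction (`ser`) tracks the ground-truth
FA and MD maps better than the conventional reconstruction
(higher R² in the `*_vs_truth` rows), points the principal eigenvector
closer to the true fiber orientation (smaller median angular
discrepancy), and is more repeatable across the two simulated repeats
(narrower Bland-Altman limits of agreement, `loa_width`, and smaller
CoV in the `*_repeat` rows), at negligible bias. The per-repeat ghost
estimates recover the applied corruption:

```r
st$ghost_estimates[[1]][c("phi0_hat", "phi1_hat")]
#> $phi0_hat [1] 0.2995   (truth 0.3)
#> $phi1_hat [1] 0.000954 (truth 0.001)
```

`autoplot(report)` produces Bland-Altman panels and angular-discrepancy
histograms; `plot_map(st$fits$ser_r1$fa)` shows the FA map.

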