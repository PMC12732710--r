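# Packaged experiments: the resolution measurement of the conventional
# reconstruction on the emulated acquisition, and the SNR-gain operating
# point calibration of the joint reconstruction. These are the analyses
# the acceptance script and the validation suite both run.

#' Erode a logical mask
#'
#' Shrinks a mask by `k` 4-neighbor erosion passes; used to build
#' edge-free regions of interest from phantom labels.
#'
#' @param mask logical matrix.
#' @param k number of erosion passes.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, k = 1L) {
  for (i in seq_len(k)) {
    ny <- nrow(mask); nx <- ncol(mask)
    mask <- mask &
      rbind(mask[-1, , drop = FALSE], FALSE) &
      rbind(FALSE, mask[-ny, , drop = FALSE]) &
      cbind(mask[, -1, drop = FALSE], FALSE) &
      cbind(FALSE, mask[, -nx, drop = FALSE])
  }
  mask
}

#' Effective resolution of the conventional reconstruction
#'
#' Emulates the study acquisition (default 130 x 130 matrix, 260 mm FOV,
#' 2 mm voxels, 6/8 partial Fourier) on a noiseless phantom and measures
#' the conventional reconstruction's effective in-plane resolution (the
#' square root of the full area at half maximum of the 2-D spatial
#' response function) under both Hamming windowing conventions: the
#' window spanning the acquired k-space extent per axis, and the window
#' spanning the full grid.
#'
#' @param matrix_size acquisition matrix (default `c(130, 130)`).
#' @param seed phantom seed.
#' @return List with `srf_acquired`, `srf_full` (both `srf_report`s) and
#'   `resolution_mm` (named vector of the two effective resolutions).
#' @export
conventional_resolution_study <- function(matrix_size = c(130L, 130L), seed = 1L) {
  proto <- dti_protocol(n_directions = 2, matrix_size = matrix_size)
  ph <- make_phantom(matrix_size, seed = seed)
  co <- make_coils(1, matrix_size, mode = "uniform")
  ks <- acquire(simulate_dwi(ph, proto), co, proto, noise_sigma = 0)
  sens <- estimate_sensitivities(ks, "ground_truth")
  probe <- round(matrix_size / 2)
  rc <- function(w) function(k) recon_conventional(k, sens, window = w)$images[, , 1]
  sa <- compute_srf(rc("acquired"), ks, probe)
  sf <- compute_srf(rc("full"), ks, probe)
  list(srf_acquired = sa, srf_full = sf,
       resolution_mm = c(acquired = sa$effective_resolution_mm,
                         full = sf$effective_resolution_mm))
}

#' Calibrate the joint reconstruction to the target SNR operating point
#'
#' Runs the full operating-point experiment: simulates a low-field
#' acquisition of the phantom, bisects `lambda_mrf` until the joint
#' reconstruction's smooth-region SNR gain over the conventional
#' reconstruction reaches `target_gain` (measured over `n_realizations`
#' Monte-Carlo noise draws; each draw's reconstruction is warm-started
#' from the noise-free solution), then measures the effective resolution
#' of the tuned reconstruction at a smooth-region probe and at a probe
#' adjacent to a tissue edge, plus the conventional reference resolution.
#' The smooth ROI is the interior of the WM mass (eroded by 4 voxels);
#' a small protocol (b = 0 plus `n_directions` DWIs) is used since the
#' smooth-region noise behavior is per-encoding.
#'
#' @param grid simulation matrix (default `c(64, 64)`, 2 mm voxels).
#' @param n_channels,n_directions,snr acquisition conditions.
#' @param target_gain,tol gain target for [tune_to_operating_point()].
#' @param n_realizations Monte-Carlo draws per gain evaluation.
#' @param lambda_bounds bisection bracket for `lambda_mrf`.
#' @param seed master seed.
#' @return List with `tuning` (`ser_tuning`), `gain`, `lambda_mrf`,
#'   `srf_smooth`, `srf_edge`, `srf_conventional` (`srf_report`s) and
#'   `resolution_mm` (named vector).
#' @export
snr_operating_point_study <- function(grid = c(64L, 64L), n_channels = 4L,
                                      n_directions = 2L, snr = 15,
                                      target_gain = 4, tol = 0.1,
                                      n_realizations = 50L,
                                      lambda_bounds = c(2, 80), seed = 1L) {
  ph <- make_phantom(grid, seed = seed)
  co <- make_coils(n_channels, grid, seed = seed + 1000L)
  proto <- dti_protocol(n_directions = n_directions, matrix_size = grid)
  img <- simulate_dwi(ph, proto)
  sigma <- sigma_for_snr(ph, co, snr)
  ks0 <- acquire(img, co, proto, noise_sigma = 0)
  sens <- estimate_sensitivities(ks0, "ground_truth")
  phase <- estimate_phase_maps(ks0, sens)
  tau <- 0.008 * proto$n_encodings

  roi <- erode_mask(ph$labels == 3L, 4L)
  idx <- which(roi, arr.ind = TRUE)
  ctr <- colMeans(idx)
  probe <- idx[which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2), ]
  # probe immediately adjacent to the ventricle (CSF) edge
  wm_near_edge <- (ph$labels == 3L) & !erode_mask(ph$labels != 1L, 1L)
  idx_e <- which(wm_near_edge, arr.ind = TRUE)
  probe_edge <- idx_e[which.max(idx_e[, 1]), ]

  gen <- function(s) acquire(img, co, proto, noise_sigma = sigma, seed = s)
  conv_fn <- function(k) recon_conventional(k, sens)$images[, , 1]
  full_cfg <- function(lam) ser_config(lambda_mrf = lam, tau = tau,
                                       lambda_imag = 1, outer_iters = 20L,
                                       cg_iters = 20L)
  factory <- function(lam) {
    x0 <- recon_ser(ks0, sens, phase, full_cfg(lam))$images
    warm_cfg <- ser_config(lambda_mrf = lam, tau = tau, lambda_imag = 1,
                           outer_iters = 6L, cg_iters = 12L)
    function(k) recon_ser(k, sens, phase, warm_cfg, x_init = x0)$images[, , 1]
  }
  tuning <- tune_to_operating_point(conv_fn, factory, gen, roi,
                                    target_gain = target_gain, tol = tol,
                                    lambda_bounds = lambda_bounds,
                                    n_realizations = n_realizations,
                                    seed = seed, labels = ph$labels)
  ser_fn <- function(k) recon_ser(k, sens, phase, full_cfg(tuning$lambda_mrf))$images[, , 1]
  srf_smooth <- compute_srf(ser_fn, ks0, probe)
  srf_edge <- compute_srf(ser_fn, ks0, probe_edge)
  srf_conv <- compute_srf(conv_fn, ks0, probe)
  list(tuning = tuning, gain = tuning$gain, lambda_mrf = tuning$lambda_mrf,
       srf_smooth = srf_smooth, srf_edge = srf_edge, srf_conventional = srf_conv,
       resolution_mm = c(ser_smooth = srf_smooth$effective_resolution_mm,
                         ser_edge = srf_edge$effective_resolution_mm,
                         conventional = srf_conv$effective_resolution_mm))
}
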