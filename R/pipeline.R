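# End-to-end synthetic study: phantom -> acquisition (with ghost + noise)
# -> ghost correction -> conventional and joint reconstruction -> tensor
# fitting -> comparison statistics. This is the harness the repeatability
# experiments and the acceptance analyses run on.

#' Simulate a complete low-field DTI study and compare reconstructions
#'
#' Builds a tensor phantom and coil array, simulates `n_repeats`
#' independent noisy acquisitions of the same protocol at a b = 0 SNR
#' emulating the chosen field strength, estimates and corrects the EPI
#' ghost per repeat, reconstructs each repeat both conventionally and
#' with the SNR-enhancing joint reconstruction, fits diffusion tensors to
#' all magnitude series, and returns the fits together with the phantom
#' ground truth.
#'
#' @param grid integer pair, simulation matrix (default `c(64, 64)`).
#' @param n_directions diffusion directions (plus one b = 0).
#' @param n_channels receive channels.
#' @param snr b = 0 coil-combined SNR of the acquisition (the low-field
#'   condition uses the default 15; a high-field acquisition would be
#'   emulated with a proportionally larger value).
#' @param ghost true `ghost_model` applied during acquisition.
#' @param ser_cfg `ser_config` for the joint reconstruction.
#' @param n_repeats number of independent noise repeats (default 2).
#' @param seed master seed; repeat r uses `seed + r` for its noise.
#' @param correct_ghost estimate and apply the ghost correction (default
#'   TRUE when the true ghost is nonzero).
#' @param fit_method tensor estimator passed to [fit_tensor()].
#' @return List with `phantom`, `coils`, `protocol`, `truth` (list with
#'   `fa`, `md`, `e1`, `fit_mask` on the phantom support), `fits` (named
#'   `conv_r<r>` / `ser_r<r>`), `ghost_estimates`, and `series` (the
#'   corrected k-space series per repeat).
#' @export
simulate_study <- function(grid = c(64L, 64L), n_directions = 24L,
                           n_channels = 8L, snr = 15,
                           ghost = ghost_model(0.3, 0.001),
                           ser_cfg = ser_config(lambda_mrf = 1.5,
                                                tau = 0.008 * (n_directions + 1),
                                                lambda_imag = 1,
                                                outer_iters = 12L, cg_iters = 15L),
                           n_repeats = 2L, seed = 1L,
                           correct_ghost = NULL,
                           fit_method = "wls") {
  phantom <- make_phantom(grid, voxel_mm = c(2, 2), seed = seed)
  coils <- make_coils(n_channels, grid, seed = seed + 1000L)
  proto <- dti_protocol(n_directions = n_directions, matrix_size = grid)
  images <- simulate_dwi(phantom, proto)
  sigma <- sigma_for_snr(phantom, coils, snr)
  if (is.null(correct_ghost)) correct_ghost <- ghost$phi0 != 0 || ghost$phi1 != 0

  truth <- list(fa = ifelse(phantom$labels > 0, phantom$fa_map, NA_real_),
                md = ifelse(phantom$labels > 0, phantom$md_map, NA_real_),
                e1 = phantom$e1_true,
                fit_mask = phantom$labels > 0)

  fits <- list(); ghost_estimates <- list(); series <- list()
  for (r in seq_len(n_repeats)) {
    ks <- acquire(images, coils, proto, ghost = ghost,
                  noise_sigma = sigma, seed = seed + r)
    if (correct_ghost) {
      ge <- estimate_ghost(ks)
      ks <- apply_ghost_correction(ks, ge)
      ghost_estimates[[r]] <- ge
    }
    sens <- estimate_sensitivities(ks, "ground_truth")
    phase <- estimate_phase_maps(ks, sens)
    conv <- recon_conventional(ks, sens, window = "acquired")
    ser <- recon_ser(ks, sens, phase, ser_cfg)
    fits[[paste0("conv_r", r)]] <- fit_tensor(conv, method = fit_method)
    fits[[paste0("ser_r", r)]] <- fit_tensor(ser, method = fit_method)
    series[[r]] <- ks
  }
  list(phantom = phantom, coils = coils, protocol = proto, truth = truth,
       fits = fits, ghost_estimates = ghost_estimates, series = series,
       noise_sigma = sigma)
}

#' Standard pairing set for a two-repeat study
#'
#' Accuracy pairings of each method's first repeat against ground truth,
#' and repeatability pairings of repeat 1 vs repeat 2 per method.
#'
#' @return List of pairing specifications for [compare_report()].
#' @export
standard_pairings <- function() {
  list(
    list(name = "ser_vs_truth", a = "ser_r1", b = "truth", kind = "accuracy"),
    list(name = "conv_vs_truth", a = "conv_r1", b = "truth", kind = "accuracy"),
    list(name = "ser_repeat", a = "ser_r1", b = "ser_r2", kind = "repeatability"),
    list(name = "conv_repeat", a = "conv_r1", b = "conv_r2", kind = "repeatability")
  )
}
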