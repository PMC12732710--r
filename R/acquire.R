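#' EPI even/odd line phase-error model
#'
#' Constant plus linear phase applied to odd-indexed phase-encode lines in
#' hybrid (x, ky) space, the standard first-order model of the even/odd
#' readout mismatch that produces FOV/2 Nyquist ghosts in EPI.
#'
#' @param phi0 constant phase offset, radians.
#' @param phi1 linear phase slope, radians per readout-sample index (the
#'   readout index grid is centered: `-floor(nx/2) .. ceiling(nx/2)-1`).
#' @return `ghost_model` list.
#' @export
ghost_model <- function(phi0 = 0, phi1 = 0) {
  structure(list(phi0 = phi0, phi1 = phi1), class = "ghost_model")
}

# Multiply odd-indexed phase-encode rows (0-based storage index) of a
# (ky, kx) k-space matrix by exp(+/- i (phi0 + phi1 * x)) in hybrid space.
#' @noRd
apply_ghost_phase_k <- function(k, phi0, phi1, sign = +1) {
  if (phi0 == 0 && phi1 == 0) return(k)
  ny <- nrow(k); nx <- ncol(k)
  odd <- (seq_len(ny) - 1L) %% 2L == 1L
  h <- ift_readout(k)                    # hybrid (ky rows, x columns)
  ramp <- exp(sign * 1i * (phi0 + phi1 * kgrid(nx)))
  h[odd, ] <- sweep(h[odd, , drop = FALSE], 2, ramp, `*`)
  ft_readout(h)
}

# Same phase ramp applied to a single k-space line (length nx).
#' @noRd
apply_ghost_phase_line <- function(line, phi0, phi1, sign = +1) {
  nx <- length(line)
  idxf <- fftshift_vec_idx(nx); idxi <- ifftshift_vec_idx(nx)
  h <- stats::fft(line[idxi], inverse = TRUE)[idxf] / sqrt(nx)
  h <- h * exp(sign * 1i * (phi0 + phi1 * kgrid(nx)))
  stats::fft(h[idxi])[idxf] / sqrt(nx)
}

#' Simulate a multichannel diffusion EPI k-space series
#'
#' Per channel and encoding, forms the unitary centered 2-D Fourier
#' transform of sensitivity times image, applies the even/odd ghost phase
#' in hybrid space, discards the partial-Fourier lines (the most-negative
#' ky band), and adds i.i.d. complex Gaussian noise to acquired samples
#' only. Three-line navigators (polarities +, -, +, i.e. the middle line
#' carries the odd-line ghost phase) are generated per encoding from the
#' b = 0 coil data at ky = 0 with the same ghost model and noise level.
#'
#' @param images complex array ny x nx x Q (e.g. from [simulate_dwi()]).
#' @param coils a `coil_set` on the same grid.
#' @param protocol a `dwi_protocol` with matching matrix size.
#' @param ghost a `ghost_model` (default: no ghost).
#' @param noise_sigma standard deviation of each real/imaginary noise
#'   component, per channel.
#' @param seed integer seed for the noise stream.
#' @return `kspace_series`: list with `data` (complex ny x nx x C x Q,
#'   unacquired lines exactly zero), `mask` (logical ny, acquired
#'   phase-encode lines), `navigators` (complex nx x 3 x C x Q),
#'   `nav_polarity` (`c(1, -1, 1)`), `noise_sigma`, `protocol`,
#'   `ghost_truth`, `coils` (simulator ground truth), and `meta`
#'   (acquired-line count and ky range).
#' @export
acquire <- function(images, coils, protocol, ghost = ghost_model(0, 0),
                    noise_sigma = 0, seed = 1L) {
  dims <- dim(images)
  ny <- protocol$matrix_size[1]; nx <- protocol$matrix_size[2]
  if (!(dims[1] == ny && dims[2] == nx)) stop("images and protocol grids disagree")
  if (!(dim(coils$sens)[1] == ny && dim(coils$sens)[2] == nx)) {
    stop("coil maps and protocol grids disagree")
  }
  Q <- protocol$n_encodings
  if (dims[3] != Q) stop("one image per protocol encoding required")
  C <- coils$n_channels
  mask <- protocol$acquired_pe
  b0_idx <- which(protocol$bvals == 0)[1]
  ky0_row <- floor(ny / 2) + 1L

  data <- array(0 + 0i, c(ny, nx, C, Q))
  navs <- array(0 + 0i, c(nx, 3, C, Q))
  with_seed(seed, {
    for (q in seq_len(Q)) {
      for (c in seq_len(C)) {
        k <- ft2(coils$sens[, , c] * images[, , q])
        k <- apply_ghost_phase_k(k, ghost$phi0, ghost$phi1)
        k[!mask, ] <- 0 + 0i
        if (noise_sigma > 0) {
          n_acq <- sum(mask)
          noise <- matrix(stats::rnorm(n_acq * nx, sd = noise_sigma) +
                            1i * stats::rnorm(n_acq * nx, sd = noise_sigma),
                          n_acq, nx)
          k[mask, ] <- k[mask, ] + noise
        }
        data[, , c, q] <- k

        kb0 <- ft2(coils$sens[, , c] * images[, , b0_idx])
        base <- kb0[ky0_row, ]
        oddl <- apply_ghost_phase_line(base, ghost$phi0, ghost$phi1)
        nav <- cbind(base, oddl, base)
        if (noise_sigma > 0) {
          nav <- nav + matrix(stats::rnorm(3 * nx, sd = noise_sigma) +
                                1i * stats::rnorm(3 * nx, sd = noise_sigma), nx, 3)
        }
        navs[, , c, q] <- nav
      }
    }
  })
  structure(list(
    data = data, mask = mask, navigators = navs, nav_polarity = c(1, -1, 1),
    noise_sigma = noise_sigma, protocol = protocol, ghost_truth = ghost,
    coils = coils,
    meta = list(n_acquired_pe = sum(mask),
                ky_acquired = range(protocol$ky[mask]))
  ), class = "kspace_series")
}

#' Per-channel noise level for a target coil-combined b = 0 SNR
#'
#' The SENSE-combined image `x = sum(s* y) / sum(|s|^2)` has per-voxel
#' noise standard deviation `sigma / rss(s)` per real component. This
#' helper returns the per-channel `sigma` such that the median over the
#' phantom support of `S0 * rss / sigma` equals `snr`.
#'
#' @param phantom a `tensor_phantom`.
#' @param coils matching `coil_set`.
#' @param snr target b = 0 SNR (dimensionless).
#' @return per-channel noise standard deviation.
#' @export
sigma_for_snr <- function(phantom, coils, snr) {
  stopifnot(snr > 0)
  rss <- coil_rss(coils)
  supp <- phantom$labels > 0
  stats::median(phantom$S0[supp] * rss[supp]) / snr
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_series> %d x %d grid, %d channels, %d encodings\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  acquired PE lines: %d of %d (ky %d..%d), noise sigma %.3g\n",
              x$meta$n_acquired_pe, d[1], x$meta$ky_acquired[1],
              x$meta$ky_acquired[2], x$noise_sigma))
  invisible(x)
}
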