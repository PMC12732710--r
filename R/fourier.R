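# Centered unitary Fourier transforms.
#
# All k-space arrays in this package are stored "centered": the DC sample
# sits at index floor(n/2)+1 along each axis, and the k-index grid along an
# axis of length n is -floor(n/2) .. ceil(n/2)-1.  Images use the natural
# pixel grid with the object centered on the same index.  Transforms are
# unitary (norm-preserving), so Parseval holds exactly.

#' @noRd
fftshift_vec_idx <- function(n) {
  # index permutation that moves DC (index 1 in fft output) to floor(n/2)+1
  c(seq.int(floor(n / 2) + 1L, n), seq_len(floor(n / 2)))
}

#' @noRd
ifftshift_vec_idx <- function(n) {
  c(seq.int(ceiling(n / 2) + 1L, n), seq_len(ceiling(n / 2)))
}

#' @noRd
fftshift2 <- function(x) x[fftshift_vec_idx(nrow(x)), fftshift_vec_idx(ncol(x)), drop = FALSE]

#' @noRd
ifftshift2 <- function(x) x[ifftshift_vec_idx(nrow(x)), ifftshift_vec_idx(ncol(x)), drop = FALSE]

#' @noRd
kgrid <- function(n) seq.int(-floor(n / 2), ceiling(n / 2) - 1L)

# 2-D unitary centered DFT: image -> k-space
#' @noRd
ft2 <- function(x) fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))

# 2-D unitary centered inverse DFT: k-space -> image
#' @noRd
ift2 <- function(k) fftshift2(stats::fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))

# 1-D unitary centered transforms along the readout (column/kx) axis of a
# (ky, kx) matrix; used for the hybrid (x, ky) space in which EPI even/odd
# phase errors act.
#' @noRd
ft_readout <- function(x) {
  idxf <- fftshift_vec_idx(ncol(x))
  idxi <- ifftshift_vec_idx(ncol(x))
  t(stats::mvfft(t(x[, idxi, drop = FALSE])))[, idxf, drop = FALSE] / sqrt(ncol(x))
}

#' @noRd
ift_readout <- function(k) {
  idxf <- fftshift_vec_idx(ncol(k))
  idxi <- ifftshift_vec_idx(ncol(k))
  t(stats::mvfft(t(k[, idxi, drop = FALSE]), inverse = TRUE))[, idxf, drop = FALSE] / sqrt(ncol(k))
}

# Reproducible local RNG scope: runs expr with the given seed and restores
# the caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
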