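#' Diffusion acquisition protocol
#'
#' Describes a single-shell 2-D diffusion EPI acquisition: matrix size,
#' field of view, b-values, unit gradient directions, and the partial
#' Fourier factor along the phase-encode axis.
#'
#' The phase-encode axis is the first (row) array dimension throughout the
#' package. With partial Fourier fraction `pf` and `N` phase-encode lines,
#' the acquired band covers ky indices `-ceiling((pf - 1/2) * N)` through
#' `N/2 - 1` on the centered grid `-floor(N/2) .. ceiling(N/2)-1`; the
#' most-negative ky lines are the omitted ones. For the default protocol
#' (6/8 of 130 lines) this yields 98 acquired lines, recorded in
#' `$n_acquired_pe`.
#'
#' @param matrix_size integer pair, (phase-encode, readout) matrix size.
#' @param fov_mm length pair, field of view in mm.
#' @param bvals numeric vector of b-values in s/mm^2 (one per encoding).
#' @param bvecs 3 x Q matrix of unit gradient directions (columns). For
#'   b = 0 encodings the column may be zero.
#' @param partial_fourier fraction in (1/2, 1] of phase-encode lines
#'   acquired.
#' @return An object of class `dwi_protocol`.
#' @examples
#' p <- dti_protocol(n_directions = 12, matrix_size = c(64, 64))
#' p$n_acquired_pe
#' @export
dwi_protocol <- function(matrix_size = c(130L, 130L),
                         fov_mm = c(260, 260),
                         bvals,
                         bvecs,
                         partial_fourier = 1) {
  matrix_size <- as.integer(matrix_size)
  stopifnot(length(matrix_size) == 2L, all(matrix_size >= 8L),
            length(fov_mm) == 2L, all(fov_mm > 0))
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L) stop("bvecs must be a 3 x Q matrix of column vectors")
  if (ncol(bvecs) != length(bvals)) stop("bvals and bvecs disagree on the number of encodings")
  nrm <- sqrt(colSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-8
  if (any(bad)) {
    stop("non-unit bvec for diffusion-weighted encoding(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (partial_fourier <= 0.5 || partial_fourier > 1) {
    stop("partial_fourier must lie in (1/2, 1]")
  }
  n_pe <- matrix_size[1]
  ky <- kgrid(n_pe)
  ky_min_acq <- -as.integer(ceiling((partial_fourier - 0.5) * n_pe))
  acquired <- ky >= ky_min_acq
  structure(list(
    matrix_size = matrix_size,
    fov_mm = as.numeric(fov_mm),
    voxel_mm = as.numeric(fov_mm) / matrix_size,
    bvals = as.numeric(bvals),
    bvecs = bvecs,
    n_encodings = length(bvals),
    partial_fourier = partial_fourier,
    pf_axis = 1L,
    ky = ky,
    acquired_pe = acquired,
    n_acquired_pe = sum(acquired)
  ), class = "dwi_protocol")
}

#' Single-shell DTI protocol with evenly spread directions
#'
#' Builds the emulated study protocol: one b = 0 image plus `n_directions`
#' diffusion-weighted encodings at a single b-value, with directions spread
#' quasi-uniformly over the half sphere by a spherical Fibonacci spiral.
#'
#' @param n_directions number of diffusion-weighted directions (default 64).
#' @param bval shell b-value in s/mm^2 (default 1000).
#' @param matrix_size,fov_mm,partial_fourier see [dwi_protocol()]. Defaults
#'   are the emulated acquisition: 130 x 130 matrix, 260 mm FOV, 6/8
#'   partial Fourier along phase encoding.
#' @return A `dwi_protocol` whose first encoding is b = 0.
#' @export
dti_protocol <- function(n_directions = 64L,
                         bval = 1000,
                         matrix_size = c(130L, 130L),
                         fov_mm = NULL,
                         partial_fourier = 6 / 8) {
  if (is.null(fov_mm)) fov_mm <- 2 * as.numeric(matrix_size)
  g <- fibonacci_hemisphere(n_directions)
  dwi_protocol(matrix_size = matrix_size, fov_mm = fov_mm,
               bvals = c(0, rep(bval, n_directions)),
               bvecs = cbind(c(0, 0, 0), g),
               partial_fourier = partial_fourier)
}

# Quasi-uniform unit directions on the upper hemisphere (sign is irrelevant
# for diffusion encoding).
#' @noRd
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # cos(polar angle) in (0, 1): upper half
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Write and read FSL-style bval/bvec files
#'
#' `write_bvalbvec()` writes the protocol's b-values (one whitespace-
#' separated row) and gradient directions (three rows: x, y, z) as plain
#' text; `read_bvalbvec()` reads them back. Values are written with full
#' double precision so a write/read round trip reproduces the protocol
#' exactly.
#'
#' @param protocol a `dwi_protocol`.
#' @param bval_path,bvec_path file paths.
#' @return `read_bvalbvec()` returns a list with elements `bvals` and
#'   `bvecs`.
#' @export
write_bvalbvec <- function(protocol, bval_path, bvec_path) {
  writeLines(paste(format(protocol$bvals, digits = 17, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(protocol$bvecs, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bvalbvec
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  if (length(bv) != 3L * length(bvals)) stop("bvec/bval size mismatch")
  list(bvals = bvals, bvecs = matrix(bv, nrow = 3, byrow = TRUE))
}
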