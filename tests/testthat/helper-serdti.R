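# Shared small fixtures, built in code. Sizes are kept small; the
# full-scale emulation lives in the acceptance tests.

small_grid <- c(32L, 32L)

small_protocol <- function(n_directions = 6, matrix_size = small_grid,
                           partial_fourier = 6 / 8) {
  dti_protocol(n_directions = n_directions, matrix_size = matrix_size,
               partial_fourier = partial_fourier)
}

small_setup <- function(n_directions = 6, n_channels = 2, seed = 7,
                        matrix_size = small_grid, partial_fourier = 6 / 8) {
  proto <- small_protocol(n_directions, matrix_size, partial_fourier)
  ph <- make_phantom(matrix_size, seed = seed)
  co <- make_coils(n_channels, matrix_size, seed = seed + 1)
  img <- simulate_dwi(ph, proto)
  list(proto = proto, phantom = ph, coils = co, images = img)
}

# hand-made single-voxel-style phantom with a prescribed constant tensor
flat_phantom <- function(grid, D6, s0 = 1, phase = 0) {
  ny <- grid[1]; nx <- grid[2]
  D <- array(0, c(ny, nx, 6))
  for (i in 1:6) D[, , i] <- D6[i]
  structure(list(labels = matrix(1L, ny, nx), D = D,
                 S0 = matrix(s0, ny, nx), phase = matrix(phase, ny, nx),
                 voxel_mm = c(2, 2)),
            class = "tensor_phantom")
}

# unitary centered 2-D DFT by explicit double summation: the independent
# oracle for anything that relies on the package's FFT convention
dft2_naive <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  ky <- seq.int(-floor(ny / 2), ceiling(ny / 2) - 1)
  kx <- seq.int(-floor(nx / 2), ceiling(nx / 2) - 1)
  out <- matrix(0 + 0i, ny, nx)
  for (a in seq_len(ny)) for (b in seq_len(nx)) {
    s <- 0 + 0i
    for (m in seq_len(ny)) for (n in seq_len(nx)) {
      s <- s + x[m, n] * exp(-2i * pi * (ky[a] * ky[m] / ny + kx[b] * kx[n] / nx))
    }
    out[a, b] <- s / sqrt(ny * nx)
  }
  out
}

# naive double-loop evaluation of the joint-reconstruction objective,
# independent of the package's FFT/array machinery
ser_objective_naive <- function(x_all, kseries, sens_arr, phase, cfg) {
  Q <- dim(x_all)[3]; C <- dim(sens_arr)[3]
  beta <- rep_len(cfg$beta, Q)
  val <- 0
  for (q in seq_len(Q)) for (c in seq_len(C)) {
    k <- dft2_naive(sens_arr[, , c] * x_all[, , q])
    k[!kseries$mask, ] <- 0 + 0i
    val <- val + sum(Mod(k - kseries$data[, , c, q])^2)
  }
  ny <- dim(x_all)[1]; nx <- dim(x_all)[2]
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    for (nb in list(c(i + 1, j), c(i, j + 1))) {
      if (nb[1] > ny || nb[2] > nx) next
      v <- 0
      for (q in seq_len(Q)) {
        v <- v + beta[q] * Mod(x_all[i, j, q] - x_all[nb[1], nb[2], q])^2
      }
      val <- val + cfg$lambda_mrf * min(v, cfg$tau)
    }
  }
  if (cfg$lambda_imag > 0) {
    for (q in seq_len(Q)) {
      val <- val + cfg$lambda_imag *
        sum(Im(exp(-1i * phase[, , q]) * x_all[, , q])^2)
    }
  }
  val
}


# signals for a constant-tensor "image" under a protocol, optionally noisy
tensor_signals <- function(D6, proto, grid = c(8, 10), s0 = 1,
                           sigma = 0, seed = 1) {
  ph <- flat_phantom(grid, D6, s0 = s0)
  img <- simulate_dwi(ph, proto)
  m <- Mod(img)
  if (sigma > 0) {
    set.seed(seed)
    n <- array(complex(real = rnorm(length(img), sd = sigma),
                       imaginary = rnorm(length(img), sd = sigma)), dim(img))
    m <- Mod(img + n)
  }
  m
}

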