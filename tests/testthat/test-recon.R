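test_that("sensitivity estimates reproduce or track the simulator maps", {
  s <- small_setup(n_channels = 3)
  ks <- acquire(s$images, s$coils, s$proto, noise_sigma = 0)
  gt <- estimate_sensitivities(ks, "ground_truth")
  expect_identical(gt$maps, s$coils$sens)

  co_u <- make_coils(1, small_grid, mode = "uniform")
  ks_u <- acquire(s$images, co_u, s$proto, noise_sigma = 0)
  sm <- estimate_sensitivities(ks_u, "smoothed_ratio")
  supp <- s$phantom$labels > 0
  # single uniform coil: unit magnitude up to global phase on the support
  expect_lt(max(abs(Mod(sm$maps[, , 1])[supp] - 1)), 1e-6)

  # self-calibrated maps track the truth (the calibration region of the
  # tiny 32-voxel grid is too coarse, so this check runs at 48 x 48)
  s48 <- small_setup(n_channels = 3, matrix_size = c(48, 48))
  ks48 <- acquire(s48$images, s48$coils, s48$proto, noise_sigma = 0)
  sm3 <- estimate_sensitivities(ks48, "smoothed_ratio")
  supp48 <- s48$phantom$labels > 0
  for (c in 1:3) {
    a <- sm3$maps[, , c][supp48]; b <- s48$coils$sens[, , c][supp48]
    r <- Mod(sum(Conj(a) * b)) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
    expect_gt(r, 0.97)
  }
})

test_that("phase maps are recovered from the symmetric k-space region", {
  # real-valued object with a uniform coil: estimated phase ~ 0 on the
  # (eroded) support
  s <- small_setup(n_channels = 2)
  ph0 <- s$phantom; ph0$phase <- matrix(0, small_grid[1], small_grid[2])
  img0 <- simulate_dwi(ph0, s$proto)
  co_u <- make_coils(1, small_grid, mode = "uniform")
  ks_u <- acquire(img0, co_u, s$proto, noise_sigma = 0)
  pm <- estimate_phase_maps(ks_u, estimate_sensitivities(ks_u, "ground_truth"))
  core <- erode_mask(ph0$labels > 0, 2)
  expect_lt(max(abs(pm[, , 1][core])), 1e-6)

  # smooth nonzero phase, realistic coils: recovered within 0.05 rad on
  # the support core
  sens <- estimate_sensitivities(
    acquire(img0, s$coils, s$proto, noise_sigma = 0), "ground_truth")
  img1 <- simulate_dwi(s$phantom, s$proto)
  ks1 <- acquire(img1, s$coils, s$proto, noise_sigma = 0)
  pm1 <- estimate_phase_maps(ks1, sens)
  expect_lt(max(abs(pm1[, , 1][core] - s$phantom$phase[core])), 0.05)

  full <- small_setup(n_channels = 1, partial_fourier = 1)
  ks_f <- acquire(full$images, full$coils, full$proto, noise_sigma = 0)
  expect_silent(estimate_phase_maps(ks_f, estimate_sensitivities(ks_f, "ground_truth")))
})

test_that("conventional reconstruction is exact when nothing degrades it", {
  s <- small_setup(n_channels = 1, partial_fourier = 1)
  co_u <- make_coils(1, small_grid, mode = "uniform")
  ks <- acquire(s$images, co_u, s$proto, noise_sigma = 0)
  sens <- estimate_sensitivities(ks, "ground_truth")
  rec <- recon_conventional(ks, sens, window = "none")
  expect_equal(rec$images, s$images, tolerance = 1e-12)
  # Hamming windowing attenuates but keeps DC scaling near 1 at center
  recw <- recon_conventional(ks, sens, window = "acquired")
  expect_false(isTRUE(all.equal(recw$images, s$images)))
})

test_that("ser_objective matches the naive double-loop oracle", {
  set.seed(31)
  ny <- 8; nx <- 8; C <- 2; Q <- 3
  proto <- dwi_protocol(matrix_size = c(ny, nx), fov_mm = c(16, 16),
                        bvals = c(0, 1000, 1000),
                        bvecs = cbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        partial_fourier = 6 / 8)
  imgs <- array(complex(real = rnorm(ny * nx * Q), imaginary = rnorm(ny * nx * Q)),
                c(ny, nx, Q))
  co <- make_coils(C, c(ny, nx), seed = 3)
  ks <- acquire(imgs, co, proto, noise_sigma = 0.1, seed = 5)
  x <- array(complex(real = rnorm(ny * nx * Q), imaginary = rnorm(ny * nx * Q)),
             c(ny, nx, Q))
  phase <- array(runif(ny * nx * Q, -pi, pi), c(ny, nx, Q))
  cfg <- ser_config(lambda_mrf = 0.7, tau = 2.5, lambda_imag = 0.3,
                    beta = c(1, 0.5, 2))
  got <- ser_objective(x, ks, co, phase, cfg)
  want <- ser_objective_naive(x, ks, co$sens, phase, cfg)
  expect_equal(got, want, tolerance = 1e-10)
  expect_identical(ser_objective(array(0i, c(ny, nx, Q)), ks, co, phase,
                                 ser_config(lambda_mrf = 1, tau = 1)) > 0, TRUE)
  expect_error(ser_objective(x[, , 1:2], ks, co, phase, cfg), "match")
})

test_that("with no regularization the joint recon solves SENSE least squares", {
  s <- small_setup(n_channels = 3, partial_fourier = 1)
  ks <- acquire(s$images, s$coils, s$proto, noise_sigma = 0.02, seed = 2)
  sens <- estimate_sensitivities(ks, "ground_truth")
  rec <- recon_ser(ks, sens, NULL, ser_config(lambda_mrf = 0, lambda_imag = 0,
                                              outer_iters = 2, cg_iters = 60,
                                              cg_tol = 1e-10))
  # full sampling: closed form x = sum(conj(s) ift(d)) / sum(|s|^2)
  num <- matrix(0 + 0i, small_grid[1], small_grid[2])
  den <- matrix(0, small_grid[1], small_grid[2])
  for (c in 1:3) {
    num <- num + Conj(s$coils$sens[, , c]) * serdti:::ift2(ks$data[, , c, 1])
    den <- den + Mod(s$coils$sens[, , c])^2
  }
  expect_equal(rec$images[, , 1], num / den, tolerance = 1e-6)
})

test_that("the tau -> Inf limit matches the dense quadratic solution", {
  ny <- 16; nx <- 16; Q <- 2
  proto <- dwi_protocol(matrix_size = c(ny, nx), fov_mm = c(32, 32),
                        bvals = c(0, 1000), bvecs = cbind(c(0, 0, 0), c(1, 0, 0)),
                        partial_fourier = 1)
  set.seed(8)
  imgs <- array(complex(real = rnorm(ny * nx * Q), imaginary = rnorm(ny * nx * Q)),
                c(ny, nx, Q))
  co <- make_coils(1, c(ny, nx), mode = "uniform")
  ks <- acquire(imgs, co, proto, noise_sigma = 0.05, seed = 4)
  lam <- 2
  rec <- recon_ser(ks, co, NULL, ser_config(lambda_mrf = lam, tau = Inf,
                                            lambda_imag = 0, outer_iters = 4,
                                            cg_iters = 400, cg_tol = 1e-12))
  # dense oracle: (I + lam L) x = ift(d), with L the 4-neighbor Laplacian
  N <- ny * nx
  L <- matrix(0, N, N)
  id <- function(i, j) (j - 1L) * ny + i
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    for (nb in list(c(i + 1, j), c(i, j + 1))) {
      if (nb[1] > ny || nb[2] > nx) next
      a <- id(i, j); b <- id(nb[1], nb[2])
      L[a, a] <- L[a, a] + 1; L[b, b] <- L[b, b] + 1
      L[a, b] <- L[a, b] - 1; L[b, a] <- L[b, a] - 1
    }
  }
  Amat <- diag(N) + lam * L
  for (q in 1:Q) {
    y <- as.vector(serdti:::ift2(ks$data[, , 1, q]))
    xq <- solve(Amat, y)
    expect_equal(as.vector(rec$images[, , q]), xq, tolerance = 1e-6)
  }
})

test_that("the half-quadratic solver is monotone and beats coordinate descent", {
  ny <- 12; nx <- 12; Q <- 2
  proto <- dwi_protocol(matrix_size = c(ny, nx), fov_mm = c(24, 24),
                        bvals = c(0, 1000), bvecs = cbind(c(0, 0, 0), c(1, 0, 0)),
                        partial_fourier = 1)
  # piecewise-constant object with a shared edge
  base <- matrix(0.2, ny, nx); base[, 7:12] <- 1
  imgs <- array(0 + 0i, c(ny, nx, Q))
  imgs[, , 1] <- base; imgs[, , 2] <- 0.7 * base
  co <- make_coils(1, c(ny, nx), mode = "uniform")
  ks <- acquire(imgs, co, proto, noise_sigma = 0.05, seed = 10)
  cfg <- ser_config(lambda_mrf = 0.8, tau = 0.3, lambda_imag = 0,
                    outer_iters = 40, cg_iters = 100, cg_tol = 1e-10,
                    outer_tol = 1e-10)
  rec <- recon_ser(ks, co, NULL, cfg)
  trace <- rec$recon_meta$objective_trace
  expect_true(all(diff(trace) <= 1e-8 * trace[-length(trace)] + 1e-12))

  # coordinate-descent oracle on the same objective (full sampling +
  # uniform coil make the data term separable: |x_qv - y_qv|^2)
  y <- array(0 + 0i, c(ny, nx, Q))
  for (q in 1:Q) y[, , q] <- serdti:::ift2(ks$data[, , 1, q])
  x <- y
  local_obj <- function(par, i, j) {
    xv <- complex(real = par[c(1, 3)], imaginary = par[c(2, 4)])
    v <- sum(Mod(xv - y[i, j, ])^2)
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > ny || nb[2] < 1 || nb[2] > nx) next
      v <- v + cfg$lambda_mrf * min(sum(Mod(xv - x[nb[1], nb[2], ])^2), cfg$tau)
    }
    v
  }
  for (sweep in 1:25) {
    delta <- 0
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      p0 <- c(Re(x[i, j, 1]), Im(x[i, j, 1]), Re(x[i, j, 2]), Im(x[i, j, 2]))
      opt <- optim(p0, local_obj, i = i, j = j, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 300))
      delta <- delta + sum(abs(opt$par - p0))
      x[i, j, ] <- complex(real = opt$par[c(1, 3)], imaginary = opt$par[c(2, 4)])
    }
    if (delta < 1e-8) break
  }
  obj_cd <- ser_objective(x, ks, co, NULL, cfg)
  obj_ser <- tail(trace, 1)
  expect_lte(obj_ser, obj_cd + 1e-6)
})

test_that("partial Fourier recovery and shared edges behave as designed", {
  # real-valued phantom, 6/8 PF, noise-free: the imaginary-part penalty
  # recovers detail the zero-filled reconstruction loses
  s <- small_setup(n_channels = 1)
  ph0 <- s$phantom; ph0$phase <- matrix(0, small_grid[1], small_grid[2])
  img0 <- simulate_dwi(ph0, s$proto)
  co_u <- make_coils(1, small_grid, mode = "uniform")
  ks <- acquire(img0, co_u, s$proto, noise_sigma = 0)
  sens <- estimate_sensitivities(ks, "ground_truth")
  pm <- estimate_phase_maps(ks, sens)
  zf <- recon_conventional(ks, sens, window = "none")
  pf <- recon_ser(ks, sens, pm, ser_config(lambda_mrf = 0, lambda_imag = 5,
                                           outer_iters = 2, cg_iters = 80,
                                           cg_tol = 1e-9))
  err_zf <- sqrt(mean(Mod(zf$images[, , 1] - img0[, , 1])^2))
  err_pf <- sqrt(mean(Mod(pf$images[, , 1] - img0[, , 1])^2))
  expect_lt(err_pf, err_zf)

  # shared-edge preservation at the default operating point: the
  # ventricle boundary contrast in the b = 0 image stays >= 90% of truth
  s2 <- small_setup(n_channels = 2, seed = 21, matrix_size = c(48, 48))
  ks2 <- acquire(s2$images, s2$coils, s2$proto, noise_sigma = 0)
  sens2 <- estimate_sensitivities(ks2, "ground_truth")
  pm2 <- estimate_phase_maps(ks2, sens2)
  cfg2 <- ser_config(lambda_mrf = 1.5, tau = 0.008 * s2$proto$n_encodings,
                     lambda_imag = 1, outer_iters = 12, cg_iters = 15)
  rec2 <- recon_ser(ks2, sens2, pm2, cfg2)
  lab <- s2$phantom$labels
  pairs <- which(lab[-1, ] == 1L & lab[-48, ] == 3L, arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  truth_c <- mean(abs(Mod(s2$images[, , 1])[cbind(i + 1, j)] -
                        Mod(s2$images[, , 1])[cbind(i, j)]))
  ser_c <- mean(abs(Mod(rec2$images[, , 1])[cbind(i + 1, j)] -
                      Mod(rec2$images[, , 1])[cbind(i, j)]))
  expect_gt(ser_c, 0.9 * truth_c)
})
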