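test_that("phantom generation is deterministic and geometrically valid", {
  p1 <- make_phantom(small_grid, seed = 3)
  p2 <- make_phantom(small_grid, seed = 3)
  expect_identical(p1, p2)
  p3 <- make_phantom(small_grid, seed = 4)
  expect_false(identical(p1$S0, p3$S0))

  expect_setequal(unique(as.vector(p1$labels)), 0:4)
  expect_true(all(p1$S0[p1$labels == 0] == 0))
  expect_true(all(p1$S0[p1$labels > 0] > 0))
  expect_error(make_phantom(c(16, 16)), "at least 32")
})

test_that("phantom tensors are SPD with the configured FA/MD and orientations", {
  ph <- make_phantom(c(48, 48), seed = 5)
  idx <- which(ph$labels > 0, arr.ind = TRUE)
  sam <- idx[seq(1, nrow(idx), by = 17), , drop = FALSE]
  for (r in seq_len(nrow(sam))) {
    i <- sam[r, 1]; j <- sam[r, 2]
    dv <- ph$D[i, j, ]
    Dm <- matrix(c(dv[1], dv[4], dv[5], dv[4], dv[2], dv[6],
                   dv[5], dv[6], dv[3]), 3, 3)
    ed <- eigen(Dm, symmetric = TRUE)
    expect_gte(min(ed$values), 0)
    m <- tensor_metrics(ed$values)
    expect_equal(m$md, ph$md_map[i, j], tolerance = 1e-10)
    expect_equal(m$fa, ph$fa_map[i, j], tolerance = 1e-8)
    if (ph$labels[i, j] %in% c(3L, 4L)) {
      # principal eigendirection parallels the stored tract orientation
      expect_gt(abs(sum(ed$vectors[, 1] * ph$e1_true[i, j, ])), 0.999)
    }
  }
  # isotropic regions have FA exactly 0
  csf <- which(ph$labels == 1L, arr.ind = TRUE)[1, ]
  dv <- ph$D[csf[1], csf[2], ]
  expect_equal(dv[1], dv[2])
  expect_equal(dv[4:6], rep(0, 3))
  expect_equal(ph$fa_map[csf[1], csf[2]], 0)
})

test_that("the DWI signal follows the monoexponential tensor model", {
  # b = 0 reproduces S0 with the phantom phase attached
  s <- small_setup()
  b0 <- which(s$proto$bvals == 0)
  expect_equal(Mod(s$images[, , b0]), s$phantom$S0, tolerance = 1e-12)
  expect_equal(Arg(s$images[, , b0])[s$phantom$S0 > 0],
               s$phantom$phase[s$phantom$S0 > 0], tolerance = 1e-10)
  expect_true(all(apply(Mod(s$images), 3, function(m) all(m <= s$phantom$S0 + 1e-12))))

  # isotropic tensor: identical attenuation exp(-b * md) in every direction
  md <- 2.0e-3
  iso <- flat_phantom(small_grid, c(md, md, md, 0, 0, 0))
  proto <- small_protocol(n_directions = 5)
  img <- simulate_dwi(iso, proto)
  for (q in which(proto$bvals > 0)) {
    expect_equal(Mod(img[, , q]) / iso$S0,
                 matrix(exp(-1000 * md), small_grid[1], small_grid[2]),
                 tolerance = 1e-12)
  }

  # anisotropic: g along x for D = diag(1.7, 0.3, 0.3)e-3 gives exp(-1.7)
  ani <- flat_phantom(small_grid, c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0))
  proto_x <- dwi_protocol(matrix_size = small_grid, fov_mm = 2 * small_grid,
                          bvals = c(0, 1000, 1000),
                          bvecs = cbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                          partial_fourier = 1)
  img_x <- simulate_dwi(ani, proto_x)
  expect_equal(Mod(img_x[1, 1, 2]), exp(-1.7), tolerance = 1e-12)
  expect_equal(Mod(img_x[1, 1, 3]), exp(-0.3), tolerance = 1e-12)

  bad <- proto_x; bad$bvecs[, 2] <- c(2, 0, 0)
  expect_error(dwi_protocol(matrix_size = small_grid, fov_mm = 2 * small_grid,
                            bvals = c(0, 1000), bvecs = cbind(c(0, 0, 0), c(2, 0, 0))),
               "non-unit")
})

test_that("coil maps are smooth, positive in quadrature, and deterministic", {
  co <- make_coils(1, small_grid, mode = "uniform")
  expect_true(all(co$sens == 1 + 0i))

  c1 <- make_coils(6, small_grid, seed = 2)
  c2 <- make_coils(6, small_grid, seed = 2)
  expect_identical(c1, c2)
  ph <- make_phantom(small_grid, seed = 1)
  expect_true(all(coil_rss(c1)[ph$labels > 0] > 0))

  # spatial smoothness: energy above |k| > kmax/4 is under 1% of total.
  # A Hann taper removes the periodization discontinuity at the FOV
  # boundary so the test measures the map's intrinsic bandwidth.
  ny <- small_grid[1]; nx <- small_grid[2]
  hann <- outer(0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1)),
                0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1)))
  for (c in 1:6) {
    K <- Mod(serdti:::ft2(hann * c1$sens[, , c]))^2
    ky <- serdti:::kgrid(small_grid[1]); kx <- serdti:::kgrid(small_grid[2])
    high <- outer(ky, kx, function(a, b) pmax(abs(a) / max(abs(ky)),
                                              abs(b) / max(abs(kx))) > 0.25)
    expect_lt(sum(K[high]) / sum(K), 0.01)
  }
})

test_that("acquisition applies sampling, ghost and noise as specified", {
  # FFT round trip: uniform single coil, full sampling, no ghost/noise
  s <- small_setup(n_channels = 1, partial_fourier = 1)
  co_u <- make_coils(1, small_grid, mode = "uniform")
  ks <- acquire(s$images, co_u, s$proto, noise_sigma = 0)
  rec <- serdti:::ift2(ks$data[, , 1, 1])
  expect_equal(rec, s$images[, , 1], tolerance = 1e-12)

  # energy conservation (unitary transform, noise-free, with coils)
  s2 <- small_setup(n_channels = 3, partial_fourier = 1)
  ks2 <- acquire(s2$images, s2$coils, s2$proto, noise_sigma = 0)
  e_img <- sum(vapply(1:3, function(c)
    sum(Mod(s2$coils$sens[, , c] * s2$images[, , 1])^2), numeric(1)))
  e_k <- sum(Mod(ks2$data[, , , 1])^2)
  expect_equal(e_k, e_img, tolerance = 1e-10)

  # 6/8 partial Fourier on 130 lines: exactly 98 acquired, most-negative
  # ky omitted
  p130 <- dti_protocol(n_directions = 2, matrix_size = c(130, 130))
  expect_identical(p130$n_acquired_pe, 98L)
  expect_identical(range(p130$ky[p130$acquired_pe]), c(-33L, 64L))
  s3 <- small_setup()               # 32 lines at 6/8 -> 24 acquired
  expect_identical(s3$proto$n_acquired_pe, 24L)
  ks3 <- acquire(s3$images, s3$coils, s3$proto, noise_sigma = 0)
  expect_true(all(ks3$data[!ks3$mask, , , ] == 0))
  expect_identical(ks3$meta$n_acquired_pe, 24L)

  # determinism of the noise stream
  ka <- acquire(s3$images, s3$coils, s3$proto, noise_sigma = 0.05, seed = 9)
  kb <- acquire(s3$images, s3$coils, s3$proto, noise_sigma = 0.05, seed = 9)
  expect_identical(ka$data, kb$data)
  expect_identical(ka$navigators, kb$navigators)

  # a ghost produces a FOV/2 replica: ghost energy metric is positive and
  # far above the ghost-free level
  sF <- small_setup(n_channels = 2, partial_fourier = 1)
  ksg <- acquire(sF$images, sF$coils, sF$proto, ghost = ghost_model(0.4, 0.002),
                 noise_sigma = 0)
  ks0 <- acquire(sF$images, sF$coils, sF$proto, noise_sigma = 0)
  sens <- estimate_sensitivities(ks0, "ground_truth")
  supp <- sF$phantom$labels > 0
  img_g <- recon_conventional(ksg, sens, window = "none")$images[, , 1]
  img_0 <- recon_conventional(ks0, sens, window = "none")$images[, , 1]
  expect_gt(ghost_energy(img_g, supp), 100 * ghost_energy(img_0, supp))
})

test_that("bval/bvec files round-trip the protocol exactly", {
  proto <- small_protocol(n_directions = 9)
  bval <- tempfile(fileext = ".bval"); bvec <- tempfile(fileext = ".bvec")
  write_bvalbvec(proto, bval, bvec)
  rt <- read_bvalbvec(bval, bvec)
  expect_identical(rt$bvals, proto$bvals)
  expect_identical(rt$bvecs, unname(proto$bvecs))
  unlink(c(bval, bvec))
})

test_that("the package Fourier convention matches an explicit DFT", {
  set.seed(42)
  x <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  expect_equal(serdti:::ft2(x), dft2_naive(x), tolerance = 1e-10)
})
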