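test_that("noise-free tensors are recovered exactly by both estimators", {
  proto <- dti_protocol(n_directions = 64, matrix_size = c(8, 10), fov_mm = c(16, 20))
  D6 <- c(1.3e-3, 0.5e-3, 0.4e-3, 0.2e-3, -0.1e-3, 0.05e-3)
  m <- tensor_signals(D6, proto)
  for (method in c("ols", "wls")) {
    fit <- fit_tensor(m, method = method, protocol = proto)
    for (i in 1:6) {
      expect_equal(fit$D[3, 3, i], D6[i], tolerance = 1e-10 * max(abs(D6)))
    }
    expect_equal(fit$s0_fit[3, 3], 1, tolerance = 1e-10)
  }

  # isotropic: fa = 0, md = the input diffusivity
  iso <- tensor_signals(c(2e-3, 2e-3, 2e-3, 0, 0, 0), proto)
  fiso <- fit_tensor(iso, protocol = proto)
  expect_equal(max(abs(fiso$fa), na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(fiso$md[2, 2], 2e-3, tolerance = 1e-12)

  # degenerate direction set: error naming the conditioning
  bad <- dwi_protocol(matrix_size = c(8, 10), fov_mm = c(16, 20),
                      bvals = c(0, rep(1000, 6)),
                      bvecs = cbind(0, matrix(rep(c(1, 0, 0), 6), 3)))
  expect_error(fit_tensor(m[, , 1:7], protocol = bad), "condition")
})

test_that("tensor metrics match their defining formulas", {
  m <- tensor_metrics(c(1, 1, 1) * 1e-3)
  expect_equal(m$md, 1e-3); expect_equal(m$fa, 0)
  expect_equal(tensor_metrics(c(5e-3, 0, 0))$fa, 1, tolerance = 1e-12)
  m2 <- tensor_metrics(c(1.7, 0.3, 0.3) * 1e-3)
  expect_equal(m2$md, 2.3e-3 / 3, tolerance = 1e-12)
  expect_equal(m2$fa, 0.7992, tolerance = 5e-4)
  # row-wise matrix input and clamping
  mm <- tensor_metrics(rbind(c(1, 1, 1), c(2, -0.1, -0.1)))
  expect_length(mm$fa, 2)
  expect_true(all(mm$fa >= 0 & mm$fa <= 1))
})

test_that("fits are equivariant under joint rotation of tensor and gradients", {
  proto <- dti_protocol(n_directions = 30, matrix_size = c(8, 10), fov_mm = c(16, 20))
  D <- matrix(c(1.6e-3, 0.1e-3, 0, 0.1e-3, 0.4e-3, 0, 0, 0, 0.3e-3), 3, 3)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  DR <- R %*% D %*% t(R)
  protoR <- proto; protoR$bvecs <- R %*% proto$bvecs
  m1 <- tensor_signals(D[c(1, 5, 9, 2, 3, 6)], proto)
  m2 <- tensor_signals(DR[c(1, 5, 9, 2, 3, 6)], protoR)
  expect_equal(m1, m2, tolerance = 1e-12)       # same quadratic forms
  f1 <- fit_tensor(m1, protocol = proto)
  f2 <- fit_tensor(m2, protocol = protoR)
  expect_equal(f1$fa[2, 2], f2$fa[2, 2], tolerance = 1e-9)
  expect_equal(f1$md[2, 2], f2$md[2, 2], tolerance = 1e-12)
  e1r <- R %*% f1$e1[2, 2, ]
  expect_gt(abs(sum(e1r * f2$e1[2, 2, ])), 1 - 1e-9)
})

test_that("log-linear WLS agrees with a nonlinear least-squares oracle", {
  proto <- dti_protocol(n_directions = 32, matrix_size = c(8, 10), fov_mm = c(16, 20))
  D6 <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  m <- tensor_signals(D6, proto, sigma = 0.1, seed = 5)   # SNR 10
  fit <- fit_tensor(m, method = "wls", protocol = proto)
  nls_fa <- function(i, j) {
    start <- c(log(fit$s0_fit[i, j]), fit$D[i, j, ])
    obj <- function(p) {
      pred <- exp(p[1]) * exp(-proto$bvals *
        (proto$bvecs[1, ]^2 * p[2] + proto$bvecs[2, ]^2 * p[3] +
           proto$bvecs[3, ]^2 * p[4] + 2 * proto$bvecs[1, ] * proto$bvecs[2, ] * p[5] +
           2 * proto$bvecs[1, ] * proto$bvecs[3, ] * p[6] +
           2 * proto$bvecs[2, ] * proto$bvecs[3, ] * p[7]))
      sum((m[i, j, ] - pred)^2)
    }
    p <- optim(start, obj, method = "BFGS",
               control = list(reltol = 1e-12, maxit = 500))$par
    Dm <- matrix(c(p[2], p[5], p[6], p[5], p[3], p[7], p[6], p[7], p[4]), 3, 3)
    tensor_metrics(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values)$fa
  }
  idx <- expand.grid(i = 1:6, j = 1:5)
  fa_nls <- mapply(nls_fa, idx$i, idx$j)
  fa_wls <- fit$fa[cbind(idx$i, idx$j)]
  truth <- tensor_metrics(c(1.7, 0.3, 0.3) * 1e-3)$fa
  # the two estimators track each other; bound recorded at first
  # implementation of this comparison
  expect_lt(median(abs(fa_wls - fa_nls)), 0.05)
  expect_lt(abs(median(fa_wls) - truth), 0.15)
})

test_that("parameter maps survive a NIfTI round trip with correct geometry", {
  proto <- dti_protocol(n_directions = 12, matrix_size = c(8, 10), fov_mm = c(16, 20))
  m <- tensor_signals(c(1.5e-3, 0.4e-3, 0.4e-3, 0, 0, 0), proto)
  fit <- fit_tensor(m, protocol = proto)
  dir <- tempfile("maps")
  paths <- export_maps(fit, dir)
  expect_true(all(file.exists(paths)))
  fa_in <- RNifti::readNifti(paths["fa"])
  expect_equal(drop(fa_in[]), fit$fa, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(RNifti::pixdim(fa_in)[1:2], proto$voxel_mm, tolerance = 1e-6)
  # color FA of an isotropic voxel is black
  iso <- fit_tensor(tensor_signals(c(1e-3, 1e-3, 1e-3, 0, 0, 0), proto),
                    protocol = proto)
  p2 <- export_maps(iso, dir, prefix = "iso")
  cfa <- RNifti::readNifti(p2["cfa"])
  expect_lt(max(abs(cfa[])), 1e-6)
  unlink(dir, recursive = TRUE)
})
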