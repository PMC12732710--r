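#' Fit diffusion tensors to a reconstructed DWI series
#'
#' Standard log-linear tensor estimation per voxel: solves
#' `log S_q = log S0 - b_q g_q' D g_q` in (weighted) least squares over
#' the 6 unique tensor components plus the log intercept. `wls` weights
#' each encoding by the squared signal (the first-order variance model for
#' log-transformed magnitude data); `ols` is unweighted. Magnitudes are
#' clipped at `min_signal` before the log. Voxels whose b = 0 magnitude
#' falls below `s0_threshold` times the maximum are excluded via
#' `fit_mask`. Eigenvalues are returned sorted descending; negative
#' eigenvalues are retained but counted in `n_negative_eig`.
#'
#' @param dwi a `dwi_series` (complex images; magnitudes are fitted) or a
#'   real array ny x nx x Q of magnitudes with a protocol attached via
#'   the `protocol` argument.
#' @param method `"wls"` (default) or `"ols"`.
#' @param min_signal positive clip applied to magnitudes before `log`.
#' @param s0_threshold support threshold relative to the maximum b = 0
#'   magnitude.
#' @param protocol protocol override when `dwi` is a bare array.
#' @return `tensor_fit`: list with `D` (ny x nx x 6: xx, yy, zz, xy, xz,
#'   yz), `eigvals` (ny x nx x 3, descending), `e1` (ny x nx x 3 unit
#'   vectors), `fa`, `md`, `s0_fit`, `fit_mask`, `residual` (per-voxel
#'   RMS log-domain residual), `n_negative_eig`, `protocol`.
#' @export
fit_tensor <- function(dwi, method = c("wls", "ols"), min_signal = 1e-6,
                       s0_threshold = 0.05, protocol = NULL) {
  method <- match.arg(method)
  if (inherits(dwi, "dwi_series")) {
    protocol <- dwi$protocol
    mags <- Mod(dwi$images)
  } else {
    if (is.null(protocol)) stop("a protocol is required with a bare magnitude array")
    mags <- abs(dwi)
  }
  stopifnot(min_signal > 0)
  Q <- protocol$n_encodings
  if (Q < 7) stop("tensor fitting needs at least 7 encodings including b = 0")
  ny <- dim(mags)[1]; nx <- dim(mags)[2]

  b <- protocol$bvals; g <- protocol$bvecs
  X <- cbind(1,
             -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  sv <- svd(X[, -1, drop = FALSE])$d
  cn <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(cn) || cn > 1e8) {
    stop(sprintf("degenerate diffusion direction set (design condition number %.3g)", cn))
  }

  b0_mag <- apply(mags[, , b == 0, drop = FALSE], c(1, 2), mean)
  fit_mask <- b0_mag >= s0_threshold * max(b0_mag)
  idx <- which(fit_mask)
  # flatten to encodings x voxels (column-major voxel order)
  S <- matrix(aperm(pmax(mags, min_signal), c(3, 1, 2)), Q, ny * nx)
  Y <- log(S[, idx, drop = FALSE])

  coef <- matrix(NA_real_, 7, length(idx))
  resid <- rep(NA_real_, length(idx))
  if (method == "ols") {
    fit <- stats::lm.fit(X, Y)
    coef <- fit$coefficients
    resid <- sqrt(colMeans(fit$residuals^2))
  } else {
    for (j in seq_along(idx)) {
      w <- S[, idx[j]]^2
      f <- stats::lm.wfit(X, Y[, j], w)
      coef[, j] <- f$coefficients
      resid[j] <- sqrt(mean(f$residuals^2))
    }
  }

  D <- array(NA_real_, c(ny, nx, 6))
  eigvals <- array(NA_real_, c(ny, nx, 3))
  e1 <- array(NA_real_, c(ny, nx, 3))
  fa <- matrix(NA_real_, ny, nx); md <- matrix(NA_real_, ny, nx)
  s0_fit <- matrix(NA_real_, ny, nx)
  res_map <- matrix(NA_real_, ny, nx)
  n_neg <- 0L
  rows <- ((idx - 1L) %% ny) + 1L
  cols <- ((idx - 1L) %/% ny) + 1L
  for (j in seq_along(idx)) {
    dv <- coef[2:7, j]
    Dm <- matrix(c(dv[1], dv[4], dv[5],
                   dv[4], dv[2], dv[6],
                   dv[5], dv[6], dv[3]), 3, 3)
    ed <- eigen(Dm, symmetric = TRUE)
    if (any(ed$values < 0)) n_neg <- n_neg + 1L
    i <- rows[j]; k <- cols[j]
    D[i, k, ] <- dv
    eigvals[i, k, ] <- ed$values
    e1[i, k, ] <- ed$vectors[, 1]
    mdfa <- tensor_metrics(ed$values)
    md[i, k] <- mdfa$md; fa[i, k] <- mdfa$fa
    s0_fit[i, k] <- exp(coef[1, j])
    res_map[i, k] <- resid[j]
  }
  structure(list(D = D, eigvals = eigvals, e1 = e1, fa = fa, md = md,
                 s0_fit = s0_fit, fit_mask = fit_mask, residual = res_map,
                 n_negative_eig = n_neg, method = method, protocol = protocol),
            class = "tensor_fit")
}

#' Mean diffusivity and fractional anisotropy from eigenvalues
#'
#' `md = (l1 + l2 + l3) / 3`;
#' `fa = sqrt(3/2) * sqrt(sum((l - md)^2)) / sqrt(sum(l^2))`, clamped to
#' `[0, 1]`. Negative eigenvalues are permitted (flagged upstream).
#'
#' @param eigvals numeric length-3 vector, or an n x 3 matrix (row-wise).
#' @return list with `md` and `fa` (vectors for matrix input).
#' @export
tensor_metrics <- function(eigvals) {
  ev <- if (is.matrix(eigvals)) eigvals else matrix(eigvals, nrow = 1)
  stopifnot(ncol(ev) == 3)
  md <- rowMeans(ev)
  num <- sqrt(rowSums((ev - md)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa <- pmin(pmax(fa, 0), 1)
  if (!is.matrix(eigvals)) list(md = md[1], fa = fa[1]) else list(md = md, fa = fa)
}

#' Export tensor parameter maps as NIfTI
#'
#' Writes FA, MD, the primary eigenvector (3-volume) and a color-FA map
#' (RGB channels `|e1| * fa`, the standard directional color convention:
#' red = x, green = y, blue = z, black where isotropic) with the voxel
#' size taken from the protocol.
#'
#' @param fit a `tensor_fit`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the written paths.
#' @export
export_maps <- function(fit, dir, prefix = "dti") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  zero_na <- function(x) { x[is.na(x)] <- 0; x }
  paths <- c(fa = file.path(dir, paste0(prefix, "_fa.nii.gz")),
             md = file.path(dir, paste0(prefix, "_md.nii.gz")),
             e1 = file.path(dir, paste0(prefix, "_e1.nii.gz")),
             cfa = file.path(dir, paste0(prefix, "_colorfa.nii.gz")))
  wr <- function(x, path) {
    img <- RNifti::asNifti(zero_na(x))
    RNifti::pixdim(img) <- c(fit$protocol$voxel_mm, 1)[seq_along(dim(img))]
    RNifti::writeNifti(img, path)
  }
  wr(fit$fa, paths["fa"])
  wr(fit$md, paths["md"])
  wr(fit$e1, paths["e1"])
  wr(abs(zero_na(fit$e1)) * array(zero_na(fit$fa), dim(fit$e1)), paths["cfa"])
  invisible(paths)
}
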