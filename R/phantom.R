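#' Labeled 2-D diffusion tensor phantom
#'
#' Constructs a per-slice digital phantom with labeled tissue regions, a
#' symmetric positive semidefinite diffusion tensor, proton density and a
#' smooth image phase at every voxel. The geometry emulates an axial
#' brain slice: a GM-like cortical rim, a CSF-like ventricle at the
#' center, and a dominant interior WM mass organized as two crossing
#' tract systems — a curved system whose orientation follows the local
#' tangent around the ventricle (emulating association fibers curving
#' around deep structures) and a straight vertical band cutting through
#' it (emulating a projection tract) — so the field contains curvature,
#' a crossing, and a realistic interior-to-boundary voxel ratio.
#'
#' Nominal per-region MD/FA values and tract orientations are returned in
#' `$regions` so downstream tests can treat them as ground truth. The seed
#' only drives a mild smooth proton-density texture and the random
#' low-order coefficients of the phase map; the geometry is deterministic.
#'
#' @param grid_size integer pair (phase-encode, readout), each >= 32.
#' @param voxel_mm voxel size pair in mm.
#' @param seed integer seed; equal seeds give bitwise-identical phantoms.
#' @param tissue optional named list overriding per-tissue `md` (mm^2/s),
#'   `fa`, and `s0` for entries `csf`, `gm`, `wm_arc`, `wm_band`.
#' @return `tensor_phantom`: list with `labels` (0 background, 1 CSF,
#'   2 GM, 3 WM arc, 4 WM band), `D` (array ny x nx x 6, components
#'   xx, yy, zz, xy, xz, yz in mm^2/s), `S0`, `phase` (radians), `e1_true`
#'   (ny x nx x 3 unit principal orientation, zero where isotropic),
#'   `fa_map`/`md_map` (the exact per-voxel ground-truth values,
#'   including a seeded smooth within-tissue modulation around the
#'   nominal region values — +/-15% for MD and +/-30% for FA, matching
#'   the wide FA heterogeneity of in-vivo white matter), `voxel_mm`, and
#'   `regions` (tibble of nominal values).
#' @examples
#' ph <- make_phantom(c(64, 64), seed = 1)
#' ph$regions
#' @export
make_phantom <- function(grid_size = c(130L, 130L),
                         voxel_mm = c(2, 2),
                         seed = 1L,
                         tissue = NULL) {
  grid_size <- as.integer(grid_size)
  if (any(grid_size < 32L)) stop("grid_size must be at least 32 per axis")
  ny <- grid_size[1]; nx <- grid_size[2]

  tis <- list(
    csf     = list(md = 3.0e-3,  fa = 0,   s0 = 1.00),
    gm      = list(md = 0.8e-3,  fa = 0,   s0 = 0.85),
    wm_arc  = list(md = 0.75e-3, fa = 0.72, s0 = 0.70),
    wm_band = list(md = 0.75e-3, fa = 0.62, s0 = 0.70)
  )
  for (nm in names(tissue)) tis[[nm]] <- utils::modifyList(tis[[nm]], tissue[[nm]])

  # normalized coordinates in [-1, 1] on the shorter half-axis
  xs <- (kgrid(nx) + 0.0) / (min(nx, ny) / 2)
  ys <- (kgrid(ny) + 0.0) / (min(nx, ny) / 2)
  X <- matrix(rep(xs, each = ny), ny, nx)
  Y <- matrix(rep(ys, times = nx), ny, nx)

  r <- sqrt((X / 1.0)^2 + (Y / 0.95)^2)
  support <- r <= 0.88
  labels <- matrix(0L, ny, nx)
  labels[support] <- 2L                                  # GM-like rim
  # dominant interior WM mass: curved tract system, tangent orientation
  wm <- r <= 0.70
  labels[wm] <- 3L
  # CSF-like ventricle at the center
  csf <- ((X / 0.20)^2 + ((Y - 0.10) / 0.13)^2) <= 1
  labels[csf] <- 1L
  # straight vertical projection band (applied last: wins at the crossing)
  band <- abs(X - 0.28) <= 0.12 & wm & !csf
  labels[band] <- 4L
  arc <- labels == 3L

  s0 <- matrix(0, ny, nx)
  s0[labels == 1L] <- tis$csf$s0
  s0[labels == 2L] <- tis$gm$s0
  s0[labels == 3L] <- tis$wm_arc$s0
  s0[labels == 4L] <- tis$wm_band$s0

  # per-voxel principal orientation (zero vector in isotropic regions)
  e1 <- array(0, c(ny, nx, 3))
  th <- atan2(Y - 0.10, X)                    # tangent around the ventricle
  idx <- which(arc)
  e1[cbind(row(labels)[idx], col(labels)[idx], 1L)] <- -sin(th[idx])
  e1[cbind(row(labels)[idx], col(labels)[idx], 2L)] <- cos(th[idx])
  idx <- which(band)
  e1[cbind(row(labels)[idx], col(labels)[idx], 2L)] <- 1
  e1[cbind(row(labels)[idx], col(labels)[idx], 1L)] <- 0

  md <- matrix(0, ny, nx); fa <- matrix(0, ny, nx)
  md[labels == 1L] <- tis$csf$md;    fa[labels == 1L] <- tis$csf$fa
  md[labels == 2L] <- tis$gm$md;     fa[labels == 2L] <- tis$gm$fa
  md[labels == 3L] <- tis$wm_arc$md; fa[labels == 3L] <- tis$wm_arc$fa
  md[labels == 4L] <- tis$wm_band$md; fa[labels == 4L] <- tis$wm_band$fa

  # smooth within-tissue biological variation (seeded), so parameter maps
  # have realistic spread around the nominal per-region values
  rnd <- with_seed(seed, {
    list(tex = 1 + 0.05 * smooth_field(ny, nx, n_lobes = 6, width = 0.35),
         fmd = smooth_field(ny, nx, n_lobes = 5, width = 0.4),
         ffa = smooth_field(ny, nx, n_lobes = 5, width = 0.4),
         cf = stats::runif(5, -1, 1))
  })
  md <- md * (1 + 0.15 * rnd$fmd)
  fa <- pmin(fa * (1 + 0.3 * rnd$ffa), 0.95)

  D <- tensor_field_from_md_fa(md, fa, e1)
  ph_map <- 0.35 * (rnd$cf[1] * X + rnd$cf[2] * Y + rnd$cf[3] * X * Y +
                      rnd$cf[4] * sin(pi * X / 2) + rnd$cf[5] * cos(pi * Y / 2))
  s0 <- s0 * rnd$tex

  regions <- tibble::tibble(
    label = 0:4,
    name = c("background", "csf", "gm", "wm_arc", "wm_band"),
    md = c(NA, tis$csf$md, tis$gm$md, tis$wm_arc$md, tis$wm_band$md),
    fa = c(NA, tis$csf$fa, tis$gm$fa, tis$wm_arc$fa, tis$wm_band$fa),
    orientation = c(NA, NA, NA, "arc tangent (in plane)", "+y")
  )

  structure(list(labels = labels, D = D, S0 = s0, phase = ph_map,
                 e1_true = e1, fa_map = fa, md_map = md,
                 voxel_mm = as.numeric(voxel_mm), regions = regions),
            class = "tensor_phantom")
}

# Axially symmetric SPD tensor field with given MD, FA and principal axis.
# Eigenvalues: l1 = md (1 + 2a), l2 = l3 = md (1 - a), a = fa / sqrt(3 - 2 fa^2).
#' @noRd
tensor_field_from_md_fa <- function(md, fa, e1) {
  a <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * a)
  l23 <- md * (1 - a)
  d <- l1 - l23
  D <- array(0, c(nrow(md), ncol(md), 6))
  D[, , 1] <- d * e1[, , 1]^2 + l23
  D[, , 2] <- d * e1[, , 2]^2 + l23
  D[, , 3] <- d * e1[, , 3]^2 + l23
  # isotropic voxels have e1 = 0: add l23 only where anisotropic, else md
  iso <- fa == 0
  D[, , 1][iso] <- md[iso]; D[, , 2][iso] <- md[iso]; D[, , 3][iso] <- md[iso]
  D[, , 4] <- d * e1[, , 1] * e1[, , 2]
  D[, , 5] <- d * e1[, , 1] * e1[, , 3]
  D[, , 6] <- d * e1[, , 2] * e1[, , 3]
  D
}

# Smooth random field: sum of broad Gaussian bumps, normalized to [-1, 1].
#' @noRd
smooth_field <- function(ny, nx, n_lobes = 6, width = 0.35) {
  xs <- kgrid(nx) / (min(nx, ny) / 2)
  ys <- kgrid(ny) / (min(nx, ny) / 2)
  X <- matrix(rep(xs, each = ny), ny, nx)
  Y <- matrix(rep(ys, times = nx), ny, nx)
  f <- matrix(0, ny, nx)
  for (i in seq_len(n_lobes)) {
    cx <- stats::runif(1, -0.8, 0.8); cy <- stats::runif(1, -0.8, 0.8)
    amp <- stats::runif(1, -1, 1)
    f <- f + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * width^2))
  }
  if (max(abs(f)) > 0) f <- f / max(abs(f))
  f
}

#' Smooth complex coil sensitivity maps
#'
#' Generates `n_channels` spatially smooth complex sensitivity maps:
#' Gaussian magnitude lobes centered on a ring just outside the image
#' support (emulating a receive array around the head) with smooth
#' low-order phase. Maps are bandlimited by construction and their
#' root-sum-of-squares is strictly positive everywhere.
#'
#' @param n_channels number of receive channels (>= 1).
#' @param grid_size integer pair (ny, nx).
#' @param seed integer seed (lobe jitter and phase coefficients).
#' @param mode `"gaussian"` (default) or `"uniform"` (all maps identically
#'   1; with `n_channels = 1` this gives an ideal single uniform coil).
#' @return `coil_set`: list with `sens` (complex array ny x nx x C) and
#'   `n_channels`.
#' @export
make_coils <- function(n_channels, grid_size, seed = 1L,
                       mode = c("gaussian", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(n_channels >= 1)
  ny <- as.integer(grid_size[1]); nx <- as.integer(grid_size[2])
  sens <- array(0 + 0i, c(ny, nx, n_channels))
  if (mode == "uniform") {
    sens[] <- 1 + 0i
    return(structure(list(sens = sens, n_channels = n_channels), class = "coil_set"))
  }
  xs <- kgrid(nx) / (min(nx, ny) / 2)
  ys <- kgrid(ny) / (min(nx, ny) / 2)
  X <- matrix(rep(xs, each = ny), ny, nx)
  Y <- matrix(rep(ys, times = nx), ny, nx)
  with_seed(seed, {
    for (c in seq_len(n_channels)) {
      th <- 2 * pi * (c - 1) / n_channels + stats::runif(1, -0.15, 0.15)
      cx <- 1.25 * cos(th); cy <- 1.25 * sin(th)
      w <- stats::runif(1, 0.85, 1.05)
      mag <- 0.05 + exp(-((X - cx)^2 + (Y - cy)^2) / (2 * w^2))
      ph <- stats::runif(1, -pi, pi) +
        0.4 * (stats::runif(1, -1, 1) * X + stats::runif(1, -1, 1) * Y)
      sens[, , c] <- mag * exp(1i * ph)
    }
  })
  structure(list(sens = sens, n_channels = n_channels), class = "coil_set")
}

#' Root-sum-of-squares magnitude of a coil set
#' @param coils a `coil_set`.
#' @return ny x nx matrix of nonnegative values.
#' @export
coil_rss <- function(coils) {
  sqrt(apply(abs(coils$sens)^2, c(1, 2), sum))
}

#' Noise-free diffusion-weighted image stack
#'
#' Evaluates the monoexponential tensor signal model per voxel and
#' encoding, `S_q = S0 * exp(-b_q g_q' D g_q)`, and attaches the phantom's
#' smooth phase map, returning one complex image per protocol encoding.
#'
#' @param phantom a `tensor_phantom` whose grid matches the protocol matrix.
#' @param protocol a `dwi_protocol`.
#' @return Complex array ny x nx x Q.
#' @export
simulate_dwi <- function(phantom, protocol) {
  ny <- nrow(phantom$S0); nx <- ncol(phantom$S0)
  if (!all(protocol$matrix_size == c(ny, nx))) {
    stop("phantom grid and protocol matrix size disagree")
  }
  Q <- protocol$n_encodings
  D <- phantom$D
  out <- array(0 + 0i, c(ny, nx, Q))
  phase <- exp(1i * phantom$phase)
  for (q in seq_len(Q)) {
    b <- protocol$bvals[q]
    if (b == 0) {
      att <- 1
    } else {
      g <- protocol$bvecs[, q]
      quad <- g[1]^2 * D[, , 1] + g[2]^2 * D[, , 2] + g[3]^2 * D[, , 3] +
        2 * (g[1] * g[2] * D[, , 4] + g[1] * g[3] * D[, , 5] +
               g[2] * g[3] * D[, , 6])
      att <- exp(-b * quad)
    }
    out[, , q] <- phantom$S0 * att * phase
  }
  out
}
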