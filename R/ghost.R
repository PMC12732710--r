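#' Navigator even/odd mismatch cost
#'
#' Least-squares mismatch between even- and odd-polarity navigator lines
#' after phase correction. Each line is taken to hybrid (x) space, the
#' odd-polarity line is multiplied by `exp(-i (phi0 + phi1 x))`, and the
#' squared difference from the mean of the even-polarity lines is summed
#' over readout samples, channels and encodings. The cost is zero iff the
#' corrected lines match exactly.
#'
#' @param phi numeric pair `c(phi0, phi1)`.
#' @param navigators a `kspace_series`, or a complex array
#'   nx x n_lines x C (x Q) of navigator k-space lines.
#' @param polarity polarity (+1 even, -1 odd) per line; defaults to the
#'   series' own, or `c(1, -1, 1)`.
#' @return Nonnegative scalar.
#' @export
navigator_cost <- function(phi, navigators, polarity = NULL) {
  if (inherits(navigators, "kspace_series")) {
    polarity <- navigators$nav_polarity
    navigators <- navigators$navigators
  }
  if (is.null(navigators) || length(navigators) == 0) {
    stop("no navigators present; acquire data with navigators to estimate ghosts")
  }
  if (is.null(polarity)) polarity <- c(1, -1, 1)
  d <- dim(navigators)
  if (length(d) == 3) dim(navigators) <- c(d, 1L)
  d <- dim(navigators)
  nx <- d[1]
  if (!any(polarity < 0)) stop("navigators contain no opposite-polarity line")
  idxf <- fftshift_vec_idx(nx); idxi <- ifftshift_vec_idx(nx)
  to_x <- function(line) stats::fft(line[idxi], inverse = TRUE)[idxf] / sqrt(nx)
  ramp <- exp(-1i * (phi[1] + phi[2] * kgrid(nx)))
  cost <- 0
  for (q in seq_len(d[4])) for (c in seq_len(d[3])) {
    ev <- 0; ne <- 0; od <- 0; no <- 0
    for (l in seq_len(d[2])) {
      h <- to_x(navigators[, l, c, q])
      if (polarity[l] > 0) { ev <- ev + h; ne <- ne + 1 }
      else { od <- od + h * ramp; no <- no + 1 }
    }
    cost <- cost + sum(Mod(ev / ne - od / no)^2)
  }
  cost
}

#' Structured low-rank (Toeplitz) ghost penalty
#'
#' Builds the convolution-structured patch matrix of the phase-corrected
#' k-space of one image (every fully-interior `filter_size` patch as a
#' row) and returns the tail energy `sum_{i > r} sigma_i^2` of its
#' singular values. A Nyquist ghost doubles the apparent image support,
#' inflating the rank of this matrix; correcting with the true phase
#' restores the compact-support structure and minimizes the tail energy.
#' Given the phase, the optimal rank-`r` subspace is eliminated in closed
#' form (the tail energy IS the variable-projection residual).
#'
#' @param kspace_one_image complex ny x nx k-space matrix (centered).
#' @param phi numeric pair `c(phi0, phi1)` used to correct odd lines
#'   before building the matrix.
#' @param rank_r retained rank (>= 1, < prod(filter_size)).
#' @param filter_size patch size, default 5 x 5.
#' @return Nonnegative scalar; 0 for an all-zero input. Invariant to
#'   global complex scaling up to `|scale|^2`.
#' @export
toeplitz_rank_penalty <- function(kspace_one_image, phi = c(0, 0),
                                  rank_r = 12L, filter_size = c(5L, 5L)) {
  f1 <- filter_size[1]; f2 <- filter_size[2]
  stopifnot(rank_r >= 1, rank_r < f1 * f2)
  if (all(kspace_one_image == 0)) return(0)
  k <- apply_ghost_phase_k(kspace_one_image, phi[1], phi[2], sign = -1)
  ny <- nrow(k); nx <- ncol(k)
  n1 <- ny - f1 + 1L; n2 <- nx - f2 + 1L
  M <- matrix(0 + 0i, n1 * n2, f1 * f2)
  col <- 0L
  for (dj in seq_len(f2) - 1L) for (di in seq_len(f1) - 1L) {
    col <- col + 1L
    M[, col] <- as.vector(k[di + seq_len(n1), dj + seq_len(n2)])
  }
  G <- crossprod(Conj(M), M)              # f1f2 x f1f2 Gram matrix, sigma^2 = eig
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(Re(ev), 0)
  sum(ev) - sum(ev[seq_len(rank_r)])
}

#' Estimate EPI ghost phase parameters by variable projection
#'
#' Minimizes a weighted combination of the navigator mismatch cost and the
#' structured low-rank Toeplitz penalty over the constant/linear phase pair
#' `(phi0, phi1)`, by coarse grid search followed by Nelder-Mead
#' refinement. For each candidate phase the low-rank subspace of the
#' Toeplitz term is eliminated in closed form, so the search runs over the
#' two phase parameters only.
#'
#' @param kseries a `kspace_series` with navigators.
#' @param weights pair `c(w_nav, w_toeplitz)`; `NULL` (default) balances
#'   the two terms' magnitudes at `phi = (0, 0)` and then down-weights
#'   the nonconvex low-rank term by 50x (the navigator mismatch has an
#'   exact zero at the true phase on noise-free data, while the low-rank
#'   term's minimizer can sit a few 1e-3 rad off it; the down-weight
#'   keeps the combined minimizer within the navigator term's basin).
#' @param search_cfg list overriding: `phi0_range` (`c(-1, 1)` rad),
#'   `phi1_range` (`c(-0.01, 0.01)` rad/sample), `n_grid` (15 per axis),
#'   `refine` (TRUE), `encodings` (default: the b = 0 index),
#'   `channels` (default first `min(2, C)`), `rank_r` (12),
#'   `filter_size` (`c(5, 5)`), `use_toeplitz` (TRUE).
#' @return `ghost_estimate`: list with `phi0_hat`, `phi1_hat`,
#'   `cost_trace` (matrix of evaluated `(phi0, phi1, cost)`), `converged`,
#'   `weights`.
#' @export
estimate_ghost <- function(kseries, weights = NULL, search_cfg = list()) {
  stopifnot(inherits(kseries, "kspace_series"))
  if (is.null(kseries$navigators)) stop("navigators required for ghost estimation")
  C <- dim(kseries$data)[3]
  cfg <- utils::modifyList(list(
    phi0_range = c(-1, 1), phi1_range = c(-0.01, 0.01), n_grid = 15L,
    refine = TRUE, encodings = which(kseries$protocol$bvals == 0)[1],
    channels = seq_len(min(2L, C)), rank_r = 12L, filter_size = c(5L, 5L),
    use_toeplitz = TRUE
  ), search_cfg)

  toe <- function(phi) {
    if (!cfg$use_toeplitz) return(0)
    s <- 0
    for (q in cfg$encodings) for (c in cfg$channels) {
      s <- s + toeplitz_rank_penalty(kseries$data[, , c, q], phi,
                                     rank_r = cfg$rank_r,
                                     filter_size = cfg$filter_size)
    }
    s
  }
  if (is.null(weights)) {
    n0 <- navigator_cost(c(0, 0), kseries)
    t0 <- toe(c(0, 0))
    weights <- c(if (n0 > 0) 1 / n0 else 1, if (t0 > 0) 0.02 / t0 else 1)
  }
  trace <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("phi0", "phi1", "cost")))
  cost_fn <- function(phi) {
    v <- weights[1] * navigator_cost(phi, kseries) + weights[2] * toe(phi)
    trace <<- rbind(trace, c(phi[1], phi[2], v))
    v
  }
  p0s <- seq(cfg$phi0_range[1], cfg$phi0_range[2], length.out = cfg$n_grid)
  p1s <- seq(cfg$phi1_range[1], cfg$phi1_range[2], length.out = cfg$n_grid)
  best <- c(0, 0); best_v <- Inf
  for (a in p0s) for (b in p1s) {
    v <- cost_fn(c(a, b))
    if (v < best_v) { best_v <- v; best <- c(a, b) }
  }
  converged <- TRUE
  if (cfg$refine) {
    # refine in grid-step units so both parameters are comparably scaled
    sc <- c(diff(cfg$phi0_range) / (cfg$n_grid - 1),
            diff(cfg$phi1_range) / (cfg$n_grid - 1))
    opt <- stats::optim(best / sc, function(p) cost_fn(p * sc),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 800))
    cand <- opt$par * sc
    cand_v <- weights[1] * navigator_cost(cand, kseries) + weights[2] * toe(cand)
    if (cand_v <= best_v) { best <- cand; best_v <- cand_v }
    else converged <- FALSE
    if (opt$convergence != 0) converged <- FALSE
  }
  structure(list(phi0_hat = best[1], phi1_hat = best[2], cost = best_v,
                 cost_trace = trace, converged = converged, weights = weights),
            class = "ghost_estimate")
}

#' Apply an even/odd phase correction to a k-space series
#'
#' Multiplies odd-indexed phase-encode lines by the conjugate estimated
#' phase in hybrid space, for both imaging data and navigators. Because
#' the correction acts row-wise (along readout only), the sampling mask is
#' untouched and unacquired lines remain exactly zero. Correcting with the
#' true parameters exactly inverts the simulated corruption (noise-free).
#'
#' @param kseries a `kspace_series`.
#' @param estimate a `ghost_estimate`, `ghost_model`, or numeric pair.
#' @return Corrected `kspace_series`.
#' @export
apply_ghost_correction <- function(kseries, estimate) {
  phi <- if (inherits(estimate, "ghost_estimate")) {
    c(estimate$phi0_hat, estimate$phi1_hat)
  } else if (inherits(estimate, "ghost_model")) {
    c(estimate$phi0, estimate$phi1)
  } else as.numeric(estimate)
  out <- kseries
  d <- dim(kseries$data)
  for (q in seq_len(d[4])) for (c in seq_len(d[3])) {
    out$data[, , c, q] <- apply_ghost_phase_k(kseries$data[, , c, q],
                                              phi[1], phi[2], sign = -1)
  }
  if (!is.null(kseries$navigators)) {
    pol <- kseries$nav_polarity
    nd <- dim(kseries$navigators)
    for (q in seq_len(nd[4])) for (c in seq_len(nd[3])) for (l in which(pol < 0)) {
      out$navigators[, l, c, q] <-
        apply_ghost_phase_line(kseries$navigators[, l, c, q],
                               phi[1], phi[2], sign = -1)
    }
  }
  out$meta$ghost_correction <- phi
  out
}

#' Nyquist ghost energy metric
#'
#' Mean squared magnitude inside the FOV/2-shifted copy of the support
#' (excluding the true support), normalized by the mean squared magnitude
#' inside the support. Near the noise floor for ghost-free images; large
#' when a FOV/2 replica is present.
#'
#' @param image complex or real image matrix.
#' @param support_mask logical matrix, TRUE on the object support.
#' @return Nonnegative scalar (0 for an all-zero image).
#' @export
ghost_energy <- function(image, support_mask) {
  ny <- nrow(image)
  if (all(image == 0)) return(0)
  shift <- floor(ny / 2)
  shifted <- support_mask[((seq_len(ny) - 1L + shift) %% ny) + 1L, , drop = FALSE]
  ghost_region <- shifted & !support_mask
  if (!any(ghost_region)) stop("shifted support leaves no ghost-only region")
  mean(Mod(image[ghost_region])^2) / mean(Mod(image[support_mask])^2)
}
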