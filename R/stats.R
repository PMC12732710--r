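# Cross-condition and test-retest comparison statistics: voxel selection
# with FA-threshold masking, simple linear regression, angular discrepancy
# of primary eigenvectors, Bland-Altman limits of agreement, and
# intra-subject coefficients of variation.

#' Voxel selection with label, FA-threshold and field-of-view rules
#'
#' Intersects (i) label-based inclusion, (ii) an FA threshold on a
#' reference FA map (the emulated analysis restricts to white-matter
#' voxels with reference FA > 0.3), and (iii) any number of
#' field-of-view/validity masks. The count surviving after each rule is
#' recorded in `rule_trace`.
#'
#' @param labels integer label map.
#' @param include_labels labels to include (default: all nonzero).
#' @param fa_reference optional reference FA map for thresholding.
#' @param fa_threshold threshold applied as `fa_reference > fa_threshold`
#'   (default 0.3); ignored if `fa_reference` is `NULL`.
#' @param fov_masks list of logical matrices intersected into the
#'   selection (e.g. fit masks of every contributing scan).
#' @return `voxel_selection`: list with logical `mask` and a `rule_trace`
#'   tibble (rule, voxels remaining).
#' @export
select_voxels <- function(labels, include_labels = NULL, fa_reference = NULL,
                          fa_threshold = 0.3, fov_masks = list()) {
  if (is.null(include_labels)) include_labels <- setdiff(unique(as.vector(labels)), 0L)
  mask <- matrix(labels %in% include_labels, nrow(labels), ncol(labels))
  trace <- tibble::tibble(rule = "labels", n = sum(mask))
  if (!is.null(fa_reference)) {
    mask <- mask & !is.na(fa_reference) & fa_reference > fa_threshold
    trace <- rbind(trace, tibble::tibble(rule = sprintf("fa > %.2f", fa_threshold),
                                         n = sum(mask)))
  }
  for (i in seq_along(fov_masks)) {
    mask <- mask & fov_masks[[i]]
    trace <- rbind(trace, tibble::tibble(rule = sprintf("fov_mask_%d", i),
                                         n = sum(mask)))
  }
  if (!any(mask)) warning("voxel selection is empty")
  structure(list(mask = mask, rule_trace = trace), class = "voxel_selection")
}

#' @noRd
selection_mask <- function(selection) {
  if (inherits(selection, "voxel_selection")) selection$mask else selection
}

#' Simple linear regression between paired parameter maps
#'
#' Ordinary least squares of `y` on `x` over the selected voxels, with
#' `r_squared = 1 - SS_res / SS_tot` (equal to the squared Pearson
#' correlation for simple OLS).
#'
#' @param x,y numeric maps (or vectors) of paired measurements.
#' @param selection a `voxel_selection` or logical mask (default: all
#'   finite pairs).
#' @return Tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress <- function(x, y, selection = NULL) {
  if (!is.null(selection)) {
    m <- selection_mask(selection)
    x <- x[m]; y <- y[m]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("regression needs at least 3 paired values")
  if (stats::var(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble::tibble(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1, n = n)
}

#' Angular discrepancy between primary eigenvector fields
#'
#' Per voxel, `angle = acos(|e1_a . e1_b|)` in degrees. The absolute
#' value folds the antipodal sign ambiguity of fiber orientations, so
#' angles lie in [0, 90].
#'
#' @param e1_a,e1_b arrays ny x nx x 3 of unit vectors (or n x 3
#'   matrices).
#' @param selection optional `voxel_selection`/mask.
#' @return `angular_report`: list with `angles` (per selected voxel,
#'   degrees), `median_deg`, `n`, and `histogram` (tibble of 5-degree
#'   bins).
#' @export
angular_discrepancy <- function(e1_a, e1_b, selection = NULL) {
  to_mat <- function(e) {
    if (length(dim(e)) == 3) matrix(e, prod(dim(e)[1:2]), 3) else as.matrix(e)
  }
  A <- to_mat(e1_a); B <- to_mat(e1_b)
  keep <- rep(TRUE, nrow(A))
  if (!is.null(selection)) keep <- as.vector(selection_mask(selection))
  keep <- keep & rowSums(is.na(A)) == 0 & rowSums(is.na(B)) == 0
  dot <- abs(rowSums(A[keep, , drop = FALSE] * B[keep, , drop = FALSE]))
  ang <- acos(pmin(dot, 1)) * 180 / pi
  brk <- seq(0, 90, by = 5)
  h <- tibble::tibble(bin_lo = brk[-length(brk)], bin_hi = brk[-1],
                      count = as.vector(table(cut(ang, brk, include.lowest = TRUE))))
  structure(list(angles = ang, median_deg = stats::median(ang), n = length(ang),
                 histogram = h),
            class = "angular_report")
}

#' Bland-Altman repeatability analysis
#'
#' Differences `d = m1 - m2` over the selection; bias is `mean(d)` and
#' the 95% limits of agreement are `bias +/- 1.96 * sd(d)` (sample sd,
#' n - 1 denominator), the interval expected to contain ~95% of paired
#' differences under normality.
#'
#' @param m1,m2 paired numeric maps or vectors.
#' @param selection optional `voxel_selection`/mask.
#' @return Tibble with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`,
#'   plus `mean_vals`/`diff_vals` kept as a list column for plotting.
#' @export
bland_altman <- function(m1, m2, selection = NULL) {
  if (!is.null(selection)) {
    m <- selection_mask(selection)
    m1 <- m1[m]; m2 <- m2[m]
  }
  ok <- is.finite(m1) & is.finite(m2)
  d <- m1[ok] - m2[ok]
  avg <- (m1[ok] + m2[ok]) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = length(d),
                 means = list(avg), diffs = list(d))
}

#' Intra-subject coefficient of variation for two repeats
#'
#' Per voxel, `cv = sd(repeats) / mean(repeats)` with the two-point sd
#' `|m1 - m2| / sqrt(2)`; the summary is the mean cv over the selection,
#' in percent. (No standard definition exists for two repeats; this
#' within-voxel sd-over-mean convention is documented package behavior.)
#'
#' @param m1,m2 paired numeric maps or vectors of the two repeats.
#' @param selection optional `voxel_selection`/mask.
#' @return Mean CoV over the selection, in percent.
#' @export
cov_intrasubject <- function(m1, m2, selection = NULL) {
  if (!is.null(selection)) {
    m <- selection_mask(selection)
    m1 <- m1[m]; m2 <- m2[m]
  }
  ok <- is.finite(m1) & is.finite(m2) & (m1 + m2) != 0
  cv <- (abs(m1[ok] - m2[ok]) / sqrt(2)) / ((m1[ok] + m2[ok]) / 2)
  100 * mean(cv)
}

#' Full comparison report for sets of tensor fits
#'
#' Runs the regression (FA and MD), angular-discrepancy, Bland-Altman and
#' CoV analyses for each configured pairing of tensor fits and collects
#' the results into a single report. A pairing is a list with `name`,
#' `a`, `b` (names into `fits`) and `kind` (`"accuracy"` for
#' method-vs-reference, `"repeatability"` for repeat-vs-repeat).
#'
#' @param fits named list of `tensor_fit` objects (a ground-truth entry
#'   may be a list with `fa`, `md`, `e1`, `fit_mask`).
#' @param pairings list of pairing specifications (see above).
#' @param selection a `voxel_selection` or logical mask applied to every
#'   pairing (intersected with both fits' masks).
#' @return `dti_comparison`: list with `summary` (one tibble row per
#'   pairing and metric), `angular` (list of `angular_report`s),
#'   `bland_altman` (list of tibbles), and `pairings`.
#' @export
compare_report <- function(fits, pairings, selection) {
  base_mask <- selection_mask(selection)
  rows <- list(); angs <- list(); bas <- list()
  for (p in pairings) {
    fa_ <- fits[[p$a]]; fb_ <- fits[[p$b]]
    m <- base_mask
    if (!is.null(fa_$fit_mask)) m <- m & fa_$fit_mask
    if (!is.null(fb_$fit_mask)) m <- m & fb_$fit_mask
    for (metric in c("fa", "md")) {
      reg <- regress(fb_[[metric]], fa_[[metric]], m)
      ba <- bland_altman(fa_[[metric]], fb_[[metric]], m)
      cv <- cov_intrasubject(fa_[[metric]], fb_[[metric]], m)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pairing = p$name, kind = p$kind, metric = toupper(metric),
        slope = reg$slope, intercept = reg$intercept, r_squared = reg$r_squared,
        bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
        loa_width = ba$loa_high - ba$loa_low,
        cov_pct = cv,
        n = reg$n)
      bas[[paste(p$name, metric, sep = "_")]] <- ba
    }
    ang <- angular_discrepancy(fa_$e1, fb_$e1, m)
    angs[[p$name]] <- ang
  }
  structure(list(summary = do.call(rbind, rows), angular = angs,
                 bland_altman = bas, pairings = pairings),
            class = "dti_comparison")
}

#' Serialize a comparison report to JSON
#'
#' Writes the summary table and per-pairing median angular discrepancies
#' (voxel-level vectors are omitted) as JSON.
#'
#' @param report a `dti_comparison`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_comparison_json <- function(report, path) {
  out <- list(
    summary = report$summary[, setdiff(names(report$summary), c("means", "diffs"))],
    median_angle_deg = lapply(report$angular, function(a) a$median_deg)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @export
print.dti_comparison <- function(x, ...) {
  cat("<dti_comparison>\n")
  print(x$summary[, c("pairing", "metric", "r_squared", "bias", "loa_width", "cov_pct", "n")])
  for (nm in names(x$angular)) {
    cat(sprintf("  median angular discrepancy [%s]: %.2f deg (n = %d)\n",
                nm, x$angular[[nm]]$median_deg, x$angular[[nm]]$n))
  }
  invisible(x)
}
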