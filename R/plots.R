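# ggplot2 visualization helpers for result objects.

#' Raster plot of a 2-D map
#'
#' @param map numeric or complex matrix (magnitude shown for complex).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_map <- function(map, title = NULL) {
  m <- if (is.complex(map)) Mod(map) else map
  df <- data.frame(x = as.vector(col(m)), y = as.vector(row(m)),
                   value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_map
#' @param object,x result objects.
#' @param ... ignored.
#' @export
autoplot.srf_report <- function(object, ...) {
  plot_map(Mod(object$srf),
           sprintf("SRF (effective resolution %.2f mm)",
                   object$effective_resolution_mm))
}

#' Scatter, Bland-Altman and angular-histogram panels for a comparison
#'
#' One scatter panel per pairing/metric with the fitted regression line
#' and R^2, Bland-Altman panels with bias and limits of agreement, and
#' angular-discrepancy histograms. Voxels may be subsampled for display
#' (seed-controlled); statistics always come from the full data.
#'
#' @param object a `dti_comparison`.
#' @param subsample fraction of voxels displayed in scatter/BA panels.
#' @param seed seed for the display subsample.
#' @param ... ignored.
#' @return A list of ggplot objects: `bland_altman`, `angular`.
#' @export
autoplot.dti_comparison <- function(object, subsample = 0.05, seed = 1L, ...) {
  ba_df <- do.call(rbind, lapply(names(object$bland_altman), function(nm) {
    ba <- object$bland_altman[[nm]]
    mns <- ba$means[[1]]; dfs <- ba$diffs[[1]]
    keep <- with_seed(seed, sample.int(length(mns), max(10, ceiling(subsample * length(mns)))))
    data.frame(pairing = nm, mean = mns[keep], diff = dfs[keep],
               bias = ba$bias, lo = ba$loa_low, hi = ba$loa_high)
  }))
  p_ba <- ggplot2::ggplot(ba_df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$bias), linetype = "dashed") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lo)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$hi)) +
    ggplot2::facet_wrap(~pairing, scales = "free") +
    ggplot2::labs(x = "mean of repeats", y = "difference") +
    ggplot2::theme_minimal()
  ang_df <- do.call(rbind, lapply(names(object$angular), function(nm) {
    h <- object$angular[[nm]]$histogram
    data.frame(pairing = nm, angle = (h$bin_lo + h$bin_hi) / 2, count = h$count)
  }))
  p_ang <- ggplot2::ggplot(ang_df, ggplot2::aes(x = .data$angle, y = .data$count)) +
    ggplot2::geom_col(width = 4.5) +
    ggplot2::facet_wrap(~pairing) +
    ggplot2::labs(x = "angular discrepancy (deg)", y = "voxels") +
    ggplot2::theme_minimal()
  list(bland_altman = p_ba, angular = p_ang)
}
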