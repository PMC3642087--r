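#' Plot a segregation curve
#'
#' Two-focus fraction against cell size for one channel; suppressed
#' (under-occupied) bins are drawn hollow.
#'
#' @param curves output of [segregation_curves()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_segregation_curve <- function(curves, ...) {
  graphics::plot(curves$bin_mid, 100 * curves$f2, type = "b",
       pch = ifelse(curves$reported, 19, 1),
       xlab = "cell size (µm)", ylab = "two-focus cells (%)",
       ylim = c(0, 100), main = curves$channel[1], ...)
  graphics::abline(h = 50, lty = 3)
}

#' Plot a switching-rule median-position profile
#'
#' Per-bin medians from [segregation_profile_curve()]: a single point on the
#' one-focus branch, a pair of points on the two-focus branch.
#'
#' @param profile output of [segregation_profile_curve()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_segregation_profile <- function(profile, ...) {
  graphics::plot(profile$bin_mid, profile$median_lo, pch = 19, ylim = c(0, 1),
       xlab = "cell size (µm)",
       ylab = "relative position (0 = new pole)",
       main = profile$channel[1], ...)
  two <- !is.na(profile$median_hi)
  graphics::points(profile$bin_mid[two], profile$median_hi[two], pch = 19)
  graphics::abline(h = 0.5, lty = 3)
}
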