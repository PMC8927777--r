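# Diagnostic plots: ENC-GC3 with the expected curve, the PR2 scatter with
# its centre lines, and the neutrality scatter with its fitted line.

#' ENC versus GC3 with the expected curve
#'
#' @param profiles data.frame from [composition_profiles()].
#' @return A ggplot object.
#' @export
plot_enc_gc3 <- function(profiles) {
  curve <- data.frame(gc3 = seq(0, 1, length.out = 201))
  curve$enc <- expected_enc(curve$gc3)
  ggplot2::ggplot(profiles, ggplot2::aes(x = gc3, y = enc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "GC3", y = "ENC") +
    ggplot2::theme_bw()
}

#' Parity-rule-2 scatter
#'
#' @param points data.frame from [pr2_points()].
#' @return A ggplot object.
#' @export
plot_pr2 <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3 / (G3 + C3)", y = "A3 / (A3 + T3)") +
    ggplot2::theme_bw()
}

#' Neutrality plot (GC12 against GC3s) with the regression line
#'
#' @param profiles data.frame from [composition_profiles()].
#' @param fit Optional [neutrality_fit()] result (computed if missing).
#' @return A ggplot object.
#' @export
plot_neutrality <- function(profiles, fit = NULL) {
  if (is.null(fit)) fit <- neutrality_fit(profiles)
  ggplot2::ggplot(profiles, ggplot2::aes(x = gc3s, y = gc12)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "red") +
    ggplot2::labs(x = "GC3s", y = "GC12",
                  title = sprintf("slope = %.3f, r = %.3f", fit$slope,
                                  fit$pearson_r)) +
    ggplot2::theme_bw()
}

utils::globalVariables(c("gc3", "enc", "x", "y", "gc3s", "gc12"))
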