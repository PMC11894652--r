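#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FDR curve
#'
#' Estimated FDR (raw and monotonized) against the number of accepted target
#' matches.
#'
#' @param object An `fdr_curve` tibble.
#' @param max_fdr Upper limit of the FDR axis (default 0.1, i.e. 10%).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fdr_curve <- function(object, max_fdr = 0.1, ...) {
  df <- dplyr::filter(object, .data$fdr_hat_monotone <= max_fdr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_target_above)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fdr_hat_capped),
                       colour = "grey60") +
    ggplot2::geom_step(ggplot2::aes(y = .data$fdr_hat_monotone),
                       colour = "#2166ac") +
    ggplot2::labs(x = "accepted target matches",
                  y = "estimated FDR",
                  title = "FDR estimate vs acceptance-set size",
                  subtitle = "grey: raw (capped at 1); blue: monotonized (q-value)") +
    ggplot2::theme_minimal()
}

#' Plot a calibration summary (FDP vs nominal FDR)
#'
#' Mean realized false discovery proportion across repetitions against the
#' nominal FDR level, with the pointwise 68% band and the identity line a
#' perfectly calibrated estimator would follow.
#'
#' @param object A `scenario_summary` tibble from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_summary <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$nominal_fdr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low,
                                      ymax = .data$band_high),
                         fill = "#2166ac", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_fdp), colour = "#2166ac") +
    ggplot2::labs(x = "nominal FDR", y = "mean FDP",
                  title = "Calibration of the QMM FDR estimate",
                  subtitle = sprintf("N = %d, pi0 = %g, f_g = %g, mu1 = %g, %d repetitions",
                                     cfg$N, cfg$pi0, cfg$f_g, cfg$mu1,
                                     attr(object, "reps"))) +
    ggplot2::theme_minimal()
}
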