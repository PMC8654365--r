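#' Plot an MSD curve
#'
#' MSD versus time lag with the fitted Brownian line when a fit is supplied.
#'
#' @param curve An [ensemble_msd()] / [compute_msd()] result.
#' @param fit Optional [fit_diffusion()] result to overlay.
#' @return A ggplot object.
#' @export
plot_msd <- function(curve, fit = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.6) +
    ggplot2::labs(
      x = "time lag (s)", y = expression(MSD ~ (mu * m^2)),
      title = "Ensemble mean squared displacement"
    ) +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(
      intercept = fit$intercept, slope = 4 * fit$D,
      linetype = 2, colour = "firebrick"
    ) +
      ggplot2::labs(subtitle = sprintf(
        "D = %.3g [%.3g, %.3g] um^2/s", fit$D, fit$ci95_lo, fit$ci95_hi
      ))
  }
  p
}

#' Plot per-cell diffusion coefficient distributions
#'
#' @param ... Named numeric vectors (or one-column data frames) of per-cell
#'   D values, one per condition.
#' @return A ggplot object (jittered points + median bar per condition).
#' @export
plot_D_distribution <- function(...) {
  groups <- list(...)
  df <- purrr::imap(groups, function(v, nm) {
    tibble(condition = nm, D = as.numeric(unlist(v)))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$D)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.5) +
    ggplot2::stat_summary(
      fun = stats::median, geom = "crossbar",
      width = 0.4, linewidth = 0.4, colour = "firebrick"
    ) +
    ggplot2::labs(x = NULL, y = expression(D ~ (mu * m^2 / s))) +
    ggplot2::theme_classic()
}

#' Plot correlated-motion statistics versus pair separation
#'
#' Mean jump magnitude and mean uncorrelated jump distance per separation
#' bin; a drop of the uncorrelated jump at small separations is the
#' correlated-motion signature of complex formation.
#'
#' @param stats A [correlated_jump_stats()] result.
#' @return A ggplot object.
#' @export
plot_correlated_motion <- function(stats) {
  long <- tidyr::pivot_longer(
    dplyr::select(
      stats, "sep_bin_nm", "mean_jump_nm", "mean_uncorr_jump_nm"
    ),
    cols = -"sep_bin_nm", names_to = "metric", values_to = "nm"
  ) |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
      mean_jump_nm = "jump magnitude",
      mean_uncorr_jump_nm = "uncorrelated jump"
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sep_bin_nm, y = .data$nm, colour = .data$metric
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "pair separation (nm)", y = "distance per frame (nm)",
      colour = NULL, title = "Correlated motion"
    ) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a bivariate Ripley result
#'
#' Experimental L(r) - r with the dashed Monte-Carlo CSR envelope; curves
#' above the envelope indicate significant co-clustering.
#'
#' @param result A [ripley_analysis()] result.
#' @return A ggplot object.
#' @export
plot_ripley <- function(result) {
  ggplot2::ggplot(result, ggplot2::aes(x = .data$r_nm)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$env_lo_nm, ymax = .data$env_hi_nm),
      fill = "grey85"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$env_lo_nm), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$env_hi_nm), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$L_minus_r_nm),
      colour = "magenta3", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "r (nm)", y = "L(r) - r (nm)",
      title = "Bivariate Ripley analysis",
      subtitle = sprintf(
        "%d CSR simulations, %.0f%% envelope",
        attr(result, "n_sims"), 100 * (1 - attr(result, "alpha"))
      )
    ) +
    ggplot2::theme_classic()
}

#' @export
#' @method autoplot ripley_result
autoplot.ripley_result <- function(object, ...) plot_ripley(object)

#' @export
#' @method autoplot msd_curve
autoplot.msd_curve <- function(object, ...) plot_msd(object)

#' @export
#' @method autoplot correlated_motion
autoplot.correlated_motion <- function(object, ...) plot_correlated_motion(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
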