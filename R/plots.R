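#' Plot simulated population trajectories
#'
#' Pooled abundance over years for every simulation, split by total, male
#' and female abundance -- the classic picture of the simulated decline.
#'
#' @param object a `lek_sims` object from [run_scenario()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lek_sims <- function(object, ...) {
  pooled <- object$truth |>
    dplyr::group_by(.data$simulation, .data$year) |>
    dplyr::summarise(Total = sum(.data$n_total), Male = sum(.data$n_male),
                     Female = sum(.data$n_female), .groups = "drop") |>
    tidyr::pivot_longer(c("Total", "Male", "Female"),
                        names_to = "component", values_to = "abundance")
  ggplot2::ggplot(pooled,
                  ggplot2::aes(.data$year, .data$abundance,
                               group = interaction(.data$simulation,
                                                   .data$component),
                               colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_manual(values = c(Total = "black",
                                            Male = "steelblue",
                                            Female = "firebrick")) +
    ggplot2::labs(x = "Year", y = "Pooled abundance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted growth model
#'
#' Posterior mean and 95% interval of pooled abundance by year, optionally
#' overlaid with the simulated truth.
#'
#' @param object a `lek_fit` object.
#' @param truth optional tibble `year`, `n` of true pooled abundance.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lek_fit <- function(object, truth = NULL, ...) {
  ints <- pooled_abundance(object)
  g <- ggplot2::ggplot(ints, ggplot2::aes(.data$year, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Pooled abundance",
                  subtitle = if (object$kind == "ss")
                    "State-space fit (max counts)" else
                    "N-mixture fit (repeated counts)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    g <- g + ggplot2::geom_line(data = truth,
                                ggplot2::aes(.data$year, .data$n),
                                colour = "firebrick", linetype = 2)
  }
  g
}

#' Plot a scenario bias study
#'
#' Mean bias per scenario with 95% quantile whiskers across simulations,
#' separating the uncorrected state-space analyses from the N-mixture
#' variants.
#'
#' @param object a `lek_bias_study` from [evaluate_scenario()] or
#'   [scenario_bias_study()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lek_bias_study <- function(object, ...) {
  s <- tidy(object) |>
    dplyr::mutate(label = paste0(.data$scenario,
                                 ifelse(.data$nmixture, "N", "")))
  ggplot2::ggplot(s, ggplot2::aes(stats::reorder(.data$label,
                                                 .data$scenario),
                                  .data$theta_mean,
                                  colour = .data$nmixture)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$theta_q2.5,
                                          ymax = .data$theta_q97.5)) +
    ggplot2::labs(x = "Scenario", y = expression(
      "Bias " * theta == bar(lambda)[sim] - bar(lambda)[true]),
      colour = "N-mixture") +
    ggplot2::theme_minimal()
}

#' Plot posterior detection probability by year
#'
#' For N-mixture fits: posterior mean and 95% interval of the
#' (site-averaged) detection probability per year, optionally against the
#' true schedule.
#'
#' @param fit a `lek_fit` from [fit_nmixture()].
#' @param truth optional tibble `year`, `p` of true mean detection.
#' @return A ggplot object.
#' @export
plot_detection <- function(fit, truth = NULL) {
  stopifnot(inherits(fit, "lek_fit_nmix"))
  pd <- tibble::tibble(year = seq_len(ncol(fit$p)),
                       mean = colMeans(fit$p),
                       lower = apply(fit$p, 2, stats::quantile, 0.025),
                       upper = apply(fit$p, 2, stats::quantile, 0.975))
  g <- ggplot2::ggplot(pd, ggplot2::aes(.data$year, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             colour = "grey40") +
    ggplot2::labs(x = "Year", y = "Detection probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    g <- g + ggplot2::geom_point(data = truth,
                                 ggplot2::aes(.data$year, .data$p),
                                 colour = "black", shape = 4, size = 2)
  }
  g
}
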