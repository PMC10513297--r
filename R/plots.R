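# ggplot2 views of replicate results and enumeration curves.

#' Swarm-style plot of per-replicate estimates
#'
#' Jittered per-replicate values of one statistic against a generating
#' condition (typically `n_families` or `k`), with the cross-replicate
#' mean overlaid — the standard view of sampling variability of the
#' penetrance estimators under ascertainment.
#'
#' @param results Output of [run_replicates()].
#' @param statistic Statistic column to plot (bare name).
#' @param x Condition column for the horizontal axis (bare name), default
#'   `n_families`.
#' @return A ggplot object.
#' @examples
#' res <- run_replicates(tidyr::crossing(f = 0.5, k = 1,
#'                                       n_families = c(10, 30)),
#'                       n_replicates = 50, seed = 1)
#' plot_replicates(res, f_tilde)
#' @export
plot_replicates <- function(results, statistic, x = n_families) {
  n_families <- NULL # quiet R CMD check; {{ x }} captures the user column
  ggplot2::ggplot(results,
                  ggplot2::aes(factor({{ x }}), {{ statistic }})) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.25, size = 0.8,
                         na.rm = TRUE) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          colour = "firebrick", linewidth = 0.4,
                          na.rm = TRUE) +
    ggplot2::labs(x = rlang::as_label(rlang::enquo(x))) +
    ggplot2::theme_minimal()
}

#' Expected counting-estimator curves by enumeration
#'
#' Exact ascertainment-weighted expectations of the counting estimators as
#' a function of the phenocopy rate, for a set of ascertainment exponents
#' — the enumeration analogue of the simulated expected-value curves.
#'
#' @param f Attributable penetrance.
#' @param k Ascertainment exponents to draw (one line per value).
#' @param s Sibship size.
#' @param gamma_grid Phenocopy rates to evaluate.
#' @return A ggplot object faceted by estimator.
#' @examples
#' plot_expected_estimates(f = 0.5, k = c(-1, 0, 1, 2))
#' @export
plot_expected_estimates <- function(f, k = c(-1, 0, 1, 2), s = 2,
                                    gamma_grid = seq(0, 0.5, by = 0.05)) {
  curves <- tidyr::crossing(gamma = gamma_grid, k = k) |>
    dplyr::mutate(res = purrr::map2(.data$gamma, .data$k, function(g, kk) {
      expected_estimates_exact(trait_model(f, g),
                               ascertainment_model(kk, s = s))
    })) |>
    tidyr::unnest("res")
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$gamma, .data$expectation,
                               colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~estimator) +
    ggplot2::labs(x = expression(gamma), y = "expected estimate",
                  colour = "k") +
    ggplot2::theme_minimal()
}
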