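# ggplot2 methods ------------------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram
#'   geom_vline geom_hline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot detected chalcogen-bond geometry
#'
#' Scatter of `alpha_min` against `d` for every reported contact, with the
#' detection thresholds drawn as reference lines (the distance threshold of
#' the first acceptor element in `params`).
#'
#' @param object A `chb_table` from [detect_chbs()].
#' @param params The [chb_params()] whose thresholds to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chb_table
#' @export
autoplot.chb_table <- function(object, params = chb_params(), ...) {
  thr <- vdw_contact_threshold(params$acceptor_elements[1], "S",
                               params$distance_tolerance, params$vdw_radii)
  ggplot(object, aes(x = .data$d, y = .data$alpha_min,
                     colour = .data$passes)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = thr, linetype = "dashed") +
    geom_hline(yintercept = params$alpha_max, linetype = "dashed") +
    labs(x = "d [Å]", y = expression(alpha[min] * " [deg]"),
         colour = "chalcogen bond") +
    theme_minimal()
}

#' Plot model-versus-experiment geometry deviations
#'
#' Histograms of the signed delta-d and delta-alpha values (model minus
#' experimental) over all matched chalcogen bonds of a comparison or survey.
#'
#' @param object A `chb_comparison` or `chb_survey` object.
#' @param binwidth_d,binwidth_alpha Histogram bin widths (Angstrom /
#'   degrees).
#' @param ... Unused.
#' @return A ggplot object (faceted: distance and angle panels).
#' @method autoplot chb_comparison
#' @export
autoplot.chb_comparison <- function(object, binwidth_d = 0.05,
                                    binwidth_alpha = 2, ...) {
  plot_delta_histograms(object$matched, binwidth_d, binwidth_alpha)
}

#' @rdname autoplot.chb_comparison
#' @method autoplot chb_survey
#' @export
autoplot.chb_survey <- function(object, binwidth_d = 0.05,
                                binwidth_alpha = 2, ...) {
  plot_delta_histograms(object$matched, binwidth_d, binwidth_alpha)
}

plot_delta_histograms <- function(matched, binwidth_d, binwidth_alpha) {
  m <- matched[!is.na(matched$delta_d), ]
  long <- bind_rows(
    tibble(metric = "Delta-d [Å]", value = m$delta_d,
           bw = binwidth_d),
    tibble(metric = "Delta-alpha [deg]", value = m$delta_alpha,
           bw = binwidth_alpha)
  )
  ggplot(long, aes(x = .data$value)) +
    geom_histogram(data = function(df) df[df$metric == long$metric[1], ],
                   binwidth = binwidth_d, fill = "steelblue",
                   colour = "white") +
    geom_histogram(data = function(df) df[df$metric != long$metric[1], ],
                   binwidth = binwidth_alpha, fill = "steelblue",
                   colour = "white") +
    geom_vline(xintercept = 0, linetype = "dashed") +
    facet_wrap(~metric, scales = "free") +
    labs(x = "model − experimental", y = "count") +
    theme_minimal()
}

#' Recovery fraction against perturbation magnitude
#'
#' Convenience line-and-point plot for synthetic noise sweeps: one recovery
#' fraction per noise level.
#'
#' @param sweep A data frame with columns `sigma` and `recovery`.
#' @return A ggplot object.
#' @export
plot_recovery_sweep <- function(sweep) {
  ggplot(as_tibble(sweep), aes(x = .data$sigma, y = .data$recovery)) +
    ggplot2::geom_line() +
    geom_point(size = 2) +
    ggplot2::ylim(0, 1) +
    labs(x = expression(sigma * " [Å]"), y = "recovery fraction") +
    theme_minimal()
}
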