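# ggplot2 views of the main result types. These are diagnostic plots, not
# publication figures.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_errorbar
#'   geom_histogram geom_vline geom_line labs position_dodge
#' @export
ggplot2::autoplot

#' Plot expression-abundance windows against divergence
#'
#' @param object A `window_points` tibble from [gea_windows()].
#' @param y Which window mean to plot against abundance: `"omega"`, `"ks"`
#'   or `"ps"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_points <- function(object, y = c("omega", "ks", "ps"), ...) {
  y <- match.arg(y)
  ycol <- paste0("mean_", y)
  ggplot(object, aes(x = .data$mean_log10_gea, y = .data[[ycol]])) +
    geom_point(shape = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "grey40", linewidth = 0.4) +
    labs(x = "mean log10 expression abundance (per 100-locus window)",
         y = paste("mean", y))
}

#' Plot the binned normal-approximation comparison
#'
#' Observed versus normal-reference bin counts.
#'
#' @param object A `bin_summary` from [make_reference_bins()] (or the
#'   `"bins"` attribute of [norm_approx_test()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bin_summary <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, c("obs_count", "ref_count"),
                           names_to = "series", values_to = "count")
  ggplot(d, aes(x = .data$bin, y = .data$count, fill = .data$series)) +
    geom_col(position = position_dodge()) +
    labs(x = "bin", y = "count", fill = NULL)
}

#' Plot a permutation-test reference distribution
#'
#' Histogram of the permutation differences with the observed difference
#' marked.
#'
#' @param object A `perm_cor_diff` from [perm_cor_diff_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_cor_diff <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$perm_diff)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$diff, colour = "red") +
    labs(x = "permutation difference in correlations", y = "count")
}

#' Plot omega by distance band around positive-selection loci
#'
#' @param object A `band_comparison` from [compare_bands()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.band_comparison <- function(object, ...) {
  g <- object$groups
  ggplot(g, aes(x = .data$band, y = .data$mean_omega)) +
    geom_col(fill = "grey60") +
    geom_errorbar(aes(ymin = .data$mean_omega - .data$sd_omega,
                      ymax = .data$mean_omega + .data$sd_omega),
                  width = 0.2) +
    labs(x = "ordinal distance band", y = "mean omega")
}

#' Plot a group profile with its letter display
#'
#' @param object A `group_profile` from [group_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_profile <- function(object, ...) {
  g <- object$groups
  ggplot(g, aes(x = .data$group, y = .data$mean)) +
    geom_col(fill = "grey60") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    ggplot2::geom_text(aes(label = .data$letters,
                           y = .data$mean + .data$sd), vjust = -0.5) +
    labs(x = NULL, y = paste("mean", object$value))
}
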