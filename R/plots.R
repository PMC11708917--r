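#' Plot crossover placement densities
#'
#' @param density Output of [placement_density()].
#' @return A ggplot.
#' @export
plot_placement_density <- function(density) {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = .data$mid, y = .data$density,
                               colour = .data$sex)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance from LG end (% of LG length)",
                  y = "density (sums to 1)", colour = "sex") +
    ggplot2::theme_minimal()
}

#' Plot Lorenz curves of the recombination landscape
#'
#' Per-LG curves in grey, the pooled genome-wide curve dashed, the identity
#' line dotted.
#'
#' @param x Output of [lorenz_gini()].
#' @return A ggplot.
#' @export
plot_lorenz <- function(x) {
  cv <- x$curve
  ggplot2::ggplot(cv[cv$lg != "genome", ],
                  ggplot2::aes(x = .data$frac_seq, y = .data$frac_cm,
                               group = .data$lg)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_line(data = cv[cv$lg == "genome", ], linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "cumulative fraction of sequence",
                  y = "cumulative fraction of cM") +
    ggplot2::theme_minimal()
}

#' Plot a windowed recombination landscape
#'
#' @param windows Window tibble from [windows_from_track()].
#' @param lgs Optional subset of linkage groups to draw.
#' @return A ggplot.
#' @export
plot_windows <- function(windows, lgs = NULL) {
  if (!is.null(lgs)) windows <- windows[windows$lg %in% lgs, ]
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = .data$start / 1e6, y = .data$cm_per_mb)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~lg, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "cM/Mb") +
    ggplot2::theme_minimal()
}

#' Plot a recombination profile around elements
#'
#' @param profile Output of [element_profile()] (or one population of
#'   [hotspot_sharing()]).
#' @return A ggplot.
#' @export
plot_element_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset_bp / 1000,
                               y = .data$mean_rel)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "offset from element (kb)",
                  y = "mean relative rate") +
    ggplot2::theme_minimal()
}

#' Plot hotspot-sharing curves across populations
#'
#' @param sharing Output of [hotspot_sharing()].
#' @param rep_prefix Prefix of pseudoreplicate population names; replicate
#'   curves are drawn in grey.
#' @return A ggplot.
#' @export
plot_sharing <- function(sharing, rep_prefix = "rep") {
  sharing$is_rep <- startsWith(sharing$pop, rep_prefix)
  ggplot2::ggplot(sharing,
                  ggplot2::aes(x = .data$offset_bp / 1000,
                               y = .data$mean_rel, group = .data$pop)) +
    ggplot2::geom_line(data = sharing[sharing$is_rep, ], colour = "grey70") +
    ggplot2::geom_line(data = sharing[!sharing$is_rep, ],
                       ggplot2::aes(colour = .data$pop)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "offset from hotspot (kb)", y = "mean relative rate",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Plot genetic versus physical length with the fitted regression
#'
#' @param x A `recland_lenreg` from [length_regression()].
#' @return A ggplot.
#' @export
plot_length_regression <- function(x) {
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$mb, y = .data$cm)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = stats::coef(x$fit)[1],
                         slope = stats::coef(x$fit)[2]) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::labs(x = "physical length (Mb)", y = "genetic length (cM)") +
    ggplot2::theme_minimal()
}
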