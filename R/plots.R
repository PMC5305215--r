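#' Plot replicate Z-scores along a ranking
#'
#' Z-scores of each replicate against rank, mirroring the scatter used to
#' judge how consistently high-ranked proteins score across replicates.
#'
#' @param ranking A `silac_ranking` tibble.
#' @param top Show only the first `top` ranks (default 250).
#' @return A ggplot object.
#' @export
plot_ranking_zscores <- function(ranking, top = 250L) {
  dat <- as_tibble(ranking) %>%
    dplyr::filter(.data$rank <= top) %>%
    tidyr::pivot_longer(dplyr::all_of(c("z1", "z2", "z3")),
                        names_to = "replicate", values_to = "z") %>%
    dplyr::filter(!is.na(.data$z))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$z,
                                    colour = .data$replicate)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "rank", y = "Z-score of log2(+NTR/Ctl)",
                  colour = "replicate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.silac_ranking <- function(object, ...) {
  plot_ranking_zscores(object, ...)
}

#' Plot an evaluation sweep
#'
#' Reported-cargo rate and recall against the percentile cutoff, with
#' -log10 Fisher p-value on a companion panel of points.
#'
#' @param points A `silac_evaluation` tibble.
#' @return A ggplot object.
#' @export
plot_evaluation_sweep <- function(points) {
  dat <- as_tibble(points) %>%
    select("cutoff_pct", "rate", "recall") %>%
    tidyr::pivot_longer(-"cutoff_pct", names_to = "measure")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cutoff_pct, y = .data$value,
                                    colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank cutoff (%)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.silac_evaluation <- function(object, ...) {
  plot_evaluation_sweep(object)
}

#' Plot a sliding-window motif density profile
#'
#' @param profile A `density_profile` tibble from [windowed_density()].
#' @return A ggplot object.
#' @export
plot_density_profile <- function(profile) {
  ggplot2::ggplot(as_tibble(profile),
                  ggplot2::aes(x = .data$position, y = .data$pct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start rank",
                  y = sprintf("motif-positive proteins per %d ranks (%%)",
                              attr(profile, "window") %||% 50L)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.density_profile <- function(object, ...) {
  plot_density_profile(object)
}

#' Plot a cargo-profile dendrogram
#'
#' @param dend A `cargo_dendrogram` from [ward_cluster()].
#' @param ... Passed to [stats::plot.hclust()].
#' @export
plot_cargo_dendrogram <- function(dend, ...) {
  plot(dend$hclust, hang = -1, xlab = "", sub = "",
       main = "Cargo-profile clustering", ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
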