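#' Heatmap of TF occupancy per regulatory region
#'
#' The standard overview figure of the occupancy analysis: miRNAs by TFs,
#' one panel per region type, tile fill = binding-site count.
#'
#' @param object An `mg_occupancy` from [tabulate_occupancy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mg_occupancy
#' @export
autoplot.mg_occupancy <- function(object, ...) {
  d <- object$entries |>
    mutate(region_type = factor(.data$region_type, levels = region_types()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf, y = .data$mir_id,
                                  fill = .data$n_sites)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n_sites > 0,
                                                   .data$n_sites, "")),
                       size = 3) +
    ggplot2::facet_wrap(~region_type) +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 name = "sites") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "TF binding-site occupancy per regulatory window") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Boxplot-style view of a group comparison
#'
#' Mean +/- SD boxes with min-max whiskers per group, the reporting style
#' used for log-scale serum miRNA levels.
#'
#' @param object An `mg_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mg_group_comparison
#' @export
autoplot.mg_group_comparison <- function(object, ...) {
  d <- object$descriptives
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$mean,
                                        ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           fill = "grey90", width = 0.5) +
    ggplot2::labs(x = NULL, y = object$meta$value_col,
                  title = "Group comparison (mean +/- SD, min-max whiskers)") +
    ggplot2::theme_minimal()
}

#' Probability profile of a motif
#'
#' Stacked per-position base probabilities (a text-free sequence-logo
#' surrogate), with the IUPAC consensus as subtitle.
#'
#' @param motif An `mg_motif` from [pwm_from_counts()].
#' @return A ggplot object.
#' @export
plot_motif <- function(motif) {
  stopifnot(inherits(motif, "mg_motif"))
  d <- as_tibble(t(motif$prob)) |>
    mutate(position = row_number()) |>
    pivot_longer(c("A", "C", "G", "T"), names_to = "base",
                 values_to = "probability")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$position),
                                  y = .data$probability, fill = .data$base)) +
    ggplot2::geom_col(color = "grey40", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255c99",
                                          G = "#f7b32b", T = "#d62839")) +
    ggplot2::labs(x = "position", y = "probability", title = motif$name,
                  subtitle = paste("consensus:", consensus_string(motif))) +
    ggplot2::theme_minimal()
}
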