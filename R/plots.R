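# ggplot2 views of triage results.

#' Filter-funnel plot of an audit trail
#'
#' Bar chart of variant counts entering and leaving each filter stage,
#' faceted by phase (initial vs post-Sanger) when both are present.
#'
#' @param object A `glioseg_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glioseg_result <- function(object, ...) {
  audit <- select(object$audit, -"dropped") |>
    mutate(stage = factor(.data$stage, levels = unique(.data$stage)))
  ggplot2::ggplot(audit,
                  ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4,
                       size = 3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$phase), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "variants retained",
                  title = "Variant filtering funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scaled C-score plot of the final candidates
#'
#' Lollipop chart of candidate records ordered by rank, coloured by
#' deleteriousness tier, with the tier boundaries (10, 20, 30) marked.
#'
#' @param result A `glioseg_result`, or a ranked candidate-record tibble.
#' @return A ggplot object.
#' @export
plot_candidate_scores <- function(result) {
  cand <- if (inherits(result, "glioseg_result")) result$candidates
          else result
  cand <- cand |>
    mutate(label = paste0(.data$gene, " (", .data$family_id, ")")) |>
    mutate(label = factor(.data$label, levels = rev(unique(.data$label))))
  ggplot2::ggplot(cand,
                  ggplot2::aes(x = .data$cadd_scaled, y = .data$label,
                               colour = .data$tier)) +
    ggplot2::geom_vline(xintercept = c(10, 20, 30), linetype = "dashed",
                        colour = "grey70") +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$cadd_scaled,
                                       yend = .data$label),
                          colour = "grey80") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "CADD scaled C-score", y = NULL, colour = "tier",
                  title = "Final candidates by predicted deleteriousness") +
    ggplot2::theme_minimal()
}
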