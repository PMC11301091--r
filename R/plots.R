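# ggplot2 visualisations of the main result types.

#' Plot category sizes of a classified OG table
#'
#' @param classified Output of [og_classify()].
#' @param og_flags Optional diet flags (`og_id`, `diet`) to fill bars by.
#' @return A ggplot.
#' @export
plot_category_summary <- function(classified, og_flags = NULL) {
  d <- classified
  if (!is.null(og_flags)) {
    d <- left_join(d, select(og_flags, "og_id", "diet"), by = "og_id") |>
      mutate(diet = ifelse(.data$diet, "diet", "non-diet"))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$category, fill = .data$diet)) +
      ggplot2::geom_bar() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = NULL, y = "ortho-groups", fill = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$category)) +
      ggplot2::geom_bar() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = NULL, y = "ortho-groups") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.diet_enrichment <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("fraction_in", "fraction_out"),
                        names_to = "side", values_to = "fraction") |>
    mutate(side = ifelse(.data$side == "fraction_in", "group", "rest"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$comparison, y = .data$fraction,
                                  fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "diet-OG fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.editome_summary <- function(object, ...) {
  ggplot2::ggplot(object$substitutions,
                  ggplot2::aes(x = stats::reorder(.data$sub, -.data$fraction),
                               y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution (transcript strand)", y = "fraction of sites") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.og_direction_test <- function(object, alpha = 0.05, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("mean_pred", "mean_phyt"),
                        names_to = "group", values_to = "mean") |>
    mutate(sem = ifelse(.data$group == "mean_pred", .data$sem_pred, .data$sem_phyt),
           group = ifelse(.data$group == "mean_pred", "predaceous", "phytophagous"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$og_id, y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean gene number (+/- SEM)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.ld_contrast <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$pair_type, y = .data$r2)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = expression(r^2)) +
    ggplot2::theme_minimal()
}

#' Plot per-category editing level and depth distributions
#'
#' @param sites Annotated editing-site tibble.
#' @return A ggplot (levels by category; depth mapped to point size in an
#'   overlaid jitter).
#' @export
plot_editing_levels <- function(sites) {
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$category, y = .data$level)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(size = .data$depth), alpha = 0.2, width = 0.2) +
    ggplot2::scale_size_continuous(range = c(0.3, 2)) +
    ggplot2::labs(x = NULL, y = "editing level", size = "depth") +
    ggplot2::theme_minimal()
}
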