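map_to_tibble <- function(m, value_name = "value") {
  idx <- which(upper.tri(m) | lower.tri(m), arr.ind = TRUE)
  out <- tibble::tibble(i = idx[, 1], j = idx[, 2], value = m[idx])
  names(out)[3] <- value_name
  out
}

#' Plot a contact map
#'
#' Upper-triangle tile plot of the binary contacts; sequence position on both
#' axes, j reversed so the diagonal runs top-left to bottom-right as in the
#' usual contact-map convention.
#'
#' @param object a `contact_map`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.contact_map <- function(object, ...) {
  df <- map_to_tibble(unclass(object))
  df <- df[df$value == 1, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position j", y = "position i",
                  title = "Contact map") +
    ggplot2::theme_minimal()
}

#' Plot a structural contact-frequency template
#'
#' @param object a `template_weight`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.template_weight <- function(object, ...) {
  df <- map_to_tibble(unclass(object), "frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position j", y = "position i",
                  fill = "contact\nfrequency",
                  title = "Template contact frequency") +
    ggplot2::theme_minimal()
}

#' Plot the true-positive curve of an evaluation
#'
#' Cumulative native contacts among the top-k predictions as a function of
#' rank k.
#'
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$tp_curve,
                  ggplot2::aes(x = .data$rank, y = .data$true_positives)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "rank", y = "true positives",
                  title = sprintf("Top-%d PPV = %.2f", object$n,
                                  object$ppv_at_n)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
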