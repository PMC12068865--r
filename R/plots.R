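# ggplot2 views of the summary objects. All plots are plain ggplot objects
# and can be re-themed by the caller.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the accessibility-score distribution
#'
#' Bar chart of score counts in width-0.1 bins.
#'
#' @param scores A per-article score tibble from [accessibility_score()],
#'   or a numeric vector of scores.
#' @return A ggplot object.
#' @export
plot_score_histogram <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  h <- score_histogram(scores)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "accessibility score", y = "articles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot resource availability by study type
#'
#' Proportion of articles stating each resource available, per study type,
#' from a battery's count table.
#'
#' @param battery A `resource_battery` object.
#' @return A ggplot object.
#' @export
plot_availability <- function(battery) {
  stopifnot(inherits(battery, "resource_battery"))
  d <- dplyr::mutate(battery$counts,
                     prop = .data$yes / (.data$yes + .data$no))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$study_type, y = .data$prop,
                                  fill = .data$resource)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "proportion stated available") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Autoplot a screening summary
#'
#' @param object A `screening_summary` from [summarize_records()].
#' @param type `"scores"` (histogram, default), `"availability"` (requires
#'   the battery) or `"repeatability"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screening_summary <- function(object,
                                       type = c("scores", "availability",
                                                "repeatability"), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    if (is.null(object$scores)) stop("no scored articles", call. = FALSE)
    return(plot_score_histogram(object$scores))
  }
  if (type == "availability") {
    if (is.null(object$battery)) stop("no battery in this summary",
                                      call. = FALSE)
    return(plot_availability(object$battery))
  }
  d <- tidyr::pivot_longer(object$repeatability,
                           cols = c("replicable", "reproducible"),
                           names_to = "dimension", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$status, y = .data$count,
                                  fill = .data$dimension)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_discrete(limits = c("NONE", "PARTIAL", "FULL")) +
    ggplot2::labs(x = "potential repeatability", y = "articles") +
    ggplot2::theme_minimal()
}
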