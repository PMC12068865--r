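#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-way ANOVA fit
#'
#' @param x A `transcreen_anova` object from [two_way_anova()].
#' @param ... Unused.
#' @return A tibble with one row per effect: `term`, `method`, `df`,
#'   `df_residual`, `statistic`, `p_raw`, `p_adjusted`.
#' @export
tidy.transcreen_anova <- function(x, ...) x$table

#' Glance at a two-way ANOVA fit
#'
#' @param x A `transcreen_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`, `nobs`.
#' @export
glance.transcreen_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, df.residual = x$fit$df.residual,
    nobs = stats::nobs(x$fit)
  )
}

#' Tidy a resource-sharing battery
#'
#' @param x A `resource_battery` object from [resource_battery()].
#' @param which `"pairwise"` (default) or `"omnibus"`.
#' @param ... Unused.
#' @return The requested results tibble.
#' @export
tidy.resource_battery <- function(x, which = c("pairwise", "omnibus"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' Glance at a resource-sharing battery
#'
#' @param x A `resource_battery` object.
#' @param ... Unused.
#' @return A one-row tibble: numbers of eligible study types, omnibus and
#'   pairwise tests, Fisher fallbacks engaged, and significant pairwise
#'   differences at the battery's alpha.
#' @export
glance.resource_battery <- function(x, ...) {
  tibble::tibble(
    n_types = length(x$settings$eligible_types),
    n_omnibus = nrow(x$omnibus),
    n_pairwise = nrow(x$pairwise),
    n_fisher = sum(x$pairwise$method == "FISHER"),
    n_significant = sum(x$pairwise$significant),
    alpha = x$settings$alpha
  )
}
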