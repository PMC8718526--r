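#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted MPT model
#'
#' One row per free parameter with its estimate, standard error, boundary
#' flag and the (group, model parameter) slots it fills.
#'
#' @param x An `mpt_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `parameter`, `group`, `estimate`,
#'   `std.error`, `boundary`. A `term` shared across groups (an equality
#'   constraint) repeats over its groups.
#' @method tidy mpt_fit
#' @export
tidy.mpt_fit <- function(x, ...) {
  x$constraints |>
    dplyr::mutate(
      term = .data$free,
      estimate = unname(x$estimates[.data$free]),
      std.error = unname(x$se[.data$free]),
      boundary = unname(x$boundary[.data$free])
    ) |>
    dplyr::select("term", parameter = "param", "group", "estimate",
                  "std.error", "boundary")
}

#' Fit summary of an MPT model
#'
#' @param x An `mpt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `g.squared`, `df`, `p.value`,
#'   `n.parameters`, `n.total`, `converged`, `n.restarts`.
#' @method glance mpt_fit
#' @export
glance.mpt_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, g.squared = x$g_squared, df = x$df,
    p.value = x$p_value, n.parameters = length(x$estimates),
    n.total = x$n_total, converged = x$converged,
    n.restarts = x$n_restarts_used
  )
}

#' Tidy a likelihood-ratio test
#'
#' @param x An `mpt_test`.
#' @param ... Unused.
#' @return A one-row tibble: `label`, `statistic` (Delta G-squared), `df`,
#'   `p.value`, `cohens.w`, `n.total`.
#' @method tidy mpt_test
#' @export
tidy.mpt_test <- function(x, ...) {
  tibble::tibble(label = x$label, statistic = x$delta_g_squared,
                 df = x$df, p.value = x$p_value, cohens.w = x$cohens_w,
                 n.total = x$n_total)
}

#' Tidy a full analysis: all likelihood-ratio tests
#'
#' @param x A `cp_analysis`.
#' @param ... Unused.
#' @return A tibble, one row per test (equality tests first, then
#'   half-split tests if present).
#' @method tidy cp_analysis
#' @export
tidy.cp_analysis <- function(x, ...) {
  tests <- c(x$equality_tests, x$half_split_tests)
  dplyr::bind_rows(lapply(tests, tidy))
}

#' Base-model fit summary of a full analysis
#'
#' @param x A `cp_analysis`.
#' @param ... Unused.
#' @return A one-row tibble (see [glance.mpt_fit()]).
#' @method glance cp_analysis
#' @export
glance.cp_analysis <- function(x, ...) glance(x$base_fit)

#' Plot parameter estimates of a fitted MPT model
#'
#' Bar chart of the estimates per model parameter, dodged by group, with
#' standard-error bars (omitted for boundary estimates, where SEs are
#' suppressed).
#'
#' @param object An `mpt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpt_fit
#' @export
autoplot.mpt_fit <- function(object, ...) {
  d <- tidy.mpt_fit(object)
  d$parameter <- factor(d$parameter, levels = object$model$params)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter,
                                  y = .data$estimate,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9),
                      width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      position = ggplot2::position_dodge(0.9), width = 0.25,
      na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "parameter estimate", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mpt_fit
#' @method autoplot cp_analysis
#' @export
autoplot.cp_analysis <- function(object, ...) autoplot(object$base_fit)

#' Power curve of the chi-square test
#'
#' @param n_total Total observation count.
#' @param df Test degrees of freedom.
#' @param alpha Significance level.
#' @param w_max Right end of the effect-size axis.
#' @return A ggplot of power against effect size w.
#' @export
plot_power_curve <- function(n_total, df = 1, alpha = 0.05, w_max = 0.15) {
  d <- tibble::tibble(w = seq(0, w_max, length.out = 200))
  d$power <- chisq_power(d$w, n_total, df, alpha)
  ggplot2::ggplot(d, ggplot2::aes(.data$w, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = "effect size w", y = "power") +
    ggplot2::theme_minimal()
}
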