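#' Upper-tail probability of the central chi-square distribution
#'
#' @param x Non-negative statistic value.
#' @param df Positive degrees of freedom.
#' @return `P(X > x)` for `X ~ chi-square(df)`. For `df = 2` this equals
#'   `exp(-x / 2)` exactly.
#' @export
#' @examples
#' chisq_sf(2.35, 2)  # 0.309
#' chisq_sf(7.14, 1)  # 0.008
chisq_sf <- function(x, df) {
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  if (any(df <= 0)) stop("`df` must be positive", call. = FALSE)
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Cohen's w effect size for a chi-square statistic
#'
#' \deqn{w = \sqrt{\Delta G^2 / N}} where `N` is the total number of
#' observations entering the joint model. For the full cooperation-and-
#' punishment design this grand total is 206 participants times 14 scored
#' trials = 2884, and the same `N` is used for within-condition and
#' half-split contrasts, matching the convention of reporting w against the
#' whole joint model.
#'
#' @param delta_g_squared Non-negative likelihood-ratio statistic.
#' @param n_total Positive total observation count of the joint model.
#' @return The effect size w.
#' @export
#' @examples
#' cohens_w(7.14, 2884)  # 0.05
cohens_w <- function(delta_g_squared, n_total) {
  if (any(n_total <= 0)) stop("`n_total` must be positive", call. = FALSE)
  if (any(delta_g_squared < 0)) {
    stop("`delta_g_squared` must be non-negative", call. = FALSE)
  }
  sqrt(delta_g_squared / n_total)
}

#' Nested likelihood-ratio (Delta G-squared) test
#'
#' Compares a restricted fit (fewer free parameters, larger df) against the
#' unrestricted fit of the same data. The statistic is
#' \eqn{\Delta G^2 = G^2_{restricted} - G^2_{unrestricted}} (floored at 0),
#' with df equal to the difference in model df, a central chi-square
#' p-value, and Cohen's w computed against the joint model's total
#' observation count. No multiplicity correction is applied; p-values are
#' raw.
#'
#' @param unrestricted,restricted `mpt_fit` objects for the same data, the
#'   restricted one nested in the unrestricted one.
#' @param n_total Total observation count for Cohen's w; defaults to the
#'   unrestricted fit's grand total.
#' @param label Optional test label.
#' @return A list of class `mpt_test`: `delta_g_squared`, `df`, `p_value`,
#'   `cohens_w`, `n_total`, `label`.
#' @export
mpt_lr_test <- function(unrestricted, restricted, n_total = NULL,
                        label = NULL) {
  stopifnot(inherits(unrestricted, "mpt_fit"), inherits(restricted, "mpt_fit"))
  if (restricted$df <= unrestricted$df) {
    stop("`restricted` must be nested in `unrestricted` (its df must be ",
         "larger)", call. = FALSE)
  }
  if (abs(restricted$n_total - unrestricted$n_total) > 1e-8) {
    stop("fits compare different data (total counts differ)", call. = FALSE)
  }
  if (is.null(n_total)) n_total <- unrestricted$n_total
  dg <- max(0, restricted$g_squared - unrestricted$g_squared)
  df <- restricted$df - unrestricted$df
  structure(list(
    delta_g_squared = dg, df = df,
    p_value = chisq_sf(dg, df),
    cohens_w = cohens_w(dg, n_total),
    n_total = n_total,
    label = label %||% "likelihood-ratio test"
  ), class = "mpt_test")
}

#' @export
print.mpt_test <- function(x, ...) {
  cat(sprintf("%s: dG2(%d) = %.2f, p = %.3f, w = %.2f (N = %d)\n",
              x$label, x$df, x$delta_g_squared, x$p_value, x$cohens_w,
              x$n_total))
  invisible(x)
}

#' Power of a chi-square test at effect size w
#'
#' Probability that a noncentral chi-square variate with noncentrality
#' \eqn{\lambda = N w^2} exceeds the central critical value at level
#' `alpha`.
#'
#' @param w Non-negative effect size.
#' @param n_total Total observation count.
#' @param df Degrees of freedom of the test.
#' @param alpha Significance level in (0, 1).
#' @return The power; equals `alpha` at `w = 0`.
#' @export
#' @examples
#' chisq_power(0.07, 2884, 1)  # about 0.96
chisq_power <- function(w, n_total, df, alpha = 0.05) {
  if (any(alpha <= 0 | alpha >= 1)) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (any(w < 0)) stop("`w` must be non-negative", call. = FALSE)
  crit <- stats::qchisq(alpha, df, lower.tail = FALSE)
  stats::pchisq(crit, df, ncp = n_total * w^2, lower.tail = FALSE)
}

#' Smallest effect size detectable at a target power
#'
#' Solves `chisq_power(w, n_total, df, alpha) = target_power` for w by a
#' bracketing root-finder (tolerance 1e-6). This is the sensitivity
#' calculation behind statements like "effects of size w could be detected
#' with power 0.95".
#'
#' @param target_power Desired power, in `(alpha, 1)`.
#' @inheritParams chisq_power
#' @return The detectable effect size w.
#' @export
#' @examples
#' detectable_effect_size(0.95, 2884, 1)  # 0.07
detectable_effect_size <- function(target_power, n_total, df, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (target_power <= alpha || target_power >= 1) {
    stop("`target_power` must lie in (alpha, 1)", call. = FALSE)
  }
  f <- function(w) chisq_power(w, n_total, df, alpha) - target_power
  upper <- 1
  while (f(upper) < 0 && upper < 1e3) upper <- upper * 2
  if (f(upper) < 0) stop("target power not attainable: cannot bracket root",
                         call. = FALSE)
  stats::uniroot(f, c(0, upper), tol = 1e-6)$root
}
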