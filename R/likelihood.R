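#' @importFrom rlang .data
NULL

# Validate and normalise a frequency table: tibble(group, tree, category, n).
# A missing `group` column means a single group. Counts must be finite and
# non-negative; they may be non-integral (expected counts are legal input
# for noise-free fitting checks).
as_freq_table <- function(freqs) {
  stopifnot(is.data.frame(freqs))
  freqs <- tibble::as_tibble(freqs)
  if (!"group" %in% names(freqs)) freqs$group <- "g1"
  need <- c("group", "tree", "category", "n")
  if (!all(need %in% names(freqs))) {
    stop("frequency table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(freqs$n)) || any(freqs$n < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  freqs[, need]
}

join_probs <- function(freqs, probs) {
  probs <- tibble::as_tibble(probs)
  keys <- intersect(c("group", "tree", "category"), names(probs))
  if (!"tree" %in% keys || !"category" %in% keys) {
    stop("probability table needs `tree` and `category` columns",
         call. = FALSE)
  }
  out <- dplyr::left_join(freqs, probs[, c(keys, "prob")], by = keys)
  if (any(is.na(out$prob))) {
    stop("probability table does not cover every observed (tree, category)",
         call. = FALSE)
  }
  out
}

#' Multinomial log-likelihood of observed category counts
#'
#' Computes \eqn{\sum_i n_i \log p_i} across all groups, trees and
#' categories, with the \eqn{0 \log 0} term defined as 0. The constant
#' multinomial coefficient is omitted, so values are comparable across
#' models fitted to the same counts but are not absolute log-probabilities.
#'
#' @param freqs Data frame of counts with columns `tree`, `category`, `n`
#'   and optionally `group`.
#' @param probs Data frame of category probabilities with columns `tree`,
#'   `category`, `prob` and optionally `group` (e.g. from
#'   [category_probabilities()]).
#' @return The log-likelihood; `-Inf` (with a warning) when a category with
#'   a positive count has probability 0.
#' @export
#' @examples
#' f <- data.frame(tree = "t", category = c("a", "b"), n = c(30, 70))
#' p <- data.frame(tree = "t", category = c("a", "b"), prob = c(0.5, 0.5))
#' mpt_loglik(f, p)  # 100 * log(0.5)
mpt_loglik <- function(freqs, probs) {
  d <- join_probs(as_freq_table(freqs), probs)
  pos <- d$n > 0
  if (any(pos & d$prob <= 0)) {
    warning("positive count on a zero-probability category: ",
            "log-likelihood is -Inf", call. = FALSE)
    return(-Inf)
  }
  sum(d$n[pos] * log(d$prob[pos]))
}

#' Likelihood-ratio goodness-of-fit statistic G-squared
#'
#' \deqn{G^2 = 2 \sum_i n_i \log(n_i / e_i)} summed over all categories
#' with \eqn{n_i > 0} across trees and groups, where the expected count
#' \eqn{e_i} is the category probability times its tree's total. Equals
#' twice the log-likelihood difference between the saturated model and the
#' supplied probabilities; non-negative when the probabilities are the
#' fitted maximum-likelihood values.
#'
#' @inheritParams mpt_loglik
#' @return The G-squared statistic; `Inf` (with a warning) when a positive
#'   count has zero expected count.
#' @export
#' @examples
#' f <- data.frame(tree = "t", category = c("a", "b"), n = c(30, 70))
#' p <- data.frame(tree = "t", category = c("a", "b"), prob = c(0.5, 0.5))
#' mpt_g2(f, p)  # about 16.46
mpt_g2 <- function(freqs, probs) {
  d <- join_probs(as_freq_table(freqs), probs)
  d <- d |>
    dplyr::group_by(.data$group, .data$tree) |>
    dplyr::mutate(expected = .data$prob * sum(.data$n)) |>
    dplyr::ungroup()
  pos <- d$n > 0
  if (any(pos & d$expected <= 0)) {
    warning("positive count with zero expected count: G-squared is Inf",
            call. = FALSE)
    return(Inf)
  }
  2 * sum(d$n[pos] * log(d$n[pos] / d$expected[pos]))
}

# Saturated log-likelihood: categories at their observed tree proportions.
saturated_loglik <- function(freqs) {
  d <- as_freq_table(freqs) |>
    dplyr::group_by(.data$group, .data$tree) |>
    dplyr::mutate(phat = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  pos <- d$n > 0
  sum(d$n[pos] * log(d$phat[pos]))
}
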