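#' Aggregate trial records into category frequencies
#'
#' Maps every scored (non-training) trial to one of the model's 8
#' categories — partner type selects the tree, the participant's choice and
#' the binary punishment decision (any investment of 1-9 cents counts as
#' punishment) select the category — and tallies counts per group. The
#' model treats punishment as binary; punishment *height* is analyzed
#' separately ([punishment_height_anova()]).
#'
#' @param trials Tibble of trial records (see [simulate_experiment()]).
#' @param split_half If `TRUE`, groups are condition x experiment half
#'   (trial index 1-10 vs 11-20, training trials still excluded), labelled
#'   `"<condition>.first"` / `"<condition>.second"`.
#' @return A tibble with columns `group`, `tree`, `category`, `n`,
#'   complete over all categories (zero-filled), groups in order of first
#'   appearance.
#' @export
aggregate_frequencies <- function(trials, split_half = FALSE) {
  trials <- tibble::as_tibble(trials)
  need <- c("participant_id", "condition", "trial_index", "partner_type",
            "participant_choice", "participant_punish_cents", "is_training")
  if (!all(need %in% names(trials))) {
    stop("trials need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!trials$participant_punish_cents %in% 0:9)
  if (length(bad)) {
    stop("punish amount outside 0-9 cents in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  grp_of <- function(d) {
    if (split_half) {
      paste0(d$condition, ".",
             ifelse(d$trial_index <= 10, "first", "second"))
    } else {
      d$condition
    }
  }
  scored <- trials[!trials$is_training, ]
  grp <- grp_of(scored)
  # the group universe comes from all trials, so a group whose scored
  # trials are absent still gets an all-zero table
  groups_all <- unique(grp_of(trials))
  d <- tibble::tibble(
    group = as.character(grp),
    tree = as.character(ifelse(scored$partner_type == "defector",
                               "defector_partner", "cooperator_partner")),
    category = paste0(
      ifelse(scored$participant_choice == "cooperate", "coop", "defect"),
      ifelse(scored$participant_punish_cents > 0, "_punish", "_nopunish"))
  )
  m <- cp_model()
  layout <- purrr::map_dfr(names(m$trees), function(t)
    tibble::tibble(tree = t, category = m$trees[[t]]))
  groups <- groups_all
  if (length(groups) == 0L) {
    return(tibble::tibble(group = character(), tree = character(),
                          category = character(), n = integer()))
  }
  full <- tidyr::expand_grid(group = groups, layout)
  counts <- dplyr::count(d, .data$group, .data$tree, .data$category)
  dplyr::left_join(full, counts, by = c("group", "tree", "category")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' One-way ANOVA of mean punishment height between conditions
#'
#' Among participants who punished at least once in a scored trial,
#' compares the per-participant mean punishment investment (cents, over
#' their punishing trials only) between conditions with a standard one-way
#' ANOVA.
#'
#' @param trials Tibble of trial records.
#' @return A list of class `cp_height_anova`: `f`, `df_between`,
#'   `df_within`, `p_value`, `mean`, `sd` (grand mean/SD of the
#'   per-participant means), `by_condition` (tibble of n/mean/sd), and
#'   `heights` (the per-participant data).
#' @export
punishment_height_anova <- function(trials) {
  trials <- tibble::as_tibble(trials)
  scored <- trials[!trials$is_training &
                     trials$participant_punish_cents > 0, ]
  heights <- scored |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(mean_height = mean(.data$participant_punish_cents),
                     .groups = "drop")
  if (nrow(heights) < 2 || dplyr::n_distinct(heights$condition) < 2) {
    stop("need punishing participants in at least two conditions",
         call. = FALSE)
  }
  empty <- setdiff(unique(trials$condition), unique(heights$condition))
  if (length(empty)) {
    warning("condition(s) without any punisher skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(mean_height ~ condition, data = heights)
  a <- stats::anova(fit)
  by_cond <- heights |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$mean_height),
                     sd = stats::sd(.data$mean_height), .groups = "drop")
  structure(list(
    f = a$`F value`[1], df_between = a$Df[1], df_within = a$Df[2],
    p_value = a$`Pr(>F)`[1],
    mean = mean(heights$mean_height), sd = stats::sd(heights$mean_height),
    by_condition = by_cond, heights = heights
  ), class = "cp_height_anova")
}

#' @export
print.cp_height_anova <- function(x, ...) {
  cat(sprintf(
    "Punishment height: mean %.1f cents (SD = %.1f), F(%d,%d) = %.2f, p = %.3f\n",
    x$mean, x$sd, x$df_between, x$df_within, x$f, x$p_value))
  invisible(x)
}

# constraints equating `param` across the two halves of each condition,
# everything else free per group; groups are "<cond>.first"/"<cond>.second"
half_split_constraints <- function(model, groups, param, condition) {
  base <- mpt_constraints(model, groups)
  tied <- startsWith(base$group, paste0(condition, ".")) &
    base$param == param
  base$free[tied] <- paste0(param, "[", condition, "]")
  base
}

#' Run the full cooperation-and-punishment analysis battery
#'
#' Reproduces the complete inferential pipeline on a set of trials or a
#' simulated experiment: (1) exclusion rule (for experiments), (2)
#' aggregation to category frequencies, (3) joint base-model fit — one
#' five-parameter tree pair per condition, all parameters free (with two
#' conditions: 10 free parameters against 12 free category probabilities,
#' hence 2 df), (4) five 1-df equality tests, one per parameter, each
#' refitting with that parameter forced equal across conditions, (5)
#' optionally the half-split analyses (per parameter and condition,
#' equality across experiment halves in a joint condition-by-half model)
#' and (6) the punishment-height ANOVA. Cohen's w for every test uses the
#' grand scored-observation total of the joint model.
#'
#' @param x A `cp_experiment` or a tibble of trial records.
#' @param control An [fit_control()].
#' @param exclusion_threshold Tone-accuracy threshold (experiments only).
#' @param half_split Run the half-split analyses.
#' @param height_anova Run the punishment-height ANOVA.
#' @return A list of class `cp_analysis`: `base_fit`, `equality_tests`
#'   (named list of `mpt_test`), `half_split_tests`, `punishment_height`,
#'   `exclusions`, `provenance`.
#' @export
run_cp_analysis <- function(x, control = fit_control(),
                            exclusion_threshold = 0.75,
                            half_split = TRUE, height_anova = TRUE) {
  exclusions <- NULL
  seed <- NA_integer_
  if (inherits(x, "cp_experiment")) {
    x <- apply_exclusions(x, exclusion_threshold)
    exclusions <- x$exclusions
    seed <- x$config$seed
    trials <- x$trials
  } else {
    trials <- tibble::as_tibble(x)
  }
  conds <- unique(trials$condition)
  if (length(conds) < 2) {
    stop("the analysis needs at least two conditions", call. = FALSE)
  }
  model <- cp_model()
  freqs <- aggregate_frequencies(trials)
  log_stage("aggregate", nrow(trials), sum(freqs$n), seed)

  base_fit <- fit_mpt(freqs, model, control = control)
  n_total <- base_fit$n_total
  log_stage("base_fit", sum(freqs$n), base_fit$df, seed)

  equality_tests <- lapply(cp_param_names(), function(par) {
    restricted <- fit_mpt(freqs, model,
                          constraints = mpt_constraints(model, conds,
                                                        equate = par),
                          control = control, compute_se = FALSE)
    mpt_lr_test(base_fit, restricted, n_total = n_total,
                label = paste0(par, " equal across conditions"))
  })
  names(equality_tests) <- cp_param_names()

  half_split_tests <- NULL
  if (half_split) {
    freqs_h <- aggregate_frequencies(trials, split_half = TRUE)
    groups_h <- unique(freqs_h$group)
    fit_h <- fit_mpt(freqs_h, model, control = control, compute_se = FALSE)
    half_split_tests <- list()
    for (cond in conds) {
      for (par in cp_param_names()) {
        restricted <- fit_mpt(
          freqs_h, model,
          constraints = half_split_constraints(model, groups_h, par, cond),
          control = control, compute_se = FALSE)
        half_split_tests[[paste0(par, "|", cond)]] <-
          mpt_lr_test(fit_h, restricted, n_total = n_total,
                      label = paste0(par, " equal across halves (", cond,
                                     ")"))
      }
    }
  }

  height <- NULL
  if (height_anova) {
    height <- tryCatch(punishment_height_anova(trials),
                       error = function(e) {
                         warning(conditionMessage(e), call. = FALSE)
                         NULL
                       })
  }

  structure(list(
    base_fit = base_fit, equality_tests = equality_tests,
    half_split_tests = half_split_tests, punishment_height = height,
    exclusions = exclusions,
    provenance = list(seed = seed,
                      config_hash = rlang::hash(list(conds, control)),
                      n_total = n_total)
  ), class = "cp_analysis")
}

log_stage <- function(stage, n_in, n_out, seed) {
  message(sprintf("[mptcoop] stage=%s in=%s out=%s seed=%s",
                  stage, n_in, n_out, seed))
}

#' @export
print.cp_analysis <- function(x, ...) {
  writeLines(report_lines(x))
  invisible(x)
}

#' Journal-style text report of an analysis
#'
#' G-squared to 2 decimals, p to 3 decimals, w to 2 decimals; the
#' machine-readable serialization ([write_cp_report()]) keeps full
#' precision.
#'
#' @param analysis A `cp_analysis`.
#' @return Character vector of report lines.
#' @export
report_lines <- function(analysis) {
  b <- analysis$base_fit
  out <- c(
    "Cooperation-and-punishment MPT analysis",
    sprintf("Base model: G2(%d) = %.2f, p = %.3f  (N = %d)",
            b$df, b$g_squared, b$p_value, b$n_total),
    "Equality of parameters across conditions:")
  fmt_test <- function(t) {
    sprintf("  %-42s dG2(%d) = %.2f, p = %.3f, w = %.2f",
            t$label, t$df, t$delta_g_squared, t$p_value, t$cohens_w)
  }
  out <- c(out, vapply(analysis$equality_tests, fmt_test, character(1)))
  if (!is.null(analysis$half_split_tests)) {
    out <- c(out, "Half-split analyses:",
             vapply(analysis$half_split_tests, fmt_test, character(1)))
  }
  h <- analysis$punishment_height
  if (!is.null(h)) {
    out <- c(out, sprintf(
      "Punishment height: mean %.1f cents (SD = %.1f), F(%d,%d) = %.2f, p = %.3f",
      h$mean, h$sd, h$df_between, h$df_within, h$f, h$p_value))
  }
  if (!is.null(analysis$exclusions)) {
    out <- c(out, sprintf("Excluded participants (tone rule): %d",
                          nrow(analysis$exclusions)))
  }
  out
}

#' Serialize an analysis to a flat key-value report
#'
#' Full-precision machine-readable lines (`key=value`); deterministic, so
#' identical seeds and configs produce byte-identical files.
#'
#' @param analysis A `cp_analysis`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return The lines, invisibly when written to `path`.
#' @export
write_cp_report <- function(analysis, path = NULL) {
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  b <- analysis$base_fit
  lines <- c(
    paste0("base_fit.g_squared=", num(b$g_squared)),
    paste0("base_fit.df=", b$df),
    paste0("base_fit.p_value=", num(b$p_value)),
    paste0("base_fit.loglik=", num(b$loglik)),
    paste0("base_fit.n_total=", b$n_total),
    paste0("base_fit.converged=", b$converged),
    paste0("estimate.", names(b$estimates), "=", num(b$estimates)),
    paste0("se.", names(b$se), "=", num(b$se))
  )
  add_tests <- function(tests, prefix) {
    unlist(lapply(names(tests), function(nm) {
      t <- tests[[nm]]
      paste0(prefix, nm, ".",
             c("delta_g_squared", "df", "p_value", "cohens_w", "n_total"),
             "=", c(num(t$delta_g_squared), t$df, num(t$p_value),
                    num(t$cohens_w), t$n_total))
    }))
  }
  lines <- c(lines, add_tests(analysis$equality_tests, "test."))
  if (!is.null(analysis$half_split_tests)) {
    lines <- c(lines, add_tests(analysis$half_split_tests, "half_split."))
  }
  h <- analysis$punishment_height
  if (!is.null(h)) {
    lines <- c(lines,
               paste0("height.", c("mean", "sd", "f", "df_between",
                                   "df_within", "p_value"),
                      "=", c(num(h$mean), num(h$sd), num(h$f),
                             h$df_between, h$df_within, num(h$p_value))))
  }
  lines <- c(lines,
             paste0("provenance.seed=", analysis$provenance$seed),
             paste0("provenance.config_hash=",
                    analysis$provenance$config_hash))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
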