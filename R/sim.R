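#' Payoff and design constants of the Prisoner's Dilemma game
#'
#' All amounts are integer cents. Cooperation means investing
#' `investment` cents; the pot (sum of investments) earns a bonus of
#' `bonus_factor` times itself and the total is split evenly. Punishing
#' costs the punisher 1-9 cents and deducts `punish_ratio` times that from
#' the target. Each participant meets `partners_per_type` cooperating and
#' defecting partners; the first `training_per_type` encounters with each
#' type are unscored training trials.
#'
#' @param endowment Starting account balance in cents.
#' @param investment Cost of cooperating, cents.
#' @param bonus_factor Bonus as a fraction of the invested pot.
#' @param punish_cost_range Selectable punishment investments, cents.
#' @param punish_ratio Cents deducted from the target per cent invested.
#' @param partners_per_type Partners of each type per participant.
#' @param training_per_type Unscored initial encounters per partner type.
#' @return A list of class `game_config`.
#' @export
game_config <- function(endowment = 400L, investment = 30L,
                        bonus_factor = 1 / 3, punish_cost_range = 1:9,
                        punish_ratio = 10L, partners_per_type = 10L,
                        training_per_type = 3L) {
  stopifnot(endowment >= 0, investment >= 0, punish_ratio >= 0,
            all(punish_cost_range >= 0),
            training_per_type < partners_per_type)
  structure(list(endowment = endowment, investment = investment,
                 bonus_factor = bonus_factor,
                 punish_cost_range = punish_cost_range,
                 punish_ratio = punish_ratio,
                 partners_per_type = partners_per_type,
                 training_per_type = training_per_type),
            class = "game_config")
}

#' Payoffs of one Prisoner's Dilemma round
#'
#' Each cooperating player invests `config$investment` cents, a defector
#' invests nothing; the pot plus its bonus is split evenly and each
#' player's payoff is their share net of their own investment. With the
#' default 30-cent investment and 1/3 bonus this yields the payoff matrix
#' (+10, +10) for mutual cooperation, (0, 0) for mutual defection and
#' (-10, +20) for unilateral cooperation.
#'
#' @param choice_self,choice_partner `"cooperate"` or `"defect"`
#'   (vectorized).
#' @param config A [game_config()].
#' @return A tibble with columns `delta_self`, `delta_partner` (cents).
#' @export
#' @examples
#' pd_payoff("cooperate", "defect")  # -10 / +20
pd_payoff <- function(choice_self, choice_partner, config = game_config()) {
  chk <- c(choice_self, choice_partner) %in% c("cooperate", "defect")
  if (!all(chk)) stop('choices must be "cooperate" or "defect"',
                      call. = FALSE)
  inv_s <- ifelse(choice_self == "cooperate", config$investment, 0)
  inv_p <- ifelse(choice_partner == "cooperate", config$investment, 0)
  pot <- inv_s + inv_p
  share <- (pot + pot * config$bonus_factor) / 2
  tibble::tibble(delta_self = share - inv_s, delta_partner = share - inv_p)
}

#' Simulation design for a synthetic experiment
#'
#' Describes the between-subject design generated by
#' [simulate_experiment()]: group sizes, true generating parameters per
#' condition, the participant punish-height distribution, and the
#' tone-classification accuracy distribution used by the cognitive-load
#' exclusion rule.
#'
#' The default design mirrors a two-condition study with 105 no-load and
#' 101 cognitive-load participants, 20 one-shot trials each. Default true
#' parameters are plausible interior values consistent with the reported
#' direction of the load effects (lower cooperation and moral punishment,
#' higher punishment bias under load); they are a modelling choice, not
#' published estimates.
#'
#' @param n_per_condition Named integer vector of participants per
#'   condition.
#' @param true_params Named list (one entry per condition) of named
#'   parameter vectors for [cp_model()].
#' @param height_dist `"uniform"` (discrete uniform on 1-9 cents) or
#'   `"empirical"` (discretized normal with mean 3.7, SD 2.2 truncated to
#'   1-9) for the participant's punishment investment.
#' @param tone_mean,tone_sd Mean and SD of the truncated-normal tone-task
#'   accuracy drawn for cognitive-load participants.
#' @param game A [game_config()].
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_condition = c(no_load = 105L,
                                           cognitive_load = 101L),
                       true_params = default_true_params(),
                       height_dist = c("uniform", "empirical"),
                       tone_mean = 0.92, tone_sd = 0.05,
                       game = game_config(), seed = 1L) {
  height_dist <- match.arg(height_dist)
  stopifnot(all(n_per_condition >= 1),
            all(names(n_per_condition) %in% names(true_params)))
  for (p in true_params) check_params(cp_model(), p)
  structure(list(n_per_condition = n_per_condition,
                 true_params = true_params, height_dist = height_dist,
                 tone_mean = tone_mean, tone_sd = tone_sd, game = game,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default generating parameters for the synthetic experiment
#' @return Named list of parameter vectors for the two conditions.
#' @export
default_true_params <- function() {
  list(
    no_load = c(C = 0.55, P_moral = 0.60, P_hypocritical = 0.30,
                P_antisocial = 0.15, b = 0.05),
    cognitive_load = c(C = 0.47, P_moral = 0.48, P_hypocritical = 0.25,
                       P_antisocial = 0.12, b = 0.11)
  )
}

draw_heights <- function(k, dist) {
  if (k == 0L) return(integer(0))
  if (dist == "uniform") {
    sample.int(9L, k, replace = TRUE)
  } else {
    w <- stats::dnorm(1:9, mean = 3.7, sd = 2.2)
    sample.int(9L, k, replace = TRUE, prob = w / sum(w))
  }
}

# Vectorized trial generator used by simulate_experiment() and
# simulate_participant(). Consumes the current RNG stream.
# `participants` needs columns participant_id, condition; `params_by_cond`
# maps condition -> named parameter vector.
sim_trials <- function(participants, params_by_cond, game, height_dist) {
  ppt <- game$partners_per_type
  n_trials <- 2L * ppt
  d <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    slot = seq_len(n_trials)
  )
  d <- dplyr::left_join(d, participants, by = "participant_id")
  d$partner_type <- ifelse(d$slot <= ppt, "cooperator", "defector")
  # random presentation order within participant
  d$u <- stats::runif(nrow(d))
  d <- dplyr::arrange(d, match(d$participant_id,
                               participants$participant_id), d$u)
  d <- d |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(trial_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-"slot", -"u")

  pars <- do.call(rbind, params_by_cond)[d$condition, , drop = FALSE]
  d$partner_choice <- ifelse(d$partner_type == "cooperator",
                             "cooperate", "defect")
  coop <- stats::rbinom(nrow(d), 1L, pars[, "C"]) == 1L
  d$participant_choice <- ifelse(coop, "cooperate", "defect")

  # punish probability by outcome cell: P_cell + (1 - P_cell) * b,
  # with the mutual-cooperation cell driven by the bias alone
  p_cell <- ifelse(coop & d$partner_choice == "defect", pars[, "P_moral"],
            ifelse(!coop & d$partner_choice == "defect",
                   pars[, "P_hypocritical"],
            ifelse(!coop & d$partner_choice == "cooperate",
                   pars[, "P_antisocial"], 0)))
  p_punish <- p_cell + (1 - p_cell) * pars[, "b"]
  punishes <- stats::rbinom(nrow(d), 1L, p_punish) == 1L
  d$participant_punish_cents <- integer(nrow(d))
  d$participant_punish_cents[punishes] <-
    draw_heights(sum(punishes), height_dist)

  # the partner punishes the participant's unilateral defection only
  unilateral <- !coop & d$partner_choice == "cooperate"
  d$partner_punish_cents <- integer(nrow(d))
  d$partner_punish_cents[unilateral] <-
    game$punish_ratio * draw_heights(sum(unilateral), "uniform")

  pay <- pd_payoff(d$participant_choice, d$partner_choice, game)
  d$payoff_self <- pay$delta_self

  tr <- game$training_per_type
  d <- d |>
    dplyr::group_by(.data$participant_id, .data$partner_type) |>
    dplyr::mutate(is_training = dplyr::row_number() <= tr) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(participant_balance_after = game$endowment +
                    cumsum(.data$payoff_self -
                             .data$participant_punish_cents -
                             .data$partner_punish_cents)) |>
    dplyr::ungroup()

  d[, c("participant_id", "condition", "trial_index", "partner_type",
        "participant_choice", "partner_choice",
        "participant_punish_cents", "partner_punish_cents",
        "payoff_self", "participant_balance_after", "is_training")]
}

#' Simulate one participant's 20 game trials
#'
#' Draws a full trial sequence for a single participant under the
#' generative MPT model: 10 cooperating and 10 defecting partners in
#' random order, cooperation with probability `C` independent of partner
#' type, punishment from the tree matching the realized outcome, punish
#' heights from the configured distribution, and full account-balance
#' bookkeeping. Uses (and advances) the current RNG state; seed the
#' session or use [simulate_experiment()] for reproducibility.
#'
#' @param params Named parameter vector for [cp_model()].
#' @param game A [game_config()].
#' @param height_dist As in [sim_config()].
#' @param participant_id,condition Identifiers carried into the records.
#' @return A tibble of trial records, one row per trial in presentation
#'   order.
#' @export
simulate_participant <- function(params, game = game_config(),
                                 height_dist = "uniform",
                                 participant_id = 1L, condition = "g1") {
  check_params(cp_model(), params)
  sim_trials(
    tibble::tibble(participant_id = participant_id, condition = condition),
    stats::setNames(list(params[cp_param_names()]), condition),
    game, height_dist
  )
}

#' Simulate a full synthetic experiment
#'
#' Generates the complete between-subject design described by a
#' [sim_config()]: every participant's trial sequence plus, for
#' cognitive-load participants, a tone-classification accuracy used by the
#' 75% exclusion rule. Byte-for-byte reproducible given the seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `cp_experiment` with `trials` (tibble of trial
#'   records), `participants` (tibble with `participant_id`, `condition`,
#'   `tone_accuracy`) and `config`.
#' @export
#' @examples
#' ex <- simulate_experiment(sim_config(
#'   n_per_condition = c(no_load = 4, cognitive_load = 4), seed = 42))
#' dplyr::count(ex$trials, condition)
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)
  conds <- names(config$n_per_condition)
  participants <- purrr::map_dfr(seq_along(conds), function(i) {
    tibble::tibble(condition = conds[i],
                   k = seq_len(config$n_per_condition[[i]]))
  })
  participants$participant_id <- seq_len(nrow(participants))
  participants <- participants[, c("participant_id", "condition")]

  trials <- sim_trials(participants,
                       lapply(config$true_params, function(p)
                         p[cp_param_names()]),
                       config$game, config$height_dist)

  participants$tone_accuracy <- NA_real_
  load_idx <- participants$condition == "cognitive_load"
  if (any(load_idx)) {
    participants$tone_accuracy[load_idx] <-
      rtruncnorm01(sum(load_idx), config$tone_mean, config$tone_sd)
  }
  structure(list(trials = trials, participants = participants,
                 config = config),
            class = "cp_experiment")
}

# normal(mean, sd) truncated to [0, 1] by inverse-CDF sampling
rtruncnorm01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' @export
print.cp_experiment <- function(x, ...) {
  cat("<cp_experiment> ", nrow(x$participants), " participants, ",
      nrow(x$trials), " trials (seed ", x$config$seed, ")\n", sep = "")
  print(dplyr::count(x$participants, .data$condition))
  invisible(x)
}

#' Apply the tone-task exclusion rule
#'
#' Removes cognitive-load participants whose tone-classification accuracy
#' is strictly below the threshold (an accuracy of exactly 75% is
#' retained). No-load participants are never excluded (they performed no
#' tone task).
#'
#' @param experiment A `cp_experiment`.
#' @param threshold Exclusion threshold in \[0, 1\].
#' @return The experiment with excluded participants' rows removed and an
#'   `exclusions` element logging the removed ids and their accuracies.
#' @export
apply_exclusions <- function(experiment, threshold = 0.75) {
  stopifnot(inherits(experiment, "cp_experiment"))
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  }
  p <- experiment$participants
  drop <- !is.na(p$tone_accuracy) & p$tone_accuracy < threshold
  log <- p[drop, c("participant_id", "condition", "tone_accuracy")]
  experiment$participants <- p[!drop, ]
  experiment$trials <- experiment$trials[
    experiment$trials$participant_id %in% p$participant_id[!drop], ]
  experiment$exclusions <- log
  experiment
}

#' Write / read trial records as CSV
#'
#' Deterministic row order (participant, then trial index), UTF-8, header
#' row; identical seeds give byte-identical files.
#'
#' @param trials A tibble of trial records.
#' @param path File path.
#' @return `path` invisibly; `read_trials_csv()` returns the tibble.
#' @export
write_trials_csv <- function(trials, path) {
  trials <- dplyr::arrange(tibble::as_tibble(trials),
                           .data$participant_id, .data$trial_index)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
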