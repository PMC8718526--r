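test_that("the payoff structure is a Prisoner's Dilemma in cents", {
  pay <- pd_payoff(c("cooperate", "defect", "cooperate", "defect"),
                   c("cooperate", "defect", "defect", "cooperate"))
  expect_equal(pay$delta_self, c(10, 0, -10, 20))
  expect_equal(pay$delta_partner, c(10, 0, 20, -10))
  expect_error(pd_payoff("coop", "defect"), "cooperate")
})

test_that("forced strategies produce the forced trial patterns", {
  set.seed(31)
  always <- simulate_participant(c(C = 1, P_moral = 0, P_hypocritical = 0,
                                   P_antisocial = 0, b = 0))
  expect_identical(nrow(always), 20L)
  expect_true(all(always$participant_choice == "cooperate"))
  expect_true(all(always$participant_punish_cents == 0))
  expect_true(all(always$partner_punish_cents == 0))

  never <- simulate_participant(c(C = 0, P_moral = 0, P_hypocritical = 0,
                                  P_antisocial = 0, b = 0))
  # every trial against a cooperating partner is unilateral defection,
  # which the partner always punishes with 10-90 cents in tens
  uni <- never[never$partner_type == "cooperator", ]
  expect_identical(nrow(uni), 10L)
  expect_true(all(uni$partner_punish_cents %in% (10 * 1:9)))
  expect_true(all(never$partner_punish_cents[
    never$partner_type == "defector"] == 0))
})

test_that("design structure and bookkeeping hold for every participant", {
  ex <- simulate_experiment(sim_config(
    n_per_condition = c(no_load = 12, cognitive_load = 12), seed = 8))
  tr <- ex$trials
  cfg <- ex$config$game

  per <- dplyr::count(tr, participant_id, partner_type)
  expect_true(all(per$n == 10))
  train <- dplyr::count(tr[tr$is_training, ], participant_id, partner_type)
  expect_true(all(train$n == 3))
  scored <- dplyr::count(tr[!tr$is_training, ], participant_id,
                         partner_type)
  expect_true(all(scored$n == 7))
  # training trials are the first three encounters of their partner type
  firsts <- tr |>
    dplyr::group_by(participant_id, partner_type) |>
    dplyr::arrange(trial_index, .by_group = TRUE) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup()
  expect_identical(firsts$is_training, firsts$k <= 3)

  # exact integer account identity per participant
  tr$pay <- pd_payoff(tr$participant_choice, tr$partner_choice,
                      cfg)$delta_self
  final <- tr |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(bal = dplyr::last(participant_balance_after,
                                       order_by = trial_index),
                     check = cfg$endowment + sum(pay) -
                       sum(participant_punish_cents) -
                       sum(partner_punish_cents))
  expect_identical(final$bal, final$check)

  # punish amounts stay on the legal grids
  expect_true(all(tr$participant_punish_cents %in% 0:9))
  expect_true(all(tr$partner_punish_cents %in% c(0, 10 * 1:9)))
})

test_that("same seed reproduces the dataset byte for byte", {
  cfg <- sim_config(n_per_condition = c(no_load = 10, cognitive_load = 10),
                    seed = 77)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(simulate_experiment(cfg)$trials, f1)
  write_trials_csv(simulate_experiment(cfg)$trials, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_trials_csv(f1)
  expect_identical(nrow(back), 400L)
})

test_that("the tone-task exclusion rule is strict at 75 percent", {
  ex <- simulate_experiment(sim_config(
    n_per_condition = c(no_load = 3, cognitive_load = 4), seed = 5))
  ex$participants$tone_accuracy[ex$participants$condition ==
                                  "cognitive_load"] <-
    c(0.74, 0.75, 0.90, 0.60)
  out <- apply_exclusions(ex)
  kept <- out$participants
  expect_identical(nrow(out$exclusions), 2L)
  expect_setequal(round(out$exclusions$tone_accuracy, 2), c(0.74, 0.60))
  # exactly 75% is retained; no-load participants are never excluded
  expect_true(0.75 %in% round(kept$tone_accuracy[
    kept$condition == "cognitive_load"], 2))
  expect_identical(sum(kept$condition == "no_load"), 3L)
  expect_false(any(out$trials$participant_id %in%
                     out$exclusions$participant_id))

  all_good <- ex
  all_good$participants$tone_accuracy[
    all_good$participants$condition == "cognitive_load"] <- 1
  expect_identical(nrow(apply_exclusions(all_good)$exclusions), 0L)
  expect_error(apply_exclusions(ex, threshold = 1.2), "threshold")
})

test_that("simulated behavior converges to the generating category law", {
  # one large condition: 1e5 participants, 1e6 trials per partner type
  p <- c(C = 0.5, P_moral = 0.5, P_hypocritical = 0.3,
         P_antisocial = 0.1, b = 0.1)
  ex <- simulate_experiment(sim_config(
    n_per_condition = c(no_load = 100000),
    true_params = list(no_load = p), seed = 1301))
  tr <- ex$trials

  # punish rate in the cooperate / partner-defects cell: P + (1 - P) b
  cell <- tr$partner_type == "defector" &
    tr$participant_choice == "cooperate"
  expect_equal(mean(tr$participant_punish_cents[cell] > 0), 0.55,
               tolerance = 0.005)

  # KL divergence between empirical category proportions and the model law
  counts <- tr |>
    dplyr::mutate(
      tree = ifelse(partner_type == "defector",
                    "defector_partner", "cooperator_partner"),
      category = paste0(
        ifelse(participant_choice == "cooperate", "coop", "defect"),
        ifelse(participant_punish_cents > 0, "_punish", "_nopunish"))) |>
    dplyr::count(tree, category)
  probs <- category_probabilities(cp_model(), p)
  d <- dplyr::inner_join(probs, counts, by = c("tree", "category")) |>
    dplyr::group_by(tree) |>
    dplyr::mutate(phat = n / sum(n)) |>
    dplyr::summarise(kl = sum(phat * log(phat / prob)))
  expect_identical(nrow(d), 2L)
  expect_true(all(d$kl < 1e-4))

  # cooperation is independent of partner type
  coop_by_tree <- tapply(tr$participant_choice == "cooperate",
                         tr$partner_type, mean)
  expect_equal(unname(diff(coop_by_tree)), 0, tolerance = 0.005)
})
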