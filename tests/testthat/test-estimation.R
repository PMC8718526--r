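model <- cp_model()

test_that("noise-free frequencies recover the generating parameters", {
  truth <- c(C = 0.7, P_moral = 0.6, P_hypocritical = 0.2,
             P_antisocial = 0.1, b = 0.05)
  freqs <- expected_freqs(truth, n_per_tree = 1000)
  fit <- fit_mpt(freqs, model)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit)[names(truth)] - truth)), 1e-4)
  expect_lt(fit$g_squared, 1e-6)
  # df bookkeeping: one group, 2 trees x 3 free probabilities - 5 params
  expect_identical(fit$df, 1L)
})

test_that("equating parameters across identical groups reproduces the single-group fit", {
  truth <- c(C = 0.55, P_moral = 0.5, P_hypocritical = 0.3,
             P_antisocial = 0.15, b = 0.1)
  set.seed(11)
  f1 <- draw_freqs(truth, 700, group = "a")
  f2 <- f1
  f2$group <- "b"
  both <- rbind(f1, f2)

  single <- fit_mpt(f1, model)
  cons <- mpt_constraints(model, c("a", "b"), equate = cp_param_names())
  restricted <- fit_mpt(both, model, cons)
  expect_lt(max(abs(coef(restricted)[cp_param_names()] -
                      coef(single)[cp_param_names()])), 1e-5)

  unrestricted <- fit_mpt(both, model)
  expect_lt(restricted$g_squared - 2 * single$g_squared, 1e-4)
  # with literally identical groups the equality restriction is free
  expect_lt(restricted$g_squared - unrestricted$g_squared, 1e-4)
})

test_that("the optimizer finds the closed-form maximum from random starts alone", {
  set.seed(1)
  truth <- c(C = 0.62, P_moral = 0.55, P_hypocritical = 0.28,
             P_antisocial = 0.12, b = 0.09)
  freqs <- draw_freqs(truth, 200000)
  fit <- fit_mpt(freqs, model,
                 control = fit_control(smart_start = FALSE, restarts = 10),
                 compute_se = FALSE)
  oracle <- cp_closed_form(freqs)
  expect_lt(max(abs(coef(fit)[names(oracle)] - oracle)), 1e-5)
})

test_that("restricted fits never beat the unrestricted fit", {
  set.seed(21)
  truth <- interior_truth()
  freqs <- rbind(draw_freqs(truth$no_load, 735, "no_load"),
                 draw_freqs(truth$cognitive_load, 707, "cognitive_load"))
  base <- fit_mpt(freqs, model, compute_se = FALSE)
  expect_identical(base$df, 2L)
  for (par in cp_param_names()) {
    cons <- mpt_constraints(model, c("no_load", "cognitive_load"),
                            equate = par)
    restricted <- fit_mpt(freqs, model, cons, compute_se = FALSE)
    expect_identical(restricted$df, 3L)
    expect_gte(restricted$g_squared, base$g_squared - 1e-6)
  }
})

test_that("standard errors scale as one over the square root of the counts", {
  truth <- c(C = 0.6, P_moral = 0.5, P_hypocritical = 0.3,
             P_antisocial = 0.15, b = 0.1)
  f1 <- expected_freqs(truth, 500)
  f9 <- expected_freqs(truth, 4500)
  se1 <- fit_mpt(f1, model)$se
  se9 <- fit_mpt(f9, model)$se
  expect_lt(max(abs(se1 / se9 - 3)), 3 * 0.02)
})

test_that("a pure-bias tree reduces the SE to the binomial formula", {
  # single tree, single parameter: punish with probability b. This is the
  # cooperator-partner tree with C fixed at 1, where the punishment
  # decision is a plain Bernoulli(b).
  toy <- mpt_model(data.frame(tree = "coop",
                              category = c("punish", "nopunish"),
                              term = c("b", "(1-b)")))
  n <- 2000
  b_hat <- 0.15
  freqs <- data.frame(tree = "coop", category = c("punish", "nopunish"),
                      n = n * c(b_hat, 1 - b_hat))
  fit <- fit_mpt(freqs, toy)
  expect_equal(unname(coef(fit)["b"]), b_hat, tolerance = 1e-6)
  expect_equal(unname(fit$se["b"]), sqrt(b_hat * (1 - b_hat) / n),
               tolerance = 0.01)
})

test_that("observed-information SEs agree with the parametric bootstrap", {
  truth <- c(C = 0.6, P_moral = 0.55, P_hypocritical = 0.3,
             P_antisocial = 0.15, b = 0.1)
  n_per_tree <- 10000
  fit0 <- fit_mpt(expected_freqs(truth, n_per_tree), model)
  set.seed(1234)
  ctl <- fit_control(restarts = 0)
  boot <- replicate(2000, {
    fr <- draw_freqs(truth, n_per_tree)
    coef(fit_mpt(fr, model, control = ctl, compute_se = FALSE))
  })
  sds <- apply(boot, 1, sd)[names(fit0$se)]
  expect_lt(max(abs(fit0$se / sds - 1)), 0.15)
})

test_that("boundary estimates are clamped, flagged, and carry no SE", {
  truth <- c(C = 0.6, P_moral = 0.5, P_hypocritical = 0.3,
             P_antisocial = 0.2, b = 0)
  freqs <- expected_freqs(truth, 1000)
  fit <- fit_mpt(freqs, model)
  expect_true(fit$boundary["b"])
  expect_true(is.na(fit$se["b"]))
  expect_gte(coef(fit)["b"], 1e-6)
  expect_false(any(fit$boundary[c("C", "P_moral")]))
  expect_false(anyNA(fit$se[c("C", "P_moral")]))
})

test_that("malformed constraint maps are rejected", {
  cons <- mpt_constraints(model, c("a", "b"))
  expect_error(fit_mpt(draw_freqs(c(C = .5, P_moral = .5,
                                    P_hypocritical = .5,
                                    P_antisocial = .5, b = .5), 100),
                       model, constraints = cons[-1, ]),
               "exactly once")
  expect_error(mpt_constraints(model, "a", equate = "nope"), "nope")
})

test_that("the five-parameter model is locally identified", {
  rep <- check_identifiability(model, n_probes = 100)
  expect_identical(rep$jacobian_rank, 5L)
  expect_true(rep$locally_identified)
})

test_that("unused or confounded parameters break identifiability", {
  # sixth parameter appearing in no branch
  m6 <- mpt_model(cp_model()$branches[, c("tree", "category", "term")],
                  params = c(cp_param_names(), "ghost"))
  rep6 <- check_identifiability(m6, n_probes = 20)
  expect_identical(rep6$jacobian_rank, 5L)
  expect_identical(rep6$parameter_count, 6L)
  expect_false(rep6$locally_identified)

  # two parameters entering the category probabilities only through their
  # product are confounded: x = t1*t2, y = 1 - t1*t2
  m_conf <- mpt_model(data.frame(
    tree = "t", category = c("x", "y", "y"),
    term = c("t1*t2", "(1-t1)", "t1*(1-t2)")
  ))
  repc <- check_identifiability(m_conf, n_probes = 20)
  expect_lt(repc$jacobian_rank, repc$parameter_count)
  expect_false(repc$locally_identified)
})

test_that("tidy and glance expose the fit in broom form", {
  truth <- interior_truth()
  set.seed(5)
  freqs <- rbind(draw_freqs(truth$no_load, 735, "no_load"),
                 draw_freqs(truth$cognitive_load, 707, "cognitive_load"))
  fit <- fit_mpt(freqs, model)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 10L)
  expect_true(all(c("term", "parameter", "group", "estimate",
                    "std.error", "boundary") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$df, 2L)
  expect_equal(gl$n.total, sum(freqs$n))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
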