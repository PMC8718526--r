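test_that("branch probabilities multiply theta and complement factors", {
  expect_equal(branch_probability("C*P_moral", c(C = 1, P_moral = 1)), 1)
  expect_equal(
    branch_probability("C*(1-P_moral)*b", c(C = 0.6, P_moral = 0.5, b = 0.2)),
    0.6 * 0.5 * 0.2)
  # a zero theta-oriented factor annihilates the product
  expect_equal(
    branch_probability("C*(1-P_moral)*b", c(C = 0, P_moral = 0.3, b = 0.9)),
    0)
  expect_error(branch_probability("C*unknown_par", c(C = 0.5)),
               "unknown_par")
})

test_that("category probabilities match hand-computed values", {
  m <- cp_model()
  pars <- c(C = 0.6, P_moral = 0.5, P_hypocritical = 0.3,
            P_antisocial = 0.1, b = 0.2)
  pr <- category_probabilities(m, pars, tree = "defector_partner")
  expect_equal(pr$category, c("coop_punish", "coop_nopunish",
                              "defect_punish", "defect_nopunish"))
  expect_equal(pr$prob, c(0.36, 0.24, 0.176, 0.224))

  # forced paths
  pr <- category_probabilities(
    m, c(C = 1, P_moral = 0, P_hypocritical = 0.4, P_antisocial = 0.2,
         b = 0), tree = "defector_partner")
  expect_equal(pr$prob, c(0, 1, 0, 0))
  pr <- category_probabilities(
    m, c(C = 1, P_moral = 0.3, P_hypocritical = 0.4, P_antisocial = 0.2,
         b = 0.25), tree = "cooperator_partner")
  expect_equal(pr$prob, c(0.25, 0.75, 0, 0))

  expect_error(category_probabilities(m, c(C = 1.2, P_moral = 0,
                                           P_hypocritical = 0,
                                           P_antisocial = 0, b = 0)),
               "\\[0, 1\\]")
})

test_that("tree probabilities are a proper multinomial for random parameters", {
  m <- cp_model()
  set.seed(42)
  for (i in 1:100) {
    pars <- stats::setNames(runif(5), cp_param_names())
    pr <- category_probabilities(m, pars)
    sums <- tapply(pr$prob, pr$tree, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    # the model's independence assumption: cooperation mass equals C in
    # both trees, whatever the punishment parameters
    coop <- tapply(pr$prob[grepl("^coop", pr$category)],
                   pr$tree[grepl("^coop", pr$category)], sum)
    expect_true(all(abs(coop - pars["C"]) < 1e-12))
  }
  # no punishment process, no punishment mass
  pars <- c(C = 0.37, P_moral = 0, P_hypocritical = 0, P_antisocial = 0,
            b = 0)
  pr <- category_probabilities(m, pars)
  expect_equal(sum(pr$prob[grepl("punish$", pr$category) &
                             !grepl("nopunish", pr$category)]), 0)
})

test_that("multinomial log-likelihood follows the 0 log 0 convention", {
  f <- data.frame(tree = "t", category = c("a", "b"), n = c(30, 70))
  p <- data.frame(tree = "t", category = c("a", "b"), prob = c(0.5, 0.5))
  expect_equal(mpt_loglik(f, p), 100 * log(0.5))

  f0 <- data.frame(tree = "t", category = c("a", "b"), n = c(0, 0))
  expect_equal(mpt_loglik(f0, p), 0)

  # zero-probability category with zero count contributes nothing
  p0 <- data.frame(tree = "t", category = c("a", "b"), prob = c(0, 1))
  expect_equal(mpt_loglik(data.frame(tree = "t",
                                     category = c("a", "b"),
                                     n = c(0, 5)), p0), 0)
  # ... but with a positive count the result is a flagged -Inf, no error
  expect_warning(ll <- mpt_loglik(f, p0), "-Inf")
  expect_identical(ll, -Inf)

  # the binomial MLE maximizes the likelihood over the simplex
  f5 <- data.frame(tree = "t", category = c("a", "b"), n = c(50, 50))
  ll_half <- mpt_loglik(f5, p)
  for (q in c(0.3, 0.45, 0.55, 0.8)) {
    pq <- data.frame(tree = "t", category = c("a", "b"), prob = c(q, 1 - q))
    expect_lt(mpt_loglik(f5, pq), ll_half)
  }
})

test_that("G-squared matches direct evaluation and is linear in counts", {
  f <- data.frame(tree = "t", category = c("a", "b"), n = c(30, 70))
  p <- data.frame(tree = "t", category = c("a", "b"), prob = c(0.5, 0.5))
  expect_equal(mpt_g2(f, p), 2 * (30 * log(0.6) + 70 * log(1.4)))

  # observed equal to expected: zero
  p37 <- data.frame(tree = "t", category = c("a", "b"), prob = c(0.3, 0.7))
  expect_equal(mpt_g2(data.frame(tree = "t", category = c("a", "b"),
                                 n = c(30, 70)), p37), 0)

  # doubling all counts doubles the statistic at fixed proportions
  f2 <- transform(f, n = 2 * n)
  expect_equal(mpt_g2(f2, p), 2 * mpt_g2(f, p))

  # zero expected count with positive observed count is flagged, not thrown
  p0 <- data.frame(tree = "t", category = c("a", "b"), prob = c(0, 1))
  expect_warning(g <- mpt_g2(f, p0), "Inf")
  expect_identical(g, Inf)
})

test_that("EQN files round-trip the model losslessly", {
  m <- cp_model()
  path <- withr::local_tempfile(fileext = ".eqn")
  write_eqn(m, path)
  m2 <- read_eqn(path)
  expect_equal(nrow(m2$branches), 11L)
  set.seed(7)
  for (i in 1:10) {
    pars <- stats::setNames(runif(5), cp_param_names())
    expect_equal(category_probabilities(m2, pars),
                 category_probabilities(m, pars))
  }
  # writing the re-read model reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".eqn")
  write_eqn(m2, path2)
  expect_identical(readLines(path2), readLines(path))

  # the installed fixture is the same model
  fix <- system.file("extdata", "cp_model.eqn", package = "mptcoop")
  expect_identical(readLines(fix), readLines(path))

  expect_error(read_eqn(textConnection("not-a-number")), "number")
})
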