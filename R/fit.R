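# ---- compiled model representation ----------------------------------------
# Flatten an mpt_model into index vectors so likelihood and gradient
# evaluations inside the optimizer touch no data frames.

compile_mpt <- function(model) {
  layout <- purrr::map_dfr(names(model$trees), function(t) {
    tibble::tibble(tree = t, category = model$trees[[t]])
  })
  key <- paste(layout$tree, layout$category, sep = "\r")
  branches <- purrr::pmap(
    list(model$branches$tree, model$branches$category, model$branches$factors),
    function(tree, category, factors) {
      list(cat = match(paste(tree, category, sep = "\r"), key),
           par = match(factors$param, model$params),
           comp = factors$complement)
    })
  list(layout = layout, branches = branches,
       ncat = nrow(layout), npar = length(model$params),
       tree_rows = split(seq_len(nrow(layout)), layout$tree))
}

# Category probabilities and their Jacobian w.r.t. the parameter vector.
probs_and_jac <- function(cm, theta, jacobian = TRUE) {
  p <- numeric(cm$ncat)
  J <- if (jacobian) matrix(0, cm$ncat, cm$npar) else NULL
  for (br in cm$branches) {
    f <- ifelse(br$comp, 1 - theta[br$par], theta[br$par])
    bp <- prod(f)
    p[br$cat] <- p[br$cat] + bp
    if (jacobian) {
      for (k in seq_along(br$par)) {
        dk <- prod(f[-k]) * if (br$comp[k]) -1 else 1
        J[br$cat, br$par[k]] <- J[br$cat, br$par[k]] + dk
      }
    }
  }
  list(p = p, J = J)
}

# ---- constraints -----------------------------------------------------------

#' Equality-constraint map for a multi-group MPT fit
#'
#' Describes which free parameter fills each (group, model parameter) slot.
#' By default every slot gets its own free parameter, labelled
#' `param[group]` (or just `param` for a single group). Parameters listed
#' in `equate` share one free parameter across all groups — the restriction
#' used to test whether a parameter differs between experimental
#' conditions.
#'
#' @param model An [mpt_model()].
#' @param groups Character vector of group labels.
#' @param equate Character vector of model parameter names to force equal
#'   across groups.
#' @return A tibble with columns `free`, `group`, `param` covering every
#'   slot exactly once.
#' @export
#' @examples
#' mpt_constraints(cp_model(), c("no_load", "cognitive_load"), equate = "C")
mpt_constraints <- function(model, groups, equate = character()) {
  stopifnot(inherits(model, "mpt_model"))
  if (!all(equate %in% model$params)) {
    stop("unknown parameter(s) in `equate`: ",
         paste(setdiff(equate, model$params), collapse = ", "), call. = FALSE)
  }
  tidyr::expand_grid(group = groups, param = model$params) |>
    dplyr::mutate(free = dplyr::case_when(
      param %in% equate     ~ param,
      length(groups) == 1L  ~ param,
      TRUE                  ~ paste0(param, "[", group, "]")
    )) |>
    dplyr::select("free", "group", "param")
}

validate_constraints <- function(constraints, model, groups) {
  constraints <- tibble::as_tibble(constraints)
  need <- c("free", "group", "param")
  if (!all(need %in% names(constraints))) {
    stop("constraints need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  slots <- tidyr::expand_grid(group = groups, param = model$params)
  hit <- dplyr::count(constraints, .data$group, .data$param)
  full <- dplyr::left_join(slots, hit, by = c("group", "param"))
  if (any(is.na(full$n)) || any(full$n != 1L)) {
    stop("constraints must cover every (group, parameter) slot exactly once",
         call. = FALSE)
  }
  extra <- !constraints$param %in% model$params |
    !constraints$group %in% groups
  if (any(extra)) stop("constraints reference unknown groups or parameters",
                       call. = FALSE)
  constraints
}

# ---- control ---------------------------------------------------------------

#' Optimizer settings for [fit_mpt()]
#'
#' @param seed Integer seed for the random restart starting points; the fit
#'   is deterministic given the seed.
#' @param restarts Number of random restarts run in addition to the
#'   moment-based starting point.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param grad_tol Maximum-norm of the (logit-scale) score at which a
#'   solution is declared converged.
#' @param epsilon Reporting clamp: estimates are clamped to
#'   `[epsilon, 1 - epsilon]` and flagged when the optimum lies on the
#'   boundary.
#' @param smart_start Use the canonical model's moment estimator as the
#'   first starting point when the model layout allows it.
#' @return A list of class `mpt_control`.
#' @export
fit_control <- function(seed = 1L, restarts = 10L, reltol = 1e-10,
                        grad_tol = 1e-6, epsilon = 1e-6,
                        smart_start = TRUE) {
  structure(list(seed = as.integer(seed), restarts = as.integer(restarts),
                 reltol = reltol, grad_tol = grad_tol, epsilon = epsilon,
                 smart_start = isTRUE(smart_start)),
            class = "mpt_control")
}

ETA_MAX <- 30  # logit bound; plogis(30) is 1 within ~1e-13 but never exact

# ---- closed-form moment start for the canonical model ----------------------
# For the cooperation-and-punishment model the interior MLE has a closed
# form: C is the pooled cooperation rate (both trees have it in common and
# the punishment parts factor out), b is the punish rate after mutual
# cooperation, and each punishment parameter solves q = P + (1 - P) b where
# q is its cell's conditional punish rate. Used as a starting value and,
# with random-start fits, as an independent cross-check.

cp_moment_start <- function(n, layout) {
  get <- function(tree, cat) n[layout$tree == tree & layout$category == cat]
  d_cp <- get("defector_partner", "coop_punish")
  d_cn <- get("defector_partner", "coop_nopunish")
  d_dp <- get("defector_partner", "defect_punish")
  d_dn <- get("defector_partner", "defect_nopunish")
  c_cp <- get("cooperator_partner", "coop_punish")
  c_cn <- get("cooperator_partner", "coop_nopunish")
  c_dp <- get("cooperator_partner", "defect_punish")
  c_dn <- get("cooperator_partner", "defect_nopunish")
  rate <- function(x, y) if (x + y > 0) x / (x + y) else 0.5
  C <- rate(d_cp + d_cn + c_cp + c_cn, d_dp + d_dn + c_dp + c_dn)
  b <- rate(c_cp, c_cn)
  unbias <- function(q) if (b < 1) (q - b) / (1 - b) else q
  est <- c(C = C, P_moral = unbias(rate(d_cp, d_cn)),
           P_hypocritical = unbias(rate(d_dp, d_dn)),
           P_antisocial = unbias(rate(c_dp, c_dn)), b = b)
  pmin(pmax(est, 1e-3), 1 - 1e-3)
}

is_cp_layout <- function(model) {
  identical(sort(model$params), sort(cp_param_names())) &&
    setequal(names(model$trees), c("defector_partner", "cooperator_partner"))
}

# ---- fitting ---------------------------------------------------------------

#' Fit an MPT model by maximum likelihood
#'
#' Maximizes the joint multinomial log-likelihood of one or more groups'
#' category counts over the model parameters, optionally with equality
#' constraints across groups. Optimization runs on logit-transformed
#' parameters with a moment-based starting point plus seeded random
#' restarts; the reported optimum is the best across restarts, with ties
#' broken towards the lexicographically smallest estimate vector.
#'
#' @param freqs Data frame of counts with columns `tree`, `category`, `n`
#'   and optionally `group` (e.g. from [aggregate_frequencies()]). Counts
#'   may be non-integral (expected counts are valid input for noise-free
#'   recovery checks).
#' @param model An [mpt_model()]; defaults to the cooperation-and-punishment
#'   model.
#' @param constraints `NULL` (all parameters free per group) or a constraint
#'   map from [mpt_constraints()].
#' @param control An [fit_control()] list.
#' @param compute_se Compute standard errors from the observed information
#'   matrix (central differences of the analytic score, step 1e-5). SEs are
#'   suppressed (NA, with a flag) for boundary estimates or a singular
#'   information matrix.
#' @return An object of class `mpt_fit` with elements `estimates`, `se`,
#'   `boundary`, `loglik`, `g_squared`, `df`, `p_value`, `converged`,
#'   `n_restarts_used`, `n_total`, plus the inputs needed by [tidy()] and
#'   [mpt_lr_test()]. `df` is the number of free category probabilities
#'   (categories minus one, summed over trees and groups) minus the number
#'   of free parameters.
#' @export
#' @examples
#' m <- cp_model()
#' truth <- c(C = 0.7, P_moral = 0.6, P_hypocritical = 0.2,
#'            P_antisocial = 0.1, b = 0.05)
#' pr <- category_probabilities(m, truth)
#' freqs <- dplyr::mutate(pr, n = prob * 1000)
#' fit <- fit_mpt(freqs, m)
#' coef(fit)
fit_mpt <- function(freqs, model = cp_model(), constraints = NULL,
                    control = fit_control(), compute_se = TRUE) {
  stopifnot(inherits(model, "mpt_model"))
  freqs <- as_freq_table(freqs)
  groups <- unique(freqs$group)
  cm <- compile_mpt(model)

  # counts aligned to the compiled layout, one vector per group
  key <- paste(cm$layout$tree, cm$layout$category, sep = "\r")
  nmat <- vapply(groups, function(g) {
    fg <- freqs[freqs$group == g, ]
    idx <- match(key, paste(fg$tree, fg$category, sep = "\r"))
    if (anyNA(idx)) {
      stop("group ", g, " is missing counts for some model categories",
           call. = FALSE)
    }
    fg$n[idx]
  }, numeric(cm$ncat))
  nmat <- matrix(nmat, nrow = cm$ncat,
                 dimnames = list(NULL, groups))

  if (is.null(constraints)) {
    constraints <- mpt_constraints(model, groups)
  }
  constraints <- validate_constraints(constraints, model, groups)
  free <- unique(constraints$free)
  nfree <- length(free)
  # slot_idx[g, p] = index of the free parameter filling that slot
  slot_idx <- matrix(NA_integer_, length(groups), cm$npar,
                     dimnames = list(groups, model$params))
  slot_idx[cbind(match(constraints$group, groups),
                 match(constraints$param, model$params))] <-
    match(constraints$free, free)

  neg_loglik_grad <- function(eta, want_grad = TRUE) {
    th_free <- stats::plogis(eta)
    ll <- 0
    gr <- numeric(nfree)
    for (gi in seq_along(groups)) {
      th <- th_free[slot_idx[gi, ]]
      pj <- probs_and_jac(cm, th, jacobian = want_grad)
      p <- pj$p
      nv <- nmat[, gi]
      if (any(nv > 0 & p <= 0)) return(list(value = Inf, grad = gr))
      pos <- nv > 0
      ll <- ll + sum(nv[pos] * log(p[pos]))
      if (want_grad) {
        w <- ifelse(p > 0, nv / p, 0)
        gslot <- drop(crossprod(pj$J, w))
        for (k in seq_len(cm$npar)) {
          j <- slot_idx[gi, k]
          gr[j] <- gr[j] + gslot[k]
        }
      }
    }
    list(value = -ll, grad = -gr * th_free * (1 - th_free))
  }
  obj <- function(eta) neg_loglik_grad(eta, want_grad = FALSE)$value
  grd <- function(eta) neg_loglik_grad(eta)$grad

  # starting points: moment-based first, then seeded uniform restarts
  starts <- list()
  if (control$smart_start && is_cp_layout(model)) {
    svm <- t(vapply(seq_along(groups), function(gi) {
      cp_moment_start(nmat[, gi], cm$layout)[model$params]
    }, numeric(cm$npar)))  # groups x params, like slot_idx
    th0 <- vapply(seq_len(nfree), function(j) mean(svm[slot_idx == j]),
                  numeric(1))
    starts[[1]] <- stats::qlogis(pmin(pmax(th0, 1e-3), 1 - 1e-3))
  } else {
    starts[[1]] <- rep(0, nfree)
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(control$seed)
  for (r in seq_len(control$restarts)) {
    starts[[r + 1L]] <- stats::qlogis(stats::runif(nfree, 0.02, 0.98))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  best <- NULL
  for (eta0 in starts) {
    opt <- stats::nlminb(eta0, objective = obj, gradient = grd,
                         lower = -ETA_MAX, upper = ETA_MAX,
                         control = list(rel.tol = control$reltol,
                                        iter.max = 500L, eval.max = 1000L))
    cand <- list(eta = opt$par, value = opt$objective)
    take <- is.null(best) || cand$value < best$value - 1e-9 ||
      (abs(cand$value - best$value) <= 1e-9 &&
         lex_less(stats::plogis(cand$eta), stats::plogis(best$eta)))
    if (take) best <- cand
  }

  eta_hat <- best$eta
  gfin <- neg_loglik_grad(eta_hat)$grad
  # polish with a quasi-Newton pass when the PORT run left the score
  # above tolerance (happens occasionally in constrained fits)
  if (max(abs(gfin)) >= control$grad_tol * max(1, sum(nmat))) {
    pol <- stats::optim(eta_hat, fn = obj, gr = grd, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-14))
    if (pol$value <= best$value) {
      best$value <- pol$value
      eta_hat <- pmin(pmax(pol$par, -ETA_MAX), ETA_MAX)
      gfin <- neg_loglik_grad(eta_hat)$grad
    }
  }
  theta_hat <- stats::plogis(eta_hat)
  names(theta_hat) <- free
  boundary <- theta_hat <= control$epsilon | theta_hat >= 1 - control$epsilon
  # score tolerance scaled by the data size: the score is extensive in the
  # counts, so an absolute cut-off would misreport clean optima at large n
  converged <- max(abs(gfin)) < control$grad_tol * max(1, sum(nmat))
  if (!converged) {
    warning("fit did not reach the score tolerance; converged = FALSE",
            call. = FALSE)
  }

  loglik <- -best$value
  g2 <- 2 * (saturated_loglik(freqs) - loglik)
  if (g2 < 0 && g2 > -1e-6) g2 <- 0
  free_probs <- length(groups) * sum(lengths(model$trees) - 1L)
  df <- free_probs - nfree
  p_value <- if (df > 0) stats::pchisq(g2, df, lower.tail = FALSE) else NA_real_

  est_report <- pmin(pmax(theta_hat, control$epsilon), 1 - control$epsilon)

  se <- rep(NA_real_, nfree)
  names(se) <- free
  if (compute_se) {
    se <- mpt_observed_se(theta_free = theta_hat, slot_idx = slot_idx,
                          cm = cm, nmat = nmat, boundary = boundary)
  }

  structure(list(
    estimates = est_report, se = se, boundary = boundary,
    loglik = loglik, g_squared = g2, df = df, p_value = p_value,
    converged = converged, n_restarts_used = length(starts) - 1L,
    n_total = sum(nmat),
    model = model, freqs = freqs, constraints = constraints,
    groups = groups, control = control
  ), class = "mpt_fit")
}

lex_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 1e-12)[1]
  !is.na(i) && d[i] < 0
}

# Observed-information standard errors on the probability scale.
# Central differences of the analytic score, step 1e-5 per free parameter.
mpt_observed_se <- function(theta_free, slot_idx, cm, nmat, boundary,
                            step = 1e-5) {
  nfree <- length(theta_free)
  score <- function(th_free) {
    gr <- numeric(nfree)
    for (gi in seq_len(nrow(slot_idx))) {
      th <- th_free[slot_idx[gi, ]]
      pj <- probs_and_jac(cm, th)
      w <- ifelse(pj$p > 0, nmat[, gi] / pj$p, 0)
      gslot <- drop(crossprod(pj$J, w))
      for (k in seq_len(cm$npar)) {
        j <- slot_idx[gi, k]
        gr[j] <- gr[j] + gslot[k]
      }
    }
    gr
  }
  H <- matrix(NA_real_, nfree, nfree)
  for (j in seq_len(nfree)) {
    e <- numeric(nfree); e[j] <- step
    H[, j] <- (score(theta_free + e) - score(theta_free - e)) / (2 * step)
  }
  H <- (H + t(H)) / 2
  info <- -H
  se <- rep(NA_real_, nfree)
  ok <- !boundary
  if (any(ok)) {
    inv <- tryCatch(solve(info[ok, ok, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(inv) || any(diag(inv) <= 0)) {
      warning("observed information is singular or not positive definite; ",
              "standard errors unavailable", call. = FALSE)
    } else {
      se[ok] <- sqrt(diag(inv))
    }
  }
  names(se) <- names(theta_free)
  se
}

#' Standard errors for a fitted or supplied parameter vector
#'
#' Inverse observed information of the multinomial log-likelihood,
#' evaluated numerically (central differences of the analytic score,
#' step 1e-5). Boundary estimates get `NA` rather than a fabricated value.
#'
#' @param freqs Frequency table as in [fit_mpt()].
#' @param model An [mpt_model()].
#' @param estimates Named vector of free-parameter values (interior).
#' @param constraints As in [fit_mpt()].
#' @return Named vector of standard errors.
#' @export
mpt_standard_errors <- function(freqs, model, estimates, constraints = NULL) {
  freqs <- as_freq_table(freqs)
  groups <- unique(freqs$group)
  cm <- compile_mpt(model)
  if (is.null(constraints)) constraints <- mpt_constraints(model, groups)
  constraints <- validate_constraints(constraints, model, groups)
  free <- unique(constraints$free)
  if (!all(free %in% names(estimates))) {
    stop("`estimates` must name every free parameter", call. = FALSE)
  }
  key <- paste(cm$layout$tree, cm$layout$category, sep = "\r")
  nmat <- vapply(groups, function(g) {
    fg <- freqs[freqs$group == g, ]
    fg$n[match(key, paste(fg$tree, fg$category, sep = "\r"))]
  }, numeric(cm$ncat))
  nmat <- matrix(nmat, nrow = cm$ncat)
  slot_idx <- matrix(NA_integer_, length(groups), cm$npar,
                     dimnames = list(groups, model$params))
  slot_idx[cbind(match(constraints$group, groups),
                 match(constraints$param, model$params))] <-
    match(constraints$free, free)
  th <- estimates[free]
  mpt_observed_se(th, slot_idx, cm, nmat,
                  boundary = th <= 1e-6 | th >= 1 - 1e-6)
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat("<mpt_fit> ", length(x$estimates), " free parameter(s), ",
      length(x$groups), " group(s)\n", sep = "")
  cat(sprintf("  G2(%d) = %.2f, p = %s, logLik = %.3f%s\n", x$df,
              x$g_squared,
              if (is.na(x$p_value)) "NA" else sprintf("%.3f", x$p_value),
              x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- data.frame(estimate = round(x$estimates, 4),
                    se = round(x$se, 4))
  print(est)
  invisible(x)
}

#' @export
coef.mpt_fit <- function(object, ...) object$estimates

#' @export
logLik.mpt_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates), class = "logLik")
}

# Fitted category probabilities and expected counts per group.
fitted_probs <- function(fit) {
  cm <- compile_mpt(fit$model)
  free <- unique(fit$constraints$free)
  purrr::map_dfr(fit$groups, function(g) {
    cg <- fit$constraints[fit$constraints$group == g, ]
    th <- fit$estimates[cg$free]
    names(th) <- cg$param
    pr <- probs_and_jac(cm, th[fit$model$params], jacobian = FALSE)$p
    out <- dplyr::mutate(cm$layout, group = g, prob = pr)
    fg <- fit$freqs[fit$freqs$group == g, ]
    out <- dplyr::left_join(out, fg, by = c("tree", "category"))
    out |>
      dplyr::group_by(.data$tree) |>
      dplyr::mutate(expected = .data$prob * sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::select("group", "tree", "category", "n", "prob", "expected")
  })
}

# ---- identifiability -------------------------------------------------------

#' Local identifiability check by numerical Jacobian rank
#'
#' At each of `n_probes` random interior parameter vectors, numerically
#' differentiates the category probabilities with respect to the parameters
#' (central differences) and counts singular values exceeding `tol` times
#' the largest. The model is locally identified when the minimum rank
#' across probes equals the parameter count.
#'
#' @param model An [mpt_model()].
#' @param n_probes Number of random probes (>= 1).
#' @param tol Relative singular-value threshold.
#' @param seed Seed for the probe draws.
#' @return A list of class `mpt_identifiability`: `probe_count`,
#'   `jacobian_rank` (minimum across probes), `parameter_count`,
#'   `locally_identified`.
#' @export
#' @examples
#' check_identifiability(cp_model(), n_probes = 25)
check_identifiability <- function(model, n_probes = 100L, tol = 1e-8,
                                  seed = 1L) {
  stopifnot(inherits(model, "mpt_model"), n_probes >= 1L)
  cm <- compile_mpt(model)
  h <- 1e-6
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  ranks <- vapply(seq_len(n_probes), function(i) {
    th <- stats::runif(cm$npar, 0.1, 0.9)
    J <- vapply(seq_len(cm$npar), function(k) {
      e <- numeric(cm$npar); e[k] <- h
      (probs_and_jac(cm, th + e, jacobian = FALSE)$p -
         probs_and_jac(cm, th - e, jacobian = FALSE)$p) / (2 * h)
    }, numeric(cm$ncat))
    sv <- svd(J, nu = 0, nv = 0)$d
    sum(sv > tol * sv[1])
  }, integer(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  rank <- min(ranks)
  structure(list(probe_count = as.integer(n_probes),
                 jacobian_rank = as.integer(rank),
                 parameter_count = cm$npar,
                 locally_identified = rank == cm$npar),
            class = "mpt_identifiability")
}

#' @export
print.mpt_identifiability <- function(x, ...) {
  cat("<mpt_identifiability> rank ", x$jacobian_rank, " of ",
      x$parameter_count, " parameters over ", x$probe_count, " probes: ",
      if (x$locally_identified) "locally identified" else "NOT identified",
      "\n", sep = "")
  invisible(x)
}
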