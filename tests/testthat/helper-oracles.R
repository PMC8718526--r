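# Shared fixtures and independent oracles, all built in code.

# canonical category layout used throughout (defector tree first)
cp_layout <- function() {
  tibble::tibble(
    tree = rep(c("defector_partner", "cooperator_partner"), each = 4),
    category = rep(c("coop_punish", "coop_nopunish",
                     "defect_punish", "defect_nopunish"), 2)
  )
}

# Hand-coded category probabilities of the cooperation-and-punishment
# model, written out factor by factor (independent of the package's tree
# engine). Vectorized over parameter vectors of equal length.
cp_probs_hand <- function(C, Pm, Ph, Pa, b) {
  cbind(
    d_cp = C * Pm + C * (1 - Pm) * b,
    d_cn = C * (1 - Pm) * (1 - b),
    d_dp = (1 - C) * Ph + (1 - C) * (1 - Ph) * b,
    d_dn = (1 - C) * (1 - Ph) * (1 - b),
    c_cp = C * b,
    c_cn = C * (1 - b),
    c_dp = (1 - C) * Pa + (1 - C) * (1 - Pa) * b,
    c_dn = (1 - C) * (1 - Pa) * (1 - b)
  )
}

# frequency table with counts exactly equal to expected counts
expected_freqs <- function(params, n_per_tree, group = "g1") {
  p <- cp_probs_hand(params["C"], params["P_moral"],
                     params["P_hypocritical"], params["P_antisocial"],
                     params["b"])
  out <- cp_layout()
  out$group <- group
  out$n <- as.numeric(p) * n_per_tree
  out
}

# multinomial draw of category counts at n_per_tree observations per tree
# (uses the current RNG stream; seed in the test)
draw_freqs <- function(params, n_per_tree, group = "g1") {
  p <- drop(cp_probs_hand(params["C"], params["P_moral"],
                          params["P_hypocritical"], params["P_antisocial"],
                          params["b"]))
  out <- cp_layout()
  out$group <- group
  out$n <- c(stats::rmultinom(1, n_per_tree, p[1:4]),
             stats::rmultinom(1, n_per_tree, p[5:8]))
  out
}

# log-likelihood of one group's counts for a grid of parameter vectors
cp_loglik_grid <- function(n, C, Pm, Ph, Pa, b) {
  p <- cp_probs_hand(C, Pm, Ph, Pa, b)
  lp <- log(pmax(p, 1e-300))
  drop(lp %*% n)
}

# Brute-force grid-search MLE, independent of the package's optimizer:
# a full 0.05-step sweep of [0,1]^5 followed by one 0.01-step refinement
# in a +/-0.05 box around the coarse optimum. Chunked over C to bound
# memory. `n` is the 8-vector of counts in cp_layout() order.
cp_grid_mle <- function(n, coarse = 0.05, fine = 0.01) {
  sweep_grid <- function(gC, gPm, gPh, gPa, gb) {
    best <- list(value = -Inf)
    inner <- expand.grid(Pm = gPm, Ph = gPh, Pa = gPa, b = gb,
                         KEEP.OUT.ATTRS = FALSE)
    for (C in gC) {
      ll <- cp_loglik_grid(n, C, inner$Pm, inner$Ph, inner$Pa, inner$b)
      i <- which.max(ll)
      if (ll[i] > best$value) {
        best <- list(value = ll[i],
                     par = c(C = C, P_moral = inner$Pm[i],
                             P_hypocritical = inner$Ph[i],
                             P_antisocial = inner$Pa[i], b = inner$b[i]))
      }
    }
    best
  }
  g0 <- seq(0, 1, by = coarse)
  stage1 <- sweep_grid(g0, g0, g0, g0, g0)
  box <- function(x) {
    g <- seq(max(0, x - coarse), min(1, x + coarse), by = fine)
    g
  }
  p1 <- stage1$par
  stage2 <- sweep_grid(box(p1["C"]), box(p1["P_moral"]),
                       box(p1["P_hypocritical"]), box(p1["P_antisocial"]),
                       box(p1["b"]))
  stage2
}

# Closed-form interior MLE of the canonical model, derived independently:
# C is the pooled cooperation rate (the cooperation factor of the
# likelihood separates from the conditional punishment factors); b is the
# punish rate after mutual cooperation; each punishment parameter solves
# q = P + (1 - P) b for its cell's conditional punish rate q.
cp_closed_form <- function(freqs) {
  v <- function(tree, cat) freqs$n[freqs$tree == tree &
                                     freqs$category == cat]
  d <- vapply(c("coop_punish", "coop_nopunish", "defect_punish",
                "defect_nopunish"),
              function(k) v("defector_partner", k), numeric(1))
  cc <- vapply(c("coop_punish", "coop_nopunish", "defect_punish",
                 "defect_nopunish"),
               function(k) v("cooperator_partner", k), numeric(1))
  C <- (d[1] + d[2] + cc[1] + cc[2]) / (sum(d) + sum(cc))
  b <- cc[1] / (cc[1] + cc[2])
  solveP <- function(q) (q - b) / (1 - b)
  c(C = unname(C),
    P_moral = unname(solveP(d[1] / (d[1] + d[2]))),
    P_hypocritical = unname(solveP(d[3] / (d[3] + d[4]))),
    P_antisocial = unname(solveP(cc[3] / (cc[3] + cc[4]))),
    b = unname(b))
}

# design constants of the synthetic study
design_n_per_tree <- function() c(no_load = 105 * 7, cognitive_load = 101 * 7)
design_grand_total <- function() 2884  # 206 participants x 14 scored trials

interior_truth <- function() {
  list(no_load = c(C = 0.55, P_moral = 0.60, P_hypocritical = 0.30,
                   P_antisocial = 0.15, b = 0.10),
       cognitive_load = c(C = 0.47, P_moral = 0.48, P_hypocritical = 0.25,
                          P_antisocial = 0.12, b = 0.14))
}
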