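test_that("control calibration matches hand arithmetic and errors on degeneracy", {
  coh <- make_cohort(sle = 10, hc = c(1, 2, 3))
  st <- control_stats(coh)
  expect_equal(st$control_mean, 2)
  expect_equal(st$control_sd, 1)   # sample SD, n - 1
  expect_equal(st$cutoff, 5)

  expect_error(control_stats(make_cohort(10, hc = c(4, 4, 4))),
               "degenerate")
  expect_error(control_stats(make_cohort(10, hc = 7)), "at least 2")
})

test_that("Z-scores follow the definition exactly", {
  coh <- make_cohort(sle = c(16000, 10000, 20000),
                     hc = c(8000, 10000, 12000))
  st <- control_stats(coh)
  expect_equal(st$control_mean, 10000)
  expect_equal(st$control_sd, 2000)
  expect_equal(st$cutoff, 16000)
  z <- z_scores(coh, st)
  expect_equal(unname(z["S01", "A"]), 0)    # titer at cutoff
  expect_equal(unname(z["S02", "A"]), -3)   # titer at control mean
  expect_equal(unname(z["S03", "A"]), 2)    # (20000-16000)/2000
})

test_that("seropositive means strictly above the cutoff", {
  coh <- make_cohort(sle = c(5, 5.0001, 4.9999), hc = c(1, 2, 3))
  st <- control_stats(coh)
  calls <- call_seropositive(coh[coh$group == "SLE", ], st)
  expect_equal(unname(calls[, "A"]), c(FALSE, TRUE, FALSE))
  z <- z_scores(coh[coh$group == "SLE", ], st)
  expect_equal(unname(calls[, "A"]), unname(z[, "A"] > 0))
})

test_that("diagnostic performance reproduces the 71/94 percent pair", {
  ## 54 of 76 SLE above cutoff, 17 of 18 controls at or below
  sle <- c(rep(10, 54), rep(1, 22))
  hc <- c(rep(1, 17), 10)
  coh <- make_cohort(sle, hc)
  perf <- diagnostic_performance(coh, "A", 5)
  expect_equal(perf$sensitivity, 100 * 54 / 76)
  expect_equal(perf$specificity, 100 * 17 / 18)
  expect_equal(round_half_away(perf$sensitivity), 71)
  expect_equal(round_half_away(perf$specificity), 94)

  expect_equal(diagnostic_performance(coh, "A", 0.5)$sensitivity, 100)
  expect_equal(diagnostic_performance(coh, "A", 0.5)$specificity, 0)
  all_pos <- make_cohort(rep(10, 5), rep(1, 5))
  perf2 <- diagnostic_performance(all_pos, "A", 5)
  expect_equal(c(perf2$sensitivity, perf2$specificity), c(100, 100))
})

test_that("performance is invariant under joint monotone transforms", {
  set.seed(41)
  coh <- make_cohort(sle = rlnorm(30, 3), hc = rlnorm(10, 1))
  cutoff <- 10
  p1 <- diagnostic_performance(coh, "A", cutoff)
  coh2 <- coh; coh2$A <- coh$A^3
  p2 <- diagnostic_performance(coh2, "A", cutoff^3)
  expect_equal(p1$sensitivity, p2$sensitivity)
  expect_equal(p1$specificity, p2$specificity)
})

test_that("ROC cutoff maximizes Youden J with the stated tie-break", {
  r <- roc_cutoff(make_cohort(c(10, 11, 12), c(1, 2, 3)), "A")
  expect_equal(r$cutoff, 6.5)   # midpoint of the separating gap
  expect_equal(r$performance$sensitivity + r$performance$specificity - 100,
               100)

  r2 <- roc_cutoff(make_cohort(c(2, 4), c(1, 3)), "A")
  j2 <- r2$performance$sensitivity + r2$performance$specificity - 100
  expect_equal(j2, 50)  # brute-force optimum for this interleaving
  ## tie-break: among equal-J thresholds prefer specificity, then cutoff
  expect_equal(r2$cutoff, 3.5)

  expect_error(roc_cutoff(make_cohort(c(2, 2), c(2, 2)), "A"),
               "no separation")
})

test_that("ROC J equals the brute-force maximum on random instances", {
  set.seed(202)
  for (i in 1:200) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    ## integer titers induce heavy ties, exercising the scan
    x_sle <- sample(1:8, n1, replace = TRUE)
    x_hc <- sample(1:8, n2, replace = TRUE)
    if (length(unique(c(x_sle, x_hc))) < 2) next
    r <- roc_cutoff(make_cohort(x_sle, x_hc), "A")
    j <- r$performance$sensitivity + r$performance$specificity - 100
    expect_equal(j, oracle_best_j(x_sle, x_hc))
  }
})

test_that("estimated cutoff converges to the analytic lognormal mean+3SD", {
  mu10 <- 3.6; sigma10 <- 0.25
  m <- exp(mu10 * log(10) + (sigma10 * log(10))^2 / 2)
  s <- m * sqrt(exp((sigma10 * log(10))^2) - 1)
  analytic <- m + 3 * s
  set.seed(77)
  reps <- replicate(20, {
    hc <- 10^(mu10 + sigma10 * rnorm(10000))
    st <- control_stats(make_cohort(1, hc))
    st$cutoff
  })
  mc_sd <- sd(reps)
  expect_lt(abs(reps[1] - analytic), 3 * mc_sd)
})

test_that("panel union sensitivity is monotone and reduces to one antigen", {
  sim <- simulate_cohort(default_sim_config(n_sle = 120, seed = 13))
  st <- control_stats(sim$cohort)
  single <- panel_sensitivity(sim$cohort, st, "Sm-D3")
  direct <- diagnostic_performance(sim$cohort, "Sm-D3",
                                   st$cutoff[st$antigen == "Sm-D3"])
  expect_equal(single$sensitivity, direct$sensitivity)
  expect_equal(single$specificity, direct$specificity)

  sens_prev <- -Inf; spec_prev <- Inf
  for (k in seq_along(CORE_ANTIGENS)) {
    pp <- panel_sensitivity(sim$cohort, st, CORE_ANTIGENS[1:k])
    expect_gte(pp$sensitivity, sens_prev)
    expect_lte(pp$specificity, spec_prev)
    sens_prev <- pp$sensitivity; spec_prev <- pp$specificity
  }
})

test_that("observed seropositive fraction tracks the configured probability", {
  cfg <- default_sim_config(n_sle = 2000, n_control = 500, seed = 31)
  sim <- simulate_cohort(cfg)
  st <- control_stats(sim$cohort)
  sle <- sim$cohort[sim$cohort$group == "SLE", ]
  calls <- call_seropositive(sle, st)
  ## RNP-70k marginal rate under the generator
  p <- sum(cfg$cluster_probs[c("SM_RNP", "RO_LA")] *
             cfg$seropos_prob["RNP-70k", c("SM_RNP", "RO_LA")])
  bounds <- qbinom(c(0.005, 0.995), 2000, p)
  expect_gte(sum(calls[, "RNP-70k"]), bounds[1])
  expect_lte(sum(calls[, "RNP-70k"]), bounds[2])
})
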