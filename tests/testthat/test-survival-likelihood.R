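test_that("risk sets enumerate event times, ties and memberships", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), arm = c(1, 0, 0))
  idx <- buildRiskSets(d, stratified = FALSE)
  expect_equal(idx$time, c(1, 2))
  expect_equal(idx$n0 + idx$n1, c(3L, 2L))
  expect_equal(idx$d, c(1L, 1L))
  expect_equal(idx$s, c(1L, 0L))

  # singleton strata: only strata containing events survive
  d$st <- 1:3
  idx2 <- buildRiskSets(d, strata_cols = "st")
  expect_equal(nrow(idx2), 2L)
  expect_true(all(idx2$n0 + idx2$n1 == 1L))

  # tied event days collapse to one row with multiplicity 2
  d3 <- data.frame(time = c(7, 7, 9), event = c(1, 1, 0), arm = c(1, 0, 1))
  idx3 <- buildRiskSets(d3, stratified = FALSE)
  expect_equal(nrow(idx3), 1L)
  expect_equal(idx3$d, 2L)
  expect_equal(idx3$s, 1L)

  expect_error(buildRiskSets(data.frame(time = 1:2, event = c(0, 0),
                                        arm = c(0, 1)), stratified = FALSE),
               "no events")
})

test_that("breslow log-likelihood matches hand-derived values", {
  # A(x=1, event t=1), B(x=0, event t=2), C(x=0, censored t=3) at beta = 0:
  # log(1/3) + log(1/2)
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), arm = c(1, 0, 0))
  idx <- buildRiskSets(d, stratified = FALSE)
  expect_equal(breslowLoglik(idx, 0), log(1 / 3) + log(1 / 2),
               tolerance = 1e-12)

  # at the null with no ties the likelihood is -sum log |R(t_j)|
  set.seed(2)
  d2 <- data.frame(time = sample(seq(1, 20, by = 0.5), 12),
                   event = rbinom(12, 1, 0.6), arm = rbinom(12, 1, 0.5))
  d2$event[1] <- 1
  idx2 <- buildRiskSets(d2, stratified = FALSE)
  expect_equal(breslowLoglik(idx2, 0), -sum(idx2$d * log(idx2$n0 + idx2$n1)),
               tolerance = 1e-12)

  expect_error(breslowLoglik(idx, Inf), "finite")
})

test_that("likelihood equals the enumerated product on random small data", {
  for (s in 1:40) {
    d <- random_small_data(s)
    idx <- buildRiskSets(d, strata_cols = "stratum")
    for (b in c(-2, -0.5, 0, 1, 3)) {
      expect_equal(breslowLoglik(idx, b),
                   breslow_brute(d$time, d$event, d$arm, d$stratum, b),
                   tolerance = 1e-12, info = sprintf("seed %d beta %g", s, b))
    }
  }
})

test_that("the likelihood is a rank statistic", {
  d <- make_margin_trial_data(seed = 5)
  idx <- buildRiskSets(d)
  base <- breslowLoglik(idx, c(-1, 0.3))

  # censored subject earlier than every event changes nothing
  d_extra <- rbind(d, data.frame(subject_id = 9999, time = 0.5, event = 0L,
                                 arm = 1L, facility = 0L, age60 = 0L, us = 1L))
  expect_equal(breslowLoglik(buildRiskSets(d_extra), c(-1, 0.3)), base,
               tolerance = 1e-12)

  # positive time scaling changes nothing
  d_scaled <- d; d_scaled$time <- d$time * 3.7
  expect_equal(breslowLoglik(buildRiskSets(d_scaled), c(-1, 0.3)), base,
               tolerance = 1e-12)
})

test_that("the likelihood is concave in beta on trial-sized data", {
  idx <- buildRiskSets(make_margin_trial_data(seed = 2))
  grid <- seq(-5, 3, by = 0.1)
  ll <- breslowLoglik(idx, grid)
  expect_true(all(diff(ll, differences = 2) < 0))
})

test_that("Newton MLE solves the score equation", {
  # score 1 - 2u/(2u+1) - u/(1+u) = 0 has root u = 1/sqrt(2)
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), arm = c(1, 0, 1))
  fit <- coxMle(buildRiskSets(d, stratified = FALSE))
  expect_true(fit$converged)
  expect_equal(fit$hr, 1 / sqrt(2), tolerance = 1e-7)

  # matches a grid-search argmax on random data
  for (s in 1:10) {
    dd <- random_small_data(100 + s, n_max = 12)
    idx <- buildRiskSets(dd, strata_cols = "stratum")
    if (sum(idx$s) == 0 || sum(idx$s) == sum(idx$d)) next
    fit2 <- coxMle(idx)
    if (!fit2$converged || abs(fit2$beta) > 4) next
    grid <- seq(-5, 5, by = 1e-4)
    bhat <- grid[which.max(breslowLoglik(idx, grid))]
    expect_lt(abs(fit2$beta - bhat), 1e-4)
  }
})

test_that("all events in one arm is flagged as monotone, not diverged", {
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                  arm = c(0, 0, 1, 1))
  fit <- coxMle(buildRiskSets(d, stratified = FALSE))
  expect_true(fit$monotone)
  expect_false(fit$converged)
  expect_true(is.na(fit$hr))
})

test_that("MLE agrees with an established Cox implementation", {
  skip_if_not_installed("survival")
  d <- make_margin_trial_data(seed = 3)
  idx <- buildRiskSets(d)
  fit <- coxMle(idx)
  cph <- survival::coxph(
    survival::Surv(time, event) ~ arm + survival::strata(facility, age60, us),
    data = d, ties = "breslow")
  expect_equal(fit$beta, unname(coef(cph)), tolerance = 1e-6)
  expect_equal(fit$se, sqrt(unname(vcov(cph)[1, 1])), tolerance = 1e-6)

  # unstratified variant too
  fit_u <- coxMle(buildRiskSets(d, stratified = FALSE))
  cph_u <- survival::coxph(survival::Surv(time, event) ~ arm, data = d,
                           ties = "breslow")
  expect_equal(fit_u$beta, unname(coef(cph_u)), tolerance = 1e-6)
})

test_that("parameter recovery holds across true hazard ratios", {
  for (h in c(0.25, 1, 2)) {
    d <- simulateTrial(trialConfig(n_treat = 2000, n_ctrl = 2000,
                                   true_hr = h, p_event_ctrl = 0.053,
                                   seed = round(1e4 * h)))
    fit <- coxMle(buildRiskSets(d))
    expect_true(fit$converged)
    expect_lt(abs(fit$beta - log(h)), 3 * fit$se)
  }
})
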