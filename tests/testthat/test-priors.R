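test_that("reference priors carry the stated normal parameters", {
  mi <- referencePrior("minimally_informative")
  expect_equal(mi$mean_log_hr, 0)
  expect_equal(mi$sd_log_hr, 3)
  wo <- referencePrior("weakly_optimistic")
  expect_equal(wo$mean_log_hr, log(0.75))
  expect_equal(wo$sd_log_hr, 1)
  wp <- referencePrior("weakly_pessimistic")
  expect_equal(wp$mean_log_hr, log(1.25))
  expect_error(referencePrior("strongly_enthusiastic"), "valid names")
})

test_that("every published reference-prior probability cell is reproduced", {
  for (nm in rownames(reference_prior_cells)) {
    p <- referencePrior(nm)
    got <- c(1 - priorCdf(p, 1.25), priorCdf(p, c(1, 0.75, 0.6, 0.4, 0.2)))
    expect_equal(round(got, 2), unname(reference_prior_cells[nm, ]),
                 info = nm)
  }
})

test_that("trial summaries map to normal components by the CI-width rule", {
  # hand arithmetic: mu = ln 0.5, sd = (ln 0.8 - ln 0.3) / (2 * 1.959964)
  comp <- trialToComponent(0.5, 0.3, 0.8)
  expect_equal(unname(comp[1]), -0.6931472, tolerance = 1e-6)
  expect_equal(unname(comp[2]), 0.2502161, tolerance = 1e-6)
  # unit-SD construction
  comp2 <- trialToComponent(1, exp(-qnorm(0.975)), exp(qnorm(0.975)))
  expect_equal(unname(comp2), c(0, 1), tolerance = 1e-12)
  expect_error(trialToComponent(0.5, 0.6, 0.8), "bracket")
  expect_error(trialToComponent(0.5, -0.1, 0.8), "positive")
})

test_that("mixtures weight components by sample size within the subset", {
  tr <- data.frame(point = c(0.5, 0.9), lcl = c(0.3, 0.6), ucl = c(0.8, 1.3),
                   n = c(100, 300), class = c("DAA", "nonDAA"))
  m <- buildMixture(tr, "all")
  expect_equal(m$weights, c(0.25, 0.75))
  expect_equal(m$mean_log_hr, log(c(0.5, 0.9)))

  # single trial: mixture collapses to that normal
  m1 <- buildMixture(tr[1, ], "all")
  expect_equal(length(m1$weights), 1L)
  expect_equal(priorCdf(m1, 0.5), 0.5, tolerance = 1e-12)

  # subset weights recomputed over the subset only
  tab <- syntheticHistoricalTable(seed = 4)
  md <- buildMixture(tab, "DAA")
  daa <- tab[tab$class == "DAA", ]
  expect_equal(length(md$weights), 3L)
  expect_equal(md$weights, daa$n / sum(daa$n))
  expect_error(buildMixture(tab[tab$class == "DAA", ], "nonDAA"), "no trials")
})

test_that("prior CDF is a proper, monotone distribution for all priors", {
  tab <- syntheticHistoricalTable(seed = 4)
  priors <- c(lapply(referencePriorNames(), referencePrior),
              lapply(c("all", "DAA", "nonDAA"), buildMixture, trials = tab))
  grid <- exp(seq(log(1e-5), log(1e5), length.out = 101))
  for (p in priors) {
    v <- priorCdf(p, grid)
    expect_true(all(diff(v) >= 0), info = p$label)
    expect_lt(v[1], 1e-3)
    expect_gt(v[101], 1 - 1e-3)
  }
  expect_error(priorCdf(priors[[1]], -1), "positive")
})

test_that("equal-tail intervals invert the CDF", {
  tab <- syntheticHistoricalTable(seed = 4)
  priors <- list(referencePrior("weakly_skeptical"),
                 buildMixture(tab, "all"))
  for (p in priors) {
    for (mass in c(0.5, 0.8, 0.95)) {
      iv <- priorInterval(p, mass)
      expect_equal(priorCdf(p, iv[["upper"]]) - priorCdf(p, iv[["lower"]]),
                   mass, tolerance = 1e-8)
    }
    # widening in mass
    expect_true(priorInterval(p, 0.99)[["upper"]] >
                  priorInterval(p, 0.9)[["upper"]])
  }
})

test_that("mixture summaries match closed forms and sampling", {
  # lognormal closed form for a single standard normal on log-HR
  s1 <- mixtureSummaries(priorSpec(1, 0, 1))
  expect_equal(s1$mean_hr, exp(0.5), tolerance = 1e-10)
  expect_equal(s1$sd_log_hr, 1, tolerance = 1e-10)
  expect_equal(s1$median_hr, 1, tolerance = 1e-8)

  # two-component closed form derived by hand:
  # 0.5*0.2*e^{0.125} + 0.5*0.8*e^{0.045} = 0.531726
  m2 <- priorSpec(c(0.5, 0.5), log(c(0.2, 0.8)), c(0.5, 0.3))
  s2 <- mixtureSummaries(m2)
  expect_equal(s2$mean_hr, 0.5317265, tolerance = 1e-6)

  # sampling oracle: direct draws agree with the closed forms
  dr <- samplePrior(m2, 200000, seed = 6)
  se_mean <- sd(exp(dr)) / sqrt(length(dr))
  expect_lt(abs(mean(exp(dr)) - s2$mean_hr), 3 * se_mean)
  expect_lt(abs(sd(dr) - s2$sd_log_hr), 0.01)
  p_emp <- mean(exp(dr) < 0.6)
  p_th <- priorCdf(m2, 0.6)
  expect_lt(abs(p_emp - p_th), 3 * sqrt(p_th * (1 - p_th) / length(dr)))
})

test_that("prior sampling is seed-reproducible and MCMC path agrees", {
  p <- priorSpec(c(0.5, 0.5), c(-2, 2), c(0.1, 0.1))
  expect_identical(samplePrior(p, 1000, seed = 3), samplePrior(p, 1000, seed = 3))
  # symmetric bimodal: half the mass below zero
  dr <- samplePrior(p, 100000, seed = 3)
  expect_lt(abs(mean(dr < 0) - 0.5), 3 * sqrt(0.25 / 1e5))
  # the MCMC verification path targets the same distribution
  drm <- samplePrior(p, 20000, seed = 4, method = "mcmc",
                     chains = 4, warmup = 1000)
  expect_lt(abs(mean(drm < 0) - 0.5), 0.02)
  expect_lt(abs(mean(exp(drm) < 0.6) - priorCdf(p, 0.6)), 0.02)
})

test_that("prior configs round-trip through YAML and JSON", {
  tab <- syntheticHistoricalTable(seed = 4)
  priors <- list(referencePrior("weakly_optimistic"), buildMixture(tab, "all"))
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    writePriorConfig(priors, f)
    back <- readPriorConfig(f)
    expect_equal(length(back), 2L)
    for (i in 1:2) {
      expect_equal(back[[i]]$weights, priors[[i]]$weights, tolerance = 1e-12)
      expect_equal(back[[i]]$mean_log_hr, priors[[i]]$mean_log_hr,
                   tolerance = 1e-12)
      expect_equal(back[[i]]$sd_log_hr, priors[[i]]$sd_log_hr,
                   tolerance = 1e-12)
      expect_equal(back[[i]]$label, priors[[i]]$label)
    }
  }
})

test_that("degenerate prior specifications are rejected", {
  expect_error(priorSpec(numeric(0), numeric(0), numeric(0)), "at least one")
  expect_error(priorSpec(1, 0, 0), "positive")
  expect_error(priorSpec(c(1, 1), 0, 1), "equal length")
})
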