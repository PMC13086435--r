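# Independent oracles used across tests. These re-derive quantities from
# first principles and must stay independent of the package internals.

# Breslow partial log-likelihood by direct enumeration over subjects:
# each distinct event time contributes s_j * beta - d_j * log(sum over the
# risk set of exp(beta * x)), risk sets built within strata from raw data.
breslow_brute <- function(time, event, arm, stratum = NULL, beta = 0) {
  if (is.null(stratum)) stratum <- rep(1L, length(time))
  ll <- 0
  for (st in unique(stratum)) {
    idx <- stratum == st
    t <- time[idx]; e <- event[idx]; x <- arm[idx]
    for (tj in sort(unique(t[e == 1]))) {
      ties <- e == 1 & t == tj
      risk <- t >= tj
      ll <- ll + beta * sum(x[ties]) -
        sum(ties) * log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# deterministic grid approximation to the posterior CDF of beta:
# normalized trapezoid integration of exp(log prior + log partial lik)
grid_posterior_cdf <- function(log_post_fn, grid = seq(-6, 3, length.out = 2001)) {
  lp <- vapply(grid, log_post_fn, numeric(1))
  lp <- lp - max(lp)
  dens <- exp(lp)
  h <- diff(grid)
  cell <- h * (dens[-1] + dens[-length(dens)]) / 2
  cdf <- c(0, cumsum(cell))
  cdf <- cdf / cdf[length(cdf)]
  list(grid = grid, cdf = cdf,
       at = function(b) stats::approx(grid, cdf, xout = b, rule = 2)$y)
}

# sup distance between the empirical CDF of draws and a grid CDF
sup_cdf_distance <- function(draws, gcdf) {
  draws <- sort(draws)
  n <- length(draws)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  g <- gcdf$at(draws)
  max(abs(emp_hi - g), abs(emp_lo - g))
}

# random small survival dataset for oracle-equivalence checks
random_small_data <- function(seed, n_max = 6) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  repeat {
    d <- data.frame(
      time = sample(1:4, n, replace = TRUE),      # integer times force ties
      event = rbinom(n, 1, 0.7),
      arm = rbinom(n, 1, 0.5),
      stratum = sample(1:2, n, replace = TRUE)
    )
    if (sum(d$event) > 0) return(d)
  }
}

# printed reference-prior probability table used as an exact regression
# fixture: columns P(HR>1.25), P(HR<1), P(HR<0.75), P(HR<0.6), P(HR<0.4),
# P(HR<0.2), values as published to two decimals
reference_prior_cells <- rbind(
  minimally_informative = c(0.47, 0.50, 0.46, 0.43, 0.38, 0.30),
  weakly_skeptical      = c(0.41, 0.50, 0.39, 0.30, 0.18, 0.05),
  moderately_skeptical  = c(0.33, 0.50, 0.28, 0.15, 0.03, 0.00),
  weakly_pessimistic    = c(0.50, 0.41, 0.30, 0.23, 0.13, 0.03),
  weakly_optimistic     = c(0.30, 0.61, 0.50, 0.41, 0.26, 0.09)
)

# re-draw only the event times of an existing dataset (uniform on [2, 28]
# days, rounded), leaving subjects, arms, strata and event assignment fixed:
# isolates event-timing sensitivity from dataset-realization noise
redraw_event_times <- function(data, seed, window = c(2, 28),
                               round_days = TRUE) {
  set.seed(seed)
  ne <- sum(data$event)
  et <- runif(ne, window[1], window[2])
  if (round_days) et <- pmax(1, round(et))
  data$time[data$event == 1] <- et
  data
}

make_margin_trial_data <- function(seed = 1) {
  simulateTrial(trialConfig(events_treat = 2, events_ctrl = 15, seed = seed))
}
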