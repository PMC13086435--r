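# Adaptive random-walk Metropolis engine and MCMC convergence diagnostics.

#' Adaptive random-walk Metropolis for a one-dimensional target
#'
#' Runs `length(inits)` independent chains of Gaussian random-walk
#' Metropolis. During warm-up the proposal scale is adapted by
#' Robbins-Monro on its log toward an acceptance rate of 0.44 (the
#' one-dimensional optimum); the scale is frozen after warm-up so the saved
#' draws come from a fixed Markov kernel.
#'
#' @param log_target Function of one numeric argument returning the
#'   (unnormalized) log density.
#' @param inits Numeric vector of starting values, one per chain;
#'   overdispersed starts make the split R-hat diagnostic meaningful.
#' @param warmup,saved Iterations discarded / kept per chain.
#' @param seeds Integer vector of per-chain RNG seeds (see [deriveSeeds()]).
#' @param step0 Initial proposal SD.
#' @param target_accept Acceptance-rate target for the adaptation.
#' @return List with `draws` (`saved x chains` matrix), `step` (final
#'   proposal SD per chain) and `accept_rate` (post-warm-up rate per chain).
#' @export
mhSample <- function(log_target, inits, warmup, saved, seeds,
                     step0 = 1, target_accept = 0.44) {
  chains <- length(inits)
  stopifnot(length(seeds) == chains, saved >= 1, warmup >= 0)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  draws <- matrix(NA_real_, nrow = saved, ncol = chains)
  step <- numeric(chains)
  acc_rate <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(seeds[ch])
    beta <- inits[ch]
    lp <- log_target(beta)
    if (!is.finite(lp)) stop("log_target is not finite at init ", inits[ch])
    ls <- log(step0)
    total <- warmup + saved
    n_acc <- 0L
    for (i in seq_len(total)) {
      prop <- beta + exp(ls) * stats::rnorm(1L)
      lpp <- log_target(prop)
      alpha <- if (is.finite(lpp)) min(1, exp(lpp - lp)) else 0
      if (stats::runif(1L) < alpha) {
        beta <- prop; lp <- lpp
        if (i > warmup) n_acc <- n_acc + 1L
      }
      if (i <= warmup) {
        ls <- ls + (alpha - target_accept) / i^0.6
      } else {
        draws[i - warmup, ch] <- beta
      }
    }
    step[ch] <- exp(ls)
    acc_rate[ch] <- n_acc / saved
  }
  list(draws = draws, step = step, accept_rate = acc_rate)
}

# --- diagnostics ------------------------------------------------------------

# split each column of a draws matrix in half -> n/2 x 2m matrix
split_chains <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2L
  draws <- draws[seq_len(2L * half), , drop = FALSE]
  matrix(draws, nrow = half)
}

# rank-normalize a matrix jointly across all elements
rank_normalize <- function(draws) {
  z <- stats::qnorm((rank(draws) - 3 / 8) / (length(draws) + 1 / 4))
  matrix(z, nrow = nrow(draws))
}

# potential scale reduction on an already split (and possibly
# rank-normalized) draws matrix
rhat_basic <- function(sm) {
  n <- nrow(sm); m <- ncol(sm)
  mu <- colMeans(sm)
  W <- mean(apply(sm, 2, stats::var))
  B <- n * stats::var(mu)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# biased autocovariance sequence by FFT
acov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  M <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, M - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (M * n)
}

# effective sample size of an already split draws matrix, using chain-mean
# corrected autocorrelations and Geyer's initial monotone sequence
ess_basic <- function(sm) {
  n <- nrow(sm); m <- ncol(sm)
  if (n < 4L) return(NA_real_)
  ac <- apply(sm, 2, acov_fft)             # n x m, biased autocovariances
  chain_var <- ac[1L, ] * n / (n - 1)
  W <- mean(chain_var)
  B <- n * stats::var(colMeans(sm))
  var_plus <- W * (n - 1) / n + B / n
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (W - rowMeans(ac)) / var_plus # rho[1] corresponds to lag 0
  # Geyer: sums of adjacent pairs, truncated at first negative, then
  # forced monotone nonincreasing
  max_pairs <- (n - 2L) %/% 2L
  prev_pair <- Inf
  tau_acc <- 0
  for (k in 0:max_pairs) {
    pair <- rho[2L * k + 1L] + rho[2L * k + 2L]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau_acc <- tau_acc + pair
  }
  tau <- -rho[1L] + 2 * tau_acc
  if (tau <= 0) return(NA_real_)
  min(n * m / tau, n * m)
}

#' MCMC convergence diagnostics
#'
#' Split R-hat and rank-normalized bulk effective sample size, following the
#' standard modern definitions: chains are split in half, the pooled draws
#' are rank-normalized via the inverse normal CDF, and the between/within
#' variance ratio (R-hat) and autocorrelation-based ESS (with Geyer's initial
#' monotone sequence truncation) are computed on the transformed splits.
#'
#' @param draws A [posteriorDraws()] object or a plain `iterations x chains`
#'   numeric matrix.
#' @return List with `rhat`, `ess_bulk`, `n_chains`, `n_saved`. With a
#'   single chain R-hat is unavailable and reported as `NA` (ESS is still
#'   computed from the split halves).
#' @export
mcmcDiagnostics <- function(draws) {
  mat <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  m <- ncol(mat)
  sm <- split_chains(mat)
  z <- rank_normalize(sm)
  rhat <- if (m >= 2L) rhat_basic(z) else NA_real_
  ess <- ess_basic(z)
  list(rhat = rhat, ess_bulk = ess, n_chains = m, n_saved = nrow(mat))
}

#' Export per-chain traces as CSV
#'
#' Writes columns `chain,iteration,log_hr` for trace plotting.
#'
#' @param draws A [posteriorDraws()] object or draws matrix.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
exportTrace <- function(draws, path) {
  mat <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  out <- data.frame(
    chain = rep(seq_len(ncol(mat)), each = nrow(mat)),
    iteration = rep(seq_len(nrow(mat)), times = ncol(mat)),
    log_hr = as.vector(mat)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
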