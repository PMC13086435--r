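# Internal numerical helpers shared across modules.

# log(exp(a) + exp(b)) elementwise, tolerating -Inf entries.
log_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  # both -Inf => log(0)
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log(sum(exp(x))) for a vector.
log_sum_exp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Deterministically expands one master seed into `n` distinct integer seeds,
#' used so that independent pipeline stages (dataset simulation, one MCMC fit
#' per prior) each get their own stream while the whole run is reproducible
#' from a single integer.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds required.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
deriveSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# quantile with the median-unbiased estimator used for all posterior summaries
quantile8 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 8, names = FALSE)
}
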