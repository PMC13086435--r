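#' Risk-set index for the Breslow partial likelihood
#'
#' Pre-computes, per stratum and distinct event time `t_j`: the event
#' multiplicity `d_j` (ties share one term with the full risk-set denominator
#' used `d_j` times, the Breslow convention), the number of treated subjects
#' among the tied events `s_j`, and the risk-set composition — counts `n0_j`,
#' `n1_j` of control / treated subjects with `time >= t_j`. With a single
#' binary covariate these counts are sufficient for the partial likelihood.
#' Censored subjects contribute to risk sets only, never an event term.
#'
#' @param data Data frame with columns `time`, `event`, `arm`, and (for
#'   stratified analyses) the stratification columns.
#' @param stratified Build risk sets within each stratum separately
#'   (stratified baseline hazard, the default) or pool all subjects. The
#'   alternative to stratification — entering the factors as regression
#'   covariates — is out of scope; stratification keeps the model a
#'   single-parameter likelihood.
#' @param strata_cols Names of the stratification columns; combinations of
#'   their values define the strata. Ignored when `stratified = FALSE` or
#'   when none of the columns are present.
#' @return Object of class `risk_set_index`: a data frame with columns
#'   `stratum`, `time`, `d`, `s`, `n0`, `n1` plus attributes `n_subjects`,
#'   `n_events`. Strata without events are dropped (they contribute nothing
#'   to the likelihood).
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), arm = c(1, 0, 0))
#' buildRiskSets(d, stratified = FALSE)
#' @export
buildRiskSets <- function(data, stratified = TRUE,
                          strata_cols = c("facility", "age60", "us")) {
  stopifnot(is.data.frame(data),
            all(c("time", "event", "arm") %in% names(data)))
  if (nrow(data) == 0L) stop("empty dataset")
  if (!all(data$event %in% c(0L, 1L))) stop("event must be 0/1")
  if (!all(data$arm %in% c(0L, 1L))) stop("arm must be 0/1")
  if (any(data$time <= 0)) stop("times must be positive")
  if (sum(data$event) == 0L) {
    stop("no events in the data: the partial likelihood is constant")
  }
  use_cols <- intersect(strata_cols, names(data))
  stratum <- if (stratified && length(use_cols) > 0L) {
    interaction(data[use_cols], drop = TRUE, sep = "/")
  } else {
    factor(rep("all", nrow(data)))
  }
  pieces <- lapply(levels(stratum), function(st) {
    idx <- stratum == st
    t <- data$time[idx]
    e <- as.integer(data$event[idx]); x <- as.integer(data$arm[idx])
    tj <- sort(unique(t[e == 1L]))
    if (length(tj) == 0L) return(NULL)
    data.frame(
      stratum = st,
      time = tj,
      d = vapply(tj, function(u) sum(e == 1L & t == u), integer(1)),
      s = vapply(tj, function(u) sum(x[e == 1L & t == u]), integer(1)),
      n0 = vapply(tj, function(u) sum(t >= u & x == 0L), integer(1)),
      n1 = vapply(tj, function(u) sum(t >= u & x == 1L), integer(1))
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, class = c("risk_set_index", "data.frame"),
            n_subjects = nrow(data), n_events = sum(data$event),
            stratified = stratified)
}

#' @export
print.risk_set_index <- function(x, ...) {
  cat(sprintf("<risk_set_index> %d event times in %d strata (%d subjects, %d events)\n",
              nrow(x), length(unique(x$stratum)),
              attr(x, "n_subjects"), attr(x, "n_events")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Breslow partial log-likelihood for the treatment log hazard ratio
#'
#' `l(beta) = sum_j [ s_j beta - d_j log(n0_j + n1_j exp(beta)) ]`, summed
#' over distinct event times within strata. The denominator is evaluated as
#' a log-sum so large `|beta|` cannot overflow.
#'
#' @param index A [buildRiskSets()] result.
#' @param beta Log hazard ratio(s); vectorized.
#' @return Log partial likelihood, one value per `beta`.
#' @export
breslowLoglik <- function(index, beta) {
  stopifnot(inherits(index, "risk_set_index"))
  if (any(!is.finite(beta))) stop("beta must be finite")
  ln0 <- ifelse(index$n0 > 0, log(index$n0), -Inf)
  ln1 <- ifelse(index$n1 > 0, log(index$n1), -Inf)
  vapply(beta, function(b) {
    sum(index$s) * b - sum(index$d * log_add(ln0, ln1 + b))
  }, numeric(1))
}

# score and observed information of the Breslow log-likelihood at beta
breslow_score_info <- function(index, beta) {
  # p_j = n1 e^b / (n0 + n1 e^b), computed on the log scale
  ln0 <- ifelse(index$n0 > 0, log(index$n0), -Inf)
  ln1 <- ifelse(index$n1 > 0, log(index$n1), -Inf)
  p <- exp(ln1 + beta - log_add(ln0, ln1 + beta))
  list(score = sum(index$s) - sum(index$d * p),
       info = sum(index$d * p * (1 - p)))
}

#' Maximum partial-likelihood estimate of the hazard ratio
#'
#' Newton-Raphson maximization of [breslowLoglik()] starting at `beta = 0`,
#' with step-halving, convergence when `|delta beta| < 1e-8`, and at most 50
#' iterations. The standard error comes from the observed information and
#' the CI is the Wald interval `exp(beta +/- qnorm(0.975) * se)`. When all
#' events fall in one arm the likelihood is monotone in `beta` and the fit is
#' flagged rather than silently diverging.
#'
#' @param index A [buildRiskSets()] result.
#' @return Object of class `cox_mle_fit`: list with `beta`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `loglik`, `converged`, `monotone`, `iterations`.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), arm = c(1, 0, 1))
#' coxMle(buildRiskSets(d, stratified = FALSE))$hr # 1/sqrt(2)
#' @export
coxMle <- function(index) {
  stopifnot(inherits(index, "risk_set_index"))
  s_tot <- sum(index$s); d_tot <- sum(index$d)
  if (s_tot == 0L || s_tot == d_tot) {
    # every event in a single arm: score never vanishes at finite beta
    return(structure(list(beta = NA_real_, se = NA_real_, hr = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          monotone = TRUE, iterations = 0L),
                     class = "cox_mle_fit"))
  }
  beta <- 0; ll <- breslowLoglik(index, beta)
  converged <- FALSE; iter <- 0L
  while (iter < 50L) {
    iter <- iter + 1L
    si <- breslow_score_info(index, beta)
    if (si$info <= 0) break
    step <- si$score / si$info
    # step-halving: insist on non-decreasing likelihood
    new_beta <- beta + step
    new_ll <- breslowLoglik(index, new_beta)
    h <- 0L
    while (!is.finite(new_ll) || new_ll < ll - 1e-12) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- breslowLoglik(index, new_beta)
      h <- h + 1L
      if (h > 30L) break
    }
    done <- abs(step) < 1e-8
    beta <- new_beta; ll <- new_ll
    if (done) { converged <- TRUE; break }
  }
  info <- breslow_score_info(index, beta)$info
  se <- 1 / sqrt(info)
  z <- stats::qnorm(0.975)
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
                 loglik = ll, converged = converged, monotone = FALSE,
                 iterations = iter),
            class = "cox_mle_fit")
}

#' @export
print.cox_mle_fit <- function(x, ...) {
  if (x$monotone) {
    cat("<cox_mle_fit> monotone partial likelihood (all events in one arm);",
        "no finite MLE\n")
  } else {
    cat(sprintf(
      "<cox_mle_fit> HR %.4f (95%% CI %.4f-%.4f), log-HR %.4f (SE %.4f)%s\n",
      x$hr, x$ci_lower, x$ci_upper, x$beta, x$se,
      if (x$converged) "" else " [NOT CONVERGED]"))
  }
  invisible(x)
}
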