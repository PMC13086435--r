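#' Run the full Bayesian reanalysis over a set of priors
#'
#' Fits one posterior per prior (each with its own deterministic sub-seed of
#' the master seed), assembles the prior summary table (mean HR, SD of
#' log-HR, median, threshold probabilities) and the posterior table
#' (median HR, equal-tail 95% CrI, `P(HR < c)` on the cutoff grid), and
#' reports the headline robustness statistic: the minimum across priors of
#' `P(HR < 1)`, suppressed (`NA`) unless every fit passed the convergence
#' diagnostics.
#'
#' @param data Subject data frame (`time`, `event`, `arm`, strata columns).
#' @param priors A [priorSpec()] or list of them.
#' @param chains,warmup,saved MCMC settings per fit (see
#'   [samplePosterior()]).
#' @param seed Master integer seed.
#' @param cutoffs HR cutoff grid for the posterior table.
#' @param stratified Passed to [buildRiskSets()].
#' @param keep_draws Retain the full [posteriorDraws()] objects in the
#'   bundle (`$draws`); off by default to keep bundles light.
#' @param ... Further arguments passed to [samplePosterior()] (e.g. `step0`,
#'   `inits`).
#' @return Object of class `report_bundle`: list with `prior_table`,
#'   `posterior_table`, `summaries` (per-prior [summarizePosterior()]
#'   results), `diagnostics`, `min_p_benefit`, `all_converged`, `mle`
#'   (the frequentist [coxMle()] cross-check), `settings`, `seed`.
#' @export
runReanalysis <- function(data, priors, chains = 4, warmup = 5000,
                          saved = 20000, seed,
                          cutoffs = seq(1, 0.1, by = -0.1),
                          stratified = TRUE, keep_draws = FALSE, ...) {
  if (inherits(priors, "prior_spec")) priors <- list(priors)
  stopifnot(length(priors) >= 1,
            all(vapply(priors, inherits, logical(1), "prior_spec")))
  if (missing(seed)) stop("a master seed is required")
  labels <- vapply(priors, function(p) p$label, character(1))
  seeds <- deriveSeeds(seed, length(priors))
  index <- buildRiskSets(data, stratified = stratified)

  fits <- lapply(seq_along(priors), function(i) {
    samplePosterior(priors[[i]], index = index, chains = chains,
                    warmup = warmup, saved = saved, seed = seeds[i],
                    stratified = stratified, ...)
  })
  sums <- lapply(fits, summarizePosterior, cutoffs = cutoffs)
  diags <- lapply(fits, function(f) f$diagnostics)

  prior_rows <- lapply(seq_along(priors), function(i) {
    ms <- mixtureSummaries(priors[[i]])
    cbind(data.frame(prior = labels[i], mean_hr = ms$mean_hr,
                     sd_log_hr = ms$sd_log_hr, median_hr = ms$median_hr),
          as.data.frame(as.list(ms$thresholds), check.names = FALSE))
  })
  prior_table <- do.call(rbind, prior_rows)
  rownames(prior_table) <- NULL

  post_rows <- lapply(seq_along(sums), function(i) {
    s <- sums[[i]]
    pr <- stats::setNames(as.list(s$table$prob),
                          sprintf("P(HR<%g)", s$table$cutoff))
    cbind(data.frame(prior = labels[i], median_hr = s$median_hr,
                     cri_lower = s$cri_lower, cri_upper = s$cri_upper,
                     converged = s$converged),
          as.data.frame(pr, check.names = FALSE))
  })
  posterior_table <- do.call(rbind, post_rows)
  rownames(posterior_table) <- NULL

  all_conv <- all(posterior_table$converged)
  p_benefit <- vapply(sums, function(s) {
    s$table$prob[match(1, s$table$cutoff)]
  }, numeric(1))
  structure(
    list(prior_table = prior_table, posterior_table = posterior_table,
         summaries = stats::setNames(sums, labels),
         diagnostics = stats::setNames(diags, labels),
         min_p_benefit = if (all_conv) min(p_benefit) else NA_real_,
         all_converged = all_conv,
         draws = if (keep_draws) stats::setNames(fits, labels) else NULL,
         mle = coxMle(index),
         settings = list(chains = chains, warmup = warmup, saved = saved,
                         cutoffs = cutoffs, stratified = stratified),
         seed = seed),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d priors, %s\n",
              nrow(x$posterior_table),
              if (x$all_converged) {
                sprintf("min P(HR<1) = %.3f", x$min_p_benefit)
              } else {
                "UNCONVERGED fits present (headline statistic suppressed)"
              }))
  tab <- x$posterior_table
  tab$median_hr <- round(tab$median_hr, 2)
  tab$cri_lower <- round(tab$cri_lower, 2)
  tab$cri_upper <- round(tab$cri_upper, 2)
  num <- vapply(tab, is.numeric, logical(1)) & grepl("^P\\(", names(tab))
  tab[num] <- lapply(tab[num], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot-ready prior and posterior density curves on the HR axis
#'
#' The prior curve is analytic: the mixture density on log-HR transformed to
#' the HR axis with the change-of-variables Jacobian `1/hr`. The posterior
#' curve is a Gaussian kernel density (Silverman bandwidth) of the pooled
#' log-HR draws, transformed the same way; it is cosmetic and is not used
#' for any reported number.
#'
#' @param prior A [priorSpec()].
#' @param draws Optional [posteriorDraws()]; when `NULL` only the prior
#'   curve is returned.
#' @param grid Positive HR grid (increasing).
#' @return Data frame with `hr`, `prior_density` and (when draws are given)
#'   `posterior_density`; each curve integrates to ~1 over a wide grid.
#' @export
densityExport <- function(prior, draws = NULL,
                          grid = exp(seq(log(0.005), log(20), length.out = 512))) {
  stopifnot(inherits(prior, "prior_spec"))
  if (any(grid <= 0)) stop("HR grid points must be positive")
  lg <- log(grid)
  out <- data.frame(
    hr = grid,
    prior_density = priorLogDensity(prior, lg, log = FALSE) / grid
  )
  if (!is.null(draws)) {
    stopifnot(inherits(draws, "posterior_draws"))
    beta <- as.vector(draws$draws)
    kd <- stats::density(beta, bw = "nrd0",
                         from = min(lg) - 1, to = max(lg) + 1, n = 1024)
    out$posterior_density <- stats::approx(kd$x, kd$y, xout = lg,
                                           yleft = 0, yright = 0)$y / grid
  }
  out
}

#' Serialize a report bundle to a plain list / JSON
#'
#' `bundleToList` flattens the bundle into JSON-compatible structures;
#' `bundleFromList` restores it (data frames and numeric types round-trip
#' losslessly up to floating-point representation).
#'
#' @param bundle A [runReanalysis()] result.
#' @return A plain list, or for `bundleFromList` a `report_bundle`.
#' @export
bundleToList <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  list(
    prior_table = bundle$prior_table,
    posterior_table = bundle$posterior_table,
    summaries = lapply(bundle$summaries, function(s) {
      list(table = s$table, median_hr = s$median_hr,
           cri_lower = s$cri_lower, cri_upper = s$cri_upper,
           cri_mass = s$cri_mass, converged = s$converged,
           prior_label = s$prior_label)
    }),
    diagnostics = bundle$diagnostics,
    min_p_benefit = bundle$min_p_benefit,
    all_converged = bundle$all_converged,
    mle = unclass(bundle$mle),
    settings = bundle$settings,
    seed = bundle$seed
  )
}

#' @rdname bundleToList
#' @param x A list produced by `bundleToList` (possibly after a JSON round
#'   trip).
#' @export
bundleFromList <- function(x) {
  restore_tt <- function(s) {
    structure(list(table = as.data.frame(s$table),
                   median_hr = as.numeric(s$median_hr),
                   cri_lower = as.numeric(s$cri_lower),
                   cri_upper = as.numeric(s$cri_upper),
                   cri_mass = as.numeric(s$cri_mass),
                   converged = as.logical(s$converged),
                   prior_label = as.character(s$prior_label)),
              class = "threshold_table")
  }
  structure(
    list(prior_table = as.data.frame(x$prior_table, check.names = FALSE),
         posterior_table = as.data.frame(x$posterior_table,
                                         check.names = FALSE),
         summaries = lapply(x$summaries, restore_tt),
         diagnostics = x$diagnostics,
         min_p_benefit = as.numeric(x$min_p_benefit),
         all_converged = as.logical(x$all_converged),
         mle = structure(x$mle, class = "cox_mle_fit"),
         settings = x$settings,
         seed = x$seed),
    class = "report_bundle"
  )
}

#' Write a report bundle to a directory
#'
#' Writes `prior_table.csv`, `posterior_table.csv`, one density CSV per
#' prior under `densities/`, and `meta.json` (seed, settings, diagnostics,
#' headline statistic).
#'
#' @param bundle A [runReanalysis()] result.
#' @param dir Output directory (created if needed).
#' @param priors The list of [priorSpec()] objects used for the run
#'   (needed for the analytic density curves); optional.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(bundle, dir, priors = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$prior_table, file.path(dir, "prior_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$posterior_table,
                   file.path(dir, "posterior_table.csv"), row.names = FALSE)
  if (!is.null(priors)) {
    ddir <- file.path(dir, "densities")
    dir.create(ddir, showWarnings = FALSE)
    for (p in priors) {
      utils::write.csv(densityExport(p),
                       file.path(ddir, paste0(gsub("[^a-z0-9]+", "_",
                                                   tolower(p$label)), ".csv")),
                       row.names = FALSE)
    }
  }
  meta <- list(seed = bundle$seed, settings = bundle$settings,
               diagnostics = bundle$diagnostics,
               min_p_benefit = bundle$min_p_benefit,
               all_converged = bundle$all_converged)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
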