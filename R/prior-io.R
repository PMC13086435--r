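# Serialization of prior specifications to/from structured config files.

#' Convert a prior to / from a plain list
#'
#' The list layout is `list(label = ..., components = list(list(weight,
#' mean_log_hr, sd_log_hr), ...))`, suitable for YAML or JSON round trips.
#'
#' @param prior A [priorSpec()].
#' @return For `priorToList`, a plain list; for `priorFromList`, a
#'   [priorSpec()].
#' @export
priorToList <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  list(
    label = prior$label,
    components = lapply(seq_along(prior$weights), function(i) {
      list(weight = prior$weights[i],
           mean_log_hr = prior$mean_log_hr[i],
           sd_log_hr = prior$sd_log_hr[i])
    })
  )
}

#' @rdname priorToList
#' @param x A list in the layout written by `priorToList`.
#' @export
priorFromList <- function(x) {
  stopifnot(is.list(x), !is.null(x$components))
  comp <- x$components
  priorSpec(
    vapply(comp, function(cm) as.numeric(cm$weight), numeric(1)),
    vapply(comp, function(cm) as.numeric(cm$mean_log_hr), numeric(1)),
    vapply(comp, function(cm) as.numeric(cm$sd_log_hr), numeric(1)),
    label = if (is.null(x$label)) "custom" else x$label
  )
}

#' Read or write a set of priors as a YAML or JSON config file
#'
#' The file holds a list of prior entries in the [priorToList()] layout.
#' Format is chosen from the file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param priors A named or unnamed list of [priorSpec()] objects (a single
#'   `prior_spec` is also accepted).
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `readPriorConfig` returns a named list of [priorSpec()] objects
#'   (names taken from the labels); `writePriorConfig` returns `path`
#'   invisibly.
#' @export
writePriorConfig <- function(priors, path) {
  if (inherits(priors, "prior_spec")) priors <- list(priors)
  entries <- lapply(priors, priorToList)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(list(priors = entries), path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(list(priors = entries), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported prior config extension: ", ext)
  }
  invisible(path)
}

#' @rdname writePriorConfig
#' @export
readPriorConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unsupported prior config extension: ", ext)
  }
  out <- lapply(raw$priors, priorFromList)
  stats::setNames(out, vapply(out, function(p) p$label, character(1)))
}
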