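#' Serialize a score model to JSON
#'
#' Writes the complete model — effects with thresholds/levels and
#' integer points, the logistic risk profile, risk table, label map and
#' provenance — as a JSON document at full numeric precision, so that a
#' reloaded model reproduces predictions bit for bit.
#'
#' @param model an `ics_model`.
#' @param path file path to write.
#' @return The path, invisibly.
#' @export
write_ics_model <- function(model, path) {
  stopifnot(inherits(model, "ics_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a score model from JSON
#'
#' @param path a file written by [write_ics_model()].
#' @return An `ics_model`.
#' @export
read_ics_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$effects <- lapply(m$effects, function(eff) {
    eff <- lapply(eff, function(v) if (is.list(v)) unlist(v) else v)
    eff$points <- as.integer(eff$points)
    for (f in c("thresholds", "thresholds1", "thresholds2"))
      if (!is.null(eff[[f]])) eff[[f]] <- as.numeric(eff[[f]])
    if (!is.null(eff$dims)) eff$dims <- as.integer(eff$dims)
    eff
  })
  m$logistic <- lapply(m$logistic, as.numeric)
  m$label_map <- lapply(m$label_map, function(v) {
    if (is.numeric(v)) as.numeric(v) else v
  })
  m$risk_table <- data.frame(
    score = vapply(m$risk_table, function(r) as.numeric(r$score), 0),
    risk = vapply(m$risk_table, function(r) as.numeric(r$risk), 0))
  m$provenance <- lapply(m$provenance, function(v) if (is.list(v)) unlist(v) else v)
  structure(m, class = "ics_model")
}
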