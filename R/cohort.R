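#' Declare the column schema of a patient-level cohort file
#'
#' @param id name of the patient identifier column.
#' @param treatment name of the binary treatment column (1 = treated).
#' @param event name of the binary outcome column (1 = event occurred).
#' @param covariates named character vector mapping covariate column names
#'   to their kind, either `"continuous"` or `"categorical"`.
#' @param time optional name of the follow-up time column (months).
#' @return A `cohort_schema` object.
#' @export
cohort_schema <- function(id, treatment, event, covariates, time = NULL) {
  kinds <- unname(covariates)
  if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
    sx_abort("schema", "covariates must be a named vector of kinds")
  if (!all(kinds %in% c("continuous", "categorical")))
    sx_abort("schema", "covariate kinds must be 'continuous' or 'categorical'")
  if (anyDuplicated(names(covariates)))
    sx_abort("schema", "covariate names must be unique")
  structure(list(id = id, treatment = treatment, event = event,
                 time = time, covariates = covariates),
            class = "cohort_schema")
}

new_cohort <- function(data, covariates) {
  structure(list(data = data, covariates = covariates, n = nrow(data)),
            class = "sx_cohort")
}

#' @export
print.sx_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d treated / %d untreated\n",
              x$n, sum(x$data$.treatment == 1), sum(x$data$.treatment == 0)))
  cat(sprintf("  covariates: %s\n",
              paste(sprintf("%s (%s)", names(x$covariates), x$covariates),
                    collapse = ", ")))
  if (".follow_up" %in% names(x$data)) cat("  follow-up times present\n")
  if (any(x$data$.excluded))
    cat(sprintf("  %d records excluded from training (censored before horizon)\n",
                sum(x$data$.excluded)))
  invisible(x)
}

check_binary <- function(v, col, rows = NULL) {
  vv <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(vv) | !(vv %in% c(0, 1)))
  if (length(bad))
    sx_abort("value", "column '%s' must be binary 0/1; offending row(s): %s (value '%s')",
             col, paste(head(bad, 5L), collapse = ", "), as.character(v[bad[1L]]))
  as.integer(vv)
}

#' Read and validate a patient-level cohort from a delimited file
#'
#' Reads a CSV with header, checks it against the declared schema, coerces
#' treatment/event to 0/1 integers and covariates to their declared kinds.
#' Row order is preserved and no imputation is performed.
#'
#' @param path path to a CSV file.
#' @param schema a [cohort_schema()].
#' @return An `sx_cohort` object.
#' @export
read_cohort <- function(path, schema) {
  if (!inherits(schema, "cohort_schema"))
    sx_abort("schema", "schema must be a cohort_schema object")
  if (!file.exists(path)) sx_abort("value", "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(raw, schema)
}

#' Build a cohort from an in-memory data frame
#'
#' @param df a data frame holding one row per patient.
#' @param schema a [cohort_schema()].
#' @return An `sx_cohort` object.
#' @export
as_cohort <- function(df, schema) {
  needed <- c(schema$id, schema$treatment, schema$event, schema$time,
              names(schema$covariates))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    sx_abort("schema", "missing column(s): %s", paste(missing_cols, collapse = ", "))

  ids <- as.character(df[[schema$id]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    sx_abort("integrity", "duplicate patient id(s): %s",
             paste(unique(head(dup, 5L)), collapse = ", "))

  data <- data.frame(.id = ids, stringsAsFactors = FALSE)
  data$.treatment <- check_binary(df[[schema$treatment]], schema$treatment)
  data$.event <- check_binary(df[[schema$event]], schema$event)
  if (!is.null(schema$time)) {
    fu <- suppressWarnings(as.numeric(df[[schema$time]]))
    if (any(!is.na(fu) & fu < 0))
      sx_abort("value", "follow-up times must be non-negative")
    data$.follow_up <- fu
  }
  data$.excluded <- rep(FALSE, nrow(data))
  for (cv in names(schema$covariates)) {
    data[[cv]] <- if (schema$covariates[[cv]] == "continuous")
      suppressWarnings(as.numeric(df[[cv]])) else as.character(df[[cv]])
  }
  new_cohort(data, schema$covariates)
}

#' Write a cohort back to CSV in its schema's column layout
#'
#' @param cohort an `sx_cohort`.
#' @param path output CSV path.
#' @param schema a [cohort_schema()] naming the output columns; defaults to
#'   generic names `id`, `treatment`, `event`, `follow_up`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, schema = NULL) {
  d <- cohort$data
  out <- data.frame(id = d$.id, stringsAsFactors = FALSE)
  nm <- list(id = "id", treatment = "treatment", event = "event", time = "follow_up")
  if (!is.null(schema)) nm <- schema[c("id", "treatment", "event", "time")]
  names(out) <- nm$id
  out[[nm$treatment]] <- d$.treatment
  out[[nm$event]] <- d$.event
  if (".follow_up" %in% names(d)) out[[nm$time %||% "follow_up"]] <- d$.follow_up
  for (cv in names(cohort$covariates)) out[[cv]] <- d[[cv]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Realize the binary fixed-horizon outcome from time-to-event data
#'
#' A patient whose event occurred at or before `horizon` months is labelled
#' 1; a patient followed event-free to at least `horizon` is labelled 0; a
#' patient censored (event-free) before `horizon` has no defined label at
#' the horizon, so they are flagged excluded-from-training but retained so
#' that a fitted policy can still be applied to them.
#'
#' @param cohort an `sx_cohort` whose records all carry follow-up times.
#' @param horizon outcome horizon in months (e.g. 84 for a 7-year outcome).
#' @return The cohort with `.event` replaced by the horizon label and the
#'   excluded-from-training flag set.
#' @export
derive_horizon_label <- function(cohort, horizon) {
  d <- cohort$data
  if (!".follow_up" %in% names(d) || anyNA(d$.follow_up))
    sx_abort("value", "derive_horizon_label requires follow_up for all records")
  ev <- d$.event == 1 & d$.follow_up <= horizon
  censored <- d$.event == 0 & d$.follow_up < horizon
  late_event <- d$.event == 1 & d$.follow_up > horizon   # event-free at horizon
  d$.event <- as.integer(ev)
  d$.event[late_event] <- 0L
  d$.excluded <- censored
  new_cohort(d, cohort$covariates)
}

#' Summarize a cohort and flag records unusable downstream
#'
#' Reports per-column missingness, arm sizes and per-arm event prevalence.
#' The report is failing (`ok = FALSE`) when any covariate carries missing
#' values, since matching distances and model fits reject missing data.
#'
#' @param cohort an `sx_cohort`.
#' @return A `cohort_report` list with elements `n`, `arm_sizes`,
#'   `event_rate_by_arm`, `missing_by_column`, `offending_ids`, `ok`.
#' @export
validate_cohort <- function(cohort) {
  d <- cohort$data
  if (nrow(d) == 0) sx_abort("value", "empty cohort")
  covs <- names(cohort$covariates)
  miss <- vapply(covs, function(cv) sum(is.na(d[[cv]])), integer(1))
  bad_rows <- if (length(covs)) !complete.cases(d[covs]) else rep(FALSE, nrow(d))
  arm <- c(treated = sum(d$.treatment == 1), untreated = sum(d$.treatment == 0))
  ev <- c(treated = mean(d$.event[d$.treatment == 1]),
          untreated = mean(d$.event[d$.treatment == 0]))
  structure(list(
    n = cohort$n,
    arm_sizes = arm,
    event_rate_by_arm = ev,
    missing_by_column = miss,
    offending_ids = d$.id[bad_rows],
    excluded_from_training = sum(d$.excluded),
    ok = !any(bad_rows)
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort report> n=%d, treated=%d, untreated=%d, ok=%s\n",
              x$n, x$arm_sizes[["treated"]], x$arm_sizes[["untreated"]],
              x$ok))
  if (!x$ok)
    cat("  missing covariate values for id(s):",
        paste(head(x$offending_ids, 10L), collapse = ", "), "\n")
  invisible(x)
}

# training-eligible rows: not flagged excluded by the horizon rule
training_rows <- function(cohort) !cohort$data$.excluded
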