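#' Fit the baseline outcome-risk model on untreated patients
#'
#' Trains a probabilistic classifier g over the covariates using only the
#' untreated (`treatment == 0`), training-eligible records. Applied to
#' treated patients its predictions are counterfactual baseline risks: the
#' predicted probability of the event had the patient not been treated.
#'
#' @param cohort an `sx_cohort`.
#' @param covariates character vector of covariate names to use; defaults
#'   to all covariates in the cohort.
#' @param config model settings, see details: `method` (`"forest"` default,
#'   or `"logit"`), `ntree`, `mtry`, `max_depth`, `min_node`.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @return A `baseline_model` object.
#' @export
fit_baseline_model <- function(cohort, covariates = NULL, config = list(),
                               seed = 1L) {
  covariates <- covariates %||% names(cohort$covariates)
  kinds <- cohort$covariates[covariates]
  # larger terminal nodes than the reward models: g's job is a stable risk
  # *ranking* for banding, where smoothness beats boundary sharpness
  config <- utils::modifyList(list(min_node = 25L), config)
  d <- cohort$data
  rows <- d$.treatment == 0 & training_rows(cohort)
  if (!any(rows)) sx_abort("fit", "no untreated, training-eligible patients")
  y <- d$.event[rows]
  if (length(unique(y)) < 2)
    sx_abort("fit", "untreated patients have a single outcome class")
  clf <- fit_classifier(d[rows, , drop = FALSE], kinds, y,
                        config = config, seed = seed)
  structure(list(classifier = clf, covariates = covariates, seed = seed,
                 n_train = sum(rows)),
            class = "baseline_model")
}

#' Predict baseline (counterfactual) outcome risk for every patient
#'
#' @param model a `baseline_model`.
#' @param cohort an `sx_cohort` with compatible covariates.
#' @return Numeric vector w of risks in \[0, 1\], one per patient,
#'   treatment-blind by construction.
#' @export
predict_baseline_risk <- function(model, cohort) {
  predict_classifier(model$classifier, cohort$data)
}

make_bucket_spec <- function(breaks) {
  breaks <- sort(unique(breaks))
  data.frame(bucket = seq_len(length(breaks) - 1),
             lower = breaks[-length(breaks)], upper = breaks[-1])
}

assign_buckets <- function(w, spec) {
  # intervals are (lower, upper], first interval closed at 0
  b <- findInterval(w, c(spec$lower, spec$upper[nrow(spec)]),
                    left.open = TRUE, rightmost.closed = TRUE)
  b[w <= spec$lower[1]] <- 1L
  b[w > spec$upper[nrow(spec)]] <- nrow(spec)
  as.integer(b)
}

#' Stratify a cohort into baseline-risk buckets
#'
#' Splits patients into `m` contiguous risk intervals jointly covering
#' \[0, 1\]. With `strategy = "fixed_width"` the bands have equal width over
#' the observed risk span (anchored at 0, with the top band extended to
#' 1.0): risks spanning 0-50% with `m = 5` give the 10%-wide bands
#' 0-10%, ..., 41-50%. With `strategy = "quantile"` the breaks are risk
#' quantiles, so bucket sizes differ by at most one. While any bucket holds
#' fewer than `min_per_arm` patients in either arm, adjacent buckets are
#' merged starting from the highest-risk end, where sparsity concentrates.
#'
#' @param cohort an `sx_cohort`.
#' @param w baseline risk vector, same length as the cohort (any user-
#'   supplied risk vector, e.g. from a published nomogram, can be injected
#'   here).
#' @param strategy `"fixed_width"` or `"quantile"`.
#' @param m requested number of buckets.
#' @param min_per_arm minimum patients per arm per bucket before merging;
#'   0 disables merging.
#' @param breaks optional explicit break vector overriding the strategy.
#' @return A `stratified_cohort`: the cohort plus `w`, integer `bucket`
#'   assignments, the interval `spec`, and a `merges` log.
#' @export
stratify <- function(cohort, w, strategy = c("fixed_width", "quantile"),
                     m = 6L, min_per_arm = 0L, breaks = NULL) {
  strategy <- match.arg(strategy)
  if (length(w) != cohort$n)
    sx_abort("value", "w must have one risk per patient")
  if (any(w < 0 | w > 1)) sx_abort("value", "risks must lie in [0, 1]")
  if (m < 1) sx_abort("value", "m must be >= 1")

  if (is.null(breaks)) {
    breaks <- if (strategy == "fixed_width") {
      hi <- max(w)
      if (hi <= 0) c(0, 1) else c(seq(0, hi, length.out = m + 1L)[-(m + 1L)], 1)
    } else {
      qs <- unname(stats::quantile(w, probs = seq(0, 1, length.out = m + 1L)))
      if (anyDuplicated(qs[-c(1L, m + 1L)]) || m > length(unique(w)))
        sx_abort("value", "m exceeds the number of distinct risk values")
      c(0, qs[-c(1L, m + 1L)], 1)
    }
  } else {
    breaks <- sort(unique(c(0, breaks, 1)))
  }
  spec <- make_bucket_spec(breaks)
  b <- assign_buckets(w, spec)

  merges <- character(0)
  if (min_per_arm > 0) {
    repeat {
      if (nrow(spec) == 1L) break
      n1 <- vapply(spec$bucket, function(k)
        sum(b == k & cohort$data$.treatment == 1), integer(1))
      n0 <- vapply(spec$bucket, function(k)
        sum(b == k & cohort$data$.treatment == 0), integer(1))
      viol <- which(pmin(n1, n0) < min_per_arm)
      if (!length(viol)) break
      k <- max(viol)                      # merge from the top down
      j <- if (k == 1L) 2L else k - 1L    # with the neighbour below
      lo <- min(k, j); hi <- max(k, j)
      merges <- c(merges, sprintf("merged buckets %d and %d ([%g,%g] + [%g,%g])",
                                  lo, hi, spec$lower[lo], spec$upper[lo],
                                  spec$lower[hi], spec$upper[hi]))
      spec$upper[lo] <- spec$upper[hi]
      spec <- spec[-hi, , drop = FALSE]
      spec$bucket <- seq_len(nrow(spec))
      b <- assign_buckets(w, spec)
    }
  }
  structure(list(cohort = cohort, w = w, bucket = b, spec = spec,
                 merges = merges),
            class = "stratified_cohort")
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat(sprintf("<stratified cohort> n=%d in %d risk buckets\n",
              x$cohort$n, nrow(x$spec)))
  tab <- diagnose_balance(x)
  print(tab$table, row.names = FALSE)
  if (length(x$merges)) cat(" ", paste(x$merges, collapse = "\n  "), "\n")
  invisible(x)
}

#' Diagnose treated/untreated imbalance per risk bucket
#'
#' Computes per-bucket arm counts and the empirical probability that a
#' patient in the bucket received (or did not receive) treatment. A bucket
#' is flagged when one arm outnumbers the other by more than
#' `ratio_threshold`-fold, or when either arm is empty.
#'
#' @param sc a `stratified_cohort`.
#' @param ratio_threshold flagging ratio (default 2).
#' @return A `balance_diagnostics` list with a per-bucket `table`
#'   (`bucket, lower, upper, n_treated, n_untreated, p_treated,
#'   p_untreated, flagged`).
#' @export
diagnose_balance <- function(sc, ratio_threshold = 2) {
  d <- sc$cohort$data
  tab <- sc$spec
  tab$n_treated <- vapply(tab$bucket, function(k)
    sum(sc$bucket == k & d$.treatment == 1), integer(1))
  tab$n_untreated <- vapply(tab$bucket, function(k)
    sum(sc$bucket == k & d$.treatment == 0), integer(1))
  tot <- tab$n_treated + tab$n_untreated
  tab$p_treated <- ifelse(tot > 0, tab$n_treated / tot, NA_real_)
  tab$p_untreated <- ifelse(tot > 0, tab$n_untreated / tot, NA_real_)
  mx <- pmax(tab$n_treated, tab$n_untreated)
  mn <- pmin(tab$n_treated, tab$n_untreated)
  tab$flagged <- mn == 0 | mx > ratio_threshold * mn
  structure(list(table = tab, ratio_threshold = ratio_threshold),
            class = "balance_diagnostics")
}

#' Export the stratification table behind risk-distribution plots
#'
#' @param sc a `stratified_cohort`.
#' @param path optional CSV path; when given the table is written there.
#' @return Data frame with columns `id, w, bucket, treatment, event`.
#' @export
stratification_table <- function(sc, path = NULL) {
  d <- sc$cohort$data
  out <- data.frame(id = d$.id, w = sc$w, bucket = sc$bucket,
                    treatment = d$.treatment, event = d$.event,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
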