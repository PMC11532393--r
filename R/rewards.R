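#' Train the paired counterfactual outcome models with a confounding weight
#'
#' Fits two classifiers on the matched cohort: h0 on the matched untreated
#' arm (plain empirical cross-entropy) and h1 on the matched treated arm,
#' where treated records *without* the event carry multiplicative loss
#' weight `rho >= 1` (cost-sensitive learning). Up-weighting treated
#' no-event patients pulls the treated model's predicted risk down, which
#' is the lever used to cancel a positive confounding gap. h0 never
#' depends on `rho`. With `upweight = "untreated_no_event"` the roles are
#' swapped, the remedy for confounding that spuriously favours the treated
#' arm.
#'
#' @param mc a `matched_cohort`.
#' @param rho loss weight, `>= 1`.
#' @param config classifier settings (see [fit_baseline_model()]).
#' @param seed integer seed shared by both fits.
#' @param covariates covariate names; default all.
#' @param upweight which arm's no-event subset carries the weight.
#' @return A `reward_model_pair` with elements `h0`, `h1`, `rho`.
#' @export
fit_reward_models <- function(mc, rho = 1, config = list(), seed = 1L,
                              covariates = NULL,
                              upweight = c("treated_no_event",
                                           "untreated_no_event")) {
  upweight <- match.arg(upweight)
  if (rho < 1) sx_abort("value", "rho must be >= 1")
  cohort <- mc$cohort
  covariates <- covariates %||% names(cohort$covariates)
  kinds <- cohort$covariates[covariates]
  h1 <- fit_arm_model(cohort, kinds, arm = 1L, rho = rho,
                      weighted = upweight == "treated_no_event",
                      config = config, seed = seed)
  h0 <- fit_arm_model(cohort, kinds, arm = 0L, rho = rho,
                      weighted = upweight == "untreated_no_event",
                      config = config, seed = seed)
  structure(list(h0 = h0, h1 = h1, rho = rho, seed = seed,
                 covariates = covariates, upweight = upweight),
            class = "reward_model_pair")
}

#' Predict counterfactual risk under both treatment options
#'
#' Direct reward estimation: every patient gets two predicted outcome
#' risks, one from each counterfactual model, along with their cohort
#' means.
#'
#' @param pair a `reward_model_pair`.
#' @param cohort an `sx_cohort` with compatible covariates.
#' @return A `reward_matrix`: `data` (covariates plus columns `h0`, `h1`),
#'   `mean_h0`, `mean_h1`, `rho`.
#' @export
predict_rewards <- function(pair, cohort) {
  h0 <- predict_classifier(pair$h0, cohort$data)
  h1 <- predict_classifier(pair$h1, cohort$data)
  df <- cohort$data
  df$h0 <- h0
  df$h1 <- h1
  structure(list(data = df, covariates = cohort$covariates,
                 mean_h0 = mean(h0), mean_h1 = mean(h1), rho = pair$rho),
            class = "reward_matrix")
}

#' Signed mean confounding gap between counterfactual models
#'
#' Returns `mean(h1) - mean(h0)`. A positive gap is the minimum amount of
#' residual unobserved confounding still present after matching: the
#' treated arm's own outcomes predict worse than the untreated arm's
#' despite equalized baseline risk.
#'
#' @param rm a `reward_matrix`.
#' @return Numeric gap with attribute `flagged` (`TRUE` when positive).
#' @export
confounding_gap <- function(rm) {
  gap <- rm$mean_h1 - rm$mean_h0
  attr(gap, "flagged") <- gap > 0
  gap
}

fit_arm_model <- function(cohort, kinds, arm, rho, weighted, config, seed) {
  d <- cohort$data
  rows <- d$.treatment == arm & training_rows(cohort)
  if (!any(rows)) sx_abort("fit", "matched arm %d is empty", arm)
  y <- d$.event[rows]
  if (length(unique(y)) < 2)
    sx_abort("fit", "matched arm %d has a single outcome class", arm)
  wts <- rep(1, sum(rows))
  if (weighted) wts[y == 0] <- rho     # no-event subset carries rho
  fit_classifier(d[rows, , drop = FALSE], kinds, y, weights = wts,
                 config = config, seed = seed)
}

# pure grid scan over a gap function; separated so the selection logic can
# be exercised against stub gap curves independently of model fitting
scan_weights <- function(grid, gap_fn) {
  if (!length(grid)) sx_abort("value", "weight grid is empty")
  if (any(grid < 1)) sx_abort("value", "all grid weights must be >= 1")
  if (is.unsorted(grid)) sx_abort("value", "weight grid must be ascending")
  trace <- data.frame(rho = grid, w_hat_t1 = NA_real_, w_hat_t0 = NA_real_,
                      gap = NA_real_)
  for (i in seq_along(grid)) {
    g <- gap_fn(grid[i])
    trace$w_hat_t1[i] <- g[["w1"]]
    trace$w_hat_t0[i] <- g[["w0"]]
    trace$gap[i] <- g[["w1"]] - g[["w0"]]
    if (trace$gap[i] <= 0)
      return(list(rho = grid[i], trace = trace[seq_len(i), , drop = FALSE],
                  corrected = TRUE))
  }
  cond <- structure(
    class = c("stratarx_exhaustion", "stratarx_error", "error", "condition"),
    list(message = "no grid weight closes the confounding gap",
         call = sys.call(-1), trace = trace))
  stop(cond)
}

#' Find the minimum weight that cancels the confounding gap
#'
#' Scans an ascending weight grid, refitting the treated counterfactual
#' model at each weight with the same seed (the untreated model is fit
#' once; it does not depend on the weight), and returns the smallest grid
#' weight whose gap `mean(h1) - mean(h0) <= 0`. If the first grid point
#' already satisfies this, no correction was needed -- the unconfounded
#' randomized-trial case.
#'
#' @param mc a `matched_cohort`.
#' @param grid ascending weights, all `>= 1`; default `seq(1, 3.5, 0.05)`.
#' @param config,seed,covariates passed to [fit_reward_models()].
#' @return List with `rho` (selected weight), `trace` (data frame
#'   `rho, w_hat_t1, w_hat_t0, gap`), `corrected`.
#' @export
find_minimum_weight <- function(mc, grid = seq(1, 3.5, by = 0.05),
                                config = list(), seed = 1L,
                                covariates = NULL) {
  cohort <- mc$cohort
  covariates <- covariates %||% names(cohort$covariates)
  kinds <- cohort$covariates[covariates]
  # h0 does not depend on rho: fit once, reuse across the whole grid
  h0 <- fit_arm_model(cohort, kinds, arm = 0L, rho = 1, weighted = FALSE,
                      config = config, seed = seed)
  w0 <- mean(predict_classifier(h0, cohort$data))
  scan_weights(grid, function(rho) {
    h1 <- fit_arm_model(cohort, kinds, arm = 1L, rho = rho, weighted = TRUE,
                        config = config, seed = seed)
    c(w1 = mean(predict_classifier(h1, cohort$data)), w0 = w0)
  })
}

#' Export a weight-scan trace
#'
#' @param scan result of [find_minimum_weight()].
#' @param path optional CSV path.
#' @return The trace data frame.
#' @export
weight_trace <- function(scan, path = NULL) {
  out <- scan$trace
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
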