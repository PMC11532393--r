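# Recommendation-level validation. The policy is scored on an external
# cohort of *untreated* patients, whose outcomes reflect the natural course
# of the disease: a patient who had the event would have benefited from
# treatment (the policy should have treated them -> sensitivity), a patient
# who stayed event-free should have been spared (-> specificity). Both
# metrics are prevalence-free; NPV is not, and uses the validation
# prevalence.

wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, mid - half), min(1, mid + half))
}

# Bayes identity for NPV given sens/spec and prevalence
npv_from_rates <- function(sens, spec, prev) {
  spec * (1 - prev) / ((1 - sens) * prev + spec * (1 - prev))
}

#' Validate policy recommendations on an untreated external cohort
#'
#' Cross-tabulates the tree's recommendation against observed outcomes.
#' Sensitivity is the fraction of patients who had the event for whom
#' treatment was recommended; specificity is the fraction of event-free
#' patients spared from treatment; NPV = TN / (TN + FN) is the probability
#' that a patient the policy leaves untreated stays event-free, at this
#' cohort's prevalence. 95% intervals use the Wilson score method.
#'
#' @param tree a `policy_tree`.
#' @param validation an `sx_cohort` whose patients are all untreated (a
#'   treated patient's baseline risk is modified by the treatment, so they
#'   cannot anchor this comparison).
#' @return An `evaluation_report` list: `counts` (tp, fn, tn, fp),
#'   `sensitivity`, `specificity`, `npv`, `prevalence`, `ci` (rows
#'   sensitivity/specificity/npv), `n`.
#' @export
evaluate_policy <- function(tree, validation) {
  d <- validation$data
  if (any(d$.treatment == 1))
    sx_abort("contract", "validation cohort contains treated patients")
  rec <- assign_treatment(tree, validation)
  ev <- d$.event == 1
  if (!any(ev)) sx_abort("value", "no events in validation cohort; sensitivity undefined")
  tp <- sum(ev & rec == 1); fn <- sum(ev & rec == 0)
  tn <- sum(!ev & rec == 0); fp <- sum(!ev & rec == 1)
  sens <- tp / (tp + fn)
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  ci <- rbind(sensitivity = wilson_ci(tp, tp + fn),
              specificity = wilson_ci(tn, tn + fp),
              npv = wilson_ci(tn, tn + fn))
  colnames(ci) <- c("lower", "upper")
  structure(list(counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 sensitivity = sens, specificity = spec, npv = npv,
                 prevalence = mean(ev), ci = ci, n = nrow(d)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation> n=%d, prevalence=%.2f\n  sensitivity %.3f (%.3f-%.3f)\n  specificity %.3f (%.3f-%.3f)\n  NPV         %.3f\n",
    x$n, x$prevalence, x$sensitivity, x$ci["sensitivity", 1],
    x$ci["sensitivity", 2], x$specificity, x$ci["specificity", 1],
    x$ci["specificity", 2], x$npv))
  invisible(x)
}

#' Select a weight from a tuning table
#'
#' Rules: `max_youden` (default) maximizes sensitivity + specificity;
#' `sens_floor` takes the smallest weight whose sensitivity reaches
#' `floor`, breaking ties by higher specificity. The full table is always
#' kept for human judgment -- marginal sensitivity gains can carry
#' disproportionate specificity losses that no single rule captures.
#'
#' @param table data frame with columns `rho`, `sensitivity`,
#'   `specificity`, ordered by `rho`.
#' @param rule `"max_youden"` or `"sens_floor"`.
#' @param floor sensitivity floor for `sens_floor`.
#' @return The selected rho (one element of `table$rho`).
#' @export
select_weight <- function(table, rule = c("max_youden", "sens_floor"),
                          floor = 0.85) {
  rule <- match.arg(rule)
  if (!nrow(table)) sx_abort("value", "empty tuning table")
  if (rule == "max_youden") {
    table$rho[which.max(table$sensitivity + table$specificity)]
  } else {
    ok <- which(table$sensitivity >= floor)
    if (!length(ok)) sx_abort("value", "no weight reaches sensitivity floor %g", floor)
    cand <- ok[table$specificity[ok] == max(table$specificity[ok])]
    table$rho[min(cand)]
  }
}

#' Tune the confounding weight against a validation cohort
#'
#' For each weight in the grid: fit the counterfactual reward models on
#' the matched training cohort, fit a policy tree, and measure sensitivity
#' and specificity on the untreated validation cohort. The selected weight
#' follows `rule` (see [select_weight()]), and the whole table is
#' returned.
#'
#' @param train a `matched_cohort`.
#' @param validation an untreated `sx_cohort`.
#' @param grid ascending weights `>= 1`.
#' @param rule,floor selection rule, see [select_weight()].
#' @param config classifier settings.
#' @param seed integer seed reused for every fit.
#' @param minbucket,max_depth policy-tree hyperparameters.
#' @return A `weight_tuning` list: `table` (`rho, gap, sensitivity,
#'   specificity`), `selected`, `rule`.
#' @export
tune_weight <- function(train, validation, grid = seq(1, 3.5, by = 0.25),
                        rule = c("max_youden", "sens_floor"), floor = 0.85,
                        config = list(), seed = 1L, minbucket = 15L,
                        max_depth = 4L) {
  rule <- match.arg(rule)
  if (!length(grid)) sx_abort("value", "empty weight grid")
  rows <- lapply(grid, function(rho) {
    pair <- fit_reward_models(train, rho = rho, config = config, seed = seed)
    rm_train <- predict_rewards(pair, train$cohort)
    tree <- fit_policy_tree(rm_train, minbucket = minbucket,
                            max_depth = max_depth)
    rep <- evaluate_policy(tree, validation)
    data.frame(rho = rho, gap = confounding_gap(rm_train),
               sensitivity = rep$sensitivity, specificity = rep$specificity)
  })
  table <- do.call(rbind, rows)
  structure(list(table = table,
                 selected = select_weight(table, rule, floor), rule = rule),
            class = "weight_tuning")
}

#' Robustness of recommendations across tree hyperparameters
#'
#' Fits one policy tree per (minbucket, max_depth) combination at a fixed
#' weight and reports the spread of validation sensitivity and
#' specificity. Converging metrics across differently-shaped trees
#' indicate that the recommendations, not one particular tree, carry the
#' signal.
#'
#' @param train a `matched_cohort`.
#' @param validation an untreated `sx_cohort`.
#' @param hyper_grid data frame with columns `minbucket`, `max_depth`.
#' @param rho fixed weight.
#' @param config classifier settings; `seed` the shared seed.
#' @param seed integer seed.
#' @return A `robustness_scan` list: `table` (one row per combination),
#'   `ranges` (min/max sensitivity and specificity), `trees`.
#' @export
robustness_scan <- function(train, validation,
                            hyper_grid = expand.grid(minbucket = c(10L, 15L),
                                                     max_depth = c(3L, 4L)),
                            rho = 1, config = list(), seed = 1L) {
  pair <- fit_reward_models(train, rho = rho, config = config, seed = seed)
  rm_train <- predict_rewards(pair, train$cohort)
  trees <- list(); rows <- list()
  for (i in seq_len(nrow(hyper_grid))) {
    tree <- fit_policy_tree(rm_train, minbucket = hyper_grid$minbucket[i],
                            max_depth = hyper_grid$max_depth[i])
    rep <- evaluate_policy(tree, validation)
    trees[[i]] <- tree
    rows[[i]] <- data.frame(minbucket = hyper_grid$minbucket[i],
                            max_depth = hyper_grid$max_depth[i],
                            sensitivity = rep$sensitivity,
                            specificity = rep$specificity)
  }
  table <- do.call(rbind, rows)
  structure(list(
    table = table,
    ranges = list(sensitivity = range(table$sensitivity),
                  specificity = range(table$specificity)),
    trees = trees), class = "robustness_scan")
}
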