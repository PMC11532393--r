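#' Read a pipeline run configuration from YAML or JSON
#'
#' Required fields: `mode` ("observational" or "rct"), `train` (CSV path),
#' `schema` (named lists: `id`, `treatment`, `event`, optional `time`,
#' `covariates` mapping name -> kind), `seed`, `out`. Optional:
#' `validation` (CSV path), `horizon`, `buckets` (`strategy`, `m`,
#' `min_per_arm`, `ratio_threshold`, `breaks`), `distance_covariates`,
#' `weight` (`from`, `to`, `by` or `values`; `rule`; `floor`), `tree`
#' (`minbucket`, `max_depth`), `model` (`method`, `ntree`, ...).
#' A weight grid is rejected in rct mode: an unconfounded randomized
#' cohort needs no correction weight.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) sx_abort("value", "config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (f in c("mode", "train", "schema", "seed", "out"))
    if (is.null(cfg[[f]])) sx_abort("config", "config field '%s' is required", f)
  if (!cfg$mode %in% c("observational", "rct"))
    sx_abort("config", "mode must be 'observational' or 'rct'")
  if (cfg$mode == "rct" && !is.null(cfg$weight))
    sx_abort("config", "rct mode takes no weight grid (no confounding correction)")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

config_schema <- function(cfg) {
  s <- cfg$schema
  cohort_schema(id = s$id, treatment = s$treatment, event = s$event,
                time = s$time,
                covariates = unlist(s$covariates))
}

weight_grid_from <- function(w) {
  if (is.null(w)) return(seq(1, 3.5, by = 0.05))
  if (!is.null(w$values)) return(as.numeric(w$values))
  seq(w$from %||% 1, w$to %||% 3.5, by = w$by %||% 0.05)
}

#' Run the full pipeline from a configuration
#'
#' Executes the stages in order: read and label cohorts; fit the baseline
#' risk model on untreated patients and stratify everyone by predicted
#' risk; in observational mode, match arms 1:1 within each stratum and
#' scan the weight grid for the smallest weight cancelling the
#' confounding gap (tuning it against the validation cohort when one is
#' supplied); in rct mode, skip matching and weight correction, instead
#' oversampling flagged sparse strata; fit the policy tree on the
#' counterfactual rewards; validate recommendations on the untreated
#' validation cohort. All artifacts are written under `config$out` and a
#' run log records every data-dependent decision. Re-running the same
#' config reproduces every artifact exactly.
#'
#' @param config a `run_config` (see [read_run_config()]) or a path to
#'   one.
#' @return Invisibly, a list with the in-memory stage results and
#'   `artifacts` (named file paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("# pipeline run log", sprintf("mode: %s", config$mode),
                 sprintf("seed: %d", config$seed))
  artifacts <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- "read_cohorts"
  on.exit(writeLines(log_lines, file.path(out_dir, "run_log.txt")), add = TRUE)

  result <- tryCatch({
    schema <- config_schema(config)
    train <- read_cohort(config$train, schema)
    validation <- if (!is.null(config$validation))
      read_cohort(config$validation, schema) else NULL
    if (!is.null(config$horizon)) {
      stage <- "derive_horizon_label"
      train <- derive_horizon_label(train, config$horizon)
      if (!is.null(validation))
        validation <- derive_horizon_label(validation, config$horizon)
      note("horizon: %g months; %d training-excluded (censored early)",
           config$horizon, sum(train$data$.excluded))
    }

    stage <- "baseline_risk"
    model <- fit_baseline_model(train, config = config$model %||% list(),
                                seed = config$seed)
    w <- predict_baseline_risk(model, train)
    bk <- config$buckets %||% list()
    sc <- stratify(train, w,
                   strategy = bk$strategy %||% "fixed_width",
                   m = bk$m %||% if (config$mode == "rct") 5L
                       else if (train$n < 300) 3L else 6L,
                   min_per_arm = bk$min_per_arm %||% 5L,
                   breaks = bk$breaks)
    diag <- diagnose_balance(sc, bk$ratio_threshold %||% 2)
    for (mrg in sc$merges) note("stratify: %s", mrg)
    note("buckets: %d; flagged imbalanced: %s", nrow(sc$spec),
         paste(diag$table$bucket[diag$table$flagged], collapse = ", ") %||% "")
    stratification_table(sc, file.path(out_dir, "stratification.csv"))
    artifacts["stratification"] <- file.path(out_dir, "stratification.csv")

    tree_cfg <- config$tree %||% list()
    max_depth <- tree_cfg$max_depth %||% 4L
    model_cfg <- config$model %||% list()
    # leaves no smaller than 3% of the reward-training cohort (floor 15):
    # guards against spurious micro-subgroups when cohorts are large
    pick_minbucket <- function(n)
      as.integer(tree_cfg$minbucket %||% max(15L, ceiling(0.03 * n)))

    if (config$mode == "observational") {
      stage <- "matching"
      mc <- match_cohort(sc, config$distance_covariates)
      minbucket <- pick_minbucket(mc$cohort$n)
      if (length(mc$dropped_buckets))
        note("matching: dropped bucket(s) %s (empty arm)",
             paste(mc$dropped_buckets, collapse = ", "))
      note("matching: %d pairs retained (n_s = %d)", nrow(mc$pairs),
           2L * nrow(mc$pairs))
      pairs_table(mc, file.path(out_dir, "pairs.csv"))
      artifacts["pairs"] <- file.path(out_dir, "pairs.csv")

      stage <- "weight_scan"
      grid <- weight_grid_from(config$weight)
      scan <- find_minimum_weight(mc, grid = grid, config = model_cfg,
                                  seed = config$seed)
      weight_trace(scan, file.path(out_dir, "weight_trace.csv"))
      artifacts["weight_trace"] <- file.path(out_dir, "weight_trace.csv")
      note("weight scan: minimum correcting rho = %g%s", scan$rho,
           if (scan$rho == grid[1]) " (no correction needed)" else "")

      stage <- "weight_tuning"
      rho <- scan$rho
      tuning <- NULL
      if (!is.null(validation)) {
        vs <- untreated_subset(validation)
        if (vs$n < validation$n)
          note("tuning: dropped %d treated validation patients",
               validation$n - vs$n)
        tune_grid <- grid[grid >= scan$rho]
        if (length(tune_grid) > 6)
          tune_grid <- unique(tune_grid[round(seq(1, length(tune_grid),
                                                  length.out = 6))])
        tuning <- tune_weight(mc, vs, grid = tune_grid,
                              rule = (config$weight %||% list())$rule %||% "max_youden",
                              floor = (config$weight %||% list())$floor %||% 0.85,
                              config = model_cfg, seed = config$seed,
                              minbucket = minbucket, max_depth = max_depth)
        rho <- tuning$selected
        utils::write.csv(tuning$table, file.path(out_dir, "tuning.csv"),
                         row.names = FALSE, quote = FALSE)
        note("tuning: selected rho = %g by %s", rho, tuning$rule)
      } else {
        utils::write.csv(scan$trace[scan$trace$rho == scan$rho, , drop = FALSE],
                         file.path(out_dir, "tuning.csv"), row.names = FALSE,
                         quote = FALSE)
        note("tuning: no validation cohort; using minimum correcting rho")
      }
      artifacts["tuning"] <- file.path(out_dir, "tuning.csv")
      reward_base <- mc
    } else {
      stage <- "oversampling"
      if (any(diag$table$flagged)) {
        sc <- oversample_strata(sc, ratio_threshold = bk$ratio_threshold %||% 2,
                                seed = config$seed)
        note("rct remedy: oversampled flagged strata to per-arm target; n = %d",
             sc$cohort$n)
      } else {
        note("rct: no imbalance; no remedy applied")
      }
      rho <- 1
      reward_base <- sc
      minbucket <- pick_minbucket(sc$cohort$n)
    }

    stage <- "rewards"
    pair <- fit_reward_models(reward_base, rho = rho, config = model_cfg,
                              seed = config$seed)
    rm_train <- predict_rewards(pair, reward_base$cohort)
    note("rewards: rho = %g, mean h1 = %.4f, mean h0 = %.4f, gap = %+.4f",
         rho, rm_train$mean_h1, rm_train$mean_h0, confounding_gap(rm_train))

    stage <- "policy_tree"
    tree <- fit_policy_tree(rm_train, minbucket = minbucket,
                            max_depth = max_depth)
    writeLines(serialize_tree(tree), file.path(out_dir, "tree.json"))
    writeLines(render_tree(tree), file.path(out_dir, "tree.txt"))
    artifacts["tree_json"] <- file.path(out_dir, "tree.json")
    artifacts["tree_ascii"] <- file.path(out_dir, "tree.txt")
    assignments <- data.frame(id = train$data$.id,
                              recommended_treatment = assign_treatment(tree, train),
                              stringsAsFactors = FALSE)
    utils::write.csv(assignments, file.path(out_dir, "assignments.csv"),
                     row.names = FALSE, quote = FALSE)
    note("tree: minbucket = %d, max_depth = %d, recommends treatment for %.1f%% of training cohort",
         minbucket, max_depth, 100 * mean(assignments$recommended_treatment))

    stage <- "validation"
    report <- NULL
    if (!is.null(validation)) {
      vs <- untreated_subset(validation)
      report <- evaluate_policy(tree, vs)
      metrics <- list(counts = as.list(report$counts),
                      sensitivity = report$sensitivity,
                      specificity = report$specificity,
                      npv = report$npv, prevalence = report$prevalence,
                      ci = list(sensitivity = as.numeric(report$ci["sensitivity", ]),
                                specificity = as.numeric(report$ci["specificity", ])),
                      rho = rho, n = report$n)
      jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      note("validation: sensitivity %.3f, specificity %.3f, NPV %.3f",
           report$sensitivity, report$specificity, report$npv)
    } else {
      jsonlite::write_json(list(note = "no validation cohort supplied"),
                           file.path(out_dir, "metrics.json"), auto_unbox = TRUE)
    }
    artifacts["metrics"] <- file.path(out_dir, "metrics.json")
    artifacts["run_log"] <- file.path(out_dir, "run_log.txt")

    list(stratified = sc, tree = tree, rho = rho, report = report,
         artifacts = artifacts)
  }, stratarx_error = function(e) {
    note("ERROR in stage %s: %s", stage, conditionMessage(e))
    sx_abort("pipeline", "stage '%s' failed: %s (partial artifacts in %s)",
             stage, conditionMessage(e), out_dir)
  })
  invisible(result)
}

untreated_subset <- function(cohort) {
  keep <- cohort$data$.treatment == 0
  new_cohort(cohort$data[keep, , drop = FALSE], cohort$covariates)
}
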