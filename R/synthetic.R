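# Synthetic cohorts with known confounding structure. A single latent
# standard-normal confounder U enters both the outcome logit (gamma_y) and
# the treatment logit (gamma_t); observed risk drivers also push treatment
# (risk-driven prescribing). A covariate-defined subgroup receives a true
# treatment benefit: within the subgroup, treatment multiplies the outcome
# odds by exp(-delta). Ground truth (true risks, U, the oracle policy) is
# emitted separately so pipeline code physically cannot peek at U.

#' Configure a synthetic cohort
#'
#' @param family covariate/risk family: `"gist"` (tumor size, mitotic
#'   count, site; treatment benefits patients with mitotic count >= 10 or
#'   non-gastric tumors >= 5), `"genetic"` (adds a resistance mutation
#'   that nullifies benefit), `"sarcoma"` (age, grade, site, size;
#'   benefit for age >= 60, lower-extremity or high-grade tumors).
#' @param n cohort size (candidates drawn; participation bias in RCT mode
#'   can retain fewer).
#' @param mode `"observational"` (risk- and U-driven assignment) or
#'   `"rct"` (fair coin assignment with optional participation bias).
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   byte-for-byte.
#' @param delta treatment effect: log-odds reduction of the outcome inside
#'   the benefiting subgroup (0 = useless treatment).
#' @param gamma_y,gamma_t coefficients of the unobserved confounder U on
#'   the outcome and treatment logits (both 0 = no unobserved
#'   confounding).
#' @param risk_intercept outcome logit intercept (controls event
#'   prevalence).
#' @param assign_intercept,assign_slope treatment logit: intercept and
#'   slope on the observed risk score (observational mode).
#' @param participation_quantile,participation_strength RCT mode: patients
#'   whose observed risk exceeds this quantile, randomized to the biased
#'   arm, drop out with this probability (high-risk patients discouraged
#'   from forgoing treatment).
#' @param participation_arm arm the dropout affects (default untreated).
#' @param horizon outcome horizon in months for follow-up times.
#' @param censor_frac fraction of event-free patients administratively
#'   censored before the horizon (excluded from training downstream).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(family = c("gist", "genetic", "sarcoma"),
                             n = 2000L,
                             mode = c("observational", "rct"),
                             seed = 1L,
                             delta = 1.9,
                             gamma_y = 1.0,
                             gamma_t = 2.0,
                             risk_intercept = NULL,
                             assign_intercept = 0.2,
                             assign_slope = 1.2,
                             participation_quantile = 0.8,
                             participation_strength = 0.85,
                             participation_arm = 0L,
                             horizon = 84,
                             censor_frac = 0) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  risk_intercept <- risk_intercept %||%
    switch(family, gist = -2.0, genetic = -2.0, sarcoma = -1.3)
  if (delta < 0) sx_abort("config", "delta must be >= 0")
  if (participation_strength < 0 || participation_strength > 1)
    sx_abort("config", "participation_strength must lie in [0, 1]")
  structure(as.list(environment()), class = "synthetic_config")
}

#' GIST-like observational preset (confounded, subgroup benefit)
#' @param n cohort size
#' @param seed integer seed
#' @param ... overrides passed to [synthetic_config()]
#' @return A `synthetic_config`.
#' @export
preset_gist_observational <- function(n = 2000L, seed = 1L, ...)
  synthetic_config(family = "gist", n = n, mode = "observational",
                   seed = seed, ...)

#' Small genetic-like observational preset (mutation nullifies benefit)
#' @inheritParams preset_gist_observational
#' @return A `synthetic_config`.
#' @export
preset_genetic_observational <- function(n = 300L, seed = 1L, ...)
  synthetic_config(family = "genetic", n = n, mode = "observational",
                   seed = seed, ...)

#' Sarcoma-like randomized preset (participation bias in high-risk strata)
#' @inheritParams preset_gist_observational
#' @return A `synthetic_config`.
#' @export
preset_sarcoma_rct <- function(n = 2000L, seed = 1L, delta = 1.3, ...)
  synthetic_config(family = "sarcoma", n = n, mode = "rct", seed = seed,
                   gamma_t = 0, delta = delta, ...)

# covariate draw + observed risk score + benefit predicate, per family
draw_covariates <- function(family, n) {
  switch(family,
    gist = data.frame(
      size = rlnorm(n, meanlog = log(4.5), sdlog = 0.7),
      mitoses = rnbinom(n, size = 0.9, mu = 5.5),
      site = ifelse(runif(n) < 0.27, "nongastric", "gastric"),
      stringsAsFactors = FALSE),
    genetic = data.frame(
      size = rlnorm(n, meanlog = log(5), sdlog = 0.6),
      mitoses = rnbinom(n, size = 0.9, mu = 5.5),
      site = ifelse(runif(n) < 0.30, "nongastric", "gastric"),
      mutation = ifelse(runif(n) < 0.12, "d842", "wild"),
      stringsAsFactors = FALSE),
    sarcoma = data.frame(
      age = round(pmin(pmax(rnorm(n, 53, 15), 18), 90)),
      size = rlnorm(n, meanlog = log(7), sdlog = 0.5),
      grade = ifelse(runif(n) < 0.70, "high", "low"),
      site = sample(c("lower", "upper", "trunk"), n, replace = TRUE,
                    prob = c(0.63, 0.21, 0.16)),
      stringsAsFactors = FALSE))
}

covariate_kinds <- function(family) {
  switch(family,
    gist = c(size = "continuous", mitoses = "continuous",
             site = "categorical"),
    genetic = c(size = "continuous", mitoses = "continuous",
                site = "categorical", mutation = "categorical"),
    sarcoma = c(age = "continuous", size = "continuous",
                grade = "categorical", site = "categorical"))
}

risk_score <- function(family, X) {
  switch(family,
    gist = 1.0 * (log(X$size) - log(4.5)) +
           1.1 * (log1p(X$mitoses) - log1p(3)) +
           0.7 * (X$site == "nongastric"),
    genetic = 1.0 * (log(X$size) - log(5)) +
              1.1 * (log1p(X$mitoses) - log1p(3)) +
              0.7 * (X$site == "nongastric"),
    sarcoma = 0.035 * (X$age - 53) + 0.6 * log(X$size / 7) +
              0.9 * (X$grade == "high") + 0.4 * (X$site == "lower"))
}

benefit_predicate <- function(family, X) {
  switch(family,
    gist = X$mitoses >= 10 | (X$size >= 5 & X$site == "nongastric"),
    genetic = (X$mitoses >= 10 | (X$size >= 5 & X$site == "nongastric")) &
              X$mutation == "wild",
    sarcoma = X$age >= 60 | X$site == "lower" | X$grade == "high")
}

finish_cohort <- function(cfg, X, t, eta, U) {
  n <- nrow(X)
  sub <- benefit_predicate(cfg$family, X)
  lp0 <- cfg$risk_intercept + eta + cfg$gamma_y * U
  p0 <- plogis(lp0)
  p1 <- plogis(lp0 - cfg$delta * sub)
  y <- rbinom(n, 1, ifelse(t == 1, p1, p0))
  fu <- ifelse(y == 1, runif(n, 0, cfg$horizon),
               cfg$horizon + runif(n, 1, 60))
  if (cfg$censor_frac > 0) {
    cens <- y == 0 & runif(n) < cfg$censor_frac
    fu[cens] <- runif(sum(cens), 0, cfg$horizon)
  }
  d <- data.frame(.id = sprintf("P%05d", seq_len(n)),
                  .treatment = as.integer(t), .event = as.integer(y),
                  .follow_up = round(fu, 1), .excluded = FALSE,
                  stringsAsFactors = FALSE)
  for (cv in names(X)) d[[cv]] <-
    if (is.numeric(X[[cv]])) round(X[[cv]], 3) else X[[cv]]
  cohort <- new_cohort(d, covariate_kinds(cfg$family))
  truth <- data.frame(id = d$.id, p0 = p0, p1 = p1, U = U,
                      in_subgroup = sub,
                      oracle = as.integer(sub & cfg$delta > 0),
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = structure(truth, class = c("ground_truth",
                                                           "data.frame")))
}

#' Simulate a confounded observational cohort
#'
#' Treatment assignment follows observed risk drivers *and* the latent
#' confounder U, so treated patients carry both higher observed and higher
#' unobserved risk -- with a beneficial planted effect this produces the
#' classic inversion signature (raw event rate higher in the treated arm).
#'
#' @param config a `synthetic_config` with `mode = "observational"`.
#' @return List with `cohort` (an `sx_cohort`; U is not included) and
#'   `truth` (a `ground_truth` data frame with true risks, U and the
#'   oracle policy).
#' @export
simulate_observational_cohort <- function(config) {
  if (config$mode != "observational")
    sx_abort("config", "config mode must be 'observational'")
  set.seed(config$seed)
  X <- draw_covariates(config$family, config$n)
  eta <- risk_score(config$family, X)
  U <- rnorm(config$n)
  lp_t <- config$assign_intercept +
    config$assign_slope * (config$risk_intercept + eta) +
    config$gamma_t * U
  t <- rbinom(config$n, 1, plogis(lp_t))
  finish_cohort(config, X, t, eta, U)
}

#' Simulate a randomized cohort with optional participation bias
#'
#' Treatment is a fair coin, but candidates whose observed risk score
#' exceeds the `participation_quantile`, randomized to the
#' `participation_arm`, leave the cohort with probability
#' `participation_strength` -- recreating trials where clinicians steered
#' high-risk patients away from the untreated arm, leaving sparse
#' high-risk strata.
#'
#' @param config a `synthetic_config` with `mode = "rct"`.
#' @return As [simulate_observational_cohort()]; the retained cohort can
#'   be smaller than `config$n`.
#' @export
simulate_rct_cohort <- function(config) {
  if (config$mode != "rct") sx_abort("config", "config mode must be 'rct'")
  set.seed(config$seed)
  X <- draw_covariates(config$family, config$n)
  eta <- risk_score(config$family, X)
  U <- rnorm(config$n)
  t <- rbinom(config$n, 1, 0.5)
  keep <- rep(TRUE, config$n)
  if (config$participation_strength > 0) {
    thr <- stats::quantile(eta, config$participation_quantile)
    at_risk <- eta > thr & t == config$participation_arm
    keep[at_risk] <- runif(sum(at_risk)) >= config$participation_strength
  }
  out <- finish_cohort(config, X[keep, , drop = FALSE], t[keep],
                       eta[keep], U[keep])
  out$cohort$data$.id <- sprintf("P%05d", seq_len(sum(keep)))
  out$truth$id <- out$cohort$data$.id
  out
}

#' Simulate an untreated external validation cohort
#'
#' All patients untreated, outcomes drawn from the true baseline risk:
#' the natural-course cohort against which policy recommendations are
#' scored.
#'
#' @param config a `synthetic_config`; its `seed` should differ from the
#'   training draw's.
#' @return As [simulate_observational_cohort()].
#' @export
simulate_validation_cohort <- function(config) {
  set.seed(config$seed)
  X <- draw_covariates(config$family, config$n)
  eta <- risk_score(config$family, X)
  U <- rnorm(config$n)
  finish_cohort(config, X, rep(0L, config$n), eta, U)
}

#' Deterministic published-nomogram analogue for synthetic cohorts
#'
#' Computes baseline risk from the observed covariates alone (no latent
#' confounder), the way an established prognostic nomogram would. Useful
#' as the injected risk vector for [stratify()] in randomized-cohort
#' analyses, where the standard workflow stratifies by a published
#' model rather than refitting one.
#'
#' @param cohort an `sx_cohort` generated by this module.
#' @param config the `synthetic_config` that generated it.
#' @return Numeric risk vector in (0, 1).
#' @export
nomogram_risk <- function(cohort, config) {
  plogis(config$risk_intercept + risk_score(config$family, cohort$data))
}

#' The oracle treatment policy of a synthetic cohort
#'
#' Treat exactly the patients whose true risk under treatment is below
#' their true baseline risk -- equivalently the benefiting subgroup when
#' `delta > 0`. The benchmark a recovered policy is scored against.
#'
#' @param gt a `ground_truth` data frame.
#' @return Integer 0/1 vector.
#' @export
oracle_policy <- function(gt) as.integer(gt$p1 < gt$p0)

#' Write a simulated cohort, its ground truth and a config echo to disk
#'
#' @param sim result of a simulate_* function.
#' @param config the `synthetic_config` used.
#' @param dir output directory (created if needed).
#' @return Named vector of the three file paths, invisibly.
#' @export
write_synthetic <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.yaml"))
  write_cohort(sim$cohort, paths[["cohort"]])
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  writeLines(yaml::as.yaml(unclass(config)), paths[["config"]])
  invisible(paths)
}

#' Default file schema of synthetic cohorts
#' @param family the config family (sets the covariate list).
#' @return A [cohort_schema()] matching [write_cohort()] output.
#' @export
synthetic_schema <- function(family = "gist") {
  cohort_schema(id = "id", treatment = "treatment", event = "event",
                time = "follow_up", covariates = covariate_kinds(family))
}
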