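# Small in-code fixtures shared across test files.

gist_schema <- function() {
  cohort_schema(id = "id", treatment = "imatinib", event = "recurrence",
                covariates = c(size = "continuous", mitoses = "continuous",
                               site = "categorical"))
}

# build an sx_cohort directly from vectors (bypasses file round-trip)
make_cohort <- function(treatment, event, ..., follow_up = NULL,
                        kinds = NULL) {
  covs <- list(...)
  n <- length(treatment)
  df <- data.frame(id = sprintf("p%03d", seq_len(n)),
                   treatment = treatment, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(follow_up)) df$follow_up <- follow_up
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  if (is.null(kinds))
    kinds <- vapply(covs, function(v)
      if (is.numeric(v)) "continuous" else "categorical", character(1))
  as_cohort(df, cohort_schema(
    id = "id", treatment = "treatment", event = "event",
    time = if (is.null(follow_up)) NULL else "follow_up",
    covariates = kinds))
}

# a reward_matrix built directly from vectors, for policy-tree tests
make_rm <- function(h0, h1, ..., kinds = NULL, rho = 1) {
  covs <- list(...)
  if (is.null(kinds))
    kinds <- vapply(covs, function(v)
      if (is.numeric(v)) "continuous" else "categorical", character(1))
  df <- data.frame(covs, stringsAsFactors = FALSE)
  df$h0 <- h0
  df$h1 <- h1
  structure(list(data = df, covariates = kinds,
                 mean_h0 = mean(h0), mean_h1 = mean(h1), rho = rho),
            class = "reward_matrix")
}

# a hand-built policy tree: split on binary covariate `f` (< 0.5), left
# leaf -> t_left, right leaf -> t_right
make_binary_tree <- function(var = "f", t_left = 0L, t_right = 1L) {
  structure(list(
    root = list(type = "split", var = var, threshold = 0.5, set = NULL,
                n = 0L, mean_h0 = NA_real_, mean_h1 = NA_real_,
                left = list(type = "leaf", treatment = t_left, n = 0L,
                            mean_h0 = NA_real_, mean_h1 = NA_real_),
                right = list(type = "leaf", treatment = t_right, n = 0L,
                             mean_h0 = NA_real_, mean_h1 = NA_real_)),
    covariates = c(f = "continuous"), minbucket = 1L, max_depth = 1L,
    rho = 1), class = "policy_tree")
}

make_constant_tree <- function(treatment = 1L) {
  structure(list(
    root = list(type = "leaf", treatment = treatment, n = 0L,
                mean_h0 = NA_real_, mean_h1 = NA_real_),
    covariates = character(0), minbucket = 1L, max_depth = 0L, rho = 1),
    class = "policy_tree")
}
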