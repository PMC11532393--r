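# Internal probabilistic classifiers behind the baseline and counterfactual
# models. Two families:
#   "forest" - bagged weighted CART probability trees (compiled; default),
#              the analogue of the random-forest classifier used for risk
#              modelling in this setting.
#   "logit"  - weighted logistic regression via stats::glm. Its objective is
#              the exact weighted cross-entropy of Eqs.-style losses, which
#              makes integer-weight fits provably identical to fits on
#              duplicated records; used where an exact-loss learner matters.
# Both are deterministic given a seed.

# One-hot design with a recorded, order-stable encoding. Categorical levels
# are frozen at fit time; unseen levels at predict time are an error.
make_encoder <- function(data, covariates) {
  levels_map <- list()
  for (cv in names(covariates)) {
    if (covariates[[cv]] == "categorical")
      levels_map[[cv]] <- sort(unique(as.character(data[[cv]])))
  }
  structure(list(covariates = covariates, levels = levels_map),
            class = "sx_encoder")
}

encode_design <- function(encoder, data) {
  cols <- list()
  for (cv in names(encoder$covariates)) {
    if (!cv %in% names(data))
      sx_abort("value", "covariate '%s' missing from data", cv)
    if (encoder$covariates[[cv]] == "continuous") {
      v <- as.numeric(data[[cv]])
      if (anyNA(v)) sx_abort("value", "missing values in covariate '%s'", cv)
      cols[[cv]] <- v
    } else {
      v <- as.character(data[[cv]])
      lev <- encoder$levels[[cv]]
      unseen <- setdiff(unique(v), lev)
      if (length(unseen))
        sx_abort("value", "unseen level(s) in covariate '%s': %s",
                 cv, paste(unseen, collapse = ", "))
      if (length(lev) < 2) {
        cols[[paste0(cv, "=", lev[1])]] <- rep(1, length(v))
      } else {
        for (l in lev[-1]) cols[[paste0(cv, "=", l)]] <- as.numeric(v == l)
      }
    }
  }
  do.call(cbind, cols)
}

default_model_config <- function(config = list()) {
  utils::modifyList(list(
    method = "forest",  # or "logit"
    ntree = 400L,
    mtry = NULL,        # default: all design columns (pure bagging) --
                        # clinical problems here are low-dimensional and
                        # feature subsampling starves interaction detection
    max_depth = 10L,
    min_node = 5L
  ), config)
}

fit_classifier <- function(data, covariates, y, weights = NULL,
                           config = list(), seed = 1L) {
  cfg <- default_model_config(config)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    sx_abort("fit", "single outcome class in training data; cannot fit classifier")
  if (is.null(weights)) weights <- rep(1, length(y))
  enc <- make_encoder(data, covariates)
  X <- encode_design(enc, data)
  fit <- switch(cfg$method,
    forest = {
      mtry <- cfg$mtry %||% ncol(X)
      set.seed(seed)
      cpp_forest_fit(X, y, as.numeric(weights), as.integer(cfg$ntree),
                     as.integer(mtry), as.integer(cfg$max_depth),
                     as.integer(cfg$min_node))
    },
    logit = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                                  weights = weights))
    },
    sx_abort("value", "unknown classifier method '%s'", cfg$method)
  )
  structure(list(method = cfg$method, fit = fit, encoder = enc,
                 covariates = names(covariates), config = cfg, seed = seed),
            class = "sx_classifier")
}

predict_classifier <- function(object, data) {
  X <- encode_design(object$encoder, data)
  p <- switch(object$method,
    forest = cpp_forest_predict(object$fit, X),
    logit = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      as.numeric(stats::predict(object$fit, newdata = df, type = "response"))
    })
  pmin(pmax(p, 0), 1)
}
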