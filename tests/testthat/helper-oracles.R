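# Independent oracles: brute-force / closed-form references that never call
# the code paths they check.

# exhaustive minimum-cost injective matching of rows into columns
brute_force_match_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i], k - 1), function(p) c(v[i], p))))
  }
  best <- Inf
  for (p in perms(seq_len(m), n))
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

# exhaustive best single-split (or constant) policy objective over the same
# candidate thresholds the fitter uses, computed by direct enumeration
brute_force_depth1_objective <- function(df, h0, h1, kinds, minbucket) {
  best <- min(sum(h0), sum(h1))
  for (cv in names(kinds)) {
    x <- df[[cv]]
    cands <- if (kinds[[cv]] == "continuous") {
      u <- sort(unique(x)); if (length(u) < 2) next
      lapply((u[-1] + u[-length(u)]) / 2, function(t) x < t)
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2) next
      subs <- list()
      rest <- lev[-1]
      for (mask in 0:(2^(length(lev) - 1) - 2))
        subs[[length(subs) + 1L]] <-
          as.character(x) %in% c(lev[1], rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0])
      subs
    }
    for (inl in cands) {
      if (sum(inl) < minbucket || sum(!inl) < minbucket) next
      obj <- min(sum(h0[inl]), sum(h1[inl])) +
             min(sum(h0[!inl]), sum(h1[!inl]))
      best <- min(best, obj)
    }
  }
  best
}

# marginal event rate of the untreated potential outcome by brute-force
# Monte Carlo integration over the generator's covariate and confounder
# distributions (re-implements the generating formulas independently)
mc_untreated_event_rate_gist <- function(n = 1e6, seed = 99,
                                         risk_intercept = -2.0,
                                         gamma_y = NULL) {
  cfg <- stratarx::preset_gist_observational()
  if (is.null(gamma_y)) gamma_y <- cfg$gamma_y
  set.seed(seed)
  size <- rlnorm(n, log(4.5), 0.7)
  mitoses <- rnbinom(n, size = 0.9, mu = 5.5)
  nongastric <- runif(n) < 0.27
  eta <- 1.0 * (log(size) - log(4.5)) + 1.1 * (log1p(mitoses) - log1p(3)) +
    0.7 * nongastric
  mean(plogis(risk_intercept + eta + gamma_y * rnorm(n)))
}
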