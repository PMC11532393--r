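#' Standardize continuous covariates for distance computation
#'
#' Centers each named covariate to mean 0 and scales to population standard
#' deviation 1 (the n-denominator form), recording the statistics so the
#' same transform can be replayed.
#'
#' @param cohort an `sx_cohort` (or any data frame with the named columns).
#' @param names continuous covariate names to normalize.
#' @return List with `coords` (matrix), `center`, `scale`.
#' @export
normalize_covariates <- function(cohort, names) {
  d <- if (inherits(cohort, "sx_cohort")) cohort$data else cohort
  X <- sapply(names, function(cv) {
    v <- as.numeric(d[[cv]])
    if (anyNA(v)) sx_abort("value", "missing values in covariate '%s'", cv)
    v
  })
  X <- matrix(X, ncol = length(names), dimnames = list(NULL, names))
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  zero <- names[scale == 0]
  if (length(zero))
    sx_abort("value", "zero-variance covariate(s): %s", paste(zero, collapse = ", "))
  coords <- sweep(sweep(X, 2, center), 2, scale, "/")
  list(coords = coords, center = center, scale = scale)
}

# deterministic tie-break: among equal-cost optima prefer pairs with low
# (row, col) indices via an epsilon secondary objective; the reported cost
# is recomputed from the unperturbed distances.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  eps <- 1e-9 * (max(cost) + 1) / (n * m + 1)
  tie <- outer(seq_len(n), seq_len(m), function(i, j) (i - 1) * m + j) * eps
  cpp_assign(cost + tie)
}

#' Optimal 1:1 matching of treated to untreated patients within one bucket
#'
#' Solves the within-stratum matching program exactly: each minority-arm
#' patient is matched to exactly one majority-arm patient, each
#' majority-arm patient is used at most once, and the total squared
#' Euclidean distance between matched pairs is minimized. When treated
#' outnumber untreated the arm roles are swapped.
#'
#' @param problem a list with elements `bucket` (id), `treated_ids`,
#'   `untreated_ids`, `treated_coords`, `untreated_coords` (matrices of
#'   normalized continuous covariates, rows aligned with the ids).
#' @return A `match_result`: `pairs` data frame (`treated_id, untreated_id,
#'   dist2`), `total_cost`, `n_s` (retained patients = 2 x pairs).
#' @export
match_within_bucket <- function(problem) {
  t_ids <- problem$treated_ids; u_ids <- problem$untreated_ids
  if (!length(t_ids) || !length(u_ids))
    sx_abort("matching", "bucket %s has an empty arm", problem$bucket %||% "?")
  Xt <- problem$treated_coords; Xu <- problem$untreated_coords
  # squared Euclidean cost matrix, treated x untreated
  cross <- Xt %*% t(Xu)
  cost <- outer(rowSums(Xt^2), rowSums(Xu^2), "+") - 2 * cross
  cost[cost < 0] <- 0
  swap <- length(t_ids) > length(u_ids)   # minority arm supplies the rows
  if (swap) cost <- t(cost)
  j <- solve_assignment(cost)
  pairs <- if (swap)
    data.frame(treated_id = t_ids[j], untreated_id = u_ids,
               stringsAsFactors = FALSE)
  else
    data.frame(treated_id = t_ids, untreated_id = u_ids[j],
               stringsAsFactors = FALSE)
  pairs$dist2 <- cost[cbind(seq_along(j), j)]
  total <- sum(pairs$dist2)
  ord <- order(match(pairs$treated_id, t_ids))
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(bucket = problem$bucket, pairs = pairs,
                 total_cost = total, n_s = 2L * nrow(pairs)),
            class = "match_result")
}

#' Match treated and untreated arms within every risk bucket
#'
#' Runs [match_within_bucket()] separately in each stratum so that, after
#' retaining only matched patients, both arms are equally large in every
#' bucket and the empirical within-bucket treatment probability is 0.5 --
#' emulating randomized assignment within each risk stratum. Distances use
#' the named continuous covariates, normalized over the full population of
#' matchable buckets. Buckets with an empty arm cannot be matched and are
#' dropped with a warning.
#'
#' @param sc a `stratified_cohort`.
#' @param distance_covariates continuous covariate names for the distance;
#'   defaults to all continuous covariates.
#' @return A `matched_cohort`: `cohort` (retained patients), `pairs` table
#'   with bucket provenance, per-bucket `counts`, `dropped_buckets`, and
#'   the stratification carried over (`w`, `bucket`).
#' @export
match_cohort <- function(sc, distance_covariates = NULL) {
  cohort <- sc$cohort
  distance_covariates <- distance_covariates %||%
    names(cohort$covariates)[cohort$covariates == "continuous"]
  if (!length(distance_covariates))
    sx_abort("value", "no continuous covariates available for matching distances")
  d <- cohort$data

  n1 <- vapply(sc$spec$bucket, function(k)
    sum(sc$bucket == k & d$.treatment == 1), integer(1))
  n0 <- vapply(sc$spec$bucket, function(k)
    sum(sc$bucket == k & d$.treatment == 0), integer(1))
  ok <- n1 > 0 & n0 > 0
  dropped <- sc$spec$bucket[!ok]
  if (!any(ok)) sx_abort("pipeline", "all buckets have an empty arm; matching impossible")
  if (length(dropped))
    warning(sprintf("dropping bucket(s) with an empty arm: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)

  eligible <- sc$bucket %in% sc$spec$bucket[ok]
  norm <- normalize_covariates(d[eligible, , drop = FALSE], distance_covariates)
  coords <- matrix(NA_real_, nrow(d), length(distance_covariates))
  coords[eligible, ] <- norm$coords

  pairs_list <- list()
  for (k in sc$spec$bucket[ok]) {
    rows_t <- which(sc$bucket == k & d$.treatment == 1)
    rows_u <- which(sc$bucket == k & d$.treatment == 0)
    res <- match_within_bucket(list(
      bucket = k,
      treated_ids = d$.id[rows_t], untreated_ids = d$.id[rows_u],
      treated_coords = coords[rows_t, , drop = FALSE],
      untreated_coords = coords[rows_u, , drop = FALSE]))
    res$pairs$bucket <- k
    pairs_list[[as.character(k)]] <- res$pairs
  }
  pairs <- do.call(rbind, pairs_list)
  rownames(pairs) <- NULL

  keep_ids <- c(pairs$treated_id, pairs$untreated_id)
  keep <- d$.id %in% keep_ids
  mc_cohort <- new_cohort(d[keep, , drop = FALSE], cohort$covariates)
  counts <- data.frame(bucket = sc$spec$bucket[ok],
                       n_per_arm = vapply(sc$spec$bucket[ok], function(k)
                         sum(pairs$bucket == k), integer(1)))
  structure(list(cohort = mc_cohort, pairs = pairs, counts = counts,
                 w = sc$w[keep], bucket = sc$bucket[keep],
                 dropped_buckets = dropped,
                 distance_covariates = distance_covariates,
                 normalization = norm[c("center", "scale")]),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched cohort> %d pairs (%d patients) across %d buckets\n",
              nrow(x$pairs), x$cohort$n, nrow(x$counts)))
  invisible(x)
}

#' Oversample sparse strata of an imbalanced randomized cohort
#'
#' The remedy for trial cohorts whose high-risk strata are underpopulated:
#' within each flagged bucket, each arm smaller than the target is topped
#' up by resampling its own patients with replacement (seeded). Duplicates
#' receive fresh ids carrying the provenance of their source patient. No
#' record is ever removed.
#'
#' @param sc a `stratified_cohort` (sparse buckets already merged by
#'   [stratify()]).
#' @param target per-arm target size for flagged buckets; default is the
#'   median per-arm size of the unflagged buckets.
#' @param ratio_threshold imbalance flagging threshold passed to
#'   [diagnose_balance()].
#' @param seed integer seed for the resampling draws.
#' @return A new `stratified_cohort` containing the augmented cohort.
#' @export
oversample_strata <- function(sc, target = NULL, ratio_threshold = 2,
                              seed = 1L) {
  diag <- diagnose_balance(sc, ratio_threshold)$table
  if (!any(diag$flagged)) return(sc)
  if (is.null(target)) {
    unflagged <- diag[!diag$flagged, , drop = FALSE]
    if (nrow(unflagged) == 0)
      sx_abort("value", "all buckets flagged; supply an explicit target")
    target <- round(stats::median(
      c(unflagged$n_treated, unflagged$n_untreated)))
  }
  d <- sc$cohort$data
  if (!".source_id" %in% names(d)) d$.source_id <- d$.id
  add <- list(); add_w <- numeric(0); add_b <- integer(0)
  set.seed(seed)
  for (k in diag$bucket[diag$flagged]) {
    for (arm in c(1L, 0L)) {
      rows <- which(sc$bucket == k & d$.treatment == arm)
      have <- length(rows)
      if (have == 0)
        sx_abort("matching",
                 "bucket %d has an empty %s arm; cannot oversample",
                 k, if (arm == 1) "treated" else "untreated")
      if (have >= target) next
      draws <- rows[sample.int(have, target - have, replace = TRUE)]
      dup <- d[draws, , drop = FALSE]
      dup$.source_id <- dup$.id
      dup$.id <- sprintf("%s.dup%d", dup$.id,
                         as.integer(stats::ave(seq_along(draws), draws,
                                               FUN = seq_along)))
      add[[length(add) + 1L]] <- dup
      add_w <- c(add_w, sc$w[draws])
      add_b <- c(add_b, rep(k, length(draws)))
    }
  }
  if (length(add)) {
    d2 <- rbind(d, do.call(rbind, add))
    rownames(d2) <- NULL
    cohort2 <- new_cohort(d2, sc$cohort$covariates)
    structure(list(cohort = cohort2, w = c(sc$w, add_w),
                   bucket = c(sc$bucket, add_b), spec = sc$spec,
                   merges = sc$merges),
              class = "stratified_cohort")
  } else sc
}

#' Export the matched-pairs table
#'
#' @param mc a `matched_cohort`.
#' @param path optional CSV path.
#' @return Data frame `bucket, treated_id, untreated_id, dist2`.
#' @export
pairs_table <- function(mc, path = NULL) {
  out <- mc$pairs[, c("bucket", "treated_id", "untreated_id", "dist2")]
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
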