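test_that("normalize_covariates centers and scales by population sd", {
  co <- make_cohort(treatment = c(0L, 1L, 0L), event = c(0L, 1L, 0L),
                    a = c(2, 4, 6), b = c(1, 1, 4))
  norm <- normalize_covariates(co, c("a", "b"))
  expect_equal(norm$coords[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # idempotence: re-normalizing standardized values changes nothing
  co2 <- make_cohort(treatment = c(0L, 1L, 0L), event = c(0L, 1L, 0L),
                     a = norm$coords[, "a"])
  expect_equal(normalize_covariates(co2, "a")$coords[, "a"],
               norm$coords[, "a"], tolerance = 1e-12)
  # zero variance is rejected by name
  co3 <- make_cohort(treatment = 0:1, event = 0:1, cst = c(3, 3))
  err <- expect_error(normalize_covariates(co3, "cst"),
                      class = "stratarx_value")
  expect_match(conditionMessage(err), "cst")
})

mk_problem <- function(tx, ux) {
  list(bucket = 1L,
       treated_ids = sprintf("t%d", seq_along(tx)),
       untreated_ids = sprintf("u%d", seq_along(ux)),
       treated_coords = matrix(tx, ncol = 1),
       untreated_coords = matrix(ux, ncol = 1))
}

test_that("match_within_bucket solves small instances exactly", {
  # identical positions -> zero cost
  r0 <- match_within_bucket(mk_problem(0, 0))
  expect_equal(r0$total_cost, 0)
  expect_equal(r0$n_s, 2L)

  # treated {0, 10}, untreated {1, 9, 20}: optimum pairs (0-1), (10-9), cost 2
  r <- match_within_bucket(mk_problem(c(0, 10), c(1, 9, 20)))
  expect_equal(r$total_cost, 2)
  expect_equal(r$pairs$treated_id, c("t1", "t2"))
  expect_equal(r$pairs$untreated_id, c("u1", "u2"))

  # role swap: 3 treated vs 2 untreated -> 2 pairs, each untreated used once
  r2 <- match_within_bucket(mk_problem(c(0, 5, 10), c(1, 9)))
  expect_equal(nrow(r2$pairs), 2L)
  expect_equal(sort(r2$pairs$untreated_id), c("u1", "u2"))
  expect_equal(anyDuplicated(r2$pairs$treated_id), 0L)

  expect_error(match_within_bucket(mk_problem(numeric(0), c(1))),
               class = "stratarx_matching")
})

test_that("matching is exact: 200 random instances vs brute force", {
  set.seed(77)
  for (i in 1:200) {
    n1 <- sample(1:7, 1); n0 <- sample(1:7, 1)
    p <- sample(1:2, 1)
    tx <- matrix(rnorm(n1 * p), n1, p)
    ux <- matrix(rnorm(n0 * p), n0, p)
    r <- match_within_bucket(list(bucket = 1L,
                                  treated_ids = sprintf("t%d", 1:n1),
                                  untreated_ids = sprintf("u%d", 1:n0),
                                  treated_coords = tx, untreated_coords = ux))
    cost <- outer(rowSums(tx^2), rowSums(ux^2), "+") - 2 * tx %*% t(ux)
    if (n1 > n0) cost <- t(cost)
    expect_equal(r$total_cost, brute_force_match_cost(cost), tolerance = 1e-9)
  }
})

test_that("matching is invariant to covariate relabeling and shifts", {
  set.seed(3)
  base <- make_cohort(treatment = rep(c(1L, 0L), c(5, 8)),
                      event = rep(0:1, length.out = 13),
                      a = rnorm(13), b = rnorm(13))
  w <- rep(0.3, 13)
  sc <- stratify(base, w, m = 1)
  m1 <- match_cohort(sc, c("a", "b"))

  # swap the covariate roles
  m2 <- match_cohort(sc, c("b", "a"))
  expect_equal(m1$pairs[c("treated_id", "untreated_id")],
               m2$pairs[c("treated_id", "untreated_id")])

  # add a constant to one covariate pre-normalization
  shifted <- base
  shifted$data$a <- shifted$data$a + 100
  m3 <- match_cohort(stratify(shifted, w, m = 1), c("a", "b"))
  expect_equal(m1$pairs[c("treated_id", "untreated_id")],
               m3$pairs[c("treated_id", "untreated_id")])
  expect_equal(sum(m1$pairs$dist2), sum(m3$pairs$dist2), tolerance = 1e-9)
})

test_that("match_cohort equalizes arms and shrinks the risk imbalance", {
  sim <- simulate_observational_cohort(preset_gist_observational(n = 1500, seed = 41))
  co <- sim$cohort
  m <- fit_baseline_model(co, seed = 41)
  w <- predict_baseline_risk(m, co)
  sc <- stratify(co, w, m = 6, min_per_arm = 5)
  mc <- suppressWarnings(match_cohort(sc))

  # hard assertion: equal arms in every bucket
  d <- mc$cohort$data
  for (k in mc$counts$bucket) {
    expect_equal(sum(mc$bucket == k & d$.treatment == 1),
                 sum(mc$bucket == k & d$.treatment == 0))
  }
  # empirical within-bucket treatment probability is 0.5 everywhere
  expect_true(all(abs(tapply(d$.treatment, mc$bucket, mean) - 0.5) < 1e-12))

  # standardized mean difference of w shrinks after matching
  smd <- function(x, t) (mean(x[t == 1]) - mean(x[t == 0])) /
    sqrt((var(x[t == 1]) + var(x[t == 0])) / 2)
  before <- smd(w, co$data$.treatment)
  after <- smd(mc$w, d$.treatment)
  expect_lt(abs(after), abs(before))

  # matching never fabricates records
  expect_true(all(d$.id %in% co$data$.id))
})

test_that("an already balanced bucket of identical values is fully retained", {
  co <- make_cohort(treatment = rep(c(1L, 0L), 4), event = rep(0:1, 4),
                    a = rep(1.5, 8), b = rnorm(8))
  sc <- stratify(co, rep(0.2, 8), m = 1)
  mc <- match_cohort(sc, "b")
  expect_equal(mc$cohort$n, 8)
})

test_that("buckets with an empty arm are dropped with a warning", {
  co <- make_cohort(treatment = c(rep(c(1L, 0L), 4), 1L, 1L),
                    event = rep(0:1, 5), a = rnorm(10))
  w <- c(rep(0.2, 8), 0.9, 0.95)
  sc <- stratify(co, w, breaks = 0.5)
  expect_warning(mc <- match_cohort(sc, "a"), "empty arm")
  expect_equal(mc$dropped_buckets, 2L)

  co2 <- make_cohort(treatment = rep(1L, 4), event = rep(0:1, 2),
                     a = rnorm(4))
  expect_error(match_cohort(stratify(co2, rep(0.5, 4), m = 1), "a"),
               class = "stratarx_pipeline")
})

test_that("oversample_strata tops up flagged arms to the target", {
  co <- make_cohort(treatment = c(rep(1L, 40), rep(0L, 10), rep(1L, 40),
                                  rep(0L, 40)),
                    event = rep(0:1, length.out = 130), a = rnorm(130))
  w <- c(rep(0.8, 50), rep(0.2, 80))
  sc <- stratify(co, w, breaks = 0.5)
  out <- oversample_strata(sc, target = 40, seed = 9)
  d <- out$cohort$data
  expect_equal(sum(out$bucket == 2 & d$.treatment == 1), 40)  # high bucket
  expect_equal(sum(out$bucket == 2 & d$.treatment == 0), 40)  # 30 draws added
  expect_equal(out$cohort$n, 160)
  # never removes records; duplicates carry provenance
  expect_true(all(co$data$.id %in% d$.id))
  dups <- d[grepl("\\.dup", d$.id), ]
  expect_equal(nrow(dups), 30)
  expect_true(all(dups$.source_id %in% co$data$.id))
  # deterministic given seed
  out2 <- oversample_strata(sc, target = 40, seed = 9)
  expect_identical(out2$cohort$data, d)

  # nothing flagged -> unchanged
  bal <- make_cohort(treatment = rep(c(1L, 0L), 20), event = rep(0:1, 20),
                     a = rnorm(40))
  scb <- stratify(bal, rep(0.3, 40), m = 1)
  expect_identical(oversample_strata(scb, seed = 1), scb)

  # empty arm cannot be oversampled
  co3 <- make_cohort(treatment = c(rep(1L, 6), rep(c(1L, 0L), 12)),
                     event = rep(0:1, 15), a = rnorm(30))
  sc3 <- stratify(co3, c(rep(0.9, 6), rep(0.2, 24)), breaks = 0.5)
  expect_error(oversample_strata(sc3, seed = 1),
               class = "stratarx_matching")
})
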