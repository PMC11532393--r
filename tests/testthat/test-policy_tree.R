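test_that("uniform benefit collapses to a single treat-all leaf", {
  set.seed(2)
  rm <- make_rm(h0 = runif(20, 0.5, 0.9), h1 = runif(20, 0.1, 0.4),
                f = rnorm(20))
  tree <- fit_policy_tree(rm, minbucket = 1, max_depth = 3)
  expect_equal(tree$root$type, "leaf")
  expect_equal(tree$root$treatment, 1L)
  expect_equal(policy_objective(tree, rm), sum(rm$data$h1))
})

# the 4-patient worked instance: f=0 rewards (0.1, 0.3), f=1 rewards (0.5, 0.2)
four_patient_rm <- function() {
  make_rm(h0 = c(0.1, 0.1, 0.5, 0.5), h1 = c(0.3, 0.3, 0.2, 0.2),
          f = c(0, 0, 1, 1))
}

test_that("the 4-patient instance splits once and reaches objective 0.6", {
  rm <- four_patient_rm()
  tree <- fit_policy_tree(rm, minbucket = 1, max_depth = 1)
  expect_equal(tree$root$type, "split")
  expect_equal(tree$root$var, "f")
  expect_equal(tree$root$left$treatment, 0L)   # f = 0 -> control
  expect_equal(tree$root$right$treatment, 1L)  # f = 1 -> treat
  expect_equal(policy_objective(tree, rm), 0.6)

  # exhaustive enumeration over the same instance agrees
  oracle <- brute_force_policy_tree(rm, depth = 1, minbucket = 1)
  expect_equal(policy_objective(oracle, rm), 0.6)

  # independent enumeration helper agrees too
  expect_equal(brute_force_depth1_objective(rm$data, rm$data$h0, rm$data$h1,
                                            rm$covariates, 1), 0.6)
})

test_that("leaf ties withhold treatment", {
  rm <- make_rm(h0 = c(0.4, 0.4), h1 = c(0.4, 0.4), f = c(0, 1))
  tree <- fit_policy_tree(rm, minbucket = 1, max_depth = 1)
  expect_equal(tree$root$type, "leaf")
  expect_equal(tree$root$treatment, 0L)
})

test_that("routing follows the strict less-than convention", {
  tree <- make_binary_tree()          # split at f < 0.5
  expect_equal(assign_treatment(tree, data.frame(f = c(0.49, 0.5, 0.51))),
               c(0L, 1L, 1L))         # boundary routes right (>= side)
  expect_equal(assign_treatment(make_constant_tree(1L),
                                data.frame(anything = 1:3)),
               c(1L, 1L, 1L))
  expect_error(assign_treatment(tree, data.frame(g = 1)),
               class = "stratarx_value")
})

test_that("a mitotic-count-style first split treats high counts regardless", {
  # encoded fixture tree with the clinical routing semantics: counts at or
  # above the threshold are always treated
  tree <- structure(list(
    root = list(type = "split", var = "mitoses", threshold = 10.5, set = NULL,
                n = 0L, mean_h0 = NA_real_, mean_h1 = NA_real_,
                left = list(type = "split", var = "site", threshold = NULL,
                            set = "gastric", n = 0L, mean_h0 = NA_real_,
                            mean_h1 = NA_real_,
                            left = list(type = "leaf", treatment = 0L, n = 0L,
                                        mean_h0 = NA_real_, mean_h1 = NA_real_),
                            right = list(type = "leaf", treatment = 1L, n = 0L,
                                         mean_h0 = NA_real_, mean_h1 = NA_real_)),
                right = list(type = "leaf", treatment = 1L, n = 0L,
                             mean_h0 = NA_real_, mean_h1 = NA_real_)),
    covariates = c(mitoses = "continuous", site = "categorical"),
    minbucket = 1L, max_depth = 2L, rho = 1), class = "policy_tree")
  df <- data.frame(mitoses = c(12, 10.5, 3, 3),
                   site = c("gastric", "gastric", "gastric", "nongastric"))
  expect_equal(assign_treatment(tree, df), c(1L, 1L, 0L, 1L))
})

test_that("policy_objective sums the assigned reward columns", {
  rm <- four_patient_rm()
  expect_equal(policy_objective(make_constant_tree(0L), rm), sum(rm$data$h0))
  expect_equal(policy_objective(make_constant_tree(1L), rm), sum(rm$data$h1))
  tree <- fit_policy_tree(rm, minbucket = 1, max_depth = 2)
  expect_lte(policy_objective(tree, rm),
             min(sum(rm$data$h0), sum(rm$data$h1)))
})

test_that("node_effects reports ARR/RRR per node", {
  # RRR 50% yields ARR 40% at baseline 80%, but 20% at baseline 40%
  rm_a <- make_rm(h0 = rep(0.80, 4), h1 = rep(0.40, 4), f = c(0, 0, 1, 1))
  eff_a <- node_effects(make_constant_tree(1L), rm_a)
  expect_equal(eff_a$p0, 0.80)
  expect_equal(eff_a$arr, 0.40)
  expect_equal(eff_a$rrr, 0.50)

  rm_b <- make_rm(h0 = rep(0.40, 4), h1 = rep(0.20, 4), f = c(0, 0, 1, 1))
  expect_equal(node_effects(make_constant_tree(1L), rm_b)$arr, 0.20)

  # p1 = p0 -> ARR = RRR = 0; p0 = 0 -> RRR undefined
  rm_c <- make_rm(h0 = c(0.3, 0.3), h1 = c(0.3, 0.3), f = c(0, 1))
  eff_c <- node_effects(make_constant_tree(0L), rm_c)
  expect_equal(eff_c$arr, 0)
  expect_equal(eff_c$rrr, 0)
  rm_d <- make_rm(h0 = c(0, 0), h1 = c(0.1, 0.1), f = c(0, 1))
  expect_true(is.na(node_effects(make_constant_tree(0L), rm_d)$rrr))

  # parent statistics aggregate the children consistently
  rm <- four_patient_rm()
  tree <- fit_policy_tree(rm, minbucket = 1, max_depth = 1)
  eff <- node_effects(tree, rm)
  expect_equal(eff$n[1], sum(eff$n[-1]))
  expect_equal(eff$p0[1] * eff$n[1], sum(eff$p0[-1] * eff$n[-1]))
  expect_equal(eff$p1[1] * eff$n[1], sum(eff$p1[-1] * eff$n[-1]))
})

test_that("greedy depth-1 equals the exhaustive depth-1 oracle", {
  set.seed(14)
  for (i in 1:40) {
    n <- 50
    rm <- make_rm(h0 = runif(n), h1 = runif(n),
                  a = rnorm(n), b = sample(0:3, n, TRUE),
                  g = sample(c("x", "y", "z"), n, TRUE))
    greedy <- fit_policy_tree(rm, minbucket = 5, max_depth = 1)
    oracle <- brute_force_policy_tree(rm, depth = 1, minbucket = 5)
    expect_equal(policy_objective(greedy, rm), policy_objective(oracle, rm),
                 tolerance = 1e-12)
  }
})

test_that("greedy depth-2 stays within 10% of the exhaustive optimum", {
  # covariate-structured rewards, the class a reward matrix belongs to:
  # risks smooth in one covariate, benefit switched by another
  set.seed(15)
  ratios <- replicate(25, {
    n <- 50
    a <- rnorm(n); b <- rnorm(n)
    h0 <- plogis(-0.5 + a + rnorm(n, 0, 0.3))
    h1 <- pmax(h0 - 0.25 * (b > 0) + rnorm(n, 0, 0.1), 0.01)
    rm <- make_rm(h0 = h0, h1 = h1, a = a, b = b)
    greedy <- fit_policy_tree(rm, minbucket = 5, max_depth = 2)
    oracle <- brute_force_policy_tree(rm, depth = 2, minbucket = 5)
    og <- policy_objective(greedy, rm); oo <- policy_objective(oracle, rm)
    expect_gte(og, oo - 1e-12)         # oracle is a true lower bound
    og / oo
  })
  expect_lte(max(ratios), 1.1)

  # even on unstructured noise the greedy tree never beats the oracle
  for (i in 1:5) {
    n <- 50
    rm <- make_rm(h0 = runif(n), h1 = runif(n), a = rnorm(n), b = rnorm(n))
    expect_gte(policy_objective(fit_policy_tree(rm, minbucket = 5,
                                                max_depth = 2), rm),
               policy_objective(brute_force_policy_tree(rm, depth = 2,
                                                        minbucket = 5), rm) - 1e-12)
  }
})

test_that("brute force rejects oversized instances and depth > 2", {
  rm <- make_rm(h0 = runif(300), h1 = runif(300), a = rnorm(300))
  expect_error(brute_force_policy_tree(rm, depth = 1),
               class = "stratarx_size")
  rm2 <- make_rm(h0 = runif(10), h1 = runif(10), a = rnorm(10))
  expect_error(brute_force_policy_tree(rm2, depth = 3),
               class = "stratarx_value")
  # depth 0 is the best constant policy
  t0 <- brute_force_policy_tree(rm2, depth = 0)
  expect_equal(policy_objective(t0, rm2),
               min(sum(rm2$data$h0), sum(rm2$data$h1)))
})

test_that("lower treated rewards weakly enlarge the treated region", {
  set.seed(16)
  n <- 120
  rm1 <- make_rm(h0 = runif(n, 0.2, 0.8), h1 = runif(n, 0.2, 0.8),
                 a = rnorm(n), b = rnorm(n))
  frac <- sapply(c(0, 0.05, 0.15, 0.3), function(shift) {
    rm <- rm1
    rm$data$h1 <- pmax(rm1$data$h1 - shift, 0)
    rm$mean_h1 <- mean(rm$data$h1)
    tree <- fit_policy_tree(rm, minbucket = 10, max_depth = 3)
    mean(assign_treatment(tree, rm) == 1)
  })
  expect_true(all(diff(frac) >= 0))
})

test_that("serialization round-trips structure, statistics and objective", {
  rm <- four_patient_rm()
  tree <- fit_policy_tree(rm, minbucket = 1, max_depth = 1)
  json <- serialize_tree(tree)
  back <- deserialize_tree(json)
  expect_equal(back$root, tree$root)
  expect_equal(back$covariates, tree$covariates)
  expect_equal(policy_objective(back, rm), policy_objective(tree, rm))

  expect_error(deserialize_tree("{not json"), class = "stratarx_parse")
  expect_error(deserialize_tree("{\"a\": 1}"), class = "stratarx_parse")
})

test_that("the ASCII rendering lists splits depth-first with leaf labels", {
  rm <- four_patient_rm()
  tree <- fit_policy_tree(rm, minbucket = 1, max_depth = 1)
  expect_equal(render_tree(tree),
               c("f < 0.5 (n=4)",
                 "  yes: => no treatment (n=2, p0=0.100, p1=0.300)",
                 "  no:  => TREAT (n=2, p0=0.500, p1=0.200)"))
})

test_that("hyperparameter contracts are enforced", {
  rm <- four_patient_rm()
  expect_error(fit_policy_tree(rm, minbucket = 10), class = "stratarx_value")
  expect_error(fit_policy_tree(rm, minbucket = 0), class = "stratarx_value")
  rm$data$h1[1] <- Inf
  expect_error(fit_policy_tree(rm, minbucket = 1), class = "stratarx_value")
})
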