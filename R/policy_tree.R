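# Axis-aligned policy tree minimizing the total assigned counterfactual
# risk  sum_i [ tau(x_i)=0 ] h0(x_i) + [ tau(x_i)=1 ] h1(x_i).
# Greedy top-down search over midpoint thresholds (numeric) and category
# subsets (categorical, <= 8 levels), with an exhaustive small-depth oracle
# for testing. Routing convention: numeric goes left iff value < threshold
# (boundary values route right, the "equal or greater" side); categorical
# goes left iff the value is in the node's level set.

numeric_cuts <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(numeric(0))
  (u[-1] + u[-length(u)]) / 2
}

cat_subsets <- function(levels) {
  L <- length(levels)
  if (L < 2 || L > 8) return(list())
  out <- list()
  rest <- levels[-1]
  for (mask in 0:(2^(L - 1) - 1 - 1)) {   # exclude the full set
    s <- levels[1]
    if (L > 1) s <- c(s, rest[bitwAnd(mask, 2^(seq_len(L - 1) - 1)) > 0])
    out[[length(out) + 1L]] <- s
  }
  out
}

leaf_node <- function(h0, h1, rows) {
  n <- length(rows)
  s0 <- sum(h0[rows]); s1 <- sum(h1[rows])
  list(type = "leaf", treatment = if (s1 < s0) 1L else 0L,  # tie -> no treatment
       n = n, mean_h0 = s0 / n, mean_h1 = s1 / n,
       cost = min(s0, s1))
}

# best single split of `rows`; children are scored as leaves
best_split <- function(data, kinds, h0, h1, rows, minbucket) {
  best <- NULL
  for (cv in names(kinds)) {
    x <- data[[cv]][rows]
    if (kinds[[cv]] == "continuous") {
      ord <- order(x)
      xs <- x[ord]
      c0 <- cumsum(h0[rows][ord]); c1 <- cumsum(h1[rows][ord])
      s0 <- c0[length(c0)]; s1 <- c1[length(c1)]
      n <- length(xs)
      a <- seq_len(n - 1)
      valid <- xs[-1] > xs[-n] & a >= minbucket & (n - a) >= minbucket
      if (!any(valid)) next
      cost <- pmin(c0[a], c1[a]) + pmin(s0 - c0[a], s1 - c1[a])
      cost[!valid] <- Inf
      i <- which.min(cost)
      if (is.null(best) || cost[i] < best$cost - 1e-12) {
        thr <- (xs[i] + xs[i + 1]) / 2
        best <- list(var = cv, threshold = thr, set = NULL,
                     cost = cost[i], left = rows[x < thr])
      }
    } else {
      for (s in cat_subsets(sort(unique(x)))) {
        inl <- x %in% s
        nl <- sum(inl); nr <- length(x) - nl
        if (nl < minbucket || nr < minbucket) next
        lc <- min(sum(h0[rows][inl]), sum(h1[rows][inl]))
        rc <- min(sum(h0[rows][!inl]), sum(h1[rows][!inl]))
        if (is.null(best) || lc + rc < best$cost - 1e-12)
          best <- list(var = cv, threshold = NULL, set = s,
                       cost = lc + rc, left = rows[inl])
      }
    }
  }
  best
}

grow_tree <- function(data, kinds, h0, h1, rows, depth, minbucket, max_depth) {
  leaf <- leaf_node(h0, h1, rows)
  if (depth >= max_depth || length(rows) < 2 * minbucket) return(leaf)
  sp <- best_split(data, kinds, h0, h1, rows, minbucket)
  if (is.null(sp) || sp$cost >= leaf$cost - 1e-12) return(leaf)
  right <- setdiff(rows, sp$left)
  node <- list(type = "split", var = sp$var, threshold = sp$threshold,
               set = sp$set, n = leaf$n, mean_h0 = leaf$mean_h0,
               mean_h1 = leaf$mean_h1,
               left = grow_tree(data, kinds, h0, h1, sp$left, depth + 1,
                                minbucket, max_depth),
               right = grow_tree(data, kinds, h0, h1, right, depth + 1,
                                 minbucket, max_depth))
  node
}

#' Fit a policy tree by greedy recursive partitioning
#'
#' Grows an axis-aligned decision tree whose leaves each prescribe the
#' treatment minimizing the leaf's summed counterfactual risk (ties
#' withhold treatment). At every node all covariates and all candidate
#' cuts are scored and the split most reducing the assigned-risk objective
#' is taken; recursion stops at `max_depth`, when a child would fall below
#' `minbucket`, or when no split improves the objective.
#'
#' @param rm a `reward_matrix` from [predict_rewards()].
#' @param covariates covariate names to split on; default all in `rm`.
#' @param minbucket minimum patients per leaf.
#' @param max_depth maximum tree depth (0 = a single leaf).
#' @param seed unused by the deterministic search; kept for interface
#'   stability.
#' @return A `policy_tree` object.
#' @export
fit_policy_tree <- function(rm, covariates = NULL, minbucket = 15L,
                            max_depth = 4L, seed = NULL) {
  covariates <- covariates %||% names(rm$covariates)
  kinds <- rm$covariates[covariates]
  if (minbucket < 1) sx_abort("value", "minbucket must be >= 1")
  if (minbucket > nrow(rm$data)) sx_abort("value", "minbucket exceeds n")
  if (max_depth < 0) sx_abort("value", "max_depth must be >= 0")
  if (any(!is.finite(rm$data$h0)) || any(!is.finite(rm$data$h1)))
    sx_abort("value", "rewards must be finite")
  root <- strip_cost(grow_tree(rm$data, kinds, rm$data$h0, rm$data$h1,
                               seq_len(nrow(rm$data)), 0L, minbucket,
                               max_depth))
  structure(list(root = root, covariates = kinds, minbucket = minbucket,
                 max_depth = max_depth, rho = rm$rho),
            class = "policy_tree")
}

route_one <- function(node, row) {
  while (node$type == "split") {
    v <- row[[node$var]]
    if (is.null(v) || length(v) == 0 || (is.numeric(v) && is.na(v)))
      sx_abort("value", "missing split covariate '%s'", node$var)
    go_left <- if (!is.null(node$threshold)) v < node$threshold
               else as.character(v) %in% node$set
    node <- if (go_left) node$left else node$right
  }
  node
}

#' Assign a treatment to patients with a fitted policy tree
#'
#' @param tree a `policy_tree`.
#' @param newdata an `sx_cohort`, `reward_matrix`, or data frame holding
#'   the split covariates.
#' @return Integer vector of recommended treatments (0/1).
#' @export
assign_treatment <- function(tree, newdata) {
  d <- if (inherits(newdata, "sx_cohort")) newdata$data
       else if (inherits(newdata, "reward_matrix")) newdata$data
       else newdata
  missing_cols <- setdiff(tree_vars(tree$root), names(d))
  if (length(missing_cols))
    sx_abort("value", "missing split covariate(s): %s",
             paste(missing_cols, collapse = ", "))
  vapply(seq_len(nrow(d)), function(i)
    route_one(tree$root, d[i, , drop = FALSE])$treatment, integer(1))
}

tree_vars <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$var, tree_vars(node$left), tree_vars(node$right)))
}

#' Total assigned counterfactual risk of a policy tree
#'
#' Sums, over all patients, the reward column selected by the tree's
#' assignment: h0 where the tree withholds treatment, h1 where it treats.
#'
#' @param tree a `policy_tree`.
#' @param rm a `reward_matrix` covering all patients.
#' @return The objective value (a single number).
#' @export
policy_objective <- function(tree, rm) {
  a <- assign_treatment(tree, rm)
  sum(ifelse(a == 1, rm$data$h1, rm$data$h0))
}

#' Per-node absolute and relative risk reduction
#'
#' Walks the tree depth-first and reports, for the patients reaching each
#' node, the mean predicted baseline risk p0, mean predicted treated risk
#' p1, the absolute risk reduction ARR = p0 - p1 and the relative risk
#' reduction RRR = ARR / p0 (undefined, `NA`, when p0 = 0). The same
#' relative reduction yields a larger absolute reduction where baseline
#' risk is higher, which is what makes these per-subgroup numbers
#' clinically actionable.
#'
#' @param tree a `policy_tree`.
#' @param rm a `reward_matrix`.
#' @return Data frame, one row per node in depth-first order: `node,
#'   depth, type, rule, n, p0, p1, arr, rrr, treatment`.
#' @export
node_effects <- function(tree, rm) {
  d <- rm$data
  out <- list()
  walk <- function(node, rows, depth, rule) {
    if (!length(rows)) sx_abort("value", "empty node in tree")
    p0 <- mean(d$h0[rows]); p1 <- mean(d$h1[rows])
    out[[length(out) + 1L]] <<- data.frame(
      node = length(out) + 1L, depth = depth, type = node$type, rule = rule,
      n = length(rows), p0 = p0, p1 = p1, arr = p0 - p1,
      rrr = if (p0 == 0) NA_real_ else (p0 - p1) / p0,
      treatment = if (node$type == "leaf") node$treatment else NA_integer_,
      stringsAsFactors = FALSE)
    if (node$type == "split") {
      go_left <- if (!is.null(node$threshold)) d[[node$var]][rows] < node$threshold
                 else as.character(d[[node$var]][rows]) %in% node$set
      walk(node$left, rows[go_left], depth + 1L, describe_split(node, TRUE))
      walk(node$right, rows[!go_left], depth + 1L, describe_split(node, FALSE))
    }
  }
  walk(tree$root, seq_len(nrow(d)), 0L, "root")
  do.call(rbind, out)
}

describe_split <- function(node, left) {
  if (!is.null(node$threshold)) {
    if (left) sprintf("%s < %g", node$var, node$threshold)
    else sprintf("%s >= %g", node$var, node$threshold)
  } else {
    s <- if (left) node$set else paste0("not ", paste(node$set, collapse = "/"))
    sprintf("%s in {%s}", node$var, paste(s, collapse = ","))
  }
}

#' Exhaustive small-depth policy-tree oracle
#'
#' Enumerates every tree of depth at most `depth` (0, 1 or 2) over the
#' same candidate cuts as the greedy fitter and returns a global minimizer
#' of the assigned-risk objective. Exponential in depth; restricted to
#' small instances, where it serves as an independent bound on the greedy
#' search.
#'
#' @param rm a `reward_matrix` with at most 200 patients.
#' @param covariates covariates to split on (at most 5).
#' @param depth 0, 1 or 2.
#' @param minbucket minimum patients per leaf.
#' @return A `policy_tree` that is globally optimal at the given depth.
#' @export
brute_force_policy_tree <- function(rm, covariates = NULL, depth = 2L,
                                    minbucket = 1L) {
  covariates <- covariates %||% names(rm$covariates)
  kinds <- rm$covariates[covariates]
  d <- rm$data
  if (nrow(d) > 200 || length(covariates) > 5)
    sx_abort("size", "instance too large for exhaustive search (n <= 200, p <= 5)")
  if (!depth %in% 0:2) sx_abort("value", "depth must be 0, 1 or 2")
  h0 <- d$h0; h1 <- d$h1

  all_splits <- function(rows) {
    out <- list()
    for (cv in names(kinds)) {
      x <- d[[cv]][rows]
      if (kinds[[cv]] == "continuous") {
        for (thr in numeric_cuts(x)) {
          inl <- x < thr
          if (sum(inl) >= minbucket && sum(!inl) >= minbucket)
            out[[length(out) + 1L]] <- list(var = cv, threshold = thr,
                                            set = NULL, left = rows[inl],
                                            right = rows[!inl])
        }
      } else {
        for (s in cat_subsets(sort(unique(x)))) {
          inl <- x %in% s
          if (sum(inl) >= minbucket && sum(!inl) >= minbucket)
            out[[length(out) + 1L]] <- list(var = cv, threshold = NULL,
                                            set = s, left = rows[inl],
                                            right = rows[!inl])
        }
      }
    }
    out
  }

  best_subtree <- function(rows, dep) {
    leaf <- leaf_node(h0, h1, rows)
    best <- leaf
    if (dep == 0) return(best)
    for (sp in all_splits(rows)) {
      l <- best_subtree(sp$left, dep - 1L)
      r <- best_subtree(sp$right, dep - 1L)
      cost <- l$cost + r$cost
      if (cost < best$cost - 1e-12) {
        best <- list(type = "split", var = sp$var, threshold = sp$threshold,
                     set = sp$set, n = leaf$n, mean_h0 = leaf$mean_h0,
                     mean_h1 = leaf$mean_h1, left = l, right = r,
                     cost = cost)
      }
    }
    best
  }

  root <- best_subtree(seq_len(nrow(d)), depth)
  structure(list(root = strip_cost(root), covariates = kinds,
                 minbucket = minbucket, max_depth = depth, rho = rm$rho),
            class = "policy_tree")
}

strip_cost <- function(node) {
  node$cost <- NULL
  if (node$type == "split") {
    node$left <- strip_cost(node$left)
    node$right <- strip_cost(node$right)
  }
  node
}

#' Serialize a policy tree to JSON (and back)
#'
#' The representation is lossless: structure, thresholds and category
#' sets, leaf treatments and node statistics all round-trip exactly.
#'
#' @param tree a `policy_tree`.
#' @return A JSON string.
#' @export
serialize_tree <- function(tree) {
  payload <- list(covariates = as.list(tree$covariates),
                  minbucket = tree$minbucket, max_depth = tree$max_depth,
                  rho = tree$rho, root = tree$root)
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' @rdname serialize_tree
#' @param json a JSON string produced by [serialize_tree()].
#' @export
deserialize_tree <- function(json) {
  p <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                error = function(e) sx_abort("parse", "malformed tree JSON: %s",
                                             conditionMessage(e)))
  if (is.null(p$root) || is.null(p$root$type))
    sx_abort("parse", "malformed tree representation: no root node")
  fix <- function(node) {
    node$n <- as.integer(node$n)
    if (node$type == "leaf") {
      node$treatment <- as.integer(node$treatment)
    } else {
      if (!is.null(node$set)) node$set <- as.character(unlist(node$set))
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  structure(list(root = fix(p$root),
                 covariates = unlist(p$covariates),
                 minbucket = as.integer(p$minbucket),
                 max_depth = as.integer(p$max_depth),
                 rho = p$rho),
            class = "policy_tree")
}

#' Render a policy tree as indented ASCII
#'
#' Splits are listed in depth-first order; each leaf shows its treatment
#' label and reward statistics.
#'
#' @param tree a `policy_tree`.
#' @return Character vector of lines, invisibly printed by
#'   `print.policy_tree`.
#' @export
render_tree <- function(tree) {
  lines <- character(0)
  walk <- function(node, prefix, label) {
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf(
        "%s%s=> %s (n=%d, p0=%.3f, p1=%.3f)", prefix, label,
        if (node$treatment == 1) "TREAT" else "no treatment",
        node$n, node$mean_h0, node$mean_h1))
    } else {
      lines <<- c(lines, sprintf("%s%s%s (n=%d)", prefix, label,
                                 describe_split(node, TRUE), node$n))
      walk(node$left, paste0(prefix, "  "), "yes: ")
      walk(node$right, paste0(prefix, "  "), "no:  ")
    }
  }
  walk(tree$root, "", "")
  lines
}

#' @export
print.policy_tree <- function(x, ...) {
  cat(sprintf("<policy tree> max_depth=%d, minbucket=%d\n",
              x$max_depth, x$minbucket))
  cat(render_tree(x), sep = "\n")
  invisible(x)
}
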