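# Independent oracles used across the suite.  Each is deliberately coded
# along a different path than the package implementation it checks.

# Shared-path covariance by explicit root-path enumeration: for each tip,
# collect the edges on its root path; V[i,j] sums lengths of the common
# edges.  (The package uses ape::vcv.)
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_edges <- lapply(seq_len(n), function(tip) {
    e <- integer(0)
    node <- tip
    while (node != root) {
      e <- c(e, node)          # identify an edge by its child node
      node <- parent_of[node]
    }
    e
  })
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(path_edges[[i]], path_edges[[j]])
    V[i, j] <- sum(len_of[shared])
  }
  V
}

# Plain Newton-Raphson logistic MLE (no GEE machinery, no step-halving).
newton_logistic <- function(y, X, tol = 1e-12, max_iter = 50) {
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- plogis(drop(X %*% beta))
    W <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  mu <- plogis(drop(X %*% beta))
  list(beta = unname(beta),
       se = unname(sqrt(diag(solve(t(X) %*% (X * (mu * (1 - mu))))))))
}

# All permutations of 1..n by recursion (package uses iterative insertion).
perms_recursive <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_recursive(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- sub + (sub >= first)
    cbind(first, rest, deparse.level = 0)
  }))
}

# Midrank Spearman rho from first principles, and its exact two-sided
# permutation p-value by full enumeration.
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  rho <- pearson(rx, ry)
  perms <- perms_recursive(length(x))
  rhos <- apply(perms, 1, function(idx) pearson(rx, ry[idx]))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# Direct replay of the greedy clustering definition.
greedy_replay <- function(identity, threshold, tie_order) {
  reps <- character(0)
  for (lab in tie_order) {
    joined <- FALSE
    for (r in reps) {
      if (identity[lab, r] >= threshold) { joined <- TRUE; break }
    }
    if (!joined) reps <- c(reps, lab)
  }
  reps
}

# Estimating function of the binomial GEE, coded independently.
gee_score <- function(beta, y, X, R) {
  mu <- plogis(drop(X %*% beta))
  A <- mu * (1 - mu)
  drop(crossprod(X * A, solve(R * outer(sqrt(A), sqrt(A)), y - mu)))
}

# Random tree with uniform branch lengths (ape::rtree, independent of the
# package's own birth-death simulator).
random_tree <- function(n, min_len = 0.1, max_len = 2) {
  ape::rtree(n, br = function(k) runif(k, min_len, max_len))
}

# One simulation replicate: tree + env/trait + GEE fit; returns slope
# estimate and naive p (NA, 2 on error).
sim_fit_rep <- function(seed, n_tips, intercept, slope, rate_scale, env_rate) {
  tr <- simulate_tree(n_tips, seed = seed)
  r <- trait_rates_logistic(intercept, slope, rate_scale)
  et <- simulate_env_trait(tr, default_env_rates(env_rate),
                           r$gain, r$loss, seed = seed + 5e7)
  tryCatch({
    fit <- suppressWarnings(fit_gee(gee_design(tr, et$traits)))
    c(beta = unname(fit$beta[2]), p = unname(fit$p_naive[2]))
  }, error = function(e) c(beta = NA_real_, p = 2))
}
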