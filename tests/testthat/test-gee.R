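raw_design <- function(y, X, R, dfP = length(y)) {
  list(y = y, X = X, R = R, dfP = dfP, labels = paste0("t", seq_along(y)),
       correlation_mode = "correlation")
}

test_that("identity working correlation reduces the GEE to logistic regression", {
  # symmetric intercept-only case: beta0 = logit(0.5) = 0
  fit <- fit_gee(raw_design(c(1, 1, 0, 0), cbind(rep(1, 4)), diag(4)))
  expect_lt(abs(fit$beta[1]), 1e-8)
  expect_true(fit$converged)
})

test_that("design assembly joins by label, drops unknowns, and prunes the tree", {
  tr <- read_newick("((A:1,B:1):0.5,(C:1,D:1):0.5,(E:1,F:1):0.5);")
  tt <- trait_table(c("F", "E", "D", "C", "B", "A"),   # shuffled on purpose
                    c("present", "absent", "present", "unknown",
                      "absent", "present"),
                    iron_level = c(0L, 2L, 1L, 1L, 2L, 0L))
  des <- gee_design(tr, tt)
  expect_identical(des$labels, c("A", "B", "D", "E", "F"))  # C dropped
  expect_equal(des$y, c(1, 0, 1, 0, 1))
  expect_equal(des$X[, 2], c(0, 2, 1, 2, 0))
  expect_equal(dim(des$R), c(5, 5))
  expect_lt(des$dfP, 5 + 1e-9)
  # covariate constant after exclusions -> rank deficiency is caught
  tt2 <- trait_table(LETTERS[1:6],
                     rep(c("present", "absent"), 3),
                     iron_level = rep(1L, 6))
  expect_error(gee_design(tr, tt2), "rank deficient")
})

test_that("degenerate responses and singular working structures are errors", {
  X <- cbind(1, c(0, 1, 2, 0, 1, 2))
  expect_error(fit_gee(raw_design(rep(1, 6), X, diag(6))), "degenerate")
  expect_error(fit_gee(raw_design(rep(0, 6), X, diag(6))), "degenerate")
  Rsing <- matrix(1, 6, 6)
  expect_error(fit_gee(raw_design(c(1, 0, 1, 0, 1, 0), X, Rsing)),
               "singular")
  # and the suggested ridge rescues it
  fit <- fit_gee(raw_design(c(1, 0, 1, 0, 1, 0), X, Rsing), ridge = 0.5)
  expect_true(fit$converged)
})

test_that("complete separation is diagnosed by name", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  tt <- trait_table(c("A", "B", "C", "D"),
                    c("present", "present", "absent", "absent"),
                    iron_level = c(0L, 0L, 2L, 2L))
  expect_error(suppressWarnings(fit_gee(gee_design(tr, tt))), "separation")
})

test_that("solution solves the estimating equations and matches a root-finding oracle", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  tt <- trait_table(c("A", "B", "C", "D"),
                    c("present", "absent", "present", "absent"),
                    iron_level = c(0L, 0L, 2L, 2L))   # both levels mixed
  des <- gee_design(tr, tt)
  fit <- fit_gee(des)
  expect_true(fit$converged)
  expect_lt(fit$eq_residual, 1e-6)
  # oracle: direct minimization of ||U(beta)||^2 with an independently
  # coded estimating function
  o <- optim(c(0, 0), function(b) sum(gee_score(b, des$y, des$X, des$R)^2),
             method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(fit$beta), o$par, tolerance = 1e-4)
})

test_that("estimating-equation residual is below tolerance across random fits", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    tr <- simulate_tree(n, seed = rep + 100)
    x <- sample(0:2, n, replace = TRUE)
    y <- rbinom(n, 1, plogis(0.5 - 0.5 * x))
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    des <- raw_design(y, cbind(1, x), vcv_from_tree(tr)$R,
                      dfP = phylo_df(tr))
    fit <- tryCatch(suppressWarnings(fit_gee(des)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    scale <- max(1, max(abs(fit$beta)))
    expect_lt(fit$eq_residual, 1e-6 * scale)
  }
})

test_that("gaussian family gives generalized least squares", {
  set.seed(5)
  tr <- simulate_tree(20, seed = 55)
  R <- vcv_from_tree(tr)$R
  x <- rnorm(20)
  y <- 1 + 0.5 * x + drop(chol(R) %*% rnorm(20)) * 0.3
  fit <- fit_gee(raw_design(y, cbind(1, x), R), family = "gaussian")
  W <- solve(R)
  Xm <- cbind(1, x)
  beta_gls <- solve(t(Xm) %*% W %*% Xm, t(Xm) %*% W %*% y)
  expect_equal(unname(fit$beta), unname(drop(beta_gls)), tolerance = 1e-8)
})

test_that("wald_report matches the t reference distribution", {
  tr <- simulate_tree(30, seed = 8)
  set.seed(8)
  x <- sample(0:2, 30, replace = TRUE)
  y <- rbinom(30, 1, plogis(1 - x))
  des <- raw_design(y, cbind(1, x), vcv_from_tree(tr)$R,
                    dfP = phylo_df(tr))
  fit <- fit_gee(des)
  w <- wald_report(fit, 2)
  expect_equal(w$statistic, unname(fit$beta[2] / fit$se_naive[2]))
  expect_equal(w$df, fit$dfP - 2)
  expect_equal(w$p, 2 * pt(abs(w$statistic), w$df, lower.tail = FALSE))
  # robust variant uses the sandwich SE
  wr <- wald_report(fit, 2, se = "robust")
  expect_equal(wr$statistic, unname(fit$beta[2] / fit$se_robust[2]))
  expect_error(wald_report(fit, 9), "out of range")
  # limits of the p-value as the statistic moves
  mock <- fit
  mock$beta[2] <- 0
  expect_equal(wald_report(mock, 2)$p, 1)
  mock$beta[2] <- 1e6
  expect_lt(wald_report(mock, 2)$p, 1e-10)
})

test_that("fit report serializes to JSON with both SE flavors", {
  tr <- simulate_tree(25, seed = 8)
  set.seed(8)
  x <- sample(0:2, 25, replace = TRUE)
  y <- rbinom(25, 1, plogis(1 - x))
  fit <- fit_gee(raw_design(y, cbind(1, x), vcv_from_tree(tr)$R,
                            dfP = phylo_df(tr)))
  rep <- jsonlite::fromJSON(gee_report_json(fit))
  expect_equal(unlist(rep$coefficients), fit$beta, tolerance = 1e-12)
  expect_true(all(unlist(rep$se_robust) > 0))
  expect_true(rep$converged)
})
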