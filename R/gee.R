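#' Assemble a phylogenetic GEE design
#'
#' Joins a trait table to a tree by tip label (never by position), drops
#' organisms with unknown gene state or missing covariate, prunes the tree
#' to the retained tips, and packages the response, design matrix and
#' working correlation for [fit_gee()].  The phylogenetic degrees of
#' freedom are computed on the pruned tree.
#'
#' @param tree A `"phylo"` object; tips are matched to
#'   `traits$organism_id`.
#' @param traits A `"trait_table"`.  Rows with `fld_state == "unknown"` or
#'   `NA` covariate never enter the design.
#' @param covariate Column of `traits` used as the explanatory variable;
#'   default `"iron_level"`.
#' @param correlation_mode `"correlation"` (phylogenetic correlation matrix,
#'   unit diagonal, the default) or `"covariance"` (raw shared-path
#'   covariance) as the working structure.  The two differ for
#'   non-ultrametric trees; dispersion scaling absorbs the overall factor.
#' @param categorical If `TRUE` the covariate enters as dummy-coded factor
#'   levels instead of a single ordinal-as-linear numeric column.
#' @return An object of class `"gee_design"`: list with `y`, `X`, `R`,
#'   `labels`, `dfP`, `tree`, `correlation_mode`.
#' @export
gee_design <- function(tree, traits, covariate = "iron_level",
                       correlation_mode = c("correlation", "covariance"),
                       categorical = FALSE) {
  correlation_mode <- match.arg(correlation_mode)
  tree <- validate_phylogeny(tree)
  validate_trait_table(traits)
  if (!covariate %in% names(traits))
    stop("covariate column not in trait table: ", covariate)
  tt <- traits[match(tree$tip.label, traits$organism_id), , drop = FALSE]
  usable <- !is.na(tt$organism_id) & tt$fld_state != "unknown" &
    !is.na(tt[[covariate]])
  keep <- tree$tip.label[usable]
  if (length(keep) < 3L)
    stop("fewer than 3 usable tips after excluding unknowns")
  ptree <- ape::keep.tip(tree, keep)
  tt <- traits[match(ptree$tip.label, traits$organism_id), , drop = FALSE]
  y <- as.integer(tt$fld_state == "present")
  xv <- tt[[covariate]]
  X <- if (categorical) {
    stats::model.matrix(~ factor(xv))
  } else {
    cbind(1, as.numeric(xv))
  }
  colnames(X) <- if (categorical) {
    c("(Intercept)", paste0(covariate, levels(factor(xv))[-1]))
  } else {
    c("(Intercept)", covariate)
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (covariate constant?)")
  pv <- vcv_from_tree(ptree)
  R <- if (correlation_mode == "correlation") pv$R else pv$V
  structure(list(y = y, X = X, R = R, labels = ptree$tip.label,
                 dfP = phylo_df(ptree), tree = ptree,
                 correlation_mode = correlation_mode),
            class = "gee_design")
}

#' Fit a generalized estimating equation with phylogenetic correlation
#'
#' Solves the estimating equations
#' \deqn{U(\beta) = D^\top V^{-1} (y - \mu) = 0,}
#' with mean \eqn{\mu = g^{-1}(X\beta)} (logistic or identity link),
#' \eqn{V = \phi A^{1/2} R A^{1/2}}, \eqn{A} the variance function
#' (\eqn{\mu(1-\mu)} for binomial) and \eqn{R} the working correlation
#' supplied by the phylogeny, by Fisher-scoring iterations until the
#' relative change in \eqn{\beta} falls below `tol`.  The dispersion
#' \eqn{\phi} is estimated from Pearson residuals.  Because all tips form a
#' single correlated cluster, the classical cluster-level sandwich is
#' degenerate; `se_robust` therefore uses an observation-level sandwich
#' (squared working residuals as the meat), while `se_naive` is the
#' model-based standard error.  Wald p-values are two-sided from a t
#' distribution on `dfP - p` degrees of freedom, where `dfP` are the
#' phylogenetic degrees of freedom ([phylo_df()]) — the correction that
#' keeps the test honest when tips are effectively fewer than `n`
#' independent observations.
#'
#' @param design A `"gee_design"` from [gee_design()], or a list with
#'   fields `y`, `X`, `R` (and optionally `dfP`, `labels`,
#'   `correlation_mode`).
#' @param family `"binomial"` (logit link, the default) or `"gaussian"`
#'   (identity link).
#' @param max_iter Maximum Fisher-scoring iterations (default 100).
#' @param tol Relative convergence tolerance on the coefficients
#'   (default 1e-8).
#' @param ridge Non-negative jitter added to the diagonal of the working
#'   structure when it is numerically singular (default 0 = off).
#' @param p_se Which standard error feeds the reported `p_values`:
#'   `"naive"` (model-based, the default, matching the comparative-GEE
#'   method this package follows) or `"robust"`.
#' @return An object of class `"gee_fit"`; see Details for fields.
#' @details Fields of the returned object: `beta`, `se_naive`, `se_robust`,
#'   `phi`, `dfP`, `wald` (statistic on the `p_se` scale), `p_values`,
#'   `p_naive`, `p_robust`, `converged`, `n_iter`, `eq_residual`
#'   (max abs estimating-equation component at the solution), `fitted`,
#'   `residuals` (Pearson), `vcov_naive`, `vcov_robust`,
#'   `correlation_mode`, `family`, `labels`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tt <- trait_table(c("A","B","C","D"),
#'                   c("present","present","absent","absent"),
#'                   iron_level = c(0L, 0L, 2L, 2L))
#' \dontrun{fit_gee(gee_design(tr, tt))}  # separates: 2 distinct x values
#' @export
fit_gee <- function(design, family = c("binomial", "gaussian"),
                    max_iter = 100L, tol = 1e-8, ridge = 0,
                    p_se = c("naive", "robust")) {
  family <- match.arg(family)
  p_se <- match.arg(p_se)
  stopifnot(tol > 0, max_iter >= 1)
  y <- design$y; X <- as.matrix(design$X); R <- as.matrix(design$R)
  n <- length(y); p <- ncol(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- rep("", p)
  cn[!nzchar(cn)] <- paste0("beta", which(!nzchar(cn)) - 1L)
  colnames(X) <- cn
  if (nrow(X) != n || any(dim(R) != n))
    stop("dimensions of y, X and R disagree")
  if (family == "binomial") {
    if (!all(y %in% c(0, 1))) stop("binomial response must be 0/1")
    if (all(y == 0) || all(y == 1))
      stop("degenerate response: all observations are ", y[1],
           "; the association is not estimable")
  }
  if (ridge > 0) R <- R + diag(ridge, n)
  dfP <- if (!is.null(design$dfP)) design$dfP else n

  # score U, scoring matrix J and mean pieces at a given beta
  ee_parts <- function(beta) {
    eta <- drop(X %*% beta)
    if (family == "binomial") {
      mu <- stats::plogis(eta)
      A <- pmax(mu * (1 - mu), 1e-12)
    } else {
      mu <- eta
      A <- rep(1, n)
    }
    sA <- sqrt(A)
    V0 <- R * outer(sA, sA)
    D <- X * A                     # dmu/dbeta rows; for gaussian A = 1
    T1 <- tryCatch(solve(V0, cbind(D, y - mu)),
                   error = function(e)
                     stop("working covariance is singular (",
                          conditionMessage(e),
                          "); consider the ridge argument"))
    list(eta = eta, mu = mu, A = A, sA = sA, V0 = V0, D = D,
         J = crossprod(D, T1[, seq_len(p), drop = FALSE]),
         U = drop(crossprod(D, T1[, p + 1L])),
         T1 = T1)
  }

  # start from the independence-model fit: Fisher scoring then only has to
  # absorb the working correlation
  beta <- if (family == "binomial") {
    suppressWarnings(stats::glm.fit(X, y,
                                    family = stats::binomial())$coefficients)
  } else {
    stats::lm.fit(X, y)$coefficients
  }
  beta[!is.finite(beta)] <- 0
  at_root <- function(parts, b)
    max(abs(parts$U)) < 1e-6 * max(1, max(abs(b)))
  converged <- FALSE
  iter <- 0L
  cur <- ee_parts(beta)
  repeat {
    iter <- iter + 1L
    delta <- drop(solve(cur$J, cur$U))
    # step-halving with an Armijo-type decrease requirement on the
    # estimating-function norm: plain Fisher scoring overshoots on
    # near-separated binomial data
    step <- 1
    unorm <- sqrt(sum(cur$U^2))
    stalled <- FALSE
    repeat {
      cand <- beta + step * delta
      trial <- ee_parts(cand)
      if (sqrt(sum(trial$U^2)) <= unorm * (1 - 0.01 * step)) break
      step <- step / 2
      if (step < 1e-10) { stalled <- TRUE; break }
    }
    if (stalled) break                 # scoring direction exhausted
    beta <- cand
    cur <- trial
    rel <- max(abs(step * delta)) / max(1, max(abs(beta)))
    if (rel < tol && at_root(cur, beta)) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged && max(abs(cur$eta)) <= 20) {
    # scoring stalled away from a separation ray: finish by direct
    # minimization of the squared estimating function, with restarts
    # because BFGS quits on relative progress long before the root
    objective <- function(b) sum(ee_parts(b)$U^2)
    b_try <- beta
    for (round in 1:5) {
      o <- stats::optim(b_try, objective, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-16,
                                       abstol = 0))
      o <- stats::optim(o$par, objective,
                        control = list(maxit = 2000, reltol = 1e-16))
      b_try <- o$par
      cand <- ee_parts(b_try)
      if (sum(cand$U^2) <= sum(cur$U^2)) { beta <- b_try; cur <- cand }
      if (at_root(cur, beta)) break
    }
    converged <- at_root(cur, beta)
  }
  if (family == "binomial" && !converged && max(abs(cur$eta)) > 20)
    stop("apparent complete separation: fitted probabilities pinned at ",
         "0/1 and coefficients diverging without bound")
  if (!converged)
    warning("GEE did not converge in ", max_iter, " iterations")

  mu <- cur$mu; sA <- cur$sA
  J <- cur$J; U <- cur$U
  T1 <- cur$T1
  pearson <- (y - mu) / sA
  phi <- sum(pearson^2) / (n - p)
  Jinv <- solve(J)
  vcov_naive <- phi * Jinv
  Tm <- T1[, seq_len(p), drop = FALSE]          # V0^{-1} D
  meat <- crossprod(Tm * (y - mu))              # obs-level sandwich meat
  vcov_robust <- Jinv %*% meat %*% Jinv
  se_naive <- sqrt(diag(vcov_naive))
  se_robust <- sqrt(pmax(diag(vcov_robust), 0))
  df_t <- dfP - p
  if (df_t <= 0) {
    warning("phylogenetic degrees of freedom do not exceed the number of ",
            "coefficients; p-values set to NA")
    p_naive <- p_robust <- rep(NA_real_, p)
  } else {
    p_naive <- 2 * stats::pt(abs(beta / se_naive), df = df_t,
                             lower.tail = FALSE)
    p_robust <- 2 * stats::pt(abs(beta / se_robust), df = df_t,
                              lower.tail = FALSE)
  }
  se_used <- if (p_se == "naive") se_naive else se_robust
  fit <- list(beta = stats::setNames(drop(beta), colnames(X)),
              se_naive = stats::setNames(se_naive, colnames(X)),
              se_robust = stats::setNames(se_robust, colnames(X)),
              phi = phi, dfP = dfP,
              wald = stats::setNames(drop(beta) / se_used, colnames(X)),
              p_values = if (p_se == "naive") p_naive else p_robust,
              p_naive = p_naive, p_robust = p_robust, p_se = p_se,
              converged = converged, n_iter = iter,
              eq_residual = max(abs(U)),
              fitted = mu, residuals = pearson,
              vcov_naive = vcov_naive, vcov_robust = vcov_robust,
              correlation_mode = design$correlation_mode %||% "supplied",
              family = family, n = n, labels = design$labels)
  class(fit) <- "gee_fit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald test for one coefficient of a GEE fit
#'
#' Two-sided t test of `beta[coef] = 0` against a t distribution with
#' `dfP - p` degrees of freedom, where `dfP` are the phylogenetic degrees
#' of freedom and `p` the number of coefficients.
#'
#' @param fit A converged `"gee_fit"`.
#' @param coef_index Coefficient position (or name).
#' @param se `"naive"` or `"robust"` standard error; defaults to the one
#'   the fit used for its reported p-values.
#' @return List with `statistic`, `df`, `p`.
#' @export
wald_report <- function(fit, coef_index, se = fit$p_se) {
  if (!inherits(fit, "gee_fit")) stop("not a gee_fit")
  if (!fit$converged) stop("fit did not converge; Wald test not reported")
  if (is.character(coef_index)) coef_index <- match(coef_index, names(fit$beta))
  if (is.na(coef_index) || coef_index < 1 || coef_index > length(fit$beta))
    stop("coefficient index out of range")
  sev <- if (se == "naive") fit$se_naive else fit$se_robust
  stat <- fit$beta[coef_index] / sev[coef_index]
  df <- fit$dfP - length(fit$beta)
  list(statistic = unname(stat), df = df,
       p = unname(2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)))
}

#' @export
print.gee_fit <- function(x, digits = 4, ...) {
  cat("Phylogenetic GEE fit (", x$family, " family, working ",
      x$correlation_mode, ")\n", sep = "")
  tab <- data.frame(estimate = x$beta, se_naive = x$se_naive,
                    se_robust = x$se_robust, p = x$p_values)
  print(round(tab, digits))
  cat("phi =", format(x$phi, digits = digits),
      "  dfP =", format(x$dfP, digits = digits),
      "  iterations =", x$n_iter,
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) {
  print(object, ...)
  cat("max |estimating equation| at solution:",
      format(object$eq_residual, digits = 3), "\n")
  invisible(object)
}

#' Serialize a GEE fit report to JSON
#'
#' Machine-readable fit report: coefficients, both standard errors, both
#' p-value sets, dispersion, phylogenetic df, convergence metadata.
#'
#' @param fit A `"gee_fit"`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @export
gee_report_json <- function(fit, path = NULL) {
  rep <- list(coefficients = as.list(fit$beta),
              se_naive = as.list(fit$se_naive),
              se_robust = as.list(fit$se_robust),
              p_naive = as.list(stats::setNames(fit$p_naive, names(fit$beta))),
              p_robust = as.list(stats::setNames(fit$p_robust, names(fit$beta))),
              p_se = fit$p_se,
              phi = fit$phi, dfP = fit$dfP, n = fit$n,
              converged = fit$converged, n_iter = fit$n_iter,
              eq_residual = fit$eq_residual,
              correlation_mode = fit$correlation_mode,
              family = fit$family)
  if (is.null(path))
    return(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
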