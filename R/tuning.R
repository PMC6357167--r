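#' Cross-validation fold assignment
#'
#' Leave-one-study-out (LOSOCV): one fold per study, testing cross-cohort
#' transfer. Leave-one-out (LOOCV): one fold per sample.
#'
#' @param studies study id per sample.
#' @param mode `"LOSOCV"` or `"LOOCV"`.
#' @return factor of fold ids, one per sample.
#' @export
cv_folds <- function(studies, mode = c("LOSOCV", "LOOCV")) {
  mode <- match.arg(mode)
  if (mode == "LOSOCV") factor(studies) else factor(seq_along(studies))
}

#' Cross-validated binomial deviance at fixed (alpha, lambda)
#'
#' For each fold, an elastic-net model is fitted on the remaining folds and
#' the binomial deviance of its predictions on the held-out fold is recorded;
#' the mean and its standard error across folds are returned.
#'
#' @param X samples x features matrix (PDS features).
#' @param y binary labels.
#' @param folds fold id per sample (see [cv_folds()]).
#' @param alpha,lambda elastic-net parameters.
#' @param ... passed to [fit_elastic_net()].
#' @return list `mean`, `se`, `per_fold`.
#' @export
cv_deviance <- function(X, y, folds, alpha, lambda, ...) {
  X <- as.matrix(X)
  y <- label_to_binary(y)
  folds <- factor(folds)
  if (nlevels(folds) < 2) stop("need at least 2 folds")
  per_fold <- vapply(levels(folds), function(f) {
    test <- folds == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2)
      stop("training data for fold '", f, "' lacks one class")
    model <- fit_elastic_net(X[!test, , drop = FALSE], ytr, alpha, lambda, ...)
    p <- predict_proba(model, X[test, , drop = FALSE])
    binomial_deviance(y[test], pmin(1 - 1e-12, pmax(1e-12, p)))
  }, 0)
  list(mean = mean(per_fold),
       se = sd(per_fold) / sqrt(length(per_fold)),
       per_fold = per_fold)
}

#' Global optimization by Gaussian-process expected improvement (EPSGO)
#'
#' Efficient parameter selection via global optimization: a Latin-hypercube
#' initial design is evaluated, then a Gaussian-process surrogate (anisotropic
#' squared-exponential kernel with an observation-noise nugget, hyperparameters
#' refit each iteration by maximizing the marginal likelihood) proposes the
#' next point by maximizing expected improvement (EI). Stops at the evaluation
#' budget or when the best achievable EI drops below `ei_tol` times the
#' observed objective range. Far fewer evaluations than a dense grid are
#' needed for smooth 2-D surfaces such as a CV-deviance landscape.
#'
#' @param objective function of a numeric vector (length d) returning a scalar
#'   value to minimize, or a list with elements `value` and `se`.
#' @param lower,upper numeric vectors delimiting the search box; names are
#'   carried into the trace.
#' @param budget total number of objective evaluations allowed.
#' @param n_init initial Latin-hypercube design size (default `5 * d`).
#' @param seed integer seed; the whole search is deterministic given it.
#' @param ei_tol relative expected-improvement stopping tolerance.
#' @return list with `trace` (data.frame of evaluated points, objective value,
#'   SE, provenance), `best_x`, `best_value`.
#' @export
epsgo_optimize <- function(objective, lower, upper, budget = 50L,
                           n_init = NULL, seed = 1L, ei_tol = 1e-4) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(c(lower, upper))),
            all(upper >= lower))
  if (is.null(n_init)) n_init <- 5L * d
  n_init <- min(n_init, budget)
  width <- upper - lower
  par_names <- names(lower)
  if (is.null(par_names)) par_names <- paste0("x", seq_len(d))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  denorm <- function(u) lower + u * width
  eval_point <- function(u, provenance) {
    res <- objective(denorm(u))
    out <- if (is.list(res)) list(value = res$value, se = res$se %||% NA_real_,
                                  provenance = provenance)
    else list(value = res, se = NA_real_, provenance = provenance)
    if (!is.finite(out$value)) {
      warning("non-finite objective value excluded from the surrogate",
              call. = FALSE)
      out$value <- NA_real_
    }
    out
  }

  if (all(width == 0)) {
    r <- eval_point(rep(0, d), "initial_design")
    trace <- data.frame(matrix(lower, 1L, dimnames = list(NULL, par_names)),
                        value = r$value, se = r$se,
                        provenance = "initial_design")
    return(list(trace = trace, best_x = setNames(lower, par_names),
                best_value = r$value))
  }

  U <- as.matrix(lhs::maximinLHS(n_init, d))
  U[, width == 0] <- 0
  evals <- lapply(seq_len(n_init), function(i) eval_point(U[i, ], "initial_design"))

  while (nrow(U) < budget) {
    vals <- vapply(evals, `[[`, 0, "value")
    ok <- is.finite(vals)
    # a flat observed surface offers no expected improvement
    if (sum(ok) >= n_init && diff(range(vals[ok])) < 1e-12) break
    if (sum(ok) < 2) {
      u_next <- runif(d); u_next[width == 0] <- 0
    } else {
      gp <- gp_fit(U[ok, , drop = FALSE], vals[ok])
      fmin <- min(vals[ok])
      rng <- max(diff(range(vals[ok])), 1e-12)
      cand <- as.matrix(lhs::randomLHS(512, d))
      cand[, width == 0] <- 0
      ei <- gp_expected_improvement(gp, cand, fmin)
      top <- order(ei, decreasing = TRUE)[1:3]
      refined <- lapply(top, function(i) {
        o <- optim(cand[i, ], function(u) {
          u <- pmin(1, pmax(0, u))
          -gp_expected_improvement(gp, matrix(u, 1L), fmin)
        }, method = "L-BFGS-B", lower = rep(0, d), upper = rep(1, d))
        list(u = pmin(1, pmax(0, o$par)), ei = -o$value)
      })
      best <- refined[[which.max(vapply(refined, `[[`, 0, "ei"))]]
      if (best$ei < ei_tol * rng) break
      u_next <- best$u
      u_next[width == 0] <- 0
      # avoid degenerate re-evaluation of an existing design point
      if (min(sqrt(rowSums(sweep(U, 2L, u_next)^2))) < 1e-9) {
        u_next <- runif(d); u_next[width == 0] <- 0
      }
    }
    r <- tryCatch(eval_point(u_next, "gp_iteration"), error = function(e) {
      warning("objective evaluation failed: ", conditionMessage(e),
              call. = FALSE)
      list(value = NA_real_, se = NA_real_, provenance = "gp_iteration")
    })
    U <- rbind(U, u_next)
    evals <- c(evals, list(r))
  }

  vals <- vapply(evals, `[[`, 0, "value")
  X <- sweep(sweep(U, 2L, width, `*`), 2L, lower, `+`)
  colnames(X) <- par_names
  trace <- data.frame(X,
                      value = vals,
                      se = vapply(evals, `[[`, 0, "se"),
                      provenance = vapply(evals, `[[`, "", "provenance"))
  ok <- which(is.finite(vals))
  best <- ok[which.min(vals[ok])]
  list(trace = trace,
       best_x = setNames(as.numeric(X[best, ]), par_names),
       best_value = vals[best])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Gaussian-process surrogate ------------------------------------------

gp_kernel <- function(X1, X2, ls, sf2) {
  D <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(ncol(X1)))
    D <- D + outer(X1[, j], X2[, j], `-`)^2 / ls[j]^2
  sf2 * exp(-0.5 * D)
}

# Fit kernel hyperparameters by maximizing the log marginal likelihood,
# multi-started from fixed configurations for determinism.
gp_fit <- function(X, y, jitter = 1e-10) {
  mu <- mean(y); sdy <- sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  d <- ncol(X); n <- nrow(X)

  nll <- function(theta) {
    ls <- exp(theta[seq_len(d)]); sf2 <- exp(theta[d + 1]); sn2 <- exp(theta[d + 2])
    K <- gp_kernel(X, X, ls, sf2) + diag(sn2 + jitter, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, forwardsolve(t(L), ys))
    0.5 * sum(ys * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }
  lowerb <- c(rep(log(0.02), d), -8, -14)
  upperb <- c(rep(log(10), d), 6, 1)
  starts <- list(c(rep(log(0.3), d), 0, log(1e-4)),
                 c(rep(log(1), d), 0, log(1e-2)),
                 c(rep(log(0.1), d), 0, log(1e-6)))
  fits <- lapply(starts, function(s)
    tryCatch(optim(s, nll, method = "L-BFGS-B", lower = lowerb, upper = upperb),
             error = function(e) list(value = Inf, par = s)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  ls <- exp(best$par[seq_len(d)]); sf2 <- exp(best$par[d + 1])
  sn2 <- exp(best$par[d + 2])
  K <- gp_kernel(X, X, ls, sf2) + diag(sn2 + jitter, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, ls = ls, sf2 = sf2, sn2 = sn2,
       mu = mu, sdy = sdy)
}

gp_predict <- function(gp, Xnew) {
  Ks <- gp_kernel(Xnew, gp$X, gp$ls, gp$sf2)
  mean_s <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  var_s <- pmax(gp$sf2 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sdy * mean_s, sd = gp$sdy * sqrt(var_s))
}

gp_expected_improvement <- function(gp, Xnew, fmin) {
  pr <- gp_predict(gp, Xnew)
  z <- (fmin - pr$mean) / pr$sd
  ei <- (fmin - pr$mean) * stats::pnorm(z) + pr$sd * stats::dnorm(z)
  pmax(ei, 0)
}

# ---- top-level tuning -----------------------------------------------------

#' Tune (alpha, log lambda) by EPSGO under cross-validated deviance
#'
#' Runs [epsgo_optimize()] with the mean CV binomial deviance as objective
#' over the `(alpha, log lambda)` box. Besides the minimum-deviance point, the
#' one-standard-error choice is reported: at the selected alpha, the largest
#' lambda whose mean CV deviance stays within one standard error of the
#' minimum — the most penalized (sparsest) model statistically
#' indistinguishable from the best. Exact deviance ties prefer larger lambda,
#' then larger alpha.
#'
#' @param X samples x features PDS matrix.
#' @param y binary labels.
#' @param folds fold assignment (see [cv_folds()]).
#' @param alpha_bounds,log_lambda_bounds search box (defaults alpha in
#'   `[0.01, 1]`, log lambda in `[-8, 2]`).
#' @param budget,n_init,seed passed to [epsgo_optimize()].
#' @param n_lambda_1se grid resolution of the 1SE lambda scan.
#' @return list with `at_min_deviance`, `at_1se` (each `alpha`, `lambda`),
#'   `min_deviance`, `se_at_min`, `threshold_1se`, and the EPSGO `trace`.
#' @export
tune_elastic_net <- function(X, y, folds,
                             alpha_bounds = c(0.01, 1),
                             log_lambda_bounds = c(-8, 2),
                             budget = 50L, n_init = 10L, seed = 1L,
                             n_lambda_1se = 25L) {
  objective <- function(par) {
    cv <- cv_deviance(X, y, folds, alpha = par[1], lambda = exp(par[2]))
    list(value = cv$mean, se = cv$se)
  }
  opt <- epsgo_optimize(objective,
                        lower = c(alpha = alpha_bounds[1],
                                  log_lambda = log_lambda_bounds[1]),
                        upper = c(alpha = alpha_bounds[2],
                                  log_lambda = log_lambda_bounds[2]),
                        budget = budget, n_init = n_init, seed = seed)
  tr <- opt$trace[is.finite(opt$trace$value), , drop = FALSE]
  # exact-tie preference: larger lambda, then larger alpha (sparser model)
  tr_ord <- tr[order(tr$value, -tr$log_lambda, -tr$alpha), , drop = FALSE]
  best <- tr_ord[1L, ]
  alpha_hat <- best$alpha
  lambda_hat <- exp(best$log_lambda)
  cv_best <- cv_deviance(X, y, folds, alpha_hat, lambda_hat)
  threshold <- cv_best$mean + cv_best$se

  # 1SE rule: scan upward in lambda at the selected alpha
  ll_grid <- seq(best$log_lambda, log_lambda_bounds[2],
                 length.out = n_lambda_1se)
  lambda_1se <- lambda_hat
  for (ll in ll_grid[-1]) {
    m <- cv_deviance(X, y, folds, alpha_hat, exp(ll))$mean
    if (m <= threshold) lambda_1se <- exp(ll)
  }

  list(at_min_deviance = list(alpha = alpha_hat, lambda = lambda_hat),
       at_1se = list(alpha = alpha_hat, lambda = lambda_1se),
       min_deviance = cv_best$mean,
       se_at_min = cv_best$se,
       threshold_1se = threshold,
       trace = opt$trace)
}
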