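#' Convert resistance labels to the 0/1 coding used by the classifier
#'
#' Acquired resistance (`AR`) is the positive class (1); sensitive (`S`) is 0.
#' Numeric/logical 0-1 vectors pass through.
#'
#' @param y labels: `"AR"`/`"S"`, factor thereof, or 0/1.
#' @return integer vector of 0/1.
#' @export
label_to_binary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("AR", "S"))) stop("labels must be 'AR' or 'S'")
    return(as.integer(y == "AR"))
  }
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(y)
}

#' Fit a binomial elastic-net model at fixed (alpha, lambda)
#'
#' Minimizes the penalized negative log-likelihood
#' \deqn{-\frac{1}{n}\sum_i \ell_i(\beta_0,\beta) +
#'       \lambda\left[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right]}
#' by coordinate descent (glmnet), warm-started along a short path down to the
#' requested `lambda` for solution accuracy. `alpha` mixes the lasso (1) and
#' ridge (0) penalties; the intercept is never penalized. When
#' `standardize = TRUE` (default) features are standardized internally and
#' coefficients are reported back on the original scale.
#'
#' @param X samples x features numeric matrix (e.g. the transposed PDS
#'   matrix).
#' @param y binary labels (see [label_to_binary()]); both classes required.
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param lambda penalty strength, > 0.
#' @param standardize standardize features before fitting.
#' @param thresh coordinate-descent convergence threshold.
#' @return object of class `elastic_net_model`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, standardize = TRUE,
                            thresh = 1e-12) {
  X <- as.matrix(X)
  y <- label_to_binary(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, function(x) sqrt(mean((x - mean(x))^2)))
    scl[scl == 0] <- 1
  } else {
    center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, `/`)

  lam_seq <- warm_lambda_sequence(Xs, y, alpha, lambda)
  # class balance is validated above; glmnet's small-class caution is noise
  fit <- quiet_glmnet(Xs, y, alpha = alpha, lambda = lam_seq, thresh = thresh)
  beta_std <- as.numeric(fit$beta[, length(lam_seq)])
  b0_std <- fit$a0[length(lam_seq)]

  beta <- beta_std / scl
  intercept <- b0_std - sum(beta * center)

  model <- structure(list(
    intercept = unname(intercept),
    coefficients = setNames(beta, colnames(X)),
    alpha = alpha, lambda = lambda,
    feature_order = colnames(X),
    standardize = standardize, center = center, scale = scl,
    std_intercept = unname(b0_std),
    std_coefficients = setNames(beta_std, colnames(X))
  ), class = "elastic_net_model")

  # returned fit can never be worse than the null (all-zero) model
  obj <- elastic_net_objective(Xs, y, b0_std, beta_std, alpha, lambda)
  null_obj <- elastic_net_objective(Xs, y, qlogis(mean(y)),
                                    rep(0, ncol(Xs)), alpha, lambda)
  stopifnot(obj <= null_obj + 1e-8)
  model
}

quiet_glmnet <- function(Xs, y, alpha, lambda, thresh) {
  withCallingHandlers(
    glmnet::glmnet(Xs, y, family = "binomial", alpha = alpha,
                   lambda = lambda, standardize = FALSE, thresh = thresh),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Decreasing log-spaced warm-start sequence ending exactly at lambda.
warm_lambda_sequence <- function(Xs, y, alpha, lambda, n = 25L) {
  n_obs <- length(y)
  g0 <- abs(crossprod(Xs, y - mean(y))) / n_obs
  lam_max <- max(g0) / max(alpha, 1e-3)
  if (lambda >= lam_max) return(lambda)
  exp(seq(log(lam_max), log(lambda), length.out = n))
}

#' Penalized binomial objective
#'
#' The quantity minimized by [fit_elastic_net()]: mean negative log-likelihood
#' plus the elastic-net penalty (intercept unpenalized).
#'
#' @param X samples x features matrix (on the scale the model was fitted on).
#' @param y 0/1 labels.
#' @param intercept,beta model parameters.
#' @param alpha,lambda penalty parameters.
#' @return scalar objective value.
#' @export
elastic_net_objective <- function(X, y, intercept, beta, alpha, lambda) {
  eta <- intercept + as.numeric(X %*% beta)
  # -loglik: log(1 + e^eta) - y*eta, computed stably
  nll <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  nll + lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Karush-Kuhn-Tucker residual of a fitted elastic-net model
#'
#' Maximum violation of the stationarity conditions (subgradient check for the
#' l1 part), evaluated on the internal standardized scale the model was fit
#' on. A well-converged fit has a residual near zero.
#'
#' @param model an `elastic_net_model`.
#' @param X,y the training data.
#' @return scalar maximum KKT violation.
#' @export
kkt_residual <- function(model, X, y) {
  y <- label_to_binary(y)
  Xs <- sweep(sweep(as.matrix(X), 2L, model$center), 2L, model$scale, `/`)
  beta <- model$std_coefficients
  p <- plogis(model$std_intercept + as.numeric(Xs %*% beta))
  g <- -as.numeric(crossprod(Xs, y - p)) / length(y)
  lam <- model$lambda; a <- model$alpha
  r_int <- abs(mean(p - y))
  smooth <- g + lam * (1 - a) * beta
  active <- beta != 0
  r <- numeric(length(beta))
  r[active] <- abs(smooth[active] + lam * a * sign(beta[active]))
  r[!active] <- pmax(0, abs(smooth[!active]) - lam * a)
  max(r_int, r)
}

#' Predicted probabilities of acquired resistance
#'
#' Logistic transform of the linear predictor; the model's feature order must
#' match the columns of `X`.
#'
#' @param model an `elastic_net_model`.
#' @param X samples x features matrix.
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$feature_order))
      stop("feature count mismatch: model has ", length(model$feature_order),
           ", data has ", ncol(X))
  } else {
    missing <- setdiff(model$feature_order, colnames(X))
    if (length(missing))
      stop("features missing from data: ", paste(missing, collapse = ", "))
    X <- X[, model$feature_order, drop = FALSE]
  }
  p <- plogis(model$intercept + as.numeric(X %*% model$coefficients))
  names(p) <- rownames(X)
  p
}

#' Binomial deviance of predicted probabilities
#'
#' `-2 x` mean Bernoulli log-likelihood; zero only for perfectly confident
#' correct predictions. Probabilities at exactly 0 or 1 are clipped to
#' `1e-12` with a warning.
#'
#' @param y binary labels.
#' @param p probabilities in `[0, 1]`.
#' @return non-negative scalar.
#' @export
binomial_deviance <- function(y, p) {
  y <- label_to_binary(y)
  if (length(y) != length(p)) stop("y and p lengths differ")
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities at 0/1 clipped to 1e-12", call. = FALSE)
    p <- pmin(1 - 1e-12, pmax(1e-12, p))
  }
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit an elastic-net regularization path
#'
#' Coefficients over a decreasing log-spaced lambda sequence from
#' `lambda_max` (smallest lambda with an all-zero solution, computed from the
#' gradient at the null model) down to `lambda_max * lambda_min_ratio`, with
#' warm starts.
#'
#' @inheritParams fit_elastic_net
#' @param n_lambda number of path points (>= 2).
#' @param lambda_min_ratio ratio of smallest to largest lambda.
#' @return object of class `regularization_path`: `lambda`, `intercepts`,
#'   `coefficients` (features x lambda, original scale), `n_nonzero`.
#' @export
fit_path <- function(X, y, alpha, n_lambda = 100L, lambda_min_ratio = 1e-4,
                     standardize = TRUE, thresh = 1e-12) {
  X <- as.matrix(X)
  y <- label_to_binary(y)
  if (n_lambda < 2) stop("n_lambda must be >= 2")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, function(x) sqrt(mean((x - mean(x))^2)))
    scl[scl == 0] <- 1
  } else {
    center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, `/`)
  g0 <- abs(crossprod(Xs, y - mean(y))) / length(y)
  # nudged above the exact threshold so the first solution is exactly null
  lam_max <- max(g0) / max(alpha, 1e-3) * (1 + 1e-6)
  lam <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                 length.out = n_lambda))
  fit <- quiet_glmnet(Xs, y, alpha = alpha, lambda = lam, thresh = thresh)
  beta <- as.matrix(fit$beta) / scl
  intercepts <- as.numeric(fit$a0) - colSums(beta * center)
  structure(list(lambda = lam, alpha = alpha,
                 intercepts = intercepts, coefficients = beta,
                 n_nonzero = colSums(beta != 0),
                 feature_order = colnames(X)),
            class = "regularization_path")
}

#' Non-zero coefficients of a model, largest first
#'
#' @param model an `elastic_net_model`.
#' @return data.frame `pathway_id`, `coefficient`, sorted in descending order
#'   of the coefficient.
#' @export
nonzero_features <- function(model) {
  b <- model$coefficients[model$coefficients != 0]
  out <- data.frame(pathway_id = names(b), coefficient = unname(b),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$coefficient), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize an elastic-net model to JSON
#'
#' @param model an `elastic_net_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  nz <- model$coefficients[model$coefficients != 0]
  jsonlite::write_json(list(
    intercept = model$intercept, alpha = model$alpha, lambda = model$lambda,
    coefficients = as.list(nz), feature_order = model$feature_order,
    standardize = model$standardize,
    center = as.list(setNames(model$center, model$feature_order)),
    scale = as.list(setNames(model$scale, model$feature_order))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
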