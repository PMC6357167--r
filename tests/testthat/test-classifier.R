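random_problem <- function(n = 20, p = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(rnorm(3), rep(0, p - 3))
  y <- as.integer(plogis(X %*% beta) > runif(n))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}

# independent oracle: generic derivative-free/quasi-Newton minimization of
# the same penalized likelihood, polished with a simplex pass because BFGS
# stalls at the l1 kinks; the coordinate-descent fit may end slightly BELOW
# this oracle, never above it
oracle_objective <- function(X, y, alpha, lambda) {
  p <- ncol(X)
  obj <- function(par) elastic_net_objective(X, y, par[1], par[-1],
                                             alpha, lambda)
  fit <- optim(rep(0, p + 1), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  fit$value
}

test_that("fitted objective matches a generic optimizer on random problems", {
  for (seed in 1:10) {
    pr <- random_problem(seed = seed)
    alpha <- 0.5; lambda <- 0.1
    model <- fit_elastic_net(pr$X, pr$y, alpha, lambda, standardize = FALSE)
    ours <- elastic_net_objective(pr$X, pr$y, model$intercept,
                                  model$coefficients, alpha, lambda)
    ref <- oracle_objective(pr$X, pr$y, alpha, lambda)
    expect_lt(ours - ref, 1e-4)   # never worse than the generic optimizer
    expect_lt(abs(ours - ref), 1e-3)
    expect_lt(kkt_residual(model, pr$X, pr$y), 1e-6)
  }
})

test_that("overwhelming penalty shrinks everything to the null model", {
  pr <- random_problem(seed = 3)
  model <- fit_elastic_net(pr$X, pr$y, alpha = 1, lambda = 1e6)
  expect_true(all(model$coefficients == 0))
  expect_equal(model$intercept, qlogis(mean(pr$y)), tolerance = 1e-5)
  expect_identical(nrow(nonzero_features(model)), 0L)
})

test_that("ridge spreads weight equally over duplicated features", {
  pr <- random_problem(seed = 4)
  X <- cbind(pr$X, dup1 = pr$X[, 1])
  colnames(X)[1] <- "orig1"
  model <- fit_elastic_net(X, pr$y, alpha = 0, lambda = 0.05)
  expect_equal(model$coefficients[["orig1"]], model$coefficients[["dup1"]],
               tolerance = 1e-5)
})

test_that("probabilities follow the logistic closed form", {
  model <- structure(list(intercept = -1,
                          coefficients = c(f1 = 2, f2 = 0),
                          feature_order = c("f1", "f2"),
                          alpha = 1, lambda = 0.1),
                     class = "elastic_net_model")
  X <- matrix(c(1, 5), 1, dimnames = list("s1", c("f1", "f2")))
  expect_equal(unname(predict_proba(model, X)), plogis(1), tolerance = 1e-12)
  zero <- structure(list(intercept = 0, coefficients = c(f1 = 0, f2 = 0),
                         feature_order = c("f1", "f2")),
                    class = "elastic_net_model")
  expect_equal(unname(predict_proba(zero, X)), 0.5)
  expect_error(predict_proba(model, X[, 1, drop = FALSE]), "missing")
})

test_that("binomial deviance has its closed-form values and symmetries", {
  expect_lt(binomial_deviance(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-6)
  expect_equal(binomial_deviance(c(1, 0), c(0.5, 0.5)), 2 * log(2))
  set.seed(5)
  y <- rbinom(30, 1, 0.5); p <- runif(30)
  ord <- sample(30)
  expect_equal(binomial_deviance(y, p), binomial_deviance(y[ord], p[ord]))
  expect_warning(binomial_deviance(c(1, 0), c(1, 0)), "clipped")
})

test_that("the regularization path starts empty and densifies monotonically", {
  pr <- random_problem(n = 40, seed = 6)
  path <- fit_path(pr$X, pr$y, alpha = 0.8, n_lambda = 40)
  expect_equal(path$n_nonzero[[1]], 0)
  expect_gte(path$n_nonzero[[length(path$lambda)]], path$n_nonzero[[1]])
  expect_true(all(diff(path$lambda) < 0))
  # warm-started path agrees with a cold-start fit at a probed lambda
  k <- 25
  cold <- fit_elastic_net(pr$X, pr$y, alpha = 0.8, lambda = path$lambda[k])
  expect_equal(unname(path$coefficients[, k]), unname(cold$coefficients),
               tolerance = 1e-5)
})

test_that("nonzero features are sorted by descending coefficient", {
  model <- structure(list(coefficients = c(a = 0.5, b = -0.2, c = 0, d = 1.3)),
                     class = "elastic_net_model")
  nz <- nonzero_features(model)
  expect_identical(nz$pathway_id, c("d", "a", "b"))
  expect_identical(order(-nz$coefficient), seq_len(nrow(nz)))
})

test_that("degenerate classifier inputs are rejected", {
  pr <- random_problem(seed = 8)
  expect_error(fit_elastic_net(pr$X, rep(1, 20), 0.5, 0.1), "both classes")
  expect_error(fit_elastic_net(pr$X, pr$y, 0.5, -1), "lambda")
  expect_error(label_to_binary(c("AR", "weird")), "AR")
  expect_identical(label_to_binary(c("AR", "S", "AR")), c(1L, 0L, 1L))
})

test_that("model JSON serialization preserves the sparse representation", {
  pr <- random_problem(seed = 9)
  model <- fit_elastic_net(pr$X, pr$y, 0.9, 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$intercept, model$intercept, tolerance = 1e-12)
  nz <- model$coefficients[model$coefficients != 0]
  expect_equal(unlist(back$coefficients), nz, tolerance = 1e-12)
})
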