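make_two_batch <- function(n_genes = 50, n_per = 10, shift = 2, scale = 1,
                           seed = 9) {
  set.seed(seed)
  base <- matrix(rnorm(n_genes * 2 * n_per, mean = 7), n_genes, 2 * n_per)
  dimnames(base) <- list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(2 * n_per)))
  batches <- rep(c("b1", "b2"), each = n_per)
  list(m = base, batches = batches, idx2 = batches == "b2")
}

test_that("a single batch is returned unchanged", {
  m <- toy_matrix(10, 6)
  fit <- combat_fit(m, rep("only", 6))
  expect_equal(fit$adjusted, m)
})

test_that("a pure per-gene shift between two equal batches is suppressed", {
  tb <- make_two_batch()
  set.seed(31)
  gene_shift <- rnorm(nrow(tb$m), mean = 2)
  m <- tb$m
  m[, tb$idx2] <- m[, tb$idx2] + gene_shift
  fit <- combat_fit(m, tb$batches)
  raw_diff <- rowMeans(m[, tb$idx2]) - rowMeans(m[, !tb$idx2])
  adj_diff <- rowMeans(fit$adjusted[, tb$idx2]) -
    rowMeans(fit$adjusted[, !tb$idx2])
  # EB shrinkage removes the systematic shift; small per-gene residuals
  # toward the cross-gene prior remain by construction
  expect_lt(max(abs(adj_diff)), 0.25 * max(abs(raw_diff)))
  expect_lt(abs(mean(adj_diff)), 0.05)
})

test_that("simulated location/scale batch effects are neutralized", {
  set.seed(21)
  n_genes <- 500; n_per <- 15
  m <- matrix(rnorm(n_genes * 2 * n_per, mean = 7), n_genes, 2 * n_per)
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(2 * n_per)))
  batches <- rep(c("b1", "b2"), each = n_per)
  idx2 <- batches == "b2"
  add <- rnorm(n_genes, mean = 2)
  m[, idx2] <- sweep(sweep(m[, idx2], 1, 7), 1, 1.5, `*`) + 7 + add
  fit <- combat_fit(m, batches)
  tstat <- apply(fit$adjusted, 1L, function(x)
    t.test(x[idx2], x[!idx2])$statistic)
  expect_lte(mean(abs(tstat) > 2), 0.07)
})

test_that("EB estimates shrink raw batch effects toward the prior mean", {
  tb <- make_two_batch(seed = 3)
  m <- tb$m
  m[, tb$idx2] <- m[, tb$idx2] + rnorm(nrow(m), mean = 1)
  fit <- combat_fit(m, tb$batches)
  for (b in seq_along(fit$batch_levels)) {
    lo <- pmin(fit$gamma_hat[, b], fit$gamma_bar[b])
    hi <- pmax(fit$gamma_hat[, b], fit$gamma_bar[b])
    expect_true(all(fit$gamma_star[, b] >= lo - 1e-8 &
                    fit$gamma_star[, b] <= hi + 1e-8))
  }
})

test_that("adjustment preserves shape, gene order and finiteness", {
  cohort <- small_cohort()
  m <- do.call(cbind, unname(cohort$matrices))
  ann <- cohort$annotations
  fit <- combat_fit(m, setNames(ann$study_id, ann$sample_id))
  expect_identical(dim(fit$adjusted), dim(m))
  expect_identical(rownames(fit$adjusted), rownames(m))
  expect_true(all(is.finite(fit$adjusted)))
})

test_that("group covariate preserves the between-class expression contrast", {
  set.seed(14)
  n_genes <- 200; n_per <- 12
  m <- matrix(rnorm(n_genes * 2 * n_per, mean = 7), n_genes, 2 * n_per)
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(2 * n_per)))
  batches <- rep(c("b1", "b2"), each = n_per)
  group <- rep(rep(c("AR", "S"), each = n_per / 2), 2)  # batch orthogonal to class
  de <- group == "AR"
  m[1:20, de] <- m[1:20, de] + 1.5
  m[, batches == "b2"] <- m[, batches == "b2"] + rnorm(n_genes)
  fit <- combat_fit(m, batches, group = group)
  contrast_raw <- rowMeans(m[1:20, de]) - rowMeans(m[1:20, !de])
  contrast_adj <- rowMeans(fit$adjusted[1:20, de]) -
    rowMeans(fit$adjusted[1:20, !de])
  expect_equal(contrast_adj, contrast_raw, tolerance = 0.1)
})

test_that("agreement with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  tb <- make_two_batch(n_genes = 120, seed = 5)
  m <- tb$m
  m[, tb$idx2] <- m[, tb$idx2] + rnorm(nrow(m), mean = 1, sd = 0.5)
  fit <- combat_fit(m, tb$batches)
  ref <- suppressMessages(sva::ComBat(dat = m, batch = tb$batches))
  expect_equal(fit$adjusted, ref, tolerance = 1e-4)
})

test_that("apply is consistent on training data and aligns shifted blind sets", {
  tb <- make_two_batch(seed = 8)
  fit <- combat_fit(tb$m, tb$batches)
  again <- combat_apply(fit, tb$m, tb$batches)
  expect_equal(again, fit$adjusted)

  # blind set = copy of batch 1 with a constant +3 shift; after the joint
  # refit the systematic shift is gone (mean gap ~0) and only per-gene EB
  # shrinkage residuals remain, well under the injected shift
  blind <- tb$m[, !tb$idx2] + 3
  colnames(blind) <- paste0("new", seq_len(ncol(blind)))
  adj_blind <- combat_apply(fit, blind, rep("blind", ncol(blind)))
  gene_gap <- rowMeans(adj_blind) - rowMeans(fit$adjusted[, !tb$idx2])
  expect_lt(abs(mean(gene_gap)), 0.1)
  expect_lt(max(abs(gene_gap)), 0.25 * 3)
  expect_error(combat_apply(fit, blind, rep("blind", ncol(blind)),
                            refit = FALSE), "joint refit")
  expect_error(combat_apply(fit, tb$m[, 0], character(0)), "no samples")
})

test_that("unestimable batches are rejected", {
  m <- toy_matrix(8, 5)
  expect_error(combat_fit(m, c("a", "a", "a", "a", "b")), "single sample")
})
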