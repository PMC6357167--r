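#' Fit an empirical-Bayes batch-effect model (parametric ComBat)
#'
#' Implements the parametric location/scale empirical-Bayes adjustment of
#' Johnson, Li & Rabinovic (2007): genes are standardized against a grand
#' model, per-batch location (gamma) and scale (delta^2) effects are estimated
#' gene-wise, shrunk toward cross-gene priors (normal for location,
#' inverse-gamma for scale, hyperparameters by method of moments), and the
#' standardized data are adjusted with the shrunken estimates.
#'
#' Genes with zero pooled variance cannot be standardized; they are passed
#' through unadjusted with a warning. A single batch means there is no batch
#' effect to remove, and the input is returned unchanged.
#'
#' @param m expression matrix, genes x samples.
#' @param batches character/factor of batch (study) ids, one per column of
#'   `m`, or a named vector indexed by sample id.
#' @param group optional factor of biological class per sample, protected as a
#'   covariate during standardization (off by default).
#' @param conv convergence tolerance of the EB iterations.
#' @return object of class `batch_model`: hyperparameters, raw and shrunken
#'   batch estimates, and `$adjusted`, the batch-corrected matrix.
#' @export
combat_fit <- function(m, batches, group = NULL, conv = 1e-4) {
  validate_expression_matrix(m)
  batches <- resolve_sample_map(batches, colnames(m), "batches")
  batch <- factor(batches)
  n_i <- table(batch)
  if (any(n_i < 2))
    stop("batch scale not estimable: batch(es) with a single sample: ",
         paste(names(n_i)[n_i < 2], collapse = ", "))
  if (nlevels(batch) == 1L) {
    model <- structure(list(single_batch = TRUE, batch_levels = levels(batch),
                            dat = m, batches = batches, adjusted = m),
                       class = "batch_model")
    return(model)
  }

  batch_design <- stats::model.matrix(~ 0 + batch)
  design <- batch_design
  if (!is.null(group)) {
    group <- resolve_sample_map(group, colnames(m), "group")
    design <- cbind(batch_design, stats::model.matrix(~ factor(group))[, -1, drop = FALSE])
  }
  n_array <- ncol(m)
  B <- nlevels(batch)

  # gene-wise least squares for batch + covariate effects
  b_hat <- solve(crossprod(design), t(design) %*% t(m))
  grand_mean <- crossprod(as.numeric(n_i) / n_array, b_hat[seq_len(B), , drop = FALSE])
  var_pooled <- rowMeans((m - t(design %*% b_hat))^2)

  const <- var_pooled <= .Machine$double.eps
  if (any(const))
    warning(sum(const), " gene(s) with zero pooled variance passed through ",
            "unadjusted", call. = FALSE)

  stand_mean <- matrix(grand_mean, nrow(m), n_array)
  if (ncol(design) > B)
    stand_mean <- stand_mean +
      t(design[, -seq_len(B), drop = FALSE] %*% b_hat[-seq_len(B), , drop = FALSE])

  keep <- which(!const)
  s_data <- (m[keep, , drop = FALSE] - stand_mean[keep, , drop = FALSE]) /
    sqrt(var_pooled[keep])

  # raw per-gene batch effects on the standardized scale
  gamma_hat <- t(solve(crossprod(batch_design), t(batch_design) %*% t(s_data)))
  delta_hat <- sapply(levels(batch), function(b)
    apply(s_data[, batch == b, drop = FALSE], 1L, var))

  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2L, var)
  a_prior <- apply(delta_hat, 2L, function(d) {
    mm <- mean(d); s2 <- var(d); (2 * s2 + mm^2) / s2
  })
  b_prior <- apply(delta_hat, 2L, function(d) {
    mm <- mean(d); s2 <- var(d); (mm * s2 + mm^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(B)) {
    idx <- batch == levels(batch)[b]
    sd_b <- s_data[, idx, drop = FALSE]
    n_b <- sum(idx)
    g_old <- gamma_hat[, b]
    d_old <- delta_hat[, b]
    repeat {
      g_new <- (t2[b] * n_b * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (t2[b] * n_b + d_old)
      sum2 <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (n_b / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
  }

  bayes <- (s_data - t(batch_design %*% t(gamma_star))) /
    sqrt(t(batch_design %*% t(delta_star)))
  adjusted <- m
  adjusted[keep, ] <- bayes * sqrt(var_pooled[keep]) + stand_mean[keep, , drop = FALSE]

  structure(list(
    single_batch = FALSE,
    batch_levels = levels(batch),
    n_per_batch = as.integer(n_i),
    grand_mean = as.numeric(grand_mean),
    var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, t2 = t2, a_prior = a_prior, b_prior = b_prior,
    constant_genes = rownames(m)[const],
    group = group,
    dat = m, batches = batches,
    adjusted = adjusted
  ), class = "batch_model")
}

#' Apply a batch model to expression data
#'
#' For samples that were part of the fit, returns their stored adjusted
#' values. For samples from new (blind) batches, the model is refit jointly on
#' training plus blind data — the protocol used when external validation sets
#' are normalized into the training space — and the adjusted blind columns are
#' returned. Only batch structure, never class labels, enters the refit.
#'
#' @param model a `batch_model` from [combat_fit()].
#' @param m expression matrix of the samples to adjust (genes must match the
#'   training genes).
#' @param batches batch id per column of `m`.
#' @param refit allow a joint refit when `m` contains unseen batches.
#' @return adjusted matrix with the columns of `m`.
#' @export
combat_apply <- function(model, m, batches, refit = TRUE) {
  stopifnot(inherits(model, "batch_model"))
  if (is.null(dim(m)) || ncol(m) == 0) stop("no samples to adjust")
  if (!identical(rownames(m), rownames(model$dat)))
    stop("gene set/order differs from the fitted model")
  batches <- resolve_sample_map(batches, colnames(m), "batches")

  known_samples <- colnames(m) %in% colnames(model$dat)
  if (all(known_samples))
    return(model$adjusted[, colnames(m), drop = FALSE])
  if (!refit) {
    new_b <- setdiff(unique(batches), model$batch_levels)
    stop("unseen batch(es) ", paste(new_b, collapse = ", "),
         " require a joint refit (refit = TRUE)")
  }
  new_cols <- !known_samples
  joint <- cbind(model$dat, m[, new_cols, drop = FALSE])
  joint_batches <- c(model$batches, batches[new_cols])
  refit_model <- combat_fit(joint, joint_batches, group = NULL)
  # The joint refit centers at a grand mean that includes the blind batch;
  # re-reference its output to the frozen training frame via the per-gene
  # offset observed on the shared training samples, so blind samples land in
  # the same space as the stored training artifacts.
  train_ids <- colnames(model$dat)
  offset <- rowMeans(model$adjusted[, train_ids, drop = FALSE]) -
    rowMeans(refit_model$adjusted[, train_ids, drop = FALSE])
  out <- refit_model$adjusted[, colnames(m), drop = FALSE] + offset
  known <- colnames(m)[known_samples]
  out[, known] <- model$adjusted[, known]
  out
}

# Accept either a vector aligned with sample_ids or a named vector keyed by
# sample id; always return the aligned unnamed form.
resolve_sample_map <- function(x, sample_ids, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(sample_ids, names(x))
    if (length(missing))
      stop(what, " missing for samples: ", paste(missing, collapse = ", "))
    x <- x[sample_ids]
  } else if (length(x) != length(sample_ids)) {
    stop(what, " must have one entry per sample")
  }
  unname(as.character(x))
}
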