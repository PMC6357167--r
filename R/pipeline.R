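#' Build a pipeline configuration
#'
#' Exactly one of `synthetic` (a [synthetic_cohort_spec()]) or `inputs` (file
#' paths) must be given. The external validation set is formed by a
#' stratified draw of `external_fraction` of the samples from the designated
#' `external_studies` (by default the two largest studies, mirroring the
#' practice of reserving the best-powered cohorts for blind validation);
#' those samples take no part in batch correction, curve fitting, tuning or
#' model fitting.
#'
#' @param synthetic optional [synthetic_cohort_spec()].
#' @param inputs optional list with `expression` (character vector of per-study
#'   TSVs; study ids default to file base names), `annotations` (TSV path),
#'   `gene_sets` (GMT path), and optionally `probe_map` (TSV path, triggers
#'   IQR probe collapse).
#' @param external_studies study ids supplying the external set; `NULL` picks
#'   the two largest studies.
#' @param external_fraction stratified fraction reserved per external study.
#' @param external_validation run the external-validation stages; when
#'   `FALSE`, the reserved samples are discarded entirely (training stages are
#'   bit-identical either way).
#' @param cv_mode `"LOSOCV"` (headline) or `"LOOCV"`.
#' @param alpha_bounds,log_lambda_bounds,budget,n_init EPSGO settings.
#' @param model_rule final-model penalty choice: `"min_deviance"` or `"1se"`.
#' @param min_genes,k_max,span,tol,max_iter pathway-scoring settings.
#' @param threshold decision threshold for confusion-based metrics.
#' @param seed master seed (partitioning and tuning).
#' @param out_dir optional directory; when set, all stage artifacts are
#'   written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            external_studies = NULL, external_fraction = 0.3,
                            external_validation = TRUE,
                            cv_mode = c("LOSOCV", "LOOCV"),
                            alpha_bounds = c(0.01, 1),
                            log_lambda_bounds = c(-8, 2),
                            budget = 50L, n_init = 10L,
                            model_rule = c("min_deviance", "1se"),
                            min_genes = 3L, k_max = 5L, span = 0.3,
                            tol = 1e-4, max_iter = 30L,
                            threshold = 0.5, seed = 1L, out_dir = NULL) {
  cv_mode <- match.arg(cv_mode)
  model_rule <- match.arg(model_rule)
  cfg <- mget(setdiff(names(formals(pipeline_config)), "..."))
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of 'synthetic' or 'inputs' must be given")
  if (!is.null(inputs)) {
    need <- c("expression", "annotations", "gene_sets")
    if (!all(need %in% names(inputs)))
      stop("inputs must name: ", paste(need, collapse = ", "))
    paths <- c(inputs$expression, inputs$annotations, inputs$gene_sets,
               inputs$probe_map)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input path(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `synthetic`
#' block is passed to [synthetic_cohort_spec()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic))
    cfg$synthetic <- do.call(synthetic_cohort_spec, cfg$synthetic)
  do.call(pipeline_config, cfg)
}

#' Run the full meta-analysis pipeline
#'
#' Executes, in order: data loading (or synthesis) → gene intersection and
#' merge → stratified reservation of the external set → empirical-Bayes batch
#' correction of the internal studies → pathway dysregulation scoring with
#' controls = internal sensitive samples → EPSGO tuning of (alpha, lambda)
#' under the configured cross-validation → final elastic-net fit → internal
#' cross-validated metrics → joint batch refit including the external set →
#' external PDS by projection → external metrics. Fully deterministic given
#' the configuration.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pdsnet_run` with the fitted artifacts, metric
#'   reports and a manifest of per-stage content hashes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, cv_mode = config$cv_mode,
                   stages = character(0), hashes = list(), warnings = list())
  stage <- function(name, value) {
    manifest$stages <<- c(manifest$stages, name)
    manifest$hashes[[name]] <<- rlang::hash(value)
    value
  }

  # -- load ----------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    matrices <- cohort$matrices
    ann <- cohort$annotations
    gene_sets <- cohort$gene_sets
    truth <- cohort$truth
  } else {
    matrices <- lapply(config$inputs$expression, read_expression_tsv,
                       allow_duplicate_features = !is.null(config$inputs$probe_map))
    names(matrices) <- sub("\\.[^.]*$", "", basename(config$inputs$expression))
    if (!is.null(config$inputs$probe_map)) {
      pm <- read_probe_map(config$inputs$probe_map)
      matrices <- lapply(matrices, collapse_probes_iqr, probe_map = pm)
    }
    ann <- read_annotations(config$inputs$annotations)
    gene_sets <- read_gmt(config$inputs$gene_sets)
    truth <- NULL
  }
  if (length(matrices) > 1) matrices <- intersect_genes(matrices)
  m_all <- do.call(cbind, unname(matrices))
  ann <- validate_annotations(ann, m_all)
  stage("input", list(m_all, ann, gene_sets))

  # -- reserve the external set -------------------------------------------
  ext_studies <- config$external_studies
  if (is.null(ext_studies)) {
    sizes <- sort(table(ann$study_id), decreasing = TRUE)
    ext_studies <- names(sizes)[seq_len(min(2L, length(sizes)))]
  }
  ext_ann <- ann[ann$study_id %in% ext_studies, , drop = FALSE]
  part <- stratified_partition(ext_ann, config$external_fraction,
                               seed = config$seed)
  external_ids <- part$test
  internal_ids <- setdiff(ann$sample_id, external_ids)
  m_int <- m_all[, internal_ids, drop = FALSE]
  ann_int <- ann[match(internal_ids, ann$sample_id), , drop = FALSE]
  stage("partition", list(internal_ids, external_ids))

  # -- batch correction (internal only) -----------------------------------
  batch_model <- combat_fit(m_int, setNames(ann_int$study_id,
                                            ann_int$sample_id))
  m_adj <- batch_model$adjusted
  stage("combat", m_adj)

  # -- pathway dysregulation scores ---------------------------------------
  controls <- ann_int$sample_id[ann_int$label == "S"]
  pds_fit <- score_all_pathways(m_adj, gene_sets, controls,
                                min_genes = config$min_genes,
                                k_max = config$k_max, span = config$span,
                                tol = config$tol, max_iter = config$max_iter)
  X <- t(pds_fit$pds)
  y <- label_to_binary(ann_int$label)
  stage("pds", pds_fit$pds)

  # -- tuning --------------------------------------------------------------
  folds <- cv_folds(ann_int$study_id, config$cv_mode)
  tuning <- tune_elastic_net(X, y, folds,
                             alpha_bounds = config$alpha_bounds,
                             log_lambda_bounds = config$log_lambda_bounds,
                             budget = config$budget, n_init = config$n_init,
                             seed = config$seed)
  stage("tuning", tuning$trace)

  # -- final model ---------------------------------------------------------
  sel <- if (config$model_rule == "1se") tuning$at_1se else
    tuning$at_min_deviance
  model <- fit_elastic_net(X, y, sel$alpha, sel$lambda)
  model_1se <- fit_elastic_net(X, y, tuning$at_1se$alpha,
                               tuning$at_1se$lambda)
  stage("model", model$coefficients)

  # -- internal cross-validated metrics -----------------------------------
  p_cv <- rep(NA_real_, length(y))
  for (f in levels(folds)) {
    test <- folds == f
    fit_f <- fit_elastic_net(X[!test, , drop = FALSE], y[!test],
                             sel$alpha, sel$lambda)
    p_cv[test] <- predict_proba(fit_f, X[test, , drop = FALSE])
  }
  internal <- list(
    probabilities = data.frame(sample_id = internal_ids,
                               study_id = ann_int$study_id,
                               label = ann_int$label,
                               probability = p_cv,
                               stringsAsFactors = FALSE),
    metrics = evaluate_all(y, p_cv, config$threshold))
  stage("internal_metrics", internal$metrics)

  # -- external validation -------------------------------------------------
  external <- NULL
  if (config$external_validation && length(external_ids)) {
    m_ext <- m_all[, external_ids, drop = FALSE]
    ann_ext <- ann[match(external_ids, ann$sample_id), , drop = FALSE]
    m_ext_adj <- combat_apply(batch_model, m_ext,
                              setNames(paste0("blind_", ann_ext$study_id),
                                       ann_ext$sample_id))
    pds_ext <- score_new_samples(pds_fit, m_ext_adj)
    p_ext <- predict_proba(model, t(pds_ext))
    y_ext <- label_to_binary(ann_ext$label)
    external <- list(
      pds = pds_ext,
      probabilities = data.frame(sample_id = external_ids,
                                 study_id = ann_ext$study_id,
                                 label = ann_ext$label,
                                 probability = unname(p_ext),
                                 stringsAsFactors = FALSE),
      metrics = evaluate_all(y_ext, p_ext, config$threshold))
    manifest$stages <- c(manifest$stages, "external_metrics")
    manifest$hashes[["external_metrics"]] <- rlang::hash(external$metrics)
  }

  run <- structure(list(
    config = config,
    annotations = ann,
    internal_ids = internal_ids, external_ids = external_ids,
    batch_model = batch_model,
    pds_fit = pds_fit,
    tuning = tuning,
    model = model, model_1se = model_1se,
    internal = internal, external = external,
    truth = truth,
    manifest = manifest
  ), class = "pdsnet_run")

  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

# Persist every stage artifact in plain-text formats.
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(run$batch_model$adjusted, file.path(dir, "merged_adjusted.tsv"))
  write_expression_tsv(run$pds_fit$pds, file.path(dir, "pds.tsv"))
  write.table(run$pds_fit$skipped, file.path(dir, "pathway_skips.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$tuning$trace, file.path(dir, "tuning_trace.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(at_min_deviance = run$tuning$at_min_deviance,
                            at_1se = run$tuning$at_1se,
                            min_deviance = run$tuning$min_deviance,
                            se_at_min = run$tuning$se_at_min),
                       file.path(dir, "selected_params.json"),
                       auto_unbox = TRUE, digits = NA)
  write_model_json(run$model, file.path(dir, "model.json"))
  write.table(nonzero_features(run$model), file.path(dir, "coefficients.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$internal$metrics,
                       file.path(dir, "metrics_internal.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(run$internal$probabilities,
              file.path(dir, "probabilities_internal.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$external)) {
    jsonlite::write_json(run$external$metrics,
                         file.path(dir, "metrics_external.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(run$external$probabilities,
                file.path(dir, "probabilities_external.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pdsnet_run <- function(x, ...) {
  cat("pdsnet pipeline run\n")
  cat(sprintf("  internal samples: %d (%d studies), external samples: %d\n",
              length(x$internal_ids),
              length(unique(x$annotations$study_id[
                x$annotations$sample_id %in% x$internal_ids])),
              length(x$external_ids)))
  cat(sprintf("  pathways scored: %d (skipped %d)\n",
              nrow(x$pds_fit$pds), nrow(x$pds_fit$skipped)))
  cat(sprintf("  selected alpha = %.3f, log lambda = %.3f (%s rule)\n",
              x$model$alpha, log(x$model$lambda), x$config$model_rule))
  cat(sprintf("  non-zero pathway coefficients: %d\n",
              sum(x$model$coefficients != 0)))
  cat(sprintf("  internal %s AUROC = %.3f\n", x$config$cv_mode,
              x$internal$metrics$auroc))
  if (!is.null(x$external))
    cat(sprintf("  external AUROC = %.3f\n", x$external$metrics$auroc))
  invisible(x)
}
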