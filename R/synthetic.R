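#' Specification of a synthetic multi-study cohort
#'
#' Describes a cohort of expression studies emulating a heterogeneous
#' meta-analysis: several studies (batches) of cell-line samples with binary
#' acquired-resistance labels, a minority of "informative" pathways whose
#' member genes are displaced along a nonlinear latent trajectory in resistant
#' samples, additive/multiplicative per-study batch effects, and i.i.d.
#' Gaussian measurement noise. Defaults give 6 studies x 15 samples, 2000
#' genes, 50 pathways of which 5 carry signal, a curved trajectory and an
#' effect size of 2 gene-SD units — a cohort of roughly the size and
#' heterogeneity of an 8-study, ~90-sample public meta-analysis, scaled for
#' fast tests.
#'
#' @param n_studies number of studies.
#' @param samples_per_study samples per study (scalar or per-study vector).
#' @param n_genes gene universe size.
#' @param n_pathways number of generated gene sets (ignored when `gene_sets`
#'   is supplied).
#' @param genes_per_pathway length-2 range of set sizes.
#' @param n_informative number of pathways carrying the planted signal.
#' @param effect_size displacement of resistant samples along the latent
#'   trajectory, in units of the per-gene noise SD; 0 = null cohort.
#' @param trajectory `"curved"` (quadratic embedding — the dysregulation is
#'   nonlinear in gene space, which a first principal component
#'   under-detects) or `"linear"`.
#' @param batch_location_sd SD of per-study, per-gene additive shifts.
#' @param batch_scale_sd log-SD of per-study, per-gene multiplicative scale
#'   factors.
#' @param noise_sd per-gene measurement noise SD (log2 units).
#' @param ar_fraction fraction of resistant (AR) samples per study.
#' @param gene_sets optional pre-built gene sets (as from [read_gmt()]).
#' @param seed integer; all randomness flows from it.
#' @return list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_studies = 6L, samples_per_study = 15L,
                                  n_genes = 2000L, n_pathways = 50L,
                                  genes_per_pathway = c(15L, 50L),
                                  n_informative = 5L, effect_size = 2,
                                  trajectory = c("curved", "linear"),
                                  batch_location_sd = 1, batch_scale_sd = 0.25,
                                  noise_sd = 1, ar_fraction = 0.5,
                                  gene_sets = NULL, seed = 1L) {
  trajectory <- match.arg(trajectory)
  stopifnot(n_studies >= 1, n_genes >= 10, effect_size >= 0,
            batch_location_sd >= 0, batch_scale_sd >= 0, noise_sd > 0,
            ar_fraction > 0, ar_fraction < 1)
  if (length(samples_per_study) == 1L)
    samples_per_study <- rep(as.integer(samples_per_study), n_studies)
  stopifnot(length(samples_per_study) == n_studies)
  structure(as.list(environment()), class = "synthetic_cohort_spec")
}

#' Generate random gene sets
#'
#' @param n_pathways number of sets.
#' @param genes_per_pathway length-2 inclusive range of set sizes.
#' @param n_genes size of the gene universe `g0001 ...`.
#' @param overlap_fraction fraction of each set drawn from a common shared
#'   pool (0 = pairwise disjoint sets).
#' @param seed integer seed.
#' @return named list of gene sets (id, name, genes), GMT-writable.
#' @export
generate_gene_sets <- function(n_pathways, genes_per_pathway, n_genes,
                               overlap_fraction = 0, seed = 1L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  genes <- sprintf("g%04d", seq_len(n_genes))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sizes <- sample(seq(genes_per_pathway[1], genes_per_pathway[2]),
                  n_pathways, replace = TRUE)
  if (overlap_fraction == 0) {
    if (sum(sizes) > n_genes)
      stop("disjoint sets infeasible: need ", sum(sizes), " genes, have ",
           n_genes)
    pool <- sample(genes)
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1) + 1L)
    sets <- lapply(seq_len(n_pathways), function(i)
      list(id = sprintf("PW%03d", i), name = sprintf("synthetic pathway %d", i),
           genes = sort(pool[starts[i]:stops[i]])))
  } else {
    shared <- sample(genes, max(sizes))
    rest <- setdiff(genes, shared)
    if (length(rest) < max(sizes))
      stop("overlap structure infeasible for this universe size")
    sets <- lapply(seq_len(n_pathways), function(i) {
      n_sh <- round(overlap_fraction * sizes[i])
      g <- c(sample(shared, n_sh), sample(rest, sizes[i] - n_sh))
      list(id = sprintf("PW%03d", i), name = sprintf("synthetic pathway %d", i),
           genes = sort(g))
    })
  }
  names(sets) <- vapply(sets, `[[`, "", "id")
  sets
}

#' Generate a synthetic multi-study cohort
#'
#' Baseline expression of gene g in sample i is
#' `mu_g + batch_add + batch_scale * (signal_gi + noise)`, with per-study
#' batch terms drawn once per (study, gene). Every sample carries a latent
#' trajectory position `u`: sensitive samples sit at the origin (`u = 0`,
#' noise only), resistant samples are displaced along the trajectory
#' (`u ~ U(0.4, 1)`, heterogeneous resistance progression).
#' For genes in informative pathways the signal is
#' `effect_size * (a_g u + b_g u^2)` (curved trajectory; `b_g = 0` for
#' linear), with `(a_g, b_g)` a unit-norm gene loading — so resistant
#' samples move along a shared nonlinear curve in the pathway's gene space.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return list with `matrices` (named list of per-study expression matrices),
#'   `annotations` (data.frame), `gene_sets`, and `truth` (per-sample latent
#'   displacement, informative pathway ids, spec echo).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  n_ar <- round(spec$ar_fraction * spec$samples_per_study)
  if (any(n_ar == 0) || any(n_ar == spec$samples_per_study))
    stop("ar_fraction leaves a study without one of the classes")

  gene_sets <- spec$gene_sets
  if (is.null(gene_sets))
    gene_sets <- generate_gene_sets(spec$n_pathways, spec$genes_per_pathway,
                                    spec$n_genes, overlap_fraction = 0,
                                    seed = spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  mu <- rnorm(spec$n_genes, mean = 7, sd = 1)
  names(mu) <- genes

  informative <- sort(sample(names(gene_sets), spec$n_informative))
  # unit-norm (linear, quadratic) loading per informative-pathway gene
  loadings <- new.env(parent = emptyenv())
  for (pid in informative) {
    gs <- gene_sets[[pid]]$genes
    a <- rnorm(length(gs)); b <- if (spec$trajectory == "curved")
      rnorm(length(gs)) else rep(0, length(gs))
    nrm <- sqrt(a^2 + b^2); nrm[nrm == 0] <- 1
    ld <- cbind(a = a / nrm, b = b / nrm)
    rownames(ld) <- gs
    assign(pid, ld, envir = loadings)
  }

  matrices <- list()
  ann <- list(); truth_u <- list()
  for (s in seq_len(spec$n_studies)) {
    study_id <- sprintf("study%02d", s)
    n <- spec$samples_per_study[s]
    sample_ids <- sprintf("%s_s%02d", study_id, seq_len(n))
    label <- c(rep("AR", n_ar[s]), rep("S", n - n_ar[s]))
    u <- ifelse(label == "AR", runif(n, 0.4, 1), 0)

    signal <- matrix(0, spec$n_genes, n, dimnames = list(genes, sample_ids))
    if (spec$effect_size > 0) {
      for (pid in informative) {
        ld <- get(pid, envir = loadings)
        shift <- ld[, "a"] %o% u + ld[, "b"] %o% u^2
        signal[rownames(ld), ] <- signal[rownames(ld), ] +
          spec$effect_size * spec$noise_sd * shift
      }
    }
    noise <- matrix(rnorm(spec$n_genes * n, sd = spec$noise_sd),
                    spec$n_genes, n)
    batch_add <- rnorm(spec$n_genes, sd = spec$batch_location_sd)
    batch_scale <- rlnorm(spec$n_genes, meanlog = 0,
                          sdlog = spec$batch_scale_sd)
    m <- mu + batch_add + batch_scale * (signal + noise)
    dimnames(m) <- list(genes, sample_ids)
    matrices[[study_id]] <- m
    ann[[study_id]] <- data.frame(sample_id = sample_ids, study_id = study_id,
                                  label = label, stringsAsFactors = FALSE)
    truth_u[[study_id]] <- u
  }

  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  list(matrices = matrices,
       annotations = annotations,
       gene_sets = gene_sets,
       truth = list(displacement = setNames(unlist(truth_u, use.names = FALSE),
                                            annotations$sample_id),
                    informative_pathways = informative,
                    effect_size = spec$effect_size,
                    trajectory = spec$trajectory,
                    seed = spec$seed))
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the readers consume: one expression TSV per
#' study, an annotation TSV, a GMT of the gene sets and the truth record as
#' JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (study in names(cohort$matrices))
    write_expression_tsv(cohort$matrices[[study]],
                         file.path(dir, paste0(study, ".tsv")))
  write.table(cohort$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
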