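#' Read gene sets in GMT format
#'
#' One set per line: `id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are removed with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of gene sets, each a list with `id`, `name`, `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d fields; need id, description and >=1 gene",
                   i, length(fields)))
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' removed", fields[1]),
              call. = FALSE)
      genes <- unique(genes)
    }
    list(id = fields[1], name = fields[2], genes = genes)
  })
  names(sets) <- vapply(sets, `[[`, "", "id")
  if (anyDuplicated(names(sets))) stop("duplicate gene set ids in ", path)
  sets
}

#' Write gene sets in GMT format
#'
#' @param gene_sets list as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs)
    paste(c(gs$id, gs$name, gs$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Score one pathway: per-sample dysregulation along a principal curve
#'
#' The Pathifier-style pathway dysregulation score (PDS). The expression
#' matrix is restricted to the pathway's genes, each gene is z-scored with
#' statistics over all (training) samples, the standardized profiles are
#' reduced to their top `k_max` principal components, and a principal curve is
#' fitted through the reduced cloud. The curve is oriented so that the
#' centroid of the control (sensitive) samples projects near its start; a
#' sample's PDS is its projection's arc-length distance from the control
#' origin, normalized by the remaining curve length, so PDS lies in `[0, 1]`:
#' 0 at the control centroid, 1 at the far end of the curve.
#'
#' @param m gene-level expression matrix (genes x samples), batch-corrected.
#' @param gene_set a single gene set (list with `id`, `genes`).
#' @param controls character vector of control sample ids (a subset of
#'   `colnames(m)`).
#' @param min_genes minimum number of pathway genes that must be present (and
#'   non-constant) in `m`; smaller sets give degenerate curves.
#' @param k_max cap on the reduced dimension (default 5); the effective k is
#'   `min(genes, samples - 1, k_max)`.
#' @param span,tol,max_iter passed to [fit_principal_curve()].
#' @return list with `pds` (named vector over samples), `curve`, the frozen
#'   standardization (`center`, `scale`), the PCA `rotation`, `genes`,
#'   `origin_arclength`, and `origin_index` (curve vertex nearest the control
#'   centroid).
#' @export
score_pathway <- function(m, gene_set, controls, min_genes = 3L, k_max = 5L,
                          span = 0.3, tol = 1e-4, max_iter = 30L) {
  if (length(controls) == 0) stop("controls must be non-empty")
  if (!all(controls %in% colnames(m)))
    stop("controls not in matrix: ",
         paste(setdiff(controls, colnames(m)), collapse = ", "))
  genes <- intersect(gene_set$genes, rownames(m))
  if (length(genes) < min_genes)
    stop(sprintf("only %d of %d genes present (min_genes = %d)",
                 length(genes), length(gene_set$genes), min_genes))
  X <- t(m[genes, , drop = FALSE])
  center <- colMeans(X)
  scl <- apply(X, 2L, sd)
  ok <- scl > 0
  if (sum(ok) < min_genes)
    stop(sprintf("only %d non-constant genes (min_genes = %d)",
                 sum(ok), min_genes))
  genes <- genes[ok]
  center <- center[ok]; scl <- scl[ok]
  Z <- sweep(sweep(X[, ok, drop = FALSE], 2L, center), 2L, scl, `/`)

  k <- min(length(genes), nrow(Z) - 1L, k_max)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  rotation <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- Z %*% rotation

  curve <- fit_principal_curve(scores, span = span, tol = tol,
                               max_iter = max_iter)
  centroid <- colMeans(scores[controls, , drop = FALSE])
  lam_c <- project_to_polyline(curve, matrix(centroid, 1L))$lambda
  if (lam_c > curve$total_length / 2) {
    curve <- reverse_curve(curve)
    lam_c <- curve$total_length - lam_c
  }
  lam <- project_to_polyline(curve, scores)$lambda
  origin_index <- which.min(colSums((t(curve$vertices) - centroid)^2))
  denom <- max(curve$total_length - lam_c, .Machine$double.eps)
  pds <- pmin(1, pmax(0, (lam - lam_c) / denom))
  names(pds) <- colnames(m)

  list(pathway_id = gene_set$id, pds = pds, curve = curve, genes = genes,
       center = center, scale = scl, rotation = rotation, k = k,
       origin_arclength = lam_c, origin_index = origin_index)
}

#' Score all pathways into a PDS matrix
#'
#' Applies [score_pathway()] to every gene set; pathways that cannot be
#' scored (too few mapped genes, degenerate cloud) are skipped and recorded
#' in the skip manifest rather than NaN-filled.
#'
#' @inheritParams score_pathway
#' @param gene_sets named list of gene sets (from [read_gmt()] or
#'   [generate_gene_sets()]).
#' @return object of class `pds_fit`: `pds` (pathways x samples matrix, values
#'   in `[0, 1]`), `pathways` (per-pathway handles with frozen transforms and
#'   curves), `skipped` (data.frame `pathway_id`, `reason`), `controls`.
#' @export
score_all_pathways <- function(m, gene_sets, controls, min_genes = 3L,
                               k_max = 5L, span = 0.3, tol = 1e-4,
                               max_iter = 30L) {
  if (length(controls) == 0) stop("controls must be non-empty")
  handles <- list()
  skipped <- list()
  for (gs in gene_sets) {
    res <- tryCatch(
      score_pathway(m, gs, controls, min_genes = min_genes, k_max = k_max,
                    span = span, tol = tol, max_iter = max_iter),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[gs$id]] <- res
    } else {
      handles[[gs$id]] <- res
    }
  }
  if (length(handles) == 0) stop("no pathway could be scored")
  pds <- do.call(rbind, lapply(handles, `[[`, "pds"))
  rownames(pds) <- names(handles)
  structure(list(
    pds = pds,
    pathways = handles,
    skipped = data.frame(pathway_id = names(skipped),
                         reason = unlist(skipped, use.names = FALSE),
                         stringsAsFactors = FALSE),
    controls = controls
  ), class = "pds_fit")
}

#' Score new samples against fitted pathway curves
#'
#' External (blind) samples — already batch-corrected into the training space
#' — are standardized with the frozen training statistics, mapped through each
#' pathway's stored PCA basis, and projected onto the stored principal curve.
#' Projections beyond the curve ends are clamped, so PDS stays in `[0, 1]`.
#' No training artifact is modified: this is pure projection, with no
#' information flowing from the new samples into the model.
#'
#' @param fit a `pds_fit` from [score_all_pathways()].
#' @param m_new gene-level expression matrix of the new samples.
#' @return PDS matrix (same pathways as `fit$pds`) x new samples.
#' @export
score_new_samples <- function(fit, m_new) {
  stopifnot(inherits(fit, "pds_fit"))
  out <- matrix(NA_real_, nrow(fit$pds), ncol(m_new),
                dimnames = list(rownames(fit$pds), colnames(m_new)))
  for (pid in rownames(fit$pds)) {
    h <- fit$pathways[[pid]]
    missing <- setdiff(h$genes, rownames(m_new))
    if (length(missing))
      stop("pathway ", pid, ": genes missing from new data: ",
           paste(missing, collapse = ", "))
    X <- t(m_new[h$genes, , drop = FALSE])
    Z <- sweep(sweep(X, 2L, h$center), 2L, h$scale, `/`)
    scores <- Z %*% h$rotation
    lam <- project_to_polyline(h$curve, scores)$lambda
    denom <- max(h$curve$total_length - h$origin_arclength,
                 .Machine$double.eps)
    out[pid, ] <- pmin(1, pmax(0, (lam - h$origin_arclength) / denom))
  }
  out
}
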