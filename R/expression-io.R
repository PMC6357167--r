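#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix with features (genes or probes) in
#' rows and samples in columns, on the log2 scale. Row and column names must be
#' unique and all values finite.
#'
#' @param m numeric matrix, features x samples.
#' @param allow_duplicate_features if `TRUE`, duplicate row names are tolerated
#'   (probe-level data awaiting collapse).
#' @return `m`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(m, allow_duplicate_features = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have feature row names and sample column names")
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!allow_duplicate_features && anyDuplicated(rownames(m)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (!all(is.finite(m)))
    stop("expression matrix contains non-finite values")
  if (max(m) > 30)
    warning("maximum value exceeds 30; input may be on a raw intensity scale, ",
            "not log2", call. = FALSE)
  invisible(m)
}

#' Read a tab-separated expression matrix
#'
#' Expects features in rows: the header row holds sample ids, the first column
#' holds feature ids, remaining cells are numeric log2 expression values.
#'
#' @param path path to a TSV file.
#' @param allow_duplicate_features pass-through to
#'   [validate_expression_matrix()]; set `TRUE` for probe-level files.
#' @return numeric matrix, features x samples.
#' @export
read_expression_tsv <- function(path, allow_duplicate_features = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("malformed header (line 1): expected at least one sample column")
  if (length(lines) < 2) stop("no data rows in ", path)
  sample_ids <- header[-1]
  n <- length(lines) - 1L
  feature_ids <- character(n)
  values <- matrix(NA_real_, nrow = n, ncol = length(sample_ids))
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header))
      stop(sprintf("line %d has %d fields, expected %d",
                   i + 1L, length(fields), length(header)))
    feature_ids[i] <- fields[1]
    v <- suppressWarnings(as.numeric(fields[-1]))
    bad <- which(is.na(v) & !(fields[-1] %in% c("NA", "NaN")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at line %d, column %d",
                   fields[-1][bad[1]], i + 1L, bad[1] + 1L))
    values[i, ] <- v
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  validate_expression_matrix(values, allow_duplicate_features)
  values
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; values are written at full precision so
#' the round trip is exact.
#'
#' @param m numeric matrix, features x samples.
#' @param path output path.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the expression table of a GEO Series Matrix file
#'
#' Extracts the block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` and parses it like [read_expression_tsv()].
#' Surrounding metadata lines are ignored.
#'
#' @param path path to a Series Matrix text file.
#' @return numeric matrix, features x samples.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1 || length(e) != 1 || e <= b + 1)
    stop("no series matrix table found in ", path)
  tbl <- gsub('"', "", lines[(b + 1L):(e - 1L)])
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(tbl, tmp)
  read_expression_tsv(tmp, allow_duplicate_features = TRUE)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV with header `probe_id`, `gene_symbol`; many probes may map to
#' one gene, but each probe maps to exactly one gene.
#'
#' @param path path to the TSV.
#' @return named character vector, names = probe ids, values = gene symbols.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% colnames(df)))
    stop("probe map must have columns probe_id and gene_symbol")
  if (anyDuplicated(df$probe_id))
    stop("probes mapping to more than one gene: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  setNames(df$gene_symbol, df$probe_id)
}

#' Read per-sample annotations
#'
#' TSV with columns `sample_id`, `study_id`, `label` and optionally `drug` and
#' `cancer_type`. Labels must be `AR` (acquired resistance, the positive class)
#' or `S` (sensitive).
#'
#' @param path path to the TSV.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_annotations(df)
}

#' Validate sample annotations
#'
#' @param ann data.frame with at least `sample_id`, `study_id`, `label`.
#' @param m optional expression matrix whose samples must all be annotated.
#' @return `ann`, with rows ordered to match `m` when given.
#' @export
validate_annotations <- function(ann, m = NULL) {
  need <- c("sample_id", "study_id", "label")
  if (!all(need %in% colnames(ann)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample ids in annotations")
  if (!all(ann$label %in% c("AR", "S")))
    stop("labels must be 'AR' or 'S'; saw: ",
         paste(setdiff(unique(ann$label), c("AR", "S")), collapse = ", "))
  if (!is.null(m)) {
    missing <- setdiff(colnames(m), ann$sample_id)
    if (length(missing))
      stop("samples without annotation: ", paste(missing, collapse = ", "))
    ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

#' Collapse probe-level rows to gene level by maximum IQR
#'
#' When several probes measure the same gene, the probe with the largest
#' interquartile range of expression across samples is kept to represent the
#' gene. Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Ties keep the first probe in input order.
#'
#' @param m probe-level matrix (duplicate-probe ids not allowed; duplicate
#'   genes arise through the map).
#' @param probe_map named character vector probe id -> gene symbol, e.g. from
#'   [read_probe_map()].
#' @return gene-level matrix with gene symbols as row names.
#' @export
collapse_probes_iqr <- function(m, probe_map) {
  unmapped <- setdiff(rownames(m), names(probe_map))
  if (length(unmapped))
    stop("probes not in probe map: ", paste(unmapped, collapse = ", "))
  genes <- probe_map[rownames(m)]
  iqr <- apply(m, 1L, function(x)
    diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7)))
  # which.max keeps the first index on ties, i.e. input order wins
  keep <- vapply(split(seq_len(nrow(m)), factor(genes, levels = unique(genes))),
                 function(idx) idx[which.max(iqr[idx])], integer(1))
  out <- m[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out
}

#' Restrict several studies to their common gene set
#'
#' Studies profiled on different platforms cover different genes; before
#' merging, all matrices are restricted to the intersection of their gene
#' sets, in a common order.
#'
#' @param ms list of >= 2 gene-level expression matrices.
#' @return list of matrices sharing an identical ordered gene set.
#' @export
intersect_genes <- function(ms) {
  if (!is.list(ms) || length(ms) < 2) stop("need at least 2 matrices")
  common <- Reduce(intersect, lapply(ms, rownames))
  if (length(common) == 0) stop("gene intersection across studies is empty")
  lapply(ms, function(m) m[common, , drop = FALSE])
}

#' Stratified train/test partition
#'
#' Samples within each class independently so the test set preserves the class
#' balance: per class, `floor(fraction * class size)` samples (at least 1) go
#' to the test set. Deterministic for a given seed.
#'
#' @param ann annotation data.frame (`sample_id`, `label`).
#' @param fraction test fraction in (0, 1).
#' @param seed integer seed.
#' @return list with character vectors `train` and `test` of sample ids.
#' @export
stratified_partition <- function(ann, fraction, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  if (length(unique(ann$label)) < 2)
    stop("both classes must be present for a stratified partition")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  test <- unlist(lapply(split(ann$sample_id, ann$label), function(ids) {
    n_test <- max(1L, floor(fraction * length(ids)))
    sample(ids, n_test)
  }), use.names = FALSE)
  list(train = setdiff(ann$sample_id, test), test = test)
}
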