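test_that("GMT files round-trip and malformed lines are located", {
  sets <- list(P1 = list(id = "P1", name = "first", genes = c("A", "B", "C")),
               P2 = list(id = "P2", name = "second", genes = c("B", "D")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back, sets)

  writeLines(c("P1\tdesc\tA\tB", "P2\tonlydesc"), path)
  expect_error(read_gmt(path), "line 2")
  writeLines("P1\tdesc\tA\tB\tA", path)
  expect_warning(s <- read_gmt(path), "duplicate")
  expect_identical(s$P1$genes, c("A", "B"))
})

test_that("a planted one-dimensional pathway reduces to min-max distance", {
  # three perfectly collinear genes: the reduced cloud is 1-D, the curve a
  # line, and PDS the normalized distance past the control centroid
  x <- seq(1, 10, length.out = 20)
  m <- rbind(g1 = x, g2 = 2 * x + 1, g3 = -x + 4)
  colnames(m) <- paste0("s", seq_along(x))
  controls <- paste0("s", 1:5)
  fit <- score_pathway(m, list(id = "P", genes = rownames(m)), controls)
  z <- (x - mean(x)) / sd(x)
  z0 <- mean(z[1:5])
  expected <- pmin(1, pmax(0, (z - z0) / (max(z) - z0)))
  expect_equal(unname(fit$pds), expected, tolerance = 1e-6)
})

test_that("control centroid scores ~0 and the far end scores exactly 1", {
  cohort <- small_cohort()
  ann <- cohort$annotations
  m <- do.call(cbind, unname(cohort$matrices))
  controls <- ann$sample_id[ann$label == "S"]
  pid <- cohort$truth$informative_pathways[1]
  fit <- score_all_pathways(m, cohort$gene_sets[pid], controls)

  centroid <- matrix(rowMeans(m[, controls]), ncol = 1,
                     dimnames = list(rownames(m), "centroid"))
  expect_lt(max(score_new_samples(fit, centroid)), 1e-8)

  h <- fit$pathways[[pid]]
  far <- h$curve$vertices[nrow(h$curve$vertices), , drop = FALSE]
  # invert the reduction for a pseudo-sample sitting at the curve's far end
  z <- far %*% t(h$rotation)
  x <- z * h$scale + h$center
  far_sample <- matrix(rowMeans(m[, controls]), ncol = 1,
                       dimnames = list(rownames(m), "far"))
  far_sample[h$genes, 1] <- as.numeric(x)
  expect_equal(unname(score_new_samples(fit, far_sample)[pid, 1]), 1)
})

test_that("planted displacement is recovered monotonically", {
  cohort <- small_cohort()
  ann <- cohort$annotations
  m <- do.call(cbind, unname(cohort$matrices))
  bm <- combat_fit(m, setNames(ann$study_id, ann$sample_id))
  controls <- ann$sample_id[ann$label == "S"]
  fit <- score_all_pathways(bm$adjusted, cohort$gene_sets, controls)
  expect_true(all(fit$pds >= 0 & fit$pds <= 1))
  u <- cohort$truth$displacement[colnames(fit$pds)]
  for (pid in cohort$truth$informative_pathways) {
    expect_gt(cor(fit$pds[pid, ], u, method = "spearman"), 0.8)
    expect_gt(mean(fit$pds[pid, ann$label == "AR"]),
              mean(fit$pds[pid, ann$label == "S"]))
  }
})

test_that("re-scoring training samples reproduces training PDS", {
  cohort <- small_cohort()
  ann <- cohort$annotations
  m <- do.call(cbind, unname(cohort$matrices))
  controls <- ann$sample_id[ann$label == "S"]
  fit <- score_all_pathways(m, cohort$gene_sets, controls)
  again <- score_new_samples(fit, m)
  expect_equal(again, fit$pds, tolerance = 1e-10)
})

test_that("unscorable pathways are skipped with reasons, not NaN-filled", {
  m <- toy_matrix(10, 8)
  rownames(m) <- paste0("G", 1:10)
  sets <- list(
    ok = list(id = "ok", name = "", genes = paste0("G", 1:6)),
    tiny = list(id = "tiny", name = "", genes = c("G1", "ZZZ")),
    absent = list(id = "absent", name = "", genes = c("X1", "X2", "X3")))
  fit <- score_all_pathways(m, sets, controls = colnames(m)[1:3])
  expect_identical(rownames(fit$pds), "ok")
  expect_setequal(fit$skipped$pathway_id, c("tiny", "absent"))
  expect_error(score_all_pathways(m, sets["absent"], colnames(m)[1:3]),
               "no pathway could be scored")
  expect_error(score_all_pathways(m, sets, character(0)), "non-empty")
})

test_that("new samples missing pathway genes are rejected", {
  cohort <- small_cohort()
  m <- do.call(cbind, unname(cohort$matrices))
  ann <- cohort$annotations
  fit <- score_all_pathways(m, cohort$gene_sets[1:3],
                            ann$sample_id[ann$label == "S"])
  m_new <- m[-(1:50), 1:4]
  expect_error(score_new_samples(fit, m_new), "genes missing")
})
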