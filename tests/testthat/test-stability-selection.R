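test_that("stratified splitting follows largest-remainder allocation", {
  df <- data.frame(patient_id = sprintf("p%02d", 1:20),
                   stage = rep(c("1", "2"), each = 10))
  sp <- stratified_split(df, 0.7, strata = "stage", seed = 1)
  expect_identical(nrow(sp$train), 14L)
  expect_identical(as.vector(table(sp$train$stage)), c(7L, 7L))
  expect_identical(as.vector(table(sp$test$stage)), c(3L, 3L))

  # targets 3.5, 2.1, 1.4 -> floors 3,2,1; one leftover goes to remainder .5
  df2 <- data.frame(patient_id = sprintf("p%02d", 1:10),
                    stage = rep(c("1", "2", "3"), c(5, 3, 2)))
  sp2 <- stratified_split(df2, 0.7, strata = "stage", seed = 2)
  expect_identical(as.vector(table(factor(sp2$train$stage, c("1", "2", "3")))),
                   c(4L, 2L, 1L))

  # reproducible membership; disjoint exhaustive union
  sp3 <- stratified_split(df2, 0.7, strata = "stage", seed = 2)
  expect_identical(sp2$train$patient_id, sp3$train$patient_id)
  expect_setequal(c(sp2$train$patient_id, sp2$test$patient_id), df2$patient_id)
  expect_length(intersect(sp2$train$patient_id, sp2$test$patient_id), 0L)

  # a singleton stratum goes wholly to training, with a warning
  df3 <- data.frame(patient_id = sprintf("p%02d", 1:9),
                    stage = c(rep("1", 8), "4"))
  expect_warning(sp4 <- stratified_split(df3, 0.7, strata = "stage", seed = 3),
                 "size 1")
  expect_true("p09" %in% sp4$train$patient_id)

  # missing stratum values form their own stratum
  df4 <- data.frame(patient_id = sprintf("p%02d", 1:12),
                    stage = c(rep("1", 8), rep(NA, 4)))
  sp5 <- stratified_split(df4, 0.75, strata = "stage", seed = 4)
  expect_identical(sum(is.na(sp5$train$stage)), 3L)
  expect_error(stratified_split(df4, 1.2), "train_fraction")
})

test_that("split membership is invariant to the row order of the cohort", {
  co <- toy_cohort(40, seed = 2)
  sp_a <- stratified_split(co, 0.7, seed = 5)
  set.seed(77)
  co_shuf <- co[sample(nrow(co)), ]
  sp_b <- stratified_split(co_shuf, 0.7, seed = 5)
  expect_setequal(sp_a$train$patient_id, sp_b$train$patient_id)
})

test_that("single-split selection counts are consistent with the recorded model", {
  co <- generate_cohort(planted_config(n = 120, seed = 3))
  prof <- suppressWarnings(
    selection_frequencies(co, "os", n_splits = 1, master_seed = 2, k_folds = 5))
  expect_true(all(prof$counts %in% c(0L, 1L)))
  selected <- names(prof$coefficients[[1]])
  expect_setequal(names(prof$counts)[prof$counts == 1], selected)
  expect_true(all(prof$coefficients[[1]] != 0))
  # reproducible end to end
  prof2 <- suppressWarnings(
    selection_frequencies(co, "os", n_splits = 1, master_seed = 2, k_folds = 5))
  expect_identical(prof$counts, prof2$counts)
  expect_identical(prof$coefficients, prof2$coefficients)
})

test_that("the permutation threshold is the largest per-gene null count", {
  co <- generate_cohort(planted_config(n = 120, seed = 13))
  null <- suppressWarnings(
    permutation_null(co, "os", n_perm = 6, master_seed = 9, k_folds = 5,
                     nlambda = 25))
  expect_identical(null$threshold, max(rowSums(null$count_matrix)))
  expect_gte(null$threshold, 0)
  expect_lte(null$threshold, null$n_perm)
  expect_true(all(null$count_matrix %in% c(0L, 1L)))
})

test_that("significant_genes applies the strictly-greater rule in order", {
  prof <- structure(list(counts = c(a = 500L, b = 200L, c = 10L),
                         pct = c(a = 50, b = 20, c = 1),
                         threshold = 150L),
                    class = "selection_profile")
  sg <- significant_genes(prof)
  expect_identical(sg$gene, c("a", "b"))
  expect_identical(sg$count, c(500L, 200L))
  # all at or below the threshold: empty
  prof$threshold <- 600L
  expect_identical(nrow(significant_genes(prof)), 0L)
  # equality is excluded
  prof$threshold <- 200L
  expect_identical(significant_genes(prof)$gene, "a")
})

test_that("observed and permuted counts are exchangeable on null data", {
  # on outcome-free data a given gene clears the strictly-greater threshold
  # with probability at most ~1/#genes (it must beat the maximum of the
  # exchangeable null counts, its own included)
  n_genes <- 8
  false_rate <- vapply(1:20, function(r) {
    co <- generate_cohort(null_config(n = 100, seed = 500 + r))
    genes <- unclass(attr(co, "panel"))[seq_len(n_genes)]
    prof <- suppressWarnings(
      stability_selection(co, "os", genes = genes, n_splits = 8, n_perm = 8,
                          master_seed = r, k_folds = 5, nlambda = 25))
    length(prof$significant) / n_genes
  }, numeric(1))
  expect_lte(mean(false_rate), 0.15)
})
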