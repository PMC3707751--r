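test_that("ddct_log2_relative computes log2 relative expression", {
  expect_equal(ddct_log2_relative(25, 20, 27, 20), 2.0)
  expect_equal(ddct_log2_relative(23, 21, 23, 21), 0.0)
  expect_equal(ddct_log2_relative(26, 20, 25, 20), -1.0)
  # invariant under adding a constant to both sample or both calibrator Cts
  expect_equal(ddct_log2_relative(25 + 3, 20 + 3, 27, 20),
               ddct_log2_relative(25, 20, 27, 20))
  expect_equal(ddct_log2_relative(25, 20, 27 + 1.5, 20 + 1.5),
               ddct_log2_relative(25, 20, 27, 20))
  # linear in each argument with coefficient +/-1
  expect_equal(ddct_log2_relative(26, 20, 27, 20),
               ddct_log2_relative(25, 20, 27, 20) - 1)
  expect_error(ddct_log2_relative(NA, 20, 27, 20), "finite")
  expect_error(ddct_log2_relative(Inf, 20, 27, 20), "finite")
})

test_that("cohort files round-trip exactly and validate their schema", {
  co <- toy_cohort(n = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- suppressMessages(read_cohort(path))
  expect_identical(dim(back), dim(co))
  expect_identical(back$patient_id, co$patient_id)
  expect_equal(expression_matrix(back), expression_matrix(co), tolerance = 0)
  expect_identical(back$os_months, co$os_months)
  expect_identical(as.character(back$stage), as.character(co$stage))

  # missing required column is named in the error
  df <- as.data.frame(co)
  df$os_event <- NULL
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(read_cohort(path2)), "os_event")

  # missing tokens in a clinical column are legal and preserved
  df2 <- as.data.frame(co)
  df2$stage[1:2] <- NA
  path3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df2, path3, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  back3 <- suppressMessages(read_cohort(path3))
  expect_identical(sum(is.na(back3$stage)), sum(is.na(df2$stage)))

  # duplicate patient ids are rejected
  df3 <- as.data.frame(co)
  df3$patient_id[2] <- df3$patient_id[1]
  expect_error(cohort_table(df3), "duplicate patient_id")

  # non-numeric expression entries are located
  df4 <- as.data.frame(co)
  df4$PGR <- as.character(df4$PGR)
  df4$PGR[3] <- "oops"
  expect_error(cohort_table(df4), "PGR")
})

test_that("read_cohort applies a JSON column-renaming sidecar", {
  co <- toy_cohort(n = 5)
  df <- as.data.frame(co)
  names(df)[names(df) == "os_months"] <- "surv_time"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  sidecar <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(os_months = "surv_time"), sidecar, auto_unbox = TRUE)
  back <- suppressMessages(read_cohort(path, col_map = sidecar))
  expect_equal(back$os_months, co$os_months, tolerance = 1e-12)
})

test_that("complete_cases drops by outcome, covariates and disease-free status", {
  co <- toy_cohort(n = 10)
  df <- as.data.frame(co)
  df$stage[1:2] <- NA
  df$never_disease_free <- 0
  df$never_disease_free[5] <- 1
  df$dfs_months <- abs(df$dfs_months)
  df$dfs_months[is.na(df$dfs_months)] <- 10
  df$dfs_event[is.na(df$dfs_event)] <- 0
  co2 <- cohort_table(df)

  expect_identical(nrow(suppressMessages(complete_cases(co2, "os", "stage"))), 8L)
  # never-disease-free patients drop from recurrence models only
  expect_identical(nrow(suppressMessages(complete_cases(co2, "dfs"))), 9L)
  expect_identical(nrow(suppressMessages(complete_cases(co2, "os"))), 10L)
  # idempotent, and never grows
  cc <- suppressMessages(complete_cases(co2, "dfs", "stage"))
  expect_identical(nrow(suppressMessages(complete_cases(cc, "dfs", "stage"))), nrow(cc))
  expect_lte(nrow(cc), nrow(co2))
  expect_error(suppressMessages(complete_cases(co2, "os", "nope")), "unknown covariate")

  df$os_months <- rep(NA_real_, 10)
  df$os_event <- rep(NA_real_, 10)
  co3 <- cohort_table(df)
  expect_error(suppressMessages(complete_cases(co3, "os")), "no complete cases")
})

test_that("gene_panel validates signatures and uniqueness", {
  p <- gene_panel()
  expect_length(unclass(p), 32L)
  expect_true(all(attr(p, "os_signature") %in% unclass(p)))
  expect_true(all(attr(p, "dfs_signature") %in% unclass(p)))
  expect_setdiff <- setdiff(attr(p, "dfs_signature"), attr(p, "os_signature"))
  expect_identical(expect_setdiff, "NAT1")
  expect_error(gene_panel(c("A", "A", "B")), "duplicate")
  expect_error(gene_panel(c("A", "B"), os_signature = "C"), "not in panel")
})
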