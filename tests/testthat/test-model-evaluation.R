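test_that("harrell_c handles the canonical perfect and degenerate cases", {
  expect_equal(harrell_c(1:4, rep(1, 4), c(4, 3, 2, 1)), 1)
  expect_equal(harrell_c(1:4, rep(1, 4), c(1, 2, 3, 4)), 0)
  expect_equal(harrell_c(1:4, rep(1, 4), rep(2, 4)), 0.5)
  # censored example with tied scores, against exhaustive enumeration
  tm <- c(1, 2, 3, 4)
  ev <- c(1, 1, 0, 1)
  sc <- c(3, 3, 1, 2)
  expect_equal(harrell_c(tm, ev, sc), bf_harrell_c(tm, ev, sc))
  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)), "event")
  expect_error(harrell_c(c(2, 2), c(1, 1), c(1, 2)), "comparable")
})

test_that("harrell_c equals brute-force enumeration across random instances", {
  set.seed(606)
  for (r in 1:200) {
    n <- sample(3:30, 1)
    tm <- sample(1:8, n, replace = TRUE)       # many tied times
    ev <- rbinom(n, 1, 0.6)
    sc <- sample(seq(-2, 2, 0.5), n, replace = TRUE)  # tied scores too
    ok <- tryCatch(bf_harrell_c(tm, ev, sc), error = function(e) NULL)
    if (is.null(ok)) next
    expect_equal(harrell_c(tm, ev, sc), ok, tolerance = 1e-12)
    # complement symmetry when no comparable pair shares a score
    sc2 <- stats::runif(n)
    expect_equal(harrell_c(tm, ev, sc2) + harrell_c(tm, ev, -sc2), 1,
                 tolerance = 1e-12)
  }
})

test_that("classify_risk cuts at the training median with ties going low", {
  expect_identical(as.character(classify_risk(c(0, 1, 2), c(0.5, 3))),
                   c("low", "high"))
  expect_identical(as.character(classify_risk(c(0, 1, 2), c(1, 1))),
                   c("low", "low"))
  expect_error(classify_risk(numeric(0), 1), "empty")
})

test_that("collapse_probes keeps the most variable probe per gene", {
  expr <- rbind(p1 = c(1, 2, 3, 8), p2 = c(1, 1.5, 2, 2.5), p3 = c(0, 0, 1, 0))
  map <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB")
  out <- collapse_probes(expr, map)
  expect_identical(rownames(out), c("GENEA", "GENEB"))
  expect_equal(out["GENEA", ], expr["p1", ])
  # unique probes pass through unchanged
  expr2 <- expr
  map2 <- c(p1 = "A", p2 = "B", p3 = "C")
  expect_equal(unname(collapse_probes(expr2, map2)), unname(expr2))
  # exact variance tie: first probe in input order wins
  expr3 <- rbind(q1 = c(0, 1), q2 = c(5, 6))
  out3 <- collapse_probes(expr3, c(q1 = "G", q2 = "G"))
  expect_equal(out3["G", ], expr3["q1", ])
  expect_error(collapse_probes(expr, character()), "empty")
  expect_error(collapse_probes(expr, c(p1 = "A")), "not covered")
})

test_that("gene models outperform clinical models when only genes carry signal", {
  co <- generate_cohort(planted_config(n = 225, seed = 71))
  ev <- suppressWarnings(
    compare_models(co, "os", gene_set = names(planted_beta), n_splits = 40,
                   master_seed = 3, keep_km = TRUE))
  expect_gt(ev$summary$genes$median, ev$summary$clinical$median)
  expect_true(all(ev$splits$c_genes >= 0 & ev$splits$c_genes <= 1))
  expect_true(ev$summary$genes$ci[1] <= ev$summary$genes$median &&
                ev$summary$genes$median <= ev$summary$genes$ci[2])
})

test_that("risk classes separate the Kaplan-Meier curves under strong signal", {
  co <- generate_cohort(planted_config(
    n = 400, seed = 76,
    beta = c(RABEP1 = -0.4, FUT8 = -0.4, SCUBE2 = 0.4)))
  ev <- suppressWarnings(
    compare_models(co, "os", gene_set = c("RABEP1", "FUT8", "SCUBE2"),
                   n_splits = 40, master_seed = 4, keep_km = TRUE))
  km <- ev$km[ev$km$model == "genes", ]
  step_at <- function(cv, t) {
    idx <- which(cv$time <= t)
    if (!length(idx)) 1 else cv$surv[max(idx)]
  }
  worse <- vapply(unique(km$split), function(s) {
    lo <- km[km$split == s & km$class == "low", ]
    hi <- km[km$split == s & km$class == "high", ]
    if (!nrow(lo) || !nrow(hi)) return(NA)
    t_common <- min(max(lo$time), max(hi$time))
    step_at(hi, t_common) < step_at(lo, t_common)
  }, logical(1))
  expect_gte(mean(worse, na.rm = TRUE), 0.95)
})

test_that("an empty clinical specification collapses combined onto genes", {
  co <- generate_cohort(planted_config(n = 150, seed = 72))
  ev <- suppressWarnings(
    compare_models(co, "os", gene_set = names(planted_beta), n_splits = 8,
                   master_seed = 5, clinical_vars = character(), keep_km = FALSE))
  expect_identical(ev$splits$c_genes, ev$splits$c_combined)
  expect_identical(ev$splits$c_genes, ev$splits$c_clinical)
})

test_that("evaluation medians are invariant to patient row order", {
  co <- generate_cohort(planted_config(n = 150, seed = 73))
  ev1 <- suppressWarnings(compare_models(co, "os", gene_set = names(planted_beta),
                                         n_splits = 6, master_seed = 11,
                                         keep_km = FALSE))
  set.seed(1)
  co2 <- co[sample(nrow(co)), ]
  attr(co2, "panel") <- attr(co, "panel")
  ev2 <- suppressWarnings(compare_models(co2, "os", gene_set = names(planted_beta),
                                         n_splits = 6, master_seed = 11,
                                         keep_km = FALSE))
  expect_equal(ev1$summary$genes$median, ev2$summary$genes$median)
  expect_equal(ev1$summary$clinical$median, ev2$summary$clinical$median)
})

test_that("three-model comparison on permuted outcomes centers at one half", {
  # fresh outcome permutation per split, as in the permuted reference runs
  co <- generate_cohort(sim_config(n_patients = 225, seed = 74))
  cs <- lapply(1:200, function(s) {
    pm <- permute_outcomes(co, "os", seed = 9000 + s)
    ev <- suppressWarnings(
      compare_models(pm, "os", n_splits = 1, master_seed = s, keep_km = FALSE))
    ev$splits[, c("c_genes", "c_clinical", "c_combined")]
  })
  cs <- do.call(rbind, cs)
  for (m in c("c_genes", "c_clinical", "c_combined")) {
    expect_lt(abs(stats::median(cs[[m]]) - 0.5), 0.03)
  }
})

test_that("the random gene comparator pairs with the signature evaluation", {
  co <- generate_cohort(planted_config(n = 150, seed = 75))
  panel <- unclass(attr(co, "panel"))
  rc <- suppressWarnings(
    random_gene_comparator(co, "os", k = length(panel), n_splits = 5,
                           master_seed = 21))
  ev <- suppressWarnings(
    compare_models(co, "os", gene_set = panel, n_splits = 5, master_seed = 21,
                   clinical_vars = character(), keep_km = FALSE))
  expect_equal(as.numeric(rc), ev$splits$c_genes)
  rc2 <- suppressWarnings(
    random_gene_comparator(co, "os", k = length(panel), n_splits = 5,
                           master_seed = 21))
  expect_identical(as.numeric(rc), as.numeric(rc2))
  expect_error(random_gene_comparator(co, "os", k = 99, n_splits = 2), "panel size")
})
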