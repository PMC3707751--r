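test_that("partial likelihood at beta = 0 depends only on risk-set sizes", {
  X <- matrix(0, 3, 1)
  expect_equal(cox_partial_loglik(0, X, c(1, 2, 3), c(1, 1, 1)), -log(6))
  # censored subjects contribute no event term
  expect_equal(cox_partial_loglik(0, X, c(1, 2, 3), c(1, 0, 1)), -log(3))
  expect_error(cox_partial_loglik(0, X, c(1, 2, 3), c(0, 0, 0)), "event")
  expect_error(cox_partial_loglik(0, matrix(c(1, NA, 0), 3, 1), c(1, 2, 3),
                                  c(1, 1, 1)), "non-finite")
})

test_that("Breslow likelihood matches an explicit hand computation", {
  # 4 subjects, binary covariate, all events at distinct times 1<2<3<4
  x <- c(1, 0, 1, 0)
  b <- 1
  hand <- (b * 1 - log(exp(b) + 1 + exp(b) + 1)) +
    (b * 0 - log(1 + exp(b) + 1)) +
    (b * 1 - log(exp(b) + 1)) +
    (b * 0 - log(1))
  expect_equal(cox_partial_loglik(b, matrix(x), 1:4, rep(1, 4), "breslow"),
               hand, tolerance = 1e-12)
})

test_that("Breslow and Efron agree exactly without tied event times", {
  set.seed(31)
  X <- matrix(rnorm(40), 20, 2)
  tm <- rexp(20)
  ev <- rbinom(20, 1, 0.7)
  ev[1] <- 1
  b <- c(0.4, -0.7)
  expect_equal(cox_partial_loglik(b, X, tm, ev, "breslow"),
               cox_partial_loglik(b, X, tm, ev, "efron"), tolerance = 1e-12)
})

test_that("Newton fit handles tie symmetry and flags monotone likelihood", {
  # two events at the same time: score at 0 vanishes by symmetry
  f <- fit_cox(matrix(c(1, 0)), c(5, 5), c(1, 1), ties = "breslow")
  expect_equal(unname(stats::coef(f)), 0, tolerance = 1e-8)
  # separation: likelihood increases monotonely in beta
  f2 <- fit_cox(matrix(c(1, 0)), c(1, 2), c(1, 1))
  expect_true(any(f2$diverged))
  expect_error(fit_cox(matrix(1, 5, 1), rexp(5), rep(1, 5)), "constant covariate")
})

test_that("Newton fit matches brute-force 1-D maximization and coxph", {
  set.seed(7)
  x <- c(1, 1, 0, 0, 1, 0)
  tm <- c(2, 5, 3, 8, 9, 1)
  ev <- c(1, 0, 1, 1, 1, 1)
  for (ties in c("breslow", "efron")) {
    fit <- fit_cox(matrix(x), tm, ev, ties = ties)
    bf <- stats::optimize(function(b) cox_partial_loglik(b, matrix(x), tm, ev, ties),
                          c(-10, 10), maximum = TRUE, tol = 1e-10)
    expect_equal(unname(stats::coef(fit)), bf$maximum, tolerance = 1e-6)
  }
  # multivariable cross-check against the survival package, with ties
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  tm <- ceiling(rexp(n, 0.2 * exp(X %*% c(0.5, -0.4, 0))))
  ev <- rbinom(n, 1, 0.7)
  ev[which.max(tm)] <- 1
  for (ties in c("breslow", "efron")) {
    fit <- fit_cox(X, tm, ev, ties = ties)
    ref <- survival::coxph(survival::Surv(tm, ev) ~ X, ties = ties)
    expect_equal(unname(stats::coef(fit)), unname(stats::coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  }
  # martingale residuals sum to zero and match the reference implementation
  fitb <- fit_cox(X, tm, ev, ties = "breslow")
  refb <- survival::coxph(survival::Surv(tm, ev) ~ X, ties = "breslow")
  expect_equal(stats::residuals(fitb),
               unname(stats::residuals(refb, type = "martingale")),
               tolerance = 1e-6)
  expect_lt(abs(sum(stats::residuals(fitb))), 1e-8)
})

test_that("two-group exponential data recover the true log hazard ratio", {
  set.seed(99)
  n <- 10000
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.01 * exp(0.7 * x))
  cn <- rexp(n, 0.005)
  fit <- fit_cox(matrix(x, dimnames = list(NULL, "grp")), pmin(tm, cn),
                 as.numeric(tm <= cn))
  expect_lt(abs(stats::coef(fit) - 0.7) / 0.7, 0.1)
  # HR table is exp(beta +/- 1.96 se), exactly
  hr <- hazard_ratios(fit)
  expect_equal(hr$hr, unname(exp(stats::coef(fit))))
  expect_true(hr$lower < hr$hr && hr$hr < hr$upper)
})

test_that("linear predictor is the matrix product and checks columns", {
  co <- toy_cohort(20)
  sig <- attr(gene_panel(), "os_signature")
  X <- expression_matrix(co, sig)
  fit <- fit_cox(X, co$os_months, co$os_event)
  expect_equal(linear_predictor(fit, X), drop(X %*% stats::coef(fit)))
  x1 <- matrix(0:2, dimnames = list(NULL, "g"))
  f1 <- list(coefficients = c(g = 1))
  class(f1) <- "survsig_cox"
  expect_equal(linear_predictor(f1, x1), c(0, 1, 2))
  # rank-invariance under covariate shifts
  expect_equal(diff(linear_predictor(fit, X + 5)), diff(linear_predictor(fit, X)))
  expect_error(linear_predictor(fit, X[, -1]), "do not match")
})

test_that("kaplan_meier reproduces hand product-limit calculations", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  km2 <- kaplan_meier(c(1, 2, 2.5, 3), c(1, 0, 0, 1))
  expect_equal(km_survival(km2, c(1, 3)), c(3 / 4, 0))
  km3 <- kaplan_meier(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_equal(km_survival(km3, 100), 1)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})
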