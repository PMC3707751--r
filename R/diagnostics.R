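#' Residual-adjustment Cox analysis
#'
#' Explains sign flips between marginal and multivariable effects of a
#' correlated gene: ordinary least squares regresses the target gene on the
#' adjuster genes (with intercept), and the residuals — the component of the
#' target's expression not explained by the correlated block — enter a
#' univariate Cox model. A marginally null gene whose residual carries
#' hazard (the LRBA phenomenon: marginal HR near 1, residual HR > 1) is
#' detected this way. With an empty adjuster set the residual is the
#' centered target, so the fit equals the plain univariate model.
#'
#' @param cohort a `cohort_table`.
#' @param target_gene gene whose residual expression is tested.
#' @param adjustment_genes genes regressed out (may be empty).
#' @param outcome `"os"` or `"dfs"`.
#' @return A `survsig_cox` fit on the residual covariate, with attributes
#'   `ols` (the linear model, `NULL` if no adjusters) and `residuals`.
#' @export
residual_cox <- function(cohort, target_gene, adjustment_genes,
                         outcome = c("os", "dfs")) {
  outcome <- match.arg(outcome)
  all_genes <- c(target_gene, adjustment_genes)
  bad <- setdiff(all_genes, names(cohort))
  if (length(bad)) stop("genes not in cohort: ", paste(bad, collapse = ", "))
  cc <- complete_cases(cohort, outcome, covariates = all_genes, quiet = TRUE)
  y <- as.numeric(cc[[target_gene]])
  if (length(adjustment_genes)) {
    df <- as.data.frame(cc)[adjustment_genes]
    ols <- stats::lm(y ~ ., data = df)
    if (any(is.na(stats::coef(ols)))) {
      dropped <- names(stats::coef(ols))[is.na(stats::coef(ols))]
      stop("collinear adjusters: ", paste(dropped, collapse = ", "))
    }
    res <- stats::residuals(ols)
  } else {
    ols <- NULL
    res <- y - mean(y)
  }
  X <- matrix(res, ncol = 1,
              dimnames = list(NULL, paste0(target_gene, "_residual")))
  fit <- fit_cox(X, cc[[paste0(outcome, "_months")]],
                 cc[[paste0(outcome, "_event")]], ties = "efron")
  attr(fit, "ols") <- ols
  attr(fit, "residuals") <- res
  attr(fit, "target_gene") <- target_gene
  attr(fit, "adjustment_genes") <- adjustment_genes
  fit
}

#' Power parameters for the minimal detectable hazard ratio
#'
#' @param alpha per-test type-I error (default 0.05/32, Bonferroni-style
#'   across the 32-gene panel).
#' @param type_ii_error type-II error (default 0.2, i.e. 80% power).
#' @param n_events number of observed events D (default 68).
#' @param covariate_sd SD of the covariate, here the median per-gene SD of
#'   log2 expression (default 1.8).
#' @param sidedness `"one"` uses \eqn{z_{1-\alpha}} (the formula as printed);
#'   `"two"` uses \eqn{z_{1-\alpha/2}}.
#' @return list of validated parameters, class `power_params`.
#' @export
power_params <- function(alpha = 0.05 / 32, type_ii_error = 0.2,
                         n_events = 68, covariate_sd = 1.8,
                         sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (type_ii_error <= 0 || type_ii_error >= 1) stop("type_ii_error must be in (0,1)")
  if (n_events < 1) stop("n_events must be >= 1")
  if (covariate_sd <= 0) stop("covariate_sd must be positive")
  structure(list(alpha = alpha, type_ii_error = type_ii_error,
                 n_events = n_events, covariate_sd = covariate_sd,
                 sidedness = sidedness),
            class = "power_params")
}

#' Minimal detectable hazard ratio
#'
#' Literal evaluation of the study-power formula
#' \deqn{\log HR = \sqrt{(z_{1-\alpha} + z_{1-\beta})^2 / (D \sigma^2)}}
#' for a univariate Cox test with D events and covariate SD \eqn{\sigma};
#' returns the detectable HR and its protective reciprocal (their product is
#' exactly 1). Strictly decreasing in D and \eqn{\sigma}; strictly
#' increasing as \eqn{\alpha} decreases.
#'
#' @param params a [power_params()] object.
#' @return list with `log_hr`, `hr` and `hr_reciprocal`.
#' @examples
#' detectable_hr(power_params(alpha = 0.025, type_ii_error = 0.5,
#'                            n_events = 100, covariate_sd = 1))$hr  # ~1.2166
#' @export
detectable_hr <- function(params = power_params()) {
  stopifnot(inherits(params, "power_params"))
  z_a <- if (params$sidedness == "one") stats::qnorm(1 - params$alpha) else
    stats::qnorm(1 - params$alpha / 2)
  z_b <- stats::qnorm(1 - params$type_ii_error)
  log_hr <- sqrt((z_a + z_b)^2 / (params$n_events * params$covariate_sd^2))
  list(log_hr = log_hr, hr = exp(log_hr), hr_reciprocal = exp(-log_hr))
}

#' Gene-by-clinical interaction scan
#'
#' For each gene, fits a Cox model with the gene, the clinical variable's
#' contrasts and their products, and tests the interaction block with a Wald
#' chi-square test; p-values are BH-adjusted across genes. Genes whose model
#' cannot be fitted (e.g. insufficient events in a stratum) are skipped with
#' a warning.
#'
#' @param cohort a `cohort_table`.
#' @param genes genes to scan (default: full panel).
#' @param clinical_var one of `"stage"` (3-level, stages 3-4 pooled),
#'   `"nodes"`, `"er_pr"` (ER and PR binaries) or `"treatment"`
#'   (chemotherapy).
#' @param outcome `"os"` or `"dfs"`.
#' @return data frame: `gene`, `df`, `wald_chisq`, `p`, `p_adj`, sorted by
#'   raw p.
#' @export
interaction_scan <- function(cohort, genes = NULL,
                             clinical_var = c("stage", "nodes", "er_pr", "treatment"),
                             outcome = c("os", "dfs")) {
  clinical_var <- match.arg(clinical_var)
  outcome <- match.arg(outcome)
  if (is.null(genes)) genes <- unclass(attr(cohort, "panel"))
  vars <- switch(clinical_var,
                 stage = "stage3", nodes = "nodes", er_pr = c("er", "pr"),
                 treatment = "chemotherapy")
  Z <- .clinical_design(cohort, vars)
  tcol <- paste0(outcome, "_months")
  ecol <- paste0(outcome, "_event")
  rows <- list()
  for (g in genes) {
    x <- as.numeric(cohort[[g]])
    inter <- Z * x
    colnames(inter) <- paste0(g, ":", colnames(Z))
    X <- cbind(x, Z, inter)
    colnames(X) <- c(g, colnames(Z), colnames(inter))
    keep <- stats::complete.cases(X) & !is.na(cohort[[tcol]]) & !is.na(cohort[[ecol]])
    if (outcome == "dfs") keep <- keep & !(cohort$never_disease_free %in% 1)
    res <- tryCatch({
      fit <- fit_cox(X[keep, , drop = FALSE], cohort[[tcol]][keep],
                     cohort[[ecol]][keep], ties = "efron")
      iidx <- grep(":", names(stats::coef(fit)), fixed = TRUE)
      b <- stats::coef(fit)[iidx]
      V <- stats::vcov(fit)[iidx, iidx, drop = FALSE]
      w <- drop(t(b) %*% solve(V, b))
      data.frame(gene = g, df = length(iidx), wald_chisq = w,
                 p = stats::pchisq(w, df = length(iidx), lower.tail = FALSE))
    }, error = function(e) {
      warning("gene '", g, "' skipped in interaction scan: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[g]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene could be scanned")
  out$p_adj <- adjust_pvalues(out$p, "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
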