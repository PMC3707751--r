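#' Harrell's concordance index for right-censored data
#'
#' Estimates the probability that, of a randomly chosen comparable pair, the
#' subject with the higher risk score (shorter predicted survival) fails
#' first. A pair is comparable when the shorter observed time belongs to an
#' event and the times differ, or when the times are tied and exactly one
#' subject is an event (the event is treated as failing first). Concordant
#' pairs score 1, tied risk scores 0.5, discordant 0; C is the total over the
#' number of comparable pairs.
#'
#' @param times,events follow-up times and event indicators.
#' @param risk_scores per-subject risk scores (higher = shorter predicted
#'   survival).
#' @return concordance in \[0, 1\].
#' @examples
#' harrell_c(c(1, 2, 3, 4), c(1, 1, 1, 1), c(4, 3, 2, 1))  # 1
#' @export
harrell_c <- function(times, events, risk_scores) {
  n <- length(times)
  if (length(events) != n || length(risk_scores) != n) stop("length mismatch")
  if (anyNA(times) || anyNA(events) || anyNA(risk_scores)) stop("missing values")
  if (sum(events == 1) < 1) stop("at least one event required")
  num <- 0
  den <- 0
  for (i in which(events == 1)) {
    cmp <- (times > times[i]) | (times == times[i] & events == 0)
    cmp[i] <- FALSE
    m <- sum(cmp)
    if (!m) next
    den <- den + m
    num <- num + sum(risk_scores[i] > risk_scores[cmp]) +
      0.5 * sum(risk_scores[i] == risk_scores[cmp])
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Median-split risk classification
#'
#' Labels test subjects by comparing their risk scores to the median of the
#' *training* linear predictors: above the median is high risk, at or below
#' is low risk.
#'
#' @param train_scores training-set linear predictors (defines the cut).
#' @param test_scores scores to classify.
#' @return factor with levels `low`, `high`.
#' @export
classify_risk <- function(train_scores, test_scores) {
  if (!length(train_scores)) stop("empty training scores")
  cut <- stats::median(train_scores)
  factor(ifelse(test_scores > cut, "high", "low"), levels = c("low", "high"))
}

# design matrix for the clinical model; rows with missing source values get NA
.clinical_design <- function(cohort, vars) {
  if (!length(vars)) return(NULL)
  cols <- list()
  for (v in vars) {
    if (v == "stage3") {
      # stages 3 and 4 pooled, stage 1 reference
      cols$stage2 <- as.numeric(cohort$stage == "2")
      cols$stage34 <- as.numeric(cohort$stage %in% c("3", "4"))
      cols$stage2[is.na(cohort$stage)] <- NA
      cols$stage34[is.na(cohort$stage)] <- NA
    } else if (v == "stage4") {
      for (lv in c("2", "3", "4")) {
        cols[[paste0("stage", lv)]] <- as.numeric(cohort$stage == lv)
      }
    } else if (v == "er") {
      cols$er_neg <- as.numeric(cohort$er_status == "-")
    } else if (v == "pr") {
      cols$pr_neg <- as.numeric(cohort$pr_status == "-")
    } else if (v == "nodes") {
      cols$nodes_neg <- as.numeric(cohort$nodes == "neg")
    } else if (v == "grade") {
      cols$grade2 <- as.numeric(cohort$grade == "2")
      cols$grade34 <- as.numeric(cohort$grade == "3-4")
    } else if (v == "center") {
      lv <- levels(factor(cohort$center))
      for (l in lv[-1]) cols[[paste0("center_", l)]] <- as.numeric(cohort$center == l)
    } else if (v %in% names(cohort)) {
      cols[[v]] <- as.numeric(cohort[[v]])
    } else {
      stop("unknown clinical variable: ", v)
    }
  }
  do.call(cbind, cols)
}

.km_curve <- function(times, events) {
  km <- kaplan_meier(times, events)
  km[km$n_event > 0, c("time", "surv"), drop = FALSE]
}

#' Compare gene, clinical and combined models over repeated splits
#'
#' For each of `n_splits` stage-stratified 70/30 train/test splits, fits
#' three unpenalized Cox models on the training complete cases (fixed gene
#' set, no re-selection; clinical covariates; both together), scores the test
#' set by Harrell's C, classifies test patients into low/high risk at the
#' median training linear predictor, and records the test Kaplan-Meier curve
#' of each risk class. Also computes subgroup C-indexes on the ER+ and ER-
#' test subsets using the all-patient fits. Summaries are medians with
#' empirical 95% (2.5th/97.5th percentile) intervals; model contrasts are
#' paired per-split differences with percentile intervals.
#'
#' @param cohort a `cohort_table`.
#' @param outcome `"os"` or `"dfs"`.
#' @param gene_set character vector of signature genes (default: the panel's
#'   signature for `outcome`).
#' @param clinical_vars clinical design specification (see Details); default
#'   pooled 3-level stage, ER status and PR status. An empty vector collapses
#'   the combined model onto the gene model.
#' @param n_splits number of train/test splits.
#' @param master_seed master seed; split `i` uses [child_seed()] stream 21.
#' @param train_fraction training fraction (default 0.7).
#' @param keep_km retain per-split risk-class Kaplan-Meier curves.
#' @return Object of class `evaluation_result`.
#' @export
compare_models <- function(cohort, outcome = c("os", "dfs"), gene_set = NULL,
                           clinical_vars = c("stage3", "er", "pr"),
                           n_splits = 1000L, master_seed = 1L,
                           train_fraction = 0.7, keep_km = TRUE) {
  outcome <- match.arg(outcome)
  panel <- attr(cohort, "panel")
  if (is.null(gene_set)) gene_set <- attr(panel, paste0(outcome, "_signature"))
  bad <- setdiff(gene_set, unclass(panel))
  if (length(bad)) stop("gene_set outside panel: ", paste(bad, collapse = ", "))
  cc <- complete_cases(cohort, outcome, quiet = TRUE)
  tcol <- paste0(outcome, "_months")
  ecol <- paste0(outcome, "_event")

  one_model <- function(train, test, Xtr, Xte) {
    keep_tr <- stats::complete.cases(Xtr)
    keep_te <- stats::complete.cases(Xte)
    fit <- fit_cox(Xtr[keep_tr, , drop = FALSE],
                   train[[tcol]][keep_tr], train[[ecol]][keep_tr])
    lp_tr <- linear_predictor(fit, Xtr[keep_tr, , drop = FALSE])
    lp_te <- linear_predictor(fit, Xte[keep_te, , drop = FALSE])
    cls <- classify_risk(lp_tr, lp_te)
    er_te <- as.character(test$er_status)[keep_te]
    c_sub <- function(sel) {
      tryCatch(harrell_c(test[[tcol]][keep_te][sel], test[[ecol]][keep_te][sel],
                         lp_te[sel]), error = function(e) NA_real_)
    }
    list(c = harrell_c(test[[tcol]][keep_te], test[[ecol]][keep_te], lp_te),
         n_low = sum(cls == "low"), n_high = sum(cls == "high"),
         c_erpos = c_sub(er_te == "+"), c_erneg = c_sub(er_te == "-"),
         km = if (keep_km) {
           lapply(c(low = "low", high = "high"), function(cl) {
             sel <- cls == cl
             if (sum(sel) && sum(test[[ecol]][keep_te][sel]) > 0) {
               .km_curve(test[[tcol]][keep_te][sel], test[[ecol]][keep_te][sel])
             } else NULL
           })
         } else NULL)
  }

  models <- c("genes", "clinical", "combined")
  rows <- vector("list", n_splits)
  km_rows <- list()
  n_failed <- 0L
  for (i in seq_len(n_splits)) {
    res <- NULL
    for (attempt in 1:2) {
      sd_i <- if (attempt == 1) child_seed(master_seed, 21L, i) else child_seed(master_seed, 22L, i)
      res <- tryCatch({
        sp <- stratified_split(cc, train_fraction = train_fraction,
                               strata = "stage", seed = sd_i)
        Xg_tr <- expression_matrix(sp$train, gene_set)
        Xg_te <- expression_matrix(sp$test, gene_set)
        Xc_tr <- .clinical_design(sp$train, clinical_vars)
        Xc_te <- .clinical_design(sp$test, clinical_vars)
        out <- list(
          genes = one_model(sp$train, sp$test, Xg_tr, Xg_te),
          clinical = if (is.null(Xc_tr)) NULL else one_model(sp$train, sp$test, Xc_tr, Xc_te),
          combined = if (is.null(Xc_tr)) NULL else
            one_model(sp$train, sp$test, cbind(Xg_tr, Xc_tr), cbind(Xg_te, Xc_te)))
        if (is.null(out$clinical)) out$clinical <- out$genes
        if (is.null(out$combined)) out$combined <- out$genes
        out
      }, error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    row <- list(split = i)
    for (m in models) {
      row[[paste0("c_", m)]] <- res[[m]]$c
      row[[paste0("n_low_", m)]] <- res[[m]]$n_low
      row[[paste0("n_high_", m)]] <- res[[m]]$n_high
      row[[paste0("c_erpos_", m)]] <- res[[m]]$c_erpos
      row[[paste0("c_erneg_", m)]] <- res[[m]]$c_erneg
      if (keep_km && !is.null(res[[m]]$km)) {
        for (cl in c("low", "high")) {
          cv <- res[[m]]$km[[cl]]
          if (!is.null(cv) && nrow(cv)) {
            km_rows[[length(km_rows) + 1L]] <-
              data.frame(split = i, model = m, class = cl,
                         time = cv$time, surv = cv$surv)
          }
        }
      }
    }
    rows[[i]] <- as.data.frame(row)
  }
  splits <- do.call(rbind, rows)
  if (is.null(splits) || !nrow(splits)) stop("all splits failed")
  if (n_failed) warning(n_failed, " split(s) failed and were dropped")

  pctl <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  summ <- list()
  for (m in models) {
    v <- splits[[paste0("c_", m)]]
    summ[[m]] <- list(median = stats::median(v), ci = pctl(v),
                      median_n_low = stats::median(splits[[paste0("n_low_", m)]]),
                      median_n_high = stats::median(splits[[paste0("n_high_", m)]]))
  }
  diffs <- list(
    genes_vs_clinical = splits$c_genes - splits$c_clinical,
    combined_vs_clinical = splits$c_combined - splits$c_clinical)
  diff_summ <- lapply(diffs, function(d) list(median = stats::median(d), ci = pctl(d)))

  structure(list(splits = splits,
                 km = if (length(km_rows)) do.call(rbind, km_rows) else NULL,
                 summary = summ, differences = diff_summ,
                 outcome = outcome, gene_set = gene_set,
                 clinical_vars = clinical_vars, n_splits = n_splits,
                 n_failed = n_failed, master_seed = as.integer(master_seed)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("Model comparison (%s), %d/%d successful splits\n",
              toupper(x$outcome), nrow(x$splits), x$n_splits))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-8s median C = %.3f (95%% CI %.3f-%.3f), median low/high = %g/%g\n",
                m, s$median, s$ci[1], s$ci[2], s$median_n_low, s$median_n_high))
  }
  for (d in names(x$differences)) {
    s <- x$differences[[d]]
    cat(sprintf("  %-22s median dC = %+.3f (95%% CI %+.3f to %+.3f)\n",
                d, s$median, s$ci[1], s$ci[2]))
  }
  invisible(x)
}

#' @export
plot.evaluation_result <- function(x, ...) {
  graphics::boxplot(x$splits[c("c_genes", "c_clinical", "c_combined")],
                    names = c("genes", "clinical", "combined"),
                    ylab = "test C-index",
                    main = sprintf("C-index over %d splits (%s)",
                                   nrow(x$splits), toupper(x$outcome)), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Test-set concordance of per-split penalized fits
#'
#' The selection pipeline's predictive read-out: for each stage-stratified
#' train/test split, the L1 penalty is tuned by cross-validation on the
#' training set, the penalized Cox model is fitted there, and the test set
#' is scored by Harrell's C on the resulting linear predictor. Applied to
#' outcome-permuted data this distribution centers on 0.5; on real data its
#' median measures the honest predictive accuracy of the selected models. A
#' fit shrunk to the empty model gives constant scores, for which every
#' comparable pair counts 1/2 (C = 0.5).
#'
#' @inheritParams selection_frequencies
#' @param train_fraction training fraction.
#' @return numeric vector of per-split test C values (failed splits NA).
#' @export
penalized_split_c <- function(cohort, outcome = c("os", "dfs"), genes = NULL,
                              n_splits = 1000L, master_seed = 1L,
                              train_fraction = 0.7, k_folds = 10L,
                              nlambda = 50L) {
  outcome <- match.arg(outcome)
  if (is.null(genes)) genes <- unclass(attr(cohort, "panel"))
  genes <- as.character(genes)
  cc <- complete_cases(cohort, outcome, quiet = TRUE)
  tcol <- paste0(outcome, "_months")
  ecol <- paste0(outcome, "_event")
  cs <- rep(NA_real_, n_splits)
  for (i in seq_len(n_splits)) {
    cs[i] <- tryCatch({
      sp <- stratified_split(cc, train_fraction = train_fraction,
                             strata = "stage",
                             seed = child_seed(master_seed, 31L, i))
      train <- sp$train
      X <- expression_matrix(train, genes)
      cv <- select_lambda_cv(X, train[[tcol]], train[[ecol]], k = k_folds,
                             lambda_seq = cox_lambda_grid(X, train[[tcol]],
                                                          train[[ecol]],
                                                          nlambda = nlambda),
                             seed = child_seed(master_seed, 32L, i))
      fit <- fit_cox_lasso(X, train[[tcol]], train[[ecol]],
                           lambda = cv$lambda_opt)
      harrell_c(sp$test[[tcol]], sp$test[[ecol]],
                linear_predictor(fit, expression_matrix(sp$test, genes)))
    }, error = function(e) NA_real_)
  }
  cs
}

#' Random gene-set comparator
#'
#' Per split, draws `k` panel genes uniformly (a fresh draw each split), fits
#' an unpenalized Cox model on the training set and scores the test set by
#' Harrell's C — the reference distribution against which a fixed signature
#' of the same size is judged. Splits use the same seed stream as
#' [compare_models()], so per-split values pair with a signature run at the
#' same master seed.
#'
#' @inheritParams compare_models
#' @param k number of genes per draw.
#' @return numeric vector of per-split test C values (attribute `gene_sets`
#'   lists the drawn sets).
#' @export
random_gene_comparator <- function(cohort, outcome = c("os", "dfs"), k,
                                   n_splits = 1000L, master_seed = 1L,
                                   train_fraction = 0.7) {
  outcome <- match.arg(outcome)
  panel <- unclass(attr(cohort, "panel"))
  if (k > length(panel)) stop("k exceeds panel size")
  cc <- complete_cases(cohort, outcome, quiet = TRUE)
  tcol <- paste0(outcome, "_months")
  ecol <- paste0(outcome, "_event")
  cs <- numeric(n_splits)
  sets <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    set.seed(child_seed(master_seed, 23L, i))
    gset <- if (k == length(panel)) panel else sample(panel, k)
    sets[[i]] <- gset
    cs[i] <- tryCatch({
      sp <- stratified_split(cc, train_fraction = train_fraction,
                             strata = "stage", seed = child_seed(master_seed, 21L, i))
      fit <- fit_cox(expression_matrix(sp$train, gset),
                     sp$train[[tcol]], sp$train[[ecol]])
      harrell_c(sp$test[[tcol]], sp$test[[ecol]],
                linear_predictor(fit, expression_matrix(sp$test, gset)))
    }, error = function(e) NA_real_)
  }
  structure(cs, gene_sets = sets)
}

#' Collapse array probes to gene level
#'
#' For genes measured by several probes, retains the probe with the largest
#' variance across samples (exact ties: the first probe in input order).
#' Used to prepare external microarray validation data.
#'
#' @param expr matrix, probes in rows (rownames = probe ids), samples in
#'   columns.
#' @param map named character vector probe id -> gene symbol, covering every
#'   row of `expr`.
#' @return matrix with one row per gene (rownames = gene symbols), genes in
#'   order of first appearance.
#' @export
collapse_probes <- function(expr, map) {
  expr <- as.matrix(expr)
  if (!length(map)) stop("empty probe-to-gene map")
  missing_probes <- setdiff(rownames(expr), names(map))
  if (length(missing_probes)) {
    stop("probes not covered by map: ", paste(utils::head(missing_probes, 5), collapse = ", "))
  }
  genes <- unname(map[rownames(expr)])
  v <- apply(expr, 1, stats::var)
  keep <- vapply(unique(genes), function(g) {
    idx <- which(genes == g)
    idx[which.max(v[idx])]
  }, integer(1))
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- unique(genes)
  out
}
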